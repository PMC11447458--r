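# Lexicographic global alignment: maximise score (match +1, mismatch -1,
# linear gap -2), then matches among co-optimal alignments. Both objectives
# are additive per alignment column, so a single DP over the combined value
# score*SCALE + matches is exact when SCALE exceeds the maximum match count.
.NW_SCALE <- 65536

.nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  la <- length(ca); lb <- length(cb)
  genc <- gap * .NW_SCALE
  menc <- match * .NW_SCALE + 1
  xenc <- mismatch * .NW_SCALE
  prev <- genc * (0:lb)                     # row i = 0
  jj <- seq_len(lb)
  for (i in seq_len(la)) {
    sub <- ifelse(cb == ca[i], menc, xenc)
    t <- pmax(prev[jj] + sub, prev[jj + 1L] + genc)  # diag, up
    c0 <- prev[1L] + genc
    u <- c(c0, t - jj * genc)
    cur <- cummax(u)[jj + 1L] + jj * genc            # left-gap closure
    prev <- c(c0, cur)
  }
  val <- prev[lb + 1L]
  k <- val %% .NW_SCALE                      # matches
  score <- (val - k) / .NW_SCALE
  m <- (score + 2 * (la + lb) - 5 * k) / 3   # mismatches (from the two
  cols <- la + lb - k - m                    # conservation identities)
  list(score = score, matches = k, mismatches = m, columns = cols)
}

#' Percent identity from global alignment
#'
#' Aligns two sequences end-to-end with match +1, mismatch -1, linear gap
#' -2, and reports `100 * matches / alignment columns`. Among co-optimal
#' alignments the one with the most matched columns is used, making the
#' value well defined. Gap columns count against identity, so
#' `pairwise_identity(a, a)` is 100 and indels penalise both sequences
#' symmetrically.
#'
#' @param a,b [seq_record()]s or non-empty DNA strings.
#' @param match,mismatch,gap Scoring parameters (linear gaps).
#' @return Identity percentage, rounded to 0.1.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 75.0
#' pairwise_identity("ACGT", "ACG")   # 75.0 (one gap column)
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  sa <- as_seq(a, "a"); sb <- as_seq(b, "b")
  if (nchar(sa) == 0L || nchar(sb) == 0L) .stop("sequences must be non-empty")
  aln <- .nw_align(sa, sb, match, mismatch, gap)
  round(100 * aln$matches / aln$columns, 1)
}

#' Hamming distance between equal-length sequences
#'
#' Used for promoter comparison, where the 19-nt RNA polymerase I promoter
#' motifs of related species are compared position by position.
#'
#' @param a,b [seq_record()]s or DNA strings of equal length.
#' @return Integer number of differing positions.
#' @export
promoter_distance <- function(a, b) {
  sa <- as_seq(a, "a"); sb <- as_seq(b, "b")
  if (nchar(sa) == 0L) .stop("sequences must be non-empty")
  if (nchar(sa) != nchar(sb))
    .stop("sequences differ in length (%d vs %d); use pairwise_identity() for unequal lengths",
          nchar(sa), nchar(sb))
  sum(seq_chars(sa) != seq_chars(sb))
}

.region_seq <- function(unit, features, type) {
  f <- get_feature(features, type)
  substr(as_seq(unit), f$start + 1L, f$end)
}

#' Build a cross-unit comparison report
#'
#' Assembles the standard two-unit comparison: per-region lengths, length
#' deltas (`length_b - length_a`), per-region GC, global-alignment
#' identities for the three rRNA genes, promoter Hamming distance (when
#' both units carry a PROMOTER feature of equal length), and CpG-island
#' coverage of each unit.
#'
#' @param unit_a,unit_b [seq_record()]s.
#' @param features_a,features_b [feature_table()]s carrying the full
#'   canonical region annotation (all eight regions; an absent region is an
#'   error naming it).
#' @param genes Region types treated as genes for identity rows.
#' @return An object of class `rdna_comparison` with data frame fields
#'   `regions`, `genes`, scalar `promoter_mismatches` (NA when either
#'   promoter is missing) and `cpg_coverage` (named length-2 vector).
#' @export
build_report <- function(unit_a, features_a, unit_b, features_b,
                         genes = c("R18S", "R5_8S", "R28S")) {
  sa <- as_seq(unit_a, "unit_a"); sb <- as_seq(unit_b, "unit_b")
  for (side in list(list(features_a, "a"), list(features_b, "b"))) {
    missing <- setdiff(REGION_ORDER, side[[1L]]$type)
    if (length(missing))
      .stop("unit %s lacks canonical region(s): %s", side[[2L]],
            paste(missing, collapse = ", "))
  }
  row1 <- function(type) {
    qa <- .region_seq(sa, features_a, type)
    qb <- .region_seq(sb, features_b, type)
    data.frame(region = type, length_a = nchar(qa), length_b = nchar(qb),
               delta_length = nchar(qb) - nchar(qa),
               gc_a = gc_content(qa), gc_b = gc_content(qb))
  }
  regions <- do.call(rbind, lapply(REGION_ORDER, row1))
  gene_rows <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g,
               identity = pairwise_identity(.region_seq(sa, features_a, g),
                                            .region_seq(sb, features_b, g)))))
  pm <- NA_integer_
  if (sum(features_a$type == "PROMOTER") == 1L &&
      sum(features_b$type == "PROMOTER") == 1L) {
    pa <- .region_seq(sa, features_a, "PROMOTER")
    pb <- .region_seq(sb, features_b, "PROMOTER")
    if (nchar(pa) == nchar(pb)) pm <- promoter_distance(pa, pb)
  }
  cov <- c(a = cpg_island_coverage(cpg_islands(sa), nchar(sa)),
           b = cpg_island_coverage(cpg_islands(sb), nchar(sb)))
  structure(list(regions = regions, genes = gene_rows,
                 promoter_mismatches = pm, cpg_coverage = cov,
                 scoring = "global alignment, match +1 / mismatch -1 / gap -2; identity = matches / alignment columns"),
            class = "rdna_comparison")
}

#' @export
print.rdna_comparison <- function(x, ...) {
  cat("rDNA unit comparison\n")
  cat(sprintf("  scoring: %s\n\n", x$scoring))
  print(x$regions, row.names = FALSE)
  cat("\n")
  print(x$genes, row.names = FALSE)
  cat(sprintf("\n  promoter mismatches: %s\n",
              ifelse(is.na(x$promoter_mismatches), "not comparable",
                     x$promoter_mismatches)))
  cat(sprintf("  CpG island coverage: a %.1f%%, b %.1f%%\n",
              x$cpg_coverage[["a"]], x$cpg_coverage[["b"]]))
  invisible(x)
}

#' Render a comparison report to TSV (and optionally Markdown)
#'
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param report An `rdna_comparison`.
#' @param path Output TSV path.
#' @param markdown_path Optional companion Markdown path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, markdown_path = NULL) {
  stopifnot(inherits(report, "rdna_comparison"))
  con <- file(path, "w")
  fmt1 <- function(x) formatC(x, format = "f", digits = 1)
  writeLines(sprintf("# %s", report$scoring), con)
  writeLines("section\tregion\tlength_a\tlength_b\tdelta_length\tgc_a\tgc_b", con)
  r <- report$regions
  writeLines(sprintf("region\t%s\t%d\t%d\t%d\t%s\t%s", r$region, r$length_a,
                     r$length_b, r$delta_length, fmt1(r$gc_a), fmt1(r$gc_b)), con)
  g <- report$genes
  writeLines(sprintf("gene_identity\t%s\t\t\t\t%s\t", g$gene, fmt1(g$identity)), con)
  writeLines(sprintf("promoter_mismatches\t\t\t\t%s\t\t",
                     ifelse(is.na(report$promoter_mismatches), "NA",
                            report$promoter_mismatches)), con)
  writeLines(sprintf("cpg_coverage\t\t\t\t\t%s\t%s",
                     fmt1(report$cpg_coverage[["a"]]),
                     fmt1(report$cpg_coverage[["b"]])), con)
  close(con)
  if (!is.null(markdown_path)) {
    md <- c("# rDNA unit comparison", "",
            sprintf("Scoring: %s", report$scoring), "",
            "| region | length_a | length_b | delta | gc_a | gc_b |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %d | %d | %d | %s | %s |", r$region, r$length_a,
                    r$length_b, r$delta_length, fmt1(r$gc_a), fmt1(r$gc_b)),
            "", "| gene | identity |", "|---|---|",
            sprintf("| %s | %s |", g$gene, fmt1(g$identity)))
    writeLines(md, markdown_path)
  }
  invisible(path)
}
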