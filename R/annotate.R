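#' Terminator search parameters
#'
#' The Pol I transcription terminator is searched as a poly-T run followed,
#' within a short gap, by an inverted repeat (an arm whose reverse
#' complement recurs a short spacer downstream). Defaults are deliberately
#' permissive and are recorded in the returned feature's attributes.
#'
#' @param min_t_run Minimum length of the T-run.
#' @param max_gap Maximum bases between T-run end and the first arm.
#' @param min_arm Minimum arm length of the inverted repeat.
#' @param max_spacer Maximum bases between the arms.
#' @param search_window How far past the 28S 3' end to scan.
#' @return A list of class `terminator_params`.
#' @export
terminator_params <- function(min_t_run = 5L, max_gap = 30L, min_arm = 6L,
                              max_spacer = 20L, search_window = 800L) {
  p <- lapply(list(min_t_run = min_t_run, max_gap = max_gap, min_arm = min_arm,
                   max_spacer = max_spacer, search_window = search_window),
              as.integer)
  if (any(unlist(p) <= 0L)) .stop("terminator parameters must be positive")
  structure(p, class = "terminator_params")
}

# Map a 1-based pattern position through a local alignment to a 1-based
# subject position, extrapolating linearly outside the aligned block.
.map_through_alignment <- function(aln, pat_pos) {
  p0 <- Biostrings::start(Biostrings::pattern(aln))
  p1 <- Biostrings::end(Biostrings::pattern(aln))
  s0 <- Biostrings::start(Biostrings::subject(aln))
  s1 <- Biostrings::end(Biostrings::subject(aln))
  if (pat_pos < p0) return(s0 - (p0 - pat_pos))
  if (pat_pos > p1) return(s1 + (pat_pos - p1))
  ap <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  as <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  pi <- p0 - 1L; si <- s0 - 1L
  for (col in seq_along(ap)) {
    if (ap[col] != "-") pi <- pi + 1L
    if (as[col] != "-") si <- si + 1L
    if (pi == pat_pos && ap[col] != "-") return(max(si, s0))
  }
  s1
}

#' Transfer gene/spacer boundaries from an annotated reference unit
#'
#' For each internal boundary of the reference's canonical region layout, a
#' 40-bp reference anchor centred on the boundary is locally aligned to the
#' target ([Biostrings::pairwiseAlignment], match +1 / mismatch -1 / gap
#' -2); the boundary maps to the target position aligned with the anchor's
#' centre. Anchors matching fewer than `min_identity` of their bases are
#' flagged `UNMAPPED` (on both adjacent regions) and their coordinate is
#' interpolated between the nearest mapped boundaries at the reference's
#' relative spacing.
#'
#' @param target A [seq_record()]: the unit to annotate.
#' @param ref_record A [seq_record()]: the annotated reference unit.
#' @param ref_features [feature_table()] with the reference's eight
#'   canonical regions.
#' @param anchor Anchor length in bp.
#' @param min_identity Minimum fraction of anchor bases matched.
#' @return A [feature_table()] with the eight canonical regions on the
#'   target; each feature's attributes record the anchor identities of its
#'   boundaries.
#' @export
transfer_boundaries <- function(target, ref_record, ref_features,
                                anchor = 40L, min_identity = 0.6) {
  tseq <- as_seq(target, "target")
  rseq <- as_seq(ref_record, "reference")
  if (nchar(tseq) == 0L || nchar(rseq) == 0L) .stop("empty sequence")
  reg <- ref_features[ref_features$type %in% REGION_ORDER, , drop = FALSE]
  missing <- setdiff(REGION_ORDER, reg$type)
  if (length(missing))
    .stop("reference lacks canonical region(s): %s", paste(missing, collapse = ", "))
  reg <- reg[match(REGION_ORDER, reg$type), , drop = FALSE]
  gene_len <- min(reg$end - reg$start)
  if (nchar(tseq) < gene_len)
    .stop("target (%d bp) shorter than the shortest reference region (%d bp)",
          nchar(tseq), gene_len)
  bounds_ref <- reg$start[-1L]             # 7 internal boundaries, 0-based
  half <- anchor %/% 2L
  tdna <- Biostrings::DNAString(tseq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  mapped <- rep(NA_integer_, length(bounds_ref))
  ident <- numeric(length(bounds_ref))
  for (i in seq_along(bounds_ref)) {
    b <- bounds_ref[i]
    a0 <- max(0L, b - half); a1 <- min(nchar(rseq), b + half)
    anch <- substr(rseq, a0 + 1L, a1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(anch), tdna, type = "local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    ident[i] <- Biostrings::nmatch(aln) / nchar(anch)
    if (ident[i] >= min_identity)
      mapped[i] <- .map_through_alignment(aln, b - a0) # centre, 1-based = b-a0
  }
  # interpolate unmapped boundaries between nearest mapped neighbours,
  # scaled by reference spacing; ends of the unit act as mapped anchors
  ref_pts <- c(0L, bounds_ref, nchar(rseq))
  tgt_pts <- c(0L, mapped, nchar(tseq))
  for (i in which(is.na(tgt_pts))) {
    lo <- max(which(!is.na(tgt_pts[seq_len(i - 1L)])))
    hi <- i + min(which(!is.na(tgt_pts[(i + 1L):length(tgt_pts)])))
    fr <- (ref_pts[i] - ref_pts[lo]) / (ref_pts[hi] - ref_pts[lo])
    tgt_pts[i] <- round(tgt_pts[lo] + fr * (tgt_pts[hi] - tgt_pts[lo]))
  }
  if (is.unsorted(tgt_pts, strictly = TRUE))
    .stop("transferred boundaries are not in canonical order; reference and target disagree structurally")
  status <- ifelse(is.na(mapped), "UNMAPPED", "mapped")
  attrs <- lapply(seq_along(REGION_ORDER), function(j) {
    a <- character()
    if (j > 1L) {
      a["start_status"] <- status[j - 1L]
      a["start_anchor_identity"] <- sprintf("%.3f", ident[j - 1L])
    }
    if (j < length(REGION_ORDER)) {
      a["end_status"] <- status[j]
      a["end_anchor_identity"] <- sprintf("%.3f", ident[j])
    }
    a
  })
  validate_features(
    feature_table(type = REGION_ORDER, start = tgt_pts[-length(tgt_pts)],
                  end = tgt_pts[-1L], attributes = attrs),
    nchar(tseq))
}

#' Call the transcription start site from a coverage track
#'
#' The plateau depth is the median of the top decile of per-base depths;
#' the TSS is the smallest position at which depth stays at or above
#' `frac * plateau` for `sustain` consecutive bases — a reproducible
#' formalisation of reading the RNA-seq coverage onset off a browser track.
#'
#' @param track A [coverage_track()] with at least one positive value.
#' @param frac Fraction of the plateau that counts as "on".
#' @param sustain Number of consecutive qualifying bases required.
#' @return 0-based TSS position.
#' @export
find_tss <- function(track, frac = 0.1, sustain = 50L) {
  stopifnot(inherits(track, "coverage_track"))
  d <- track$depth
  if (all(d == 0)) .stop("no signal: coverage track is all zero")
  sustain <- as.integer(sustain)
  if (sustain < 1L || sustain > length(d)) .stop("invalid sustain")
  top <- sort(d, decreasing = TRUE)[seq_len(max(1L, ceiling(length(d) / 10)))]
  thr <- frac * median(top)
  ok <- d >= thr
  run <- cumsum(ok)
  # positions p (1-based) where [p, p+sustain-1] is all TRUE
  lag <- c(0, head(run, -1L))[seq_len(length(d) - sustain + 1L)]
  full <- run[sustain:length(d)] - lag == sustain
  if (!any(full)) .stop("no signal: no sustained coverage above threshold")
  which(full)[1L] - 1L
}

#' Locate the transcription terminator
#'
#' Scans downstream of the 28S 3' end for the first poly-T run followed
#' within `max_gap` bases by an inverted repeat: an arm of `min_arm` bases
#' whose reverse complement recurs within `max_spacer` bases downstream.
#' The 5'-most qualifying site wins; the feature spans T-run start to the
#' end of the second arm.
#'
#' @param unit A [seq_record()].
#' @param end_of_28S 0-based position just past the 28S gene.
#' @param params A [terminator_params()].
#' @return A one-row [feature_table()] of type `TERMINATOR`; attributes
#'   record the parameters and the arm sequence.
#' @export
find_terminator <- function(unit, end_of_28S, params = terminator_params()) {
  s <- as_seq(unit)
  stopifnot(inherits(params, "terminator_params"))
  end_of_28S <- as.integer(end_of_28S)
  if (end_of_28S < 0L || end_of_28S >= nchar(s)) .stop("end_of_28S outside unit")
  w0 <- end_of_28S + 1L                           # 1-based window start
  w1 <- min(nchar(s), end_of_28S + params$search_window)
  win <- substr(s, w0, w1)
  truns <- gregexpr(sprintf("T{%d,}", params$min_t_run), win)[[1L]]
  if (truns[1L] == -1L)
    .stop("no terminator in window [%d, %d): no T-run of >= %d",
          end_of_28S, end_of_28S + params$search_window, params$min_t_run)
  tlens <- attr(truns, "match.length")
  for (ti in seq_along(truns)) {
    t_end <- truns[ti] + tlens[ti] - 1L           # within window, 1-based
    for (a0 in t_end + seq_len(params$max_gap)) { # first arm start
      if (a0 + params$min_arm - 1L > nchar(win)) break
      arm <- substr(win, a0, a0 + params$min_arm - 1L)
      if (grepl("N", arm, fixed = TRUE)) next
      rc <- revcomp(arm)
      rest0 <- a0 + params$min_arm                # search space for arm 2
      rest1 <- min(nchar(win),
                   rest0 + params$max_spacer + params$min_arm - 1L)
      if (rest1 - rest0 + 1L < params$min_arm) next
      hit <- regexpr(rc, substr(win, rest0, rest1), fixed = TRUE)
      if (hit != -1L) {
        start0 <- w0 + truns[ti] - 2L             # 0-based T-run start
        end0 <- w0 + (rest0 + hit - 1L + params$min_arm - 1L) - 1L
        att <- c(arm = arm, t_run = as.character(tlens[ti]),
                 spacer = as.character(hit - 1L),
                 min_t_run = as.character(params$min_t_run),
                 min_arm = as.character(params$min_arm))
        return(feature_table("TERMINATOR", start0, end0, list(att)))
      }
    }
  }
  .stop("no terminator in window [%d, %d): no inverted repeat after a T-run",
        end_of_28S, end_of_28S + params$search_window)
}

#' Locate the Pol I promoter motif
#'
#' Reports every window position at which the motif matches the unit with
#' at most `max_mismatch` substitutions (Hamming distance; sense strand
#' only).
#'
#' @param unit A [seq_record()] or DNA string.
#' @param motif A [seq_record()] or DNA string (non-empty).
#' @param max_mismatch Maximum substitutions allowed.
#' @param window 0-based half-open interval `c(start, end)` to scan, or
#'   `NULL` for the whole unit.
#' @return Data frame `position` (0-based), `mismatches`, ascending by
#'   mismatches then position.
#' @export
locate_promoter <- function(unit, motif, max_mismatch = 4L, window = NULL) {
  s <- as_seq(unit)
  m <- as_seq(motif, "motif")
  if (nchar(m) == 0L) .stop("empty motif")
  if (is.null(window)) window <- c(0L, nchar(s))
  w0 <- as.integer(window[1L]); w1 <- as.integer(window[2L])
  if (w0 < 0L || w1 > nchar(s) || w1 - w0 < nchar(m))
    .stop("window invalid or shorter than the motif")
  win <- seq_chars(substr(s, w0 + 1L, w1))
  mc <- seq_chars(m)
  L <- length(win); k <- length(mc)
  n_pos <- L - k + 1L
  mism <- integer(n_pos)
  for (j in seq_len(k)) mism <- mism + (win[j:(j + n_pos - 1L)] != mc[j])
  keep <- which(mism <= max_mismatch)
  out <- data.frame(position = w0 + keep - 1L, mismatches = mism[keep])
  out[order(out$mismatches, out$position), , drop = FALSE]
}

#' Annotate a unit end to end
#'
#' Convenience wrapper chaining [transfer_boundaries()], [find_tss()],
#' [find_terminator()] and [locate_promoter()] into one feature table.
#'
#' @param unit Target [seq_record()].
#' @param ref_record,ref_features Annotated reference unit.
#' @param track Optional [coverage_track()] for TSS calling.
#' @param promoter_motif Optional motif to place (searched in the last
#'   `promoter_window` bases of the unit, where the Pol I promoter sits 5'
#'   of the next repeat's start).
#' @param promoter_window,max_mismatch Promoter search controls.
#' @param terminator A [terminator_params()].
#' @return A [feature_table()] with regions plus TSS/TERMINATOR/PROMOTER
#'   where determinable.
#' @export
annotate_unit <- function(unit, ref_record, ref_features, track = NULL,
                          promoter_motif = NULL, promoter_window = 200L,
                          max_mismatch = 4L,
                          terminator = terminator_params()) {
  feats <- transfer_boundaries(unit, ref_record, ref_features)
  extra <- feature_table()
  if (!is.null(track)) {
    tss <- find_tss(track)
    extra <- rbind(extra, feature_table("TSS", tss, tss + 1L))
  }
  r28 <- get_feature(feats, "R28S")
  term <- tryCatch(find_terminator(unit, r28$end, terminator),
                   error = function(e) NULL)
  if (!is.null(term)) extra <- rbind(extra, term)
  if (!is.null(motif <- promoter_motif)) {
    L <- nchar(as_seq(unit))
    hits <- locate_promoter(unit, motif, max_mismatch,
                            window = c(max(0L, L - promoter_window), L))
    if (nrow(hits)) {
      p <- hits$position[1L]
      extra <- rbind(extra, feature_table(
        "PROMOTER", p, p + nchar(as_seq(motif, "motif")),
        list(c(mismatches = as.character(hits$mismatches[1L])))))
    }
  }
  out <- rbind(feats, extra)
  rownames(out) <- NULL
  out
}
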