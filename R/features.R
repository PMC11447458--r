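#' GC content of a sequence
#'
#' @param seq A [seq_record()] or DNA string; must be non-empty and `N`-free
#'   (composition statistics are undefined over ambiguous bases).
#' @return Percentage of `G`+`C` bases, rounded to 0.1.
#' @examples
#' gc_content("TTGCTCCGCAGGAGCGAGC")  # 68.4
#' @export
gc_content <- function(seq) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence", allow_n = FALSE)
  n_gc <- nchar(gsub("[AT]", "", s))
  round(100 * n_gc / nchar(s), 1)
}

# Cumulative counts used for O(1) window statistics: G, C, and overlapping
# CG dinucleotides (the dinucleotide count is attributed to its first base).
.comp_cumsums <- function(chars) {
  n <- length(chars)
  cg <- if (n >= 2L) c(chars[-n] == "C" & chars[-1L] == "G", FALSE) else
    rep(FALSE, n)
  list(G = cumsum(chars == "G"), C = cumsum(chars == "C"), CG = cumsum(cg))
}

# Interval stats on 1-based [i, j] inclusive. CpG count includes every CG
# whose first base lies in [i, j-1].
.island_stats <- function(cs, i, j) {
  len <- j - i + 1L
  nG <- cs$G[j] - if (i > 1L) cs$G[i - 1L] else 0L
  nC <- cs$C[j] - if (i > 1L) cs$C[i - 1L] else 0L
  nCG <- (if (j > 1L) cs$CG[j - 1L] else 0L) - (if (i > 1L) cs$CG[i - 1L] else 0L)
  gc <- (nG + nC) / len
  oe <- if (nC > 0L && nG > 0L) (nCG * len) / (nC * nG) else 0
  list(len = len, gc = gc, oe = oe, nG = nG, nC = nC, nCG = nCG)
}

# Longest (ties: leftmost) substring of [lo, hi] satisfying the island
# criteria, searched exactly; vectorised over end positions per start. A
# qualifying whole interval short-circuits the scan (it is the longest).
.longest_qualifying <- function(cs, lo, hi, min_len, min_gc, min_oe) {
  whole <- .island_stats(cs, lo, hi)
  if (whole$len >= min_len && whole$gc > min_gc && whole$oe > min_oe)
    return(list(i = lo, j = hi, len = whole$len))
  best <- NULL
  js <- lo:hi
  idxG <- cs$G[js]; idxC <- cs$C[js]
  idxCG <- cs$CG[pmax(js - 1L, 1L)]; idxCG[js == 1L] <- 0L
  for (i in lo:(hi - min_len + 1L)) {
    if (!is.null(best) && (hi - i + 1L) <= best$len) break
    jmin <- i + min_len - 1L
    sel <- (jmin - lo + 1L):(hi - lo + 1L)
    j <- js[sel]
    len <- j - i + 1L
    g0 <- if (i > 1L) cs$G[i - 1L] else 0L
    c0 <- if (i > 1L) cs$C[i - 1L] else 0L
    cg0 <- if (i > 1L) cs$CG[i - 1L] else 0L
    nG <- idxG[sel] - g0; nC <- idxC[sel] - c0; nCG <- idxCG[sel] - cg0
    ok <- (nG + nC) / len > min_gc &
      nG > 0L & nC > 0L & (nCG * len) > min_oe * (nC * nG)
    if (any(ok)) {
      jbest <- j[ok][which.max(len[ok])]
      cand_len <- jbest - i + 1L
      if (is.null(best) || cand_len > best$len)
        best <- list(i = i, j = jbest, len = cand_len)
    }
  }
  best
}

#' Detect CpG islands
#'
#' A CpG island is any stretch longer than 200 bp with GC content above 50%
#' and an observed/expected CpG dinucleotide ratio above 0.6, where
#' `oe = (N_CpG * L) / (N_C * N_G)` over the stretch. The search slides
#' 200-bp windows (step 1), merges overlapping qualifying windows into
#' candidate neighbourhoods, and within each neighbourhood selects maximal
#' qualifying stretches exactly (longest first, leftmost on ties,
#' non-overlapping). Candidate neighbourhoods longer than 6 kb are first
#' tested whole (GC-rich sequence is typically one island); only if the
#' whole interval fails does the exact search run on its halves.
#'
#' @param seq A [seq_record()] or `N`-free DNA string.
#' @param min_len Minimum island length in bp (criterion is `> 200`, so 201).
#' @param min_gc GC fraction threshold (exclusive).
#' @param min_oe Observed/expected CpG ratio threshold (exclusive).
#' @return A data frame with columns `start`, `end` (0-based half-open),
#'   `length`, `gc_frac`, `oe_ratio`, sorted by `start`.
#' @export
cpg_islands <- function(seq, min_len = 201L, min_gc = 0.5, min_oe = 0.6) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence", allow_n = FALSE)
  if (min_len < 2L || min_gc <= 0 || min_gc >= 1 || min_oe <= 0)
    .stop("island parameters out of range")
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_frac = numeric(), oe_ratio = numeric())
  n <- nchar(s)
  if (n < min_len) return(empty)
  chars <- seq_chars(s)
  cs <- .comp_cumsums(chars)
  out <- list()
  search <- function(lo, hi) {
    if (hi - lo + 1L < min_len) return()
    if (hi - lo + 1L > 6000L) {
      st <- .island_stats(cs, lo, hi)
      if (st$gc > min_gc && st$oe > min_oe) {
        out[[length(out) + 1L]] <<- c(lo, hi)
        return()
      }
      mid <- (lo + hi) %/% 2L
      search(lo, mid); search(mid + 1L, hi)
      return()
    }
    best <- .longest_qualifying(cs, lo, hi, min_len, min_gc, min_oe)
    if (is.null(best)) return()
    out[[length(out) + 1L]] <<- c(best$i, best$j)
    search(lo, best$i - 1L)
    search(best$j + 1L, hi)
  }
  if (n <= 6000L) {
    search(1L, n)
  } else {
    # long input: a step-1 scan of 200-bp windows locates candidate
    # neighbourhoods, which are then searched exactly
    w <- 200L
    starts <- 1L:(n - w + 1L)
    ends <- starts + w - 1L
    nG <- cs$G[ends] - c(0L, cs$G[starts[-1L] - 1L])
    nC <- cs$C[ends] - c(0L, cs$C[starts[-1L] - 1L])
    nCG <- cs$CG[ends - 1L] - c(0L, cs$CG[starts[-1L] - 1L])
    ok <- (nG + nC) / w > min_gc & nG > 0L & nC > 0L &
      (nCG * w) > min_oe * (nC * nG)
    if (!any(ok)) return(empty)
    r <- rle(ok)
    re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
    cand <- cbind(lo = pmax(1L, starts[rs[r$values]] - 2L * w),
                  hi = pmin(n, ends[re[r$values]] + 2L * w))
    if (nrow(cand) > 1L) {  # re-merge after expansion
      keep <- list(cand[1L, ])
      for (i in 2L:nrow(cand)) {
        last <- keep[[length(keep)]]
        if (cand[i, "lo"] <= last["hi"])
          keep[[length(keep)]]["hi"] <- cand[i, "hi"]
        else keep[[length(keep) + 1L]] <- cand[i, ]
      }
      cand <- do.call(rbind, keep)
    }
    for (k in seq_len(nrow(cand))) search(cand[k, "lo"], cand[k, "hi"])
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  st <- lapply(seq_len(nrow(m)), function(i) .island_stats(cs, m[i, 1L], m[i, 2L]))
  data.frame(start = m[, 1L] - 1L, end = m[, 2L],
             length = m[, 2L] - m[, 1L] + 1L,
             gc_frac = vapply(st, `[[`, numeric(1L), "gc"),
             oe_ratio = vapply(st, `[[`, numeric(1L), "oe"))
}

#' Fraction of a unit covered by CpG islands
#'
#' @param islands A data frame as returned by [cpg_islands()] (needs
#'   `start`/`end`), non-overlapping.
#' @param unit_length Unit length in bases.
#' @return Percentage of `unit_length` covered, rounded to 0.1.
#' @export
cpg_island_coverage <- function(islands, unit_length) {
  if (unit_length <= 0) .stop("unit_length must be positive")
  if (nrow(islands) == 0L) return(0.0)
  o <- order(islands$start)
  s <- islands$start[o]; e <- islands$end[o]
  if (any(e > unit_length) || any(s < 0)) .stop("island outside unit")
  if (any(s[-1L] < e[-length(e)])) .stop("overlapping islands")
  round(100 * sum(e - s) / unit_length, 1)
}

# TRUE iff motif is primitive (not a whole-number repetition of a shorter unit).
.is_primitive <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u %/% 2)) {
    if (u %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites
#'
#' Reports maximal perfect tandem runs of a primitive unit of `min_unit` to
#' `max_unit` bases with at least `min_copies` copies. When runs of
#' different phases describe the same bases (e.g. `ACCCG` vs `CCCGA`), every
#' phase that still reaches `min_copies` whole copies is reported, matching
#' the multi-phase cataloguing convention used for rDNA spacers. With
#' `degenerate = TRUE`, runs in which a single unit position alternates
#' between two bases are additionally reported with an IUPAC code at that
#' position.
#'
#' @param seq A [seq_record()] or DNA string.
#' @param min_unit,max_unit Repeat unit length range (homopolymers are
#'   excluded by the default `min_unit = 2`).
#' @param min_copies Minimum whole copies.
#' @param degenerate Also search single-position degenerate repeats.
#' @return Data frame with columns `kind` (`MICROSAT`), `motif`, `copies`,
#'   `start`, `end` (0-based half-open), sorted by `start` then motif length.
#' @export
find_microsatellites <- function(seq, min_unit = 2L, max_unit = 6L,
                                 min_copies = 3L, degenerate = FALSE) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence")
  if (min_unit < 1L) .stop("min_unit must be >= 1")
  if (max_unit < min_unit || min_copies < 2L)
    .stop("invalid unit range or copy number")
  chars <- seq_chars(s)
  n <- length(chars)
  hits <- list()
  for (u in min_unit:max_unit) {
    if (n < u * min_copies) next
    eq <- chars[1L:(n - u)] == chars[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u * (min_copies - 1L))) {
      reg_start <- starts[k]              # 1-based start of period-u region
      reg_len <- r$lengths[k] + u         # total bases with period u
      for (p in 0L:(min(u, reg_len) - 1L)) {
        q <- reg_start + p
        copies <- (reg_len - p) %/% u
        if (copies < min_copies) next
        motif <- paste(chars[q:(q + u - 1L)], collapse = "")
        if (!.is_primitive(motif)) next
        hits[[length(hits) + 1L]] <-
          data.frame(kind = "MICROSAT", motif = motif, copies = copies,
                     start = q - 1L, end = q - 1L + copies * u)
      }
    }
  }
  if (degenerate) hits <- c(hits, .degenerate_runs(chars, min_unit, max_unit,
                                                   min_copies))
  if (!length(hits))
    return(data.frame(kind = character(), motif = character(),
                      copies = integer(), start = integer(), end = integer()))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[c("motif", "start", "end")]), , drop = FALSE]
  out <- out[order(out$start, nchar(out$motif), out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# Degenerate tandem runs: period u except at one residue class of positions,
# where the bases take exactly two values (one IUPAC position per unit).
# Every phase inside a tolerant run is tried, as for perfect repeats.
.degenerate_runs <- function(chars, min_unit, max_unit, min_copies) {
  n <- length(chars)
  hits <- list()
  for (u in max(2L, min_unit):max_unit) {
    if (n < u * min_copies) next
    eq <- chars[1L:(n - u)] == chars[(u + 1L):n]
    for (cls in 0L:(u - 1L)) {
      pos <- 1L:(n - u)
      eqc <- eq | ((pos - 1L) %% u == cls)
      r <- rle(eqc)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= u * (min_copies - 1L))) {
        q <- starts[k]
        reg_len <- r$lengths[k] + u
        for (p in 0L:(min(u, reg_len) - 1L)) {
          copies <- (reg_len - p) %/% u
          if (copies < min_copies) next
          s0 <- q + p                       # 1-based phase start
          cls_rel <- (cls - (s0 - 1L)) %% u # degenerate offset within motif
          deg_idx <- s0 + cls_rel + u * (0L:(copies - 1L))
          vals <- sort(unique(chars[deg_idx]))
          if (length(vals) != 2L) next      # 1 = perfect, >2 = not one IUPAC
          motif <- chars[s0:(s0 + u - 1L)]
          motif[cls_rel + 1L] <- .IUPAC2[paste(vals, collapse = "")]
          hits[[length(hits) + 1L]] <-
            data.frame(kind = "MICROSAT_DEGENERATE",
                       motif = paste(motif, collapse = ""), copies = copies,
                       start = s0 - 1L, end = s0 - 1L + copies * u)
        }
      }
    }
  }
  hits
}

#' Count a dispersed motif and its complement
#'
#' Counts occurrences of `motif` and of its base-by-base complement (not the
#' reverse complement: the pairing convention used when cataloguing
#' dispersed "inverted" spacer repeats such as `CGG`/`GCC`). Overlapping
#' occurrences are counted by default.
#'
#' @param seq A [seq_record()] or DNA string (non-empty).
#' @param motif Non-empty motif over `A,C,G,T`.
#' @param overlapping Count overlapping occurrences.
#' @return Named integer vector `c(n_motif=, n_complement=)`.
#' @export
count_motif_and_complement <- function(seq, motif, overlapping = TRUE) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence")
  .assert_dna(motif, what = "motif", allow_n = FALSE)
  count1 <- function(m) {
    pat <- if (overlapping) sprintf("(?=%s)", m) else m
    g <- gregexpr(pat, s, perl = overlapping)[[1L]]
    if (g[1L] == -1L) 0L else length(g)
  }
  c(n_motif = count1(motif), n_complement = count1(complement_seq(motif)))
}

#' Find polypurine/polypyrimidine tracts
#'
#' Maximal runs in which every base is a purine (`A`/`G`, kind `PUR_TRACT`)
#' or every base a pyrimidine (`C`/`T`, kind `PYR_TRACT`) of at least
#' `min_len` bases. Such tracts are bendable and can adopt non-canonical
#' (H-form/triplex) structure.
#'
#' @param seq A [seq_record()] or `N`-free DNA string.
#' @param min_len Minimum tract length (>= 2).
#' @return Data frame `kind`, `motif` (the tract sequence), `copies` (1),
#'   `start`, `end`, sorted by start.
#' @export
find_pur_pyr_tracts <- function(seq, min_len = 10L) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence", allow_n = FALSE)
  if (min_len < 2L) .stop("min_len must be >= 2")
  scan1 <- function(class_re, kind) {
    g <- gregexpr(sprintf("[%s]{%d,}", class_re, min_len), s)[[1L]]
    if (g[1L] == -1L) return(NULL)
    len <- attr(g, "match.length")
    data.frame(kind = kind, motif = substring(s, g, g + len - 1L),
               copies = 1L, start = as.integer(g) - 1L,
               end = as.integer(g) + len - 1L)
  }
  out <- rbind(scan1("AG", "PUR_TRACT"), scan1("CT", "PYR_TRACT"))
  if (is.null(out))
    return(data.frame(kind = character(), motif = character(),
                      copies = integer(), start = integer(), end = integer()))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find G-quadruplex motifs
#'
#' Non-overlapping, leftmost-first matches of four G-runs of at least
#' `min_run` G's separated by three loops of `loop_min` to `loop_max`
#' arbitrary bases — the standard quadruplex-forming sequence pattern.
#'
#' @param seq A [seq_record()] or DNA string.
#' @param min_run Minimum G-run length.
#' @param loop_min,loop_max Loop length bounds.
#' @return Data frame `kind` (`G4`), `motif` (matched sequence), `copies`
#'   (1), `start`, `end`.
#' @export
find_g4_motifs <- function(seq, min_run = 3L, loop_min = 1L, loop_max = 7L) {
  s <- as_seq(seq)
  .assert_dna(s, what = "sequence")
  if (loop_min > loop_max || loop_min < 0L) .stop("invalid loop bounds")
  if (min_run < 2L) .stop("min_run must be >= 2")
  pat <- sprintf("G{%d,}(?:[ACGTN]{%d,%d}?G{%d,}){3}",
                 min_run, loop_min, loop_max, min_run)
  g <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (g[1L] == -1L)
    return(data.frame(kind = character(), motif = character(),
                      copies = integer(), start = integer(), end = integer()))
  len <- attr(g, "match.length")
  data.frame(kind = "G4", motif = substring(s, g, g + len - 1L), copies = 1L,
             start = as.integer(g) - 1L, end = as.integer(g) + len - 1L)
}
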