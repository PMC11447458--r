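#' Fishing parameters
#'
#' @param k K-mer length (5..31).
#' @param min_shared_frac Minimum containment fraction for selection.
#' @param canonical Canonicalise k-mers over reverse complement (so reads of
#'   either strand match the query).
#' @return A list of class `fish_params`.
#' @export
fish_params <- function(k = 15L, min_shared_frac = 0.10, canonical = TRUE) {
  k <- as.integer(k)
  if (k <= 4L || k >= 32L) .stop("k must satisfy 4 < k < 32")
  if (min_shared_frac <= 0 || min_shared_frac > 1)
    .stop("min_shared_frac must be in (0, 1]")
  structure(list(k = k, min_shared_frac = min_shared_frac,
                 canonical = isTRUE(canonical)), class = "fish_params")
}

# Distinct (canonical) k-mers of one sequence. K-mers containing N never
# match anything informative and are dropped.
.kmer_set <- function(seq, k, canonical) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- 1L:(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  if (canonical) {
    rc <- revcomp(seq)
    rev_km <- substring(rc, starts, starts + k - 1L)
    # k-mer starting at i pairs with the RC k-mer starting at n-k+2-i
    fwd <- pmin(fwd, rev_km[n - k + 2L - starts])
  }
  fwd <- fwd[!grepl("N", fwd, fixed = TRUE)]
  unique(fwd)
}

#' Classify reads against a conserved query by k-mer containment
#'
#' For each read, `shared_frac` is the fraction of the read's distinct
#' (canonical) k-mers that also occur in the query — a deterministic
#' containment analogue of selecting rDNA-bearing reads from a whole-genome
#' pool by similarity search against a conserved 18S-28S query. Reads at or
#' above `min_shared_frac` are returned, best first.
#'
#' @param reads List of [seq_record()] (long reads).
#' @param query A [seq_record()] or DNA string (conserved query, length >= k).
#' @param params A [fish_params()].
#' @return Data frame `read_id`, `shared_frac`, sorted by `shared_frac`
#'   descending then `read_id`; reads shorter than `k` are skipped with a
#'   warning.
#' @export
kmer_fish <- function(reads, query, params = fish_params()) {
  stopifnot(inherits(params, "fish_params"))
  q <- as_seq(query, "query")
  if (nchar(q) < params$k) .stop("query shorter than k")
  qset <- .kmer_set(q, params$k, params$canonical)
  ids <- vapply(reads, function(r) r$id, character(1L))
  short <- vapply(reads, function(r) nchar(r$seq) < params$k, logical(1L))
  if (any(short))
    warning(sprintf("skipping %d read(s) shorter than k=%d", sum(short),
                    params$k), call. = FALSE)
  frac <- vapply(reads[!short], function(r) {
    rset <- .kmer_set(r$seq, params$k, params$canonical)
    if (!length(rset)) return(0)
    sum(rset %in% qset) / length(rset)
  }, numeric(1L))
  out <- data.frame(read_id = ids[!short], shared_frac = frac,
                    stringsAsFactors = FALSE)
  out <- out[out$shared_frac >= params$min_shared_frac, , drop = FALSE]
  out <- out[order(-out$shared_frac, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a substitution-only pileup
#'
#' @param draft A [seq_record()]: the draft sequence to polish.
#' @param placements Data frame with columns `read_id`, `offset` (0-based
#'   position of the read's first base on the draft) and `seq` (read bases,
#'   already substitution-aligned to the draft: no indels).
#' @return A list of class `pileup`.
#' @export
pileup <- function(draft, placements) {
  stopifnot(inherits(draft, "seq_record"))
  req <- c("read_id", "offset", "seq")
  if (!is.data.frame(placements) || !all(req %in% names(placements)))
    .stop("placements must have columns read_id, offset, seq")
  len <- nchar(placements$seq)
  if (any(placements$offset < 0L) ||
      any(placements$offset + len > nchar(draft$seq)))
    .stop("placement outside the draft")
  structure(list(draft = draft, placements = placements), class = "pileup")
}

#' Polish a draft by pileup majority
#'
#' A stand-in for short-read-based correction of long-read drafts: at every
#' draft position covered by at least `min_depth` placed read bases, the
#' consensus is the strict majority base (more than half of the covering
#' bases). Ties, pluralities short of a majority, and under-covered
#' positions keep the draft base — edits are conservative.
#'
#' @param pile A [pileup()].
#' @param min_depth Minimum coverage to consider an edit.
#' @return List with `polished` (a [seq_record()]) and `corrected`
#'   (0-based integer positions where the draft base was changed).
#' @export
polish_consensus <- function(pile, min_depth = 3L) {
  stopifnot(inherits(pile, "pileup"))
  draft <- seq_chars(pile$draft$seq)
  L <- length(draft)
  # base-major encoding of votes: (pos-1)*4 + base
  base_code <- integer(90L)
  base_code[utf8ToInt("A")] <- 1L; base_code[utf8ToInt("C")] <- 2L
  base_code[utf8ToInt("G")] <- 3L; base_code[utf8ToInt("T")] <- 4L
  idx_all <- lapply(seq_len(nrow(pile$placements)), function(i) {
    sq <- pile$placements$seq[i]
    codes <- base_code[utf8ToInt(sq)]
    pos <- pile$placements$offset[i] + seq_len(nchar(sq))  # 1-based
    keep <- codes > 0L  # N contributes no vote
    (pos[keep] - 1L) * 4L + codes[keep]
  })
  counts <- tabulate(unlist(idx_all), nbins = 4L * L)
  m <- matrix(counts, nrow = 4L)
  cov <- colSums(m)
  top <- max.col(t(m), ties.method = "first")
  topn <- m[cbind(top, seq_len(L))]
  edit <- cov >= min_depth & topn * 2L > cov
  new <- draft
  bases <- c("A", "C", "G", "T")
  new[edit] <- bases[top[edit]]
  corrected <- which(new != draft) - 1L
  out <- draft
  out[corrected + 1L] <- new[corrected + 1L]
  list(polished = seq_record(pile$draft$id, paste(out, collapse = ""),
                             desc = pile$draft$desc),
       corrected = corrected)
}
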