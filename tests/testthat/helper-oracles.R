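# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Random DNA of length n at a GC fraction (i.i.d. per base).
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- CpG islands ----------------------------------------------------------

# All qualifying substrings (exhaustive O(n^2) enumeration over every
# (start, end) pair, using plain prefix counts), then greedy longest-first
# (leftmost on ties), non-overlapping. Use on sequences <= 2 kb.
oracle_cpg_islands <- function(seq, min_len = 201L, min_gc = 0.5,
                               min_oe = 0.6) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  pg <- c(0L, cumsum(ch == "G"))
  pc <- c(0L, cumsum(ch == "C"))
  pcg <- c(0L, 0L, cumsum(ch[-n] == "C" & ch[-1L] == "G"))
  cand <- list()
  for (i in seq_len(max(0L, n - min_len + 1L))) {
    j <- (i + min_len - 1L):n
    len <- j - i + 1L
    nG <- pg[j + 1L] - pg[i]
    nC <- pc[j + 1L] - pc[i]
    nCG <- pcg[j + 1L] - pcg[i + 1L]
    ok <- (nG + nC) / len > min_gc & nG > 0L & nC > 0L &
      (nCG * len) > min_oe * (nC * nG)
    if (any(ok))
      cand[[length(cand) + 1L]] <- cbind(i, j[ok])
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, cand)
  picked <- list()
  repeat {
    if (!nrow(m)) break
    len <- m[, 2L] - m[, 1L] + 1L
    best <- which(len == max(len))
    best <- best[which.min(m[best, 1L])]
    b <- m[best, ]
    picked[[length(picked) + 1L]] <- b
    keep <- m[, 2L] < b[1L] | m[, 1L] > b[2L]
    m <- m[keep, , drop = FALSE]
  }
  p <- do.call(rbind, picked)
  p <- p[order(p[, 1L]), , drop = FALSE]
  data.frame(start = p[, 1L] - 1L, end = p[, 2L])
}

# ---- microsatellites ------------------------------------------------------

# Test every (start, unit, copies) triple directly on the string.
oracle_microsats <- function(seq, min_unit = 2L, max_unit = 6L,
                             min_copies = 3L) {
  n <- nchar(seq)
  hits <- list()
  primitive <- function(m) {
    u <- nchar(m)
    for (d in seq_len(u %/% 2))
      if (u %% d == 0L && m == strrep(substr(m, 1L, d), u / d)) return(FALSE)
    TRUE
  }
  for (u in min_unit:max_unit) {
    for (s in 1L:(n - u * min_copies + 1L)) {
      if (s + u * min_copies - 1L > n) next
      motif <- substr(seq, s, s + u - 1L)
      if (!primitive(motif)) next
      copies <- 0L
      while (s + (copies + 1L) * u - 1L <= n &&
             substr(seq, s + copies * u, s + (copies + 1L) * u - 1L) == motif)
        copies <- copies + 1L
      if (copies < min_copies) next
      # maximal from this phase: not extendable left by a whole unit
      if (s - u >= 1L && substr(seq, s - u, s - 1L) == motif) next
      hits[[length(hits) + 1L]] <-
        data.frame(motif = motif, copies = copies, start = s - 1L,
                   end = s - 1L + copies * u)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), copies = integer(),
                      start = integer(), end = integer()))
  out <- unique(do.call(rbind, hits))
  out[order(out$start, nchar(out$motif), out$motif), , drop = FALSE]
}

# ---- motif counting -------------------------------------------------------

oracle_motif_count <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(0L)
  sum(vapply(1L:(n - k + 1L),
             function(i) substr(seq, i, i + k - 1L) == motif, logical(1L)))
}

# ---- global alignment -----------------------------------------------------

# Plain double-loop Needleman-Wunsch maximizing score then matches
# (lexicographic), with explicit matrices; returns identity as percentage.
oracle_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  la <- length(ca); lb <- length(cb)
  S <- matrix(-Inf, la + 1L, lb + 1L)  # best score
  K <- matrix(0L, la + 1L, lb + 1L)    # matches on a best-scoring path
  C <- matrix(0L, la + 1L, lb + 1L)    # columns on that path
  S[1L, ] <- gap * (0:lb); C[1L, ] <- 0:lb
  S[, 1L] <- gap * (0:la); C[, 1L] <- 0:la
  for (i in 1L:la) {
    for (j in 1L:lb) {
      hit <- ca[i] == cb[j]
      cand_s <- c(S[i, j] + if (hit) match else mismatch,
                  S[i, j + 1L] + gap, S[i + 1L, j] + gap)
      cand_k <- c(K[i, j] + hit, K[i, j + 1L], K[i + 1L, j])
      cand_c <- c(C[i, j] + 1L, C[i, j + 1L] + 1L, C[i + 1L, j] + 1L)
      best <- which(cand_s == max(cand_s))
      pick <- best[which.max(cand_k[best])]
      S[i + 1L, j + 1L] <- cand_s[pick]
      K[i + 1L, j + 1L] <- cand_k[pick]
      C[i + 1L, j + 1L] <- cand_c[pick]
    }
  }
  round(100 * K[la + 1L, lb + 1L] / C[la + 1L, lb + 1L], 1)
}
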