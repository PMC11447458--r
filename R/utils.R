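#' @importFrom methods is
#' @importFrom stats median rbinom rnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

# Canonical order of the structural regions of one rDNA repeat unit,
# promoter->terminator on the sense strand.
REGION_ORDER <- c("ETS5", "R18S", "ITS1", "R5_8S", "ITS2", "R28S", "ETS3", "IGS")

# Feature types that are not part of the tiled unit structure.
AUX_TYPES <- c("PROMOTER", "TSS", "TERMINATOR", "CPG_ISLAND", "REPEAT", "TRACT", "G4")

#' Region names of the rDNA repeat unit in canonical order
#'
#' @return Character vector `c("ETS5","R18S","ITS1","R5_8S","ITS2","R28S","ETS3","IGS")`.
#' @export
region_order <- function() REGION_ORDER

.stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string over `A,C,G,T,N`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Complement without reversal (the pairing convention used for dispersed
# motif/complement repeats, e.g. CGG <-> GCC).
complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.assert_dna <- function(seq, what = "sequence", allow_n = TRUE, allow_empty = FALSE) {
  if (!is.character(seq) || length(seq) != 1L)
    .stop("%s must be a single character string", what)
  if (!allow_empty && nchar(seq) == 0L) .stop("%s is empty", what)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nchar(bad) > 0L)
    .stop("%s contains characters outside {%s}: '%s'", what, alphabet,
          substr(bad, 1L, 10L))
  invisible(seq)
}
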