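#' Construct a sequence record
#'
#' A minimal container for one named DNA sequence (a repeat unit, a read, a
#' query, a gene). Sequences are stored uppercase over `A,C,G,T,N`; all
#' coordinates used elsewhere in the package are 0-based half-open on these
#' sequences.
#'
#' @param id Non-empty identifier.
#' @param seq DNA string; lowercase input is uppercased, whitespace stripped.
#' @param desc Optional free-text description.
#' @param allow_n Whether `N` is permitted (allowed in reads, forbidden in
#'   reference units used for composition statistics).
#' @return An object of class `seq_record` with fields `id`, `desc`, `seq`.
#' @examples
#' r <- seq_record("u1", "acgtACGT")
#' r$seq
#' @export
seq_record <- function(id, seq, desc = "", allow_n = TRUE) {
  if (!is.character(id) || length(id) != 1L || nchar(id) == 0L)
    .stop("sequence record id must be a non-empty string")
  seq <- toupper(gsub("[[:space:]]", "", seq))
  .assert_dna(seq, what = sprintf("sequence of record '%s'", id),
              allow_n = allow_n)
  structure(list(id = id, desc = desc, seq = seq), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<seq_record> %s (%d bp)%s\n  %s\n", x$id, n,
              if (nzchar(x$desc)) paste0(" ", x$desc) else "", shown))
  invisible(x)
}

# Accept a seq_record or a bare character string; return the string.
as_seq <- function(x, what = "sequence") {
  if (inherits(x, "seq_record")) return(x$seq)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  .stop("%s must be a seq_record or a single character string", what)
}

#' Build a feature table
#'
#' Features are typed, strand `+` intervals on a unit, held as a data frame
#' with 0-based half-open `start`/`end` and a list-column of named character
#' attributes. Unit-structure features (the eight canonical regions) must be
#' non-overlapping and in canonical order.
#'
#' @param type Character vector of feature types (region names or one of
#'   `PROMOTER, TSS, TERMINATOR, CPG_ISLAND, REPEAT, TRACT, G4`).
#' @param start,end Integer vectors, 0-based half-open, `start < end` (a TSS
#'   may have `end = start + 1`).
#' @param attributes List of named character vectors (one per feature), or
#'   `NULL` for none.
#' @return A `data.frame` with columns `type`, `start`, `end`, `strand`,
#'   `attributes`.
#' @export
feature_table <- function(type = character(), start = integer(),
                          end = integer(), attributes = NULL) {
  n <- length(type)
  if (length(start) != n || length(end) != n)
    .stop("type, start and end must have equal length")
  if (is.null(attributes)) attributes <- rep(list(character()), n)
  if (length(attributes) != n) .stop("attributes must have one entry per feature")
  df <- data.frame(type = as.character(type), start = as.integer(start),
                   end = as.integer(end), strand = rep("+", n),
                   stringsAsFactors = FALSE)
  df$attributes <- attributes
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Validate a feature table against a unit
#'
#' Checks coordinate bounds, `start < end`, the allowed type vocabulary, and
#' that unit-structure regions are non-overlapping and canonically ordered.
#'
#' @param features A [feature_table()].
#' @param unit_length Length of the unit in bases, or `NA` to skip the bound
#'   check.
#' @return `features`, invisibly; errors describe the first violation.
#' @export
validate_features <- function(features, unit_length = NA_integer_) {
  if (!is.data.frame(features) ||
      !all(c("type", "start", "end") %in% names(features)))
    .stop("features must be a feature_table data frame")
  allowed <- c(REGION_ORDER, AUX_TYPES)
  bad <- setdiff(unique(features$type), allowed)
  if (length(bad)) .stop("unknown feature type(s): %s", paste(bad, collapse = ", "))
  if (any(features$start < 0L)) .stop("feature start < 0")
  if (any(features$end <= features$start)) .stop("feature end <= start")
  if (!is.na(unit_length) && any(features$end > unit_length))
    .stop("feature end beyond unit length %d", unit_length)
  reg <- features[features$type %in% REGION_ORDER, , drop = FALSE]
  if (nrow(reg) > 1L) {
    ord <- match(reg$type, REGION_ORDER)
    if (is.unsorted(ord, strictly = TRUE))
      .stop("unit-structure features out of canonical order")
    if (any(reg$start[-1L] < reg$end[-nrow(reg)]))
      .stop("unit-structure features overlap")
  }
  invisible(features)
}

# Pull the single feature of a given type; error if absent/ambiguous.
get_feature <- function(features, type) {
  i <- which(features$type == type)
  if (length(i) != 1L)
    .stop("expected exactly one %s feature, found %d", type, length(i))
  features[i, , drop = FALSE]
}

#' Construct a per-base coverage track
#'
#' @param unit_id Identifier of the unit the track covers.
#' @param depth Numeric vector of non-negative depths, one per base.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(unit_id, depth) {
  if (!is.numeric(depth) || length(depth) == 0L)
    .stop("depth must be a non-empty numeric vector")
  if (any(!is.finite(depth)) || any(depth < 0))
    .stop("coverage depths must be finite and >= 0")
  structure(list(unit_id = unit_id, depth = as.numeric(depth)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bases, depth %.1f-%.1f (mean %.1f)\n",
              x$unit_id, length(x$depth), min(x$depth), max(x$depth),
              mean(x$depth)))
  invisible(x)
}
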