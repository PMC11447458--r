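#' Read a FASTA file
#'
#' Reads via [Biostrings::readBStringSet()], then enforces the package
#' alphabet: sequences are uppercased, internal whitespace stripped, and any
#' character outside `A,C,G,T,N` is a parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param allow_n Whether `N` bases are permitted.
#' @return A list of [seq_record()] in file order; an empty file gives `list()`.
#' @export
read_fasta <- function(path, allow_n = TRUE) {
  if (!file.exists(path)) .stop("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) return(list())
  first <- which(nzchar(trimws(lines)))[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    .stop("FASTA parse error at line %d of %s: expected '>' header", first, path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    .stop("FASTA parse error in %s: %s", path, conditionMessage(e)))
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  seqs <- unname(toupper(gsub("[[:space:]]", "", as.character(set))))
  bad <- which(grepl(sprintf("[^%s]", alphabet), seqs))
  if (length(bad)) {
    # locate the first offending line for the error message
    pat <- sprintf("[^%s[:space:]>]", alphabet)
    body <- !startsWith(trimws(lines), ">")
    hit <- which(body & grepl(pat, toupper(lines)))[1L]
    .stop("FASTA parse error at line %s of %s: illegal character in sequence",
          ifelse(is.na(hit), "?", hit), path)
  }
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    h <- strsplit(headers[i], "[[:space:]]+")[[1L]]
    if (length(h) == 0L || !nzchar(h[1L]))
      .stop("FASTA parse error in %s: empty header for record %d", path, i)
    seq_record(h[1L], seqs[i],
               desc = trimws(sub("^\\S+", "", headers[i])), allow_n = allow_n)
  })
}

#' Write sequence records to FASTA
#'
#' @param records A list of [seq_record()] (or a single one).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

.gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write features to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention. Unit-structure features are validated for
#' canonical order and non-overlap first. Each feature's attributes are
#' written verbatim (plus an `ID`), so a round-trip through [read_gff3()]
#' returns identical features.
#'
#' @param features A [feature_table()].
#' @param unit_id Sequence identifier for column 1.
#' @param path Output path.
#' @param unit_length Optional unit length for bound checking and the
#'   `##sequence-region` pragma.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, unit_id, path, unit_length = NA_integer_) {
  validate_features(features, unit_length)
  lines <- "##gff-version 3"
  if (!is.na(unit_length))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", unit_id, unit_length))
  if (nrow(features)) {
    attrs <- vapply(seq_len(nrow(features)), function(i) {
      a <- features$attributes[[i]]
      if (length(a)) a <- a[order(names(a))]  # stable key order for round-trip
      a <- c(ID = sprintf("%s_%03d", features$type[i], i), a)
      paste(sprintf("%s=%s", .gff3_escape(names(a)), .gff3_escape(unname(a))),
            collapse = ";")
    }, character(1L))
    lines <- c(lines, sprintf("%s\trdnaunit\t%s\t%d\t%d\t.\t+\t.\t%s",
                              unit_id, features$type, features$start + 1L,
                              features$end, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Parses with [rtracklayer::import()] and converts to the package's 0-based
#' half-open convention. The generated `ID` attribute is dropped on read so
#' that write/read is an identity on [feature_table()] contents.
#'
#' @param path Path to a GFF3 file.
#' @return A [feature_table()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) .stop("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  n <- length(gr)
  if (n == 0L) return(feature_table())
  mc <- S4Vectors::mcols(gr)
  keep <- setdiff(colnames(mc), c("source", "type", "score", "phase", "ID"))
  attrs <- lapply(seq_len(n), function(i) {
    a <- character()
    for (k in sort(keep)) {
      v <- mc[[k]][i]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      v <- as.character(v)
      if (length(v) && !is.na(v[1L])) a[k] <- paste(v, collapse = ",")
    }
    a
  })
  feature_table(type = as.character(mc$type),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                attributes = attrs)
}

#' Read a coverage track from WIG or bedGraph
#'
#' Accepts `fixedStep`/`variableStep` WIG or 4-column bedGraph (auto-detected
#' from content) and projects it onto a per-base depth vector. Positions
#' absent from the file get depth 0; any position beyond `unit_length` is a
#' parse error.
#'
#' @param path Path to the track file.
#' @param unit_length Length of the unit the track covers.
#' @param unit_id Identifier for the returned track (defaults to the
#'   sequence name in the file).
#' @return A [coverage_track()] of length `unit_length`.
#' @export
read_wig <- function(path, unit_length, unit_id = NULL) {
  if (!file.exists(path)) .stop("no such file: %s", path)
  unit_length <- as.integer(unit_length)
  body <- readLines(path, warn = FALSE)
  body <- body[nzchar(trimws(body)) & !startsWith(body, "track") &
                 !startsWith(body, "#")]
  is_wig <- any(grepl("^(fixedStep|variableStep)", body))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (is_wig) "wig" else "bedGraph"),
    error = function(e) .stop("coverage parse error in %s: %s", path,
                              conditionMessage(e)))
  depth <- numeric(unit_length)
  if (length(gr)) {
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    if (any(e > unit_length))
      .stop("coverage parse error in %s: position %d beyond unit length %d",
            path, max(e), unit_length)
    v <- as.numeric(S4Vectors::mcols(gr)$score)
    if (any(!is.finite(v)) || any(v < 0))
      .stop("coverage parse error in %s: negative or non-finite depth", path)
    for (i in seq_along(gr)) depth[s[i]:e[i]] <- v[i]
  }
  if (is.null(unit_id))
    unit_id <- if (length(gr)) as.character(GenomicRanges::seqnames(gr)[1L]) else "unit"
  coverage_track(unit_id, depth)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes the per-base depths into bedGraph intervals.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based bedGraph starts
  keep <- r$values != 0
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%g", track$unit_id, starts[keep],
                       ends[keep], r$values[keep])), path)
  invisible(path)
}
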