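#' The 19-nt RNA polymerase I promoter motif used by the default preset
#' @export
PROMOTER_MOTIF <- "TTGCTCCGCAGGAGCGAGC"

.DEFAULT_LENGTHS <- c(ETS5 = 1779L, R18S = 1823L, ITS1 = 2047L, R5_8S = 157L,
                      ITS2 = 658L, R28S = 4185L, ETS3 = 639L, IGS = 9878L)
.DEFAULT_GC <- c(ETS5 = 0.741, R18S = 0.55, ITS1 = 0.768, R5_8S = 0.55,
                 ITS2 = 0.780, R28S = 0.55, ETS3 = 0.721, IGS = 0.663)

#' Describe a planted feature
#'
#' @param kind One of `MICROSAT`, `MOTIF_DISPERSED`, `PUR_PYR_TRACT`, `G4`,
#'   `TERMINATOR`, `CPG_ISLAND`.
#' @param region Canonical region name the feature lives in.
#' @param offset 0-based offset within the region.
#' @param motif Motif (for `MICROSAT`/`MOTIF_DISPERSED`) or literal sequence
#'   (`PUR_PYR_TRACT`, `G4`, `TERMINATOR`).
#' @param copies Copy count for `MICROSAT`.
#' @param length Length for `CPG_ISLAND` (materialised stochastically).
#' @return A list of class `planted_feature`.
#' @export
planted_feature <- function(kind, region, offset, motif = NULL, copies = NULL,
                            length = NULL) {
  kinds <- c("MICROSAT", "MOTIF_DISPERSED", "PUR_PYR_TRACT", "G4",
             "TERMINATOR", "CPG_ISLAND")
  if (!kind %in% kinds) .stop("unknown planted kind '%s'", kind)
  if (!region %in% REGION_ORDER) .stop("unknown region '%s'", region)
  structure(list(kind = kind, region = region, offset = as.integer(offset),
                 motif = motif, copies = copies, length = length),
            class = "planted_feature")
}

# Materialise a planted feature into a literal DNA string.
.materialize <- function(pf) {
  switch(pf$kind,
    MICROSAT = strrep(pf$motif, pf$copies),
    MOTIF_DISPERSED = pf$motif,
    PUR_PYR_TRACT = pf$motif,
    G4 = pf$motif,
    TERMINATOR = pf$motif,
    CPG_ISLAND = NA_character_)  # stochastic, handled separately
  }

#' Specify a synthetic rDNA repeat unit
#'
#' Region lengths and per-region GC targets default to the layout of a
#' galliform rDNA repeat unit (~21 kb: transcribed block of ~11.3 kb plus a
#' 9.9 kb GC-rich IGS). The background of each region is i.i.d. bases at
#' the region's GC target; planted features overwrite the background.
#'
#' @param region_lengths Named integer vector over [region_order()].
#' @param region_gc Named numeric vector of GC fractions in (0,1).
#' @param planted List of [planted_feature()]s; they must fit inside their
#'   region and not overlap one another.
#' @param promoter_motif Promoter motif planted at the 3' end of the IGS
#'   (immediately 5' of the next repeat's transcription start).
#' @param plant_terminator Plant a default terminator (7 T's, 8-bp inverted
#'   arms, 6-bp spacer) at the 3' end of the 3'-ETS unless a `TERMINATOR`
#'   plant is supplied.
#' @param seed Integer seed making the unit deterministic.
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(region_lengths = .DEFAULT_LENGTHS,
                      region_gc = .DEFAULT_GC, planted = list(),
                      promoter_motif = PROMOTER_MOTIF,
                      plant_terminator = TRUE, seed = 1L) {
  if (!all(REGION_ORDER %in% names(region_lengths)))
    .stop("region_lengths must name all regions")
  if (!all(REGION_ORDER %in% names(region_gc)))
    .stop("region_gc must name all regions")
  region_lengths <- vapply(region_lengths[REGION_ORDER], as.integer, integer(1L))
  region_gc <- unlist(region_gc[REGION_ORDER])
  if (any(region_lengths <= 0L)) .stop("region lengths must be positive")
  if (any(region_gc <= 0 | region_gc >= 1)) .stop("gc fractions must be in (0,1)")
  for (pf in planted) {
    if (!inherits(pf, "planted_feature")) .stop("planted must be planted_feature objects")
    len <- if (pf$kind == "CPG_ISLAND") pf$length else nchar(.materialize(pf))
    if (pf$offset < 0L || pf$offset + len > region_lengths[[pf$region]])
      .stop("planted %s exceeds region %s bounds", pf$kind, pf$region)
  }
  # overlap check in unit coordinates (one guard base each side)
  starts <- cumsum(c(0L, unname(region_lengths)))[seq_along(REGION_ORDER)]
  names(starts) <- REGION_ORDER
  if (length(planted) > 1L) {
    iv <- t(vapply(planted, function(pf) {
      len <- if (pf$kind == "CPG_ISLAND") pf$length else nchar(.materialize(pf))
      c(starts[[pf$region]] + pf$offset - 1L,
        starts[[pf$region]] + pf$offset + len + 1L)
    }, numeric(2L)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      .stop("planted features overlap (guard bases included)")
  }
  structure(list(region_lengths = region_lengths, region_gc = region_gc,
                 planted = planted, promoter_motif = promoter_motif,
                 plant_terminator = isTRUE(plant_terminator),
                 seed = as.integer(seed)),
            class = "unit_spec")
}

# Background bases at a fixed GC target: exactly round(n*gc) G/C bases
# (split evenly between G and C, likewise A/T), randomly permuted. Exact
# composition keeps realised region GC at the target up to rounding and
# planted-feature overwrites; the dinucleotide structure stays exchangeable,
# so the CpG observed/expected ratio is ~1.
.bg_bases <- function(n, gc) {
  n_gc <- round(n * gc)
  n_g <- n_gc %/% 2L; n_a <- (n - n_gc) %/% 2L
  sample(c(rep("G", n_g), rep("C", n_gc - n_g),
           rep("A", n_a), rep("T", n - n_gc - n_a)))
}

# Set chars[i] (if inside the unit) to a base different from `avoid`,
# keeping the choice deterministic given the RNG state.
.guard <- function(chars, i, avoid) {
  if (i >= 1L && i <= length(chars) && chars[i] %in% avoid) {
    pool <- setdiff(c("A", "C", "G", "T"), avoid)
    chars[i] <- pool[1L + (i %% length(pool))]
  }
  chars
}

.default_terminator <- function() {
  arm <- "GCGAGCTA"
  paste0(strrep("T", 7L), arm, "CATCAC", revcomp(arm))
}

#' Generate a synthetic rDNA repeat unit with planted truth
#'
#' Deterministic for a fixed spec seed. Planted repeats are written over
#' the i.i.d. background with guard bases at their flanks (chosen so runs
#' and phases cannot extend into the background), which makes every plant
#' re-detectable at its exact recorded coordinates. Accidental T-runs long
#' enough to pre-empt the planted terminator inside its search window are
#' broken the same way.
#'
#' @param spec A [unit_spec()].
#' @return A list of class `planted_truth`: `unit` (a [seq_record()]),
#'   `features` (a [feature_table()] with the eight regions, TSS, PROMOTER,
#'   TERMINATOR and every planted repeat), and `region_starts`.
#' @export
generate_unit <- function(spec) {
  stopifnot(inherits(spec, "unit_spec"))
  lens <- spec$region_lengths
  starts <- cumsum(c(0L, unname(lens)))
  total <- starts[length(starts)]
  starts <- setNames(starts[seq_along(REGION_ORDER)], REGION_ORDER)
  with_seed(spec$seed, {
    chars <- unlist(lapply(REGION_ORDER, function(r)
      .bg_bases(lens[[r]], spec$region_gc[[r]])), use.names = FALSE)
    feats <- feature_table(REGION_ORDER, starts,
                           starts + unname(lens)[seq_along(REGION_ORDER)])
    feats <- rbind(feats, feature_table("TSS", 0L, 1L))
    planted <- spec$planted
    if (spec$plant_terminator &&
        !any(vapply(planted, function(p) p$kind == "TERMINATOR", logical(1L)))) {
      tm <- .default_terminator()
      planted <- c(planted, list(planted_feature(
        "TERMINATOR", "ETS3", lens[["ETS3"]] - nchar(tm), motif = tm)))
    }
    for (pf in planted) {
      u0 <- starts[[pf$region]] + pf$offset      # 0-based unit start
      if (pf$kind == "CPG_ISLAND") {
        isl <- .island_bases(pf$length)
        chars[(u0 + 1L):(u0 + pf$length)] <- isl
        feats <- rbind(feats, feature_table("CPG_ISLAND", u0, u0 + pf$length))
        next
      }
      lit <- seq_chars(.materialize(pf))
      L <- length(lit)
      chars[(u0 + 1L):(u0 + L)] <- lit
      f0 <- u0; f1 <- u0 + L
      if (pf$kind == "G4") {
        # record the span the canonical four-G-run pattern covers (a
        # G4-forming repeat may carry non-run flanking bases)
        g <- find_g4_motifs(.materialize(pf))
        if (nrow(g)) { f0 <- u0 + g$start[1L]; f1 <- u0 + g$end[1L] }
      }
      # guards: break run/phase continuation at both flanks
      if (pf$kind == "MICROSAT") {
        u <- nchar(pf$motif)
        chars <- .guard(chars, u0, chars[u0 + u])          # left
        chars <- .guard(chars, u0 + L + 1L, chars[u0 + L + 1L - u])
      } else if (pf$kind == "PUR_PYR_TRACT") {
        cls <- if (lit[1L] %in% c("A", "G")) c("A", "G") else c("C", "T")
        chars <- .guard(chars, u0, cls)
        chars <- .guard(chars, u0 + L + 1L, cls)
      } else if (pf$kind %in% c("G4", "TERMINATOR")) {
        chars <- .guard(chars, u0, lit[1L])
        chars <- .guard(chars, u0 + L + 1L, lit[L])
      }
      type <- switch(pf$kind, MICROSAT = "REPEAT", MOTIF_DISPERSED = "REPEAT",
                     PUR_PYR_TRACT = "TRACT", G4 = "G4",
                     TERMINATOR = "TERMINATOR")
      att <- c(kind = pf$kind,
               motif = if (!is.null(pf$motif) && pf$kind %in%
                             c("MICROSAT", "MOTIF_DISPERSED")) pf$motif else
                 paste(lit, collapse = ""),
               copies = as.character(if (is.null(pf$copies)) 1L else pf$copies))
      feats <- rbind(feats, feature_table(type, f0, f1, list(att)))
    }
    # promoter: 3' end of IGS, immediately 5' of the next unit's TSS
    pm <- seq_chars(spec$promoter_motif)
    chars[(total - length(pm) + 1L):total] <- pm
    feats <- rbind(feats, feature_table(
      "PROMOTER", total - length(pm), total,
      list(c(motif = spec$promoter_motif))))
    # keep the planted terminator first in its search window: break any
    # accidental upstream T-run of >= 5
    term_rows <- which(feats$type == "TERMINATOR")
    if (length(term_rows) == 1L) {
      w0 <- starts[["R28S"]] + lens[["R28S"]]    # 0-based window start
      t0 <- feats$start[term_rows]
      if (t0 > w0) {
        idx <- (w0 + 1L):t0                       # 1-based scan range
        is_t <- chars[idx] == "T"
        r <- rle(is_t)
        ends <- cumsum(r$lengths)
        for (k in which(r$values & r$lengths >= 5L)) {
          pos <- idx[ends[k] - 2L]                # break the run mid-way
          chars[pos] <- "C"
        }
      }
    }
    ord <- order(match(feats$type, c(REGION_ORDER, AUX_TYPES)), feats$start)
    feats <- feats[ord, , drop = FALSE]
    rownames(feats) <- NULL
    unit <- seq_record(sprintf("synthetic_unit_seed%d", spec$seed),
                       paste(chars, collapse = ""),
                       desc = "synthetic rDNA repeat unit with planted truth",
                       allow_n = FALSE)
    structure(list(unit = unit, features = feats, region_starts = starts,
                   spec = spec),
              class = "planted_truth")
  })
}

# CpG-boosted island background: i.i.d. at GC 0.7, then extra CG
# dinucleotides written until the overlapping CG count reaches 1.5x the
# i.i.d. expectation.
.island_bases <- function(len) {
  gc <- 0.7
  b <- .bg_bases(len, gc)
  target <- ceiling(1.5 * (gc / 2)^2 * (len - 1L))
  count_cg <- function(x) sum(x[-length(x)] == "C" & x[-1L] == "G")
  guard <- 0L
  while (count_cg(b) < target && guard < 10L * len) {
    i <- sample.int(len - 1L, 1L)
    b[i] <- "C"; b[i + 1L] <- "G"
    guard <- guard + 1L
  }
  b
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %s: %d bp, %d features (seed %d)\n",
              x$unit$id, nchar(x$unit$seq), nrow(x$features), x$spec$seed))
  invisible(x)
}

#' The default galliform-style preset
#'
#' Region lengths, GC targets and a catalogue of planted repeats emulating
#' the repeat classes found in galliform rDNA spacers: a 5-bp microsatellite
#' and dispersed CGG motifs in the 5'-ETS, di-/tri-/tetranucleotide
#' microsatellites and a pyrimidine bendable tract in ITS1/ITS2, an
#' `(ACCCG)`-family microsatellite block near the 3'-ETS terminator, and a
#' purine tract, `GACCT`-family repeats and a `(GAGGGG)`-type G-quadruplex
#' motif in the IGS.
#'
#' @param seed Integer seed.
#' @return A [unit_spec()].
#' @export
coturnix_preset <- function(seed = 1L) {
  plant <- list(
    planted_feature("MICROSAT", "ETS5", 600L, motif = "GTGCC", copies = 4L),
    planted_feature("MOTIF_DISPERSED", "ETS5", 900L, motif = "CGGCGGCGG"),
    planted_feature("MICROSAT", "ITS1", 300L, motif = "TC", copies = 5L),
    planted_feature("MICROSAT", "ITS1", 800L, motif = "GAG", copies = 3L),
    planted_feature("MICROSAT", "ITS1", 1200L, motif = "CCT", copies = 3L),
    planted_feature("PUR_PYR_TRACT", "ITS1", 1500L,
                    motif = "CTTCCTCCCTTTCCTCTTCCCT"),
    planted_feature("MICROSAT", "ITS2", 200L, motif = "GTTC", copies = 4L),
    planted_feature("MICROSAT", "ITS2", 400L, motif = "CG", copies = 6L),
    planted_feature("MICROSAT", "ETS3", 400L, motif = "ACCCG", copies = 5L),
    planted_feature("PUR_PYR_TRACT", "IGS", 2000L,
                    motif = "GAAGGAGGGAAGAGGAAGGAGAAGG"),
    planted_feature("G4", "IGS", 3000L, motif = "GAGGGGGAGGGGGAGGGGGAGGGG"),
    planted_feature("MICROSAT", "IGS", 6000L, motif = "GACCT", copies = 4L),
    planted_feature("MICROSAT", "IGS", 7000L, motif = "GACCTGACCC", copies = 3L))
  unit_spec(planted = plant, seed = seed)
}

#' Generate an RNA-seq-style coverage track for a synthetic unit
#'
#' Expected depth is `depth` from the TSS to the 28S 3' end, attenuates
#' linearly to 0 across the 3'-ETS (transcription attenuation at the 28S
#' border), and is 0 over the IGS. Gaussian noise of sd `noise_sd` is added
#' per base and floored at 0; `noise_sd = 0` gives the exact profile.
#'
#' @param truth A [planted_truth()] from [generate_unit()].
#' @param depth Plateau depth (> 0).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A [coverage_track()].
#' @export
generate_coverage <- function(truth, depth = 100, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (depth <= 0) .stop("depth must be > 0")
  if (noise_sd < 0) .stop("noise_sd must be >= 0")
  lens <- truth$spec$region_lengths
  end28 <- truth$region_starts[["ETS3"]]
  ets3 <- lens[["ETS3"]]
  total <- nchar(truth$unit$seq)
  prof <- c(rep(depth, end28),
            depth * (1 - seq_len(ets3) / ets3),
            rep(0, total - end28 - ets3))
  if (noise_sd > 0)
    prof <- with_seed(seed, pmax(0, prof + rnorm(total, 0, noise_sd) *
                                   (prof > 0)))
  coverage_track(truth$unit$id, prof)
}

#' Simulate long reads from the tandem repeat context
#'
#' Reads are sampled from a two-copy head-to-tail concatenation of the unit
#' (the locus is tandemly repeated, so reads may span the IGS/ETS
#' junction). Lengths are log-normal with the requested mean, clipped to
#' `[200, unit length]`; start positions are uniform over the first copy;
#' strands are sampled equally; substitution errors are i.i.d. at
#' `sub_rate`. Read ids record the true origin
#' (`read_N|start=S|len=L|strand=+/-`).
#'
#' @param truth A [planted_truth()].
#' @param n Number of reads (> 0).
#' @param mean_len Mean read length (>= 200).
#' @param sub_rate Substitution rate in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List of [seq_record()].
#' @export
generate_reads <- function(truth, n = 100L, mean_len = 2000L, sub_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  n <- as.integer(n)
  if (n <= 0L) .stop("n must be > 0")
  if (mean_len < 200L) .stop("mean_len must be >= 200")
  if (sub_rate < 0 || sub_rate >= 0.5) .stop("sub_rate must be in [0, 0.5)")
  unit <- truth$unit$seq
  L <- nchar(unit)
  tandem <- paste0(unit, unit)
  with_seed(seed, {
    sdlog <- 0.5
    lens <- pmin(L, pmax(200L, round(stats::rlnorm(
      n, meanlog = log(mean_len) - sdlog^2 / 2, sdlog = sdlog))))
    starts <- sample.int(L, n, replace = TRUE) - 1L   # 0-based, first copy
    strands <- sample(c("+", "-"), n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      s <- substr(tandem, starts[i] + 1L, starts[i] + lens[i])
      if (sub_rate > 0) {
        ch <- seq_chars(s)
        hit <- which(runif(length(ch)) < sub_rate)
        if (length(hit)) {
          subs <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
          ch[hit] <- subs
          s <- paste(ch, collapse = "")
        }
      }
      if (strands[i] == "-") s <- revcomp(s)
      seq_record(sprintf("read_%05d|start=%d|len=%d|strand=%s", i, starts[i],
                         lens[i], strands[i]), s)
    })
  })
}

#' Random background reads (non-rDNA pool)
#'
#' I.i.d. sequences at a given GC, used as the negative class when testing
#' read fishing.
#'
#' @param n Number of reads.
#' @param mean_len Mean log-normal length (clipped at 200).
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return List of [seq_record()] with ids `bg_N`.
#' @export
generate_background_reads <- function(n, mean_len = 2000L, gc = 0.5,
                                      seed = 1L) {
  with_seed(seed, {
    sdlog <- 0.5
    lens <- pmax(200L, round(stats::rlnorm(
      n, meanlog = log(mean_len) - sdlog^2 / 2, sdlog = sdlog)))
    lapply(seq_len(n), function(i)
      seq_record(sprintf("bg_%05d", i),
                 paste(.bg_bases(lens[i], gc), collapse = "")))
  })
}

#' Write a full synthetic data set to disk
#'
#' Writes the unit FASTA, the truth GFF3, simulated reads FASTA, a
#' bedGraph coverage track and a JSON truth manifest.
#'
#' @param truth A [planted_truth()].
#' @param dir Output directory (created if needed).
#' @param n_reads,mean_len,sub_rate,depth,noise_sd Simulation controls.
#' @param seed Integer seed for reads/coverage.
#' @return `dir`, invisibly.
#' @export
write_synthetic_set <- function(truth, dir, n_reads = 200L, mean_len = 2000L,
                                sub_rate = 0.05, depth = 100, noise_sd = 10,
                                seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$unit, file.path(dir, "unit.fasta"))
  write_gff3(truth$features, truth$unit$id, file.path(dir, "truth.gff3"),
             unit_length = nchar(truth$unit$seq))
  reads <- generate_reads(truth, n_reads, mean_len, sub_rate, seed)
  write_fasta(reads, file.path(dir, "reads.fasta"))
  cov <- generate_coverage(truth, depth, noise_sd, seed)
  write_bedgraph(cov, file.path(dir, "coverage.bedgraph"))
  manifest <- list(unit_id = truth$unit$id, unit_length = nchar(truth$unit$seq),
                   seed = truth$spec$seed, read_seed = seed,
                   n_reads = n_reads, sub_rate = sub_rate, depth = depth,
                   noise_sd = noise_sd,
                   region_lengths = as.list(truth$spec$region_lengths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
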