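test_that("gc_content computes percentages to 0.1", {
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCGC"), 100.0)
  expect_equal(gc_content("TTGCTCCGCAGGAGCGAGC"), 68.4)
  expect_error(gc_content("ACGN"), "outside")
  expect_error(gc_content(""), "empty")
})

test_that("gc of a concatenation equals the length-weighted region mean", {
  set.seed(41)
  parts <- replicate(5, random_dna(sample(300:900, 1), gc = runif(1, 0.3, 0.8)))
  whole <- gc_content(paste(parts, collapse = ""))
  weighted <- sum(vapply(parts, gc_content, numeric(1)) * nchar(parts)) /
    sum(nchar(parts))
  # each reported value is rounded to 0.1, so the whole and the weighted
  # mean of parts can differ by up to ~0.1
  expect_lt(abs(whole - weighted), 0.1)
})

test_that("cpg_islands on constructed extremes", {
  expect_equal(nrow(cpg_islands(strrep("AT", 150))), 0L)    # GC fails
  expect_equal(nrow(cpg_islands(strrep("CG", 75))), 0L)     # length fails
  isl <- cpg_islands(strrep("CG", 150))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 300L)
  expect_equal(isl$oe_ratio, 2.0)  # (150 * 300) / (150 * 150)
  expect_error(cpg_islands("ACGT", min_gc = 1.5), "out of range")
})

test_that("cpg_islands matches the brute-force oracle on a mixed corpus", {
  set.seed(7)
  corpus <- c(
    # CG-rich islands embedded in AT-rich background
    replicate(6, paste0(random_dna(300, 0.3), strrep("CG", sample(100:200, 1)),
                        random_dna(300, 0.3))),
    # uniformly GC-rich (island spans nearly everything)
    replicate(4, random_dna(800, 0.7)),
    # borderline GC around the 50% threshold
    replicate(6, random_dna(1000, 0.52)),
    # two separated islands
    replicate(4, paste0(random_dna(150, 0.25), strrep("GC", 60),
                        strrep("CG", 55), random_dna(400, 0.25),
                        strrep("CG", 130), random_dna(150, 0.25))))
  for (s in corpus) {
    got <- cpg_islands(s)
    exp <- oracle_cpg_islands(s)
    expect_equal(got$start, exp$start, label = substr(s, 1, 25))
    expect_equal(got$end, exp$end, label = substr(s, 1, 25))
  }
})

test_that("cpg_island_coverage arithmetic and error handling", {
  expect_equal(cpg_island_coverage(data.frame(start = integer(),
                                              end = integer()), 1000L), 0.0)
  one <- data.frame(start = 100L, end = 600L)
  expect_equal(cpg_island_coverage(one, 1000L), 50.0)
  two <- data.frame(start = c(0L, 400L), end = c(500L, 900L))
  expect_error(cpg_island_coverage(two, 1000L), "overlap")
  expect_error(cpg_island_coverage(one, 500L), "outside")
})

test_that("island coverage of the synthetic unit equals the direct sum", {
  truth <- generate_unit(coturnix_preset(seed = 1))
  isl <- cpg_islands(truth$unit$seq)
  expect_equal(cpg_island_coverage(isl, 21166L),
               round(100 * sum(isl$end - isl$start) / 21166, 1))
})

test_that("microsatellites: worked examples including the multi-phase string", {
  ms <- find_microsatellites("CCCGACCCGACCCGACCGACCCGACCCGACCGA")
  expect_true(any(ms$motif == "CCCGA" & ms$copies == 3L & ms$start == 0L))

  ms2 <- find_microsatellites("ATATATAT")
  expect_true(any(ms2$motif == "AT" & ms2$copies == 4L & ms2$start == 0L))

  expect_equal(nrow(find_microsatellites("ACGTACGT")), 0L)
  expect_error(find_microsatellites("ACGT", min_unit = 0L), "min_unit")
})

test_that("microsatellites match the brute-force oracle on random sequences", {
  set.seed(13)
  corpus <- c(
    replicate(60, random_dna(sample(50:500, 1), gc = runif(1, 0.3, 0.8))),
    # repeat-seeded sequences to exercise real hits
    replicate(60, {
      u <- sample(2:6, 1)
      motif <- random_dna(u, 0.6)
      paste0(random_dna(40, 0.5), strrep(motif, sample(3:8, 1)),
             random_dna(40, 0.5), strrep(motif, 3), random_dna(30, 0.5))
    }))
  for (s in corpus) {
    got <- find_microsatellites(s)
    exp <- oracle_microsats(s)
    expect_equal(nrow(got), nrow(exp), label = substr(s, 1, 25))
    expect_equal(got$motif, exp$motif)
    expect_equal(got$start, exp$start)
    expect_equal(got$copies, exp$copies)
  }
})

test_that("degenerate single-position repeats are found when enabled", {
  s <- paste0("TTATT", strrep("CAGA", 3), strrep("CAGC", 2), "TTATT")
  off <- find_microsatellites(s)
  on <- find_microsatellites(s, degenerate = TRUE)
  expect_false(any(grepl("M", off$motif)))
  expect_true(any(on$motif == "CAGM" & on$copies == 5L))
})

test_that("motif and complement counting uses overlapping scan semantics", {
  expect_equal(unname(count_motif_and_complement("CGGCGGCGG", "CGG")),
               c(3L, 0L))
  expect_equal(unname(count_motif_and_complement("GGGG", "GGG")), c(2L, 0L))
  expect_error(count_motif_and_complement("", "CGG"), "empty")
  expect_error(count_motif_and_complement("ACGT", "CNG"), "outside")
  # complement pairing is base-complement, not reverse complement
  got <- count_motif_and_complement("GCGATTTCGCT", "GCGA")
  expect_equal(unname(got), c(1L, 1L))  # CGCT is the complement of GCGA
})

test_that("motif counts equal the naive positional scan (property)", {
  set.seed(23)
  for (i in 1:40) {
    s <- random_dna(sample(30:300, 1), gc = runif(1, 0.35, 0.75))
    m <- random_dna(sample(2:5, 1), 0.6)
    got <- count_motif_and_complement(s, m)
    expect_equal(got[["n_motif"]], oracle_motif_count(s, m))
    expect_equal(got[["n_complement"]],
                 oracle_motif_count(s, chartr("ACGT", "TGCA", m)))
  }
})

test_that("purine/pyrimidine tracts are maximal same-class runs", {
  tr <- find_pur_pyr_tracts("GAGAGAGAGAGA")
  expect_equal(tr$kind, "PUR_TRACT")
  expect_equal(tr$end - tr$start, 12L)

  tr2 <- find_pur_pyr_tracts("TTTTTCCCCCTTTTT")
  expect_equal(tr2$kind, "PYR_TRACT")
  expect_equal(c(tr2$start, tr2$end), c(0L, 15L))

  expect_equal(nrow(find_pur_pyr_tracts(strrep("ACGT", 20))), 0L)
  expect_error(find_pur_pyr_tracts("ACGT", min_len = 1L), "min_len")

  mixed <- "CCTTTCCCTTAGGAAGAGGGAACCTCTT"  # pyr(10) pur(12) then short tail
  tr3 <- find_pur_pyr_tracts(mixed, min_len = 10L)
  expect_equal(tr3$kind, c("PYR_TRACT", "PUR_TRACT"))
  expect_equal(tr3$start, c(0L, 10L))
  expect_equal(tr3$end, c(10L, 22L))
})

test_that("G4 motifs: four G-runs with short loops, leftmost non-overlapping", {
  expect_equal(nrow(find_g4_motifs(strrep("GAGGGG", 4))), 1L)
  g <- find_g4_motifs("GGGAGGGAGGGAGGG")
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(0L, 15L))
  expect_equal(nrow(find_g4_motifs("ATATATATAT")), 0L)
  expect_error(find_g4_motifs("ACGT", loop_min = 5L, loop_max = 2L), "loop")
  # two well-separated quadruplexes give two non-overlapping hits
  s <- paste0("GGGAGGGAGGGAGGG", strrep("T", 30), "GGGTGGGTGGGTGGG")
  expect_equal(nrow(find_g4_motifs(s)), 2L)
})

test_that("every planted repeat is re-found at exact coordinates", {
  for (seed in c(1L, 9L)) {
    truth <- generate_unit(coturnix_preset(seed = seed))
    s <- truth$unit$seq
    ms <- find_microsatellites(s, max_unit = 10L)
    tr <- find_pur_pyr_tracts(s)
    g4 <- find_g4_motifs(s)
    pl <- truth$features[truth$features$type %in% c("REPEAT", "TRACT", "G4"), ]
    for (i in seq_len(nrow(pl))) {
      a <- pl$attributes[[i]]
      found <- switch(
        a[["kind"]],
        MICROSAT = any(ms$start == pl$start[i] & ms$end == pl$end[i] &
                         ms$motif == a[["motif"]]),
        PUR_PYR_TRACT = any(tr$start == pl$start[i] & tr$end == pl$end[i]),
        G4 = any(g4$start == pl$start[i] & g4$end == pl$end[i]),
        MOTIF_DISPERSED = count_motif_and_complement(
          substr(s, pl$start[i] + 1L, pl$end[i]), "CGG")[["n_motif"]] >= 3L)
      expect_true(found, label = sprintf("%s at %d (seed %d)", a[["kind"]],
                                         pl$start[i], seed))
    }
  }
})
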