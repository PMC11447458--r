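make_ref <- function(seed = 101L) {
  truth <- generate_unit(coturnix_preset(seed = seed))
  list(truth = truth,
       reg = truth$features[truth$features$type %in% region_order(), ])
}

test_that("boundary transfer onto an identical target is the identity", {
  r <- make_ref()
  got <- transfer_boundaries(r$truth$unit, r$truth$unit, r$reg)
  expect_equal(got$type, r$reg$type)
  expect_equal(got$start, r$reg$start)
  expect_equal(got$end, r$reg$end)
  expect_true(all(vapply(got$attributes, function(a)
    all(a[grepl("status", names(a))] == "mapped"), logical(1))))
})

test_that("an insertion shifts downstream boundaries by its length", {
  r <- make_ref()
  s <- r$truth$unit$seq
  its1 <- r$reg[r$reg$type == "ITS1", ]
  cut <- its1$start + 1000L  # mid-ITS1, 0-based
  ins <- strrep("ACTGACTGAC", 1)  # 10 bp
  target <- seq_record("ins", paste0(substr(s, 1, cut), ins,
                                     substr(s, cut + 1L, nchar(s))))
  got <- transfer_boundaries(target, r$truth$unit, r$reg)
  before <- r$reg$start <= cut
  expect_equal(got$start[before], r$reg$start[before])
  after <- r$reg$start > cut
  expect_equal(got$start[after], r$reg$start[after] + 10L)
  expect_equal(got$end[8], nchar(target$seq))
})

test_that("prepending k bases shifts all mapped boundaries by k (equivariance)", {
  r <- make_ref()
  set.seed(51)
  k <- 137L
  target <- seq_record("shift", paste0(random_dna(k, 0.5), r$truth$unit$seq))
  got <- transfer_boundaries(target, r$truth$unit, r$reg)
  expect_equal(got$start[-1L], r$reg$start[-1L] + k)
})

test_that("boundaries inside replaced sequence are flagged UNMAPPED", {
  r <- make_ref()
  s <- r$truth$unit$seq
  its2 <- r$reg[r$reg$type == "ITS2", ]
  set.seed(52)
  # replace ITS2 plus 30 bp into each flank, so both ITS2 boundary anchors
  # fall wholly in novel sequence
  a <- its2$start - 30L; b <- its2$end + 30L
  target <- seq_record("repl", paste0(substr(s, 1, a),
                                      random_dna(b - a, 0.5),
                                      substr(s, b + 1L, nchar(s))))
  got <- transfer_boundaries(target, r$truth$unit, r$reg)
  its2_row <- got[got$type == "ITS2", ]
  att <- its2_row$attributes[[1]]
  expect_equal(unname(att[["start_status"]]), "UNMAPPED")
  expect_equal(unname(att[["end_status"]]), "UNMAPPED")
  # boundaries away from the replacement still map exactly
  expect_equal(got$start[got$type == "R18S"], r$reg$start[r$reg$type == "R18S"])
  expect_equal(got$start[got$type == "R28S"] >= r$reg$start[r$reg$type == "R28S"] - 5L &
                 got$start[got$type == "R28S"] <= r$reg$start[r$reg$type == "R28S"] + 5L,
               TRUE)
})

test_that("a too-short target is rejected", {
  r <- make_ref()
  expect_error(transfer_boundaries(seq_record("t", "ACGTACGT"),
                                   r$truth$unit, r$reg), "shorter")
})

test_that("TSS is the onset of sustained coverage", {
  step <- coverage_track("u", c(rep(0, 500), rep(100, 700)))
  expect_equal(find_tss(step), 500L)
  expect_error(find_tss(coverage_track("u", rep(0, 100))), "no signal")
  # a short blip before the true onset is not sustained
  blip <- coverage_track("u", c(rep(0, 200), rep(100, 10), rep(0, 90),
                                rep(100, 500)))
  expect_equal(find_tss(blip), 300L)
})

test_that("TSS is recovered from noisy synthetic coverage within 25 bp", {
  truth <- generate_unit(coturnix_preset(seed = 1))
  for (s in 1:3) {
    cov <- generate_coverage(truth, depth = 100, noise_sd = 10, seed = s)
    expect_lte(abs(find_tss(cov) - 0L), 25L)
  }
})

test_that("terminator search finds a planted poly-T + inverted repeat", {
  set.seed(53)
  arm <- "GCGAGC"
  site <- paste0(strrep("T", 6), "CACAC", arm, "AATT", revcomp(arm))
  bg <- gsub("T", "A", random_dna(2000, 0.5))  # no accidental T-runs
  s <- paste0(substr(bg, 1, 1120), site, substr(bg, 1126, 2000))
  term <- find_terminator(seq_record("u", s), 1000L)
  expect_equal(term$start, 1120L)
  expect_equal(term$type, "TERMINATOR")
  expect_equal(unname(term$attributes[[1]][["arm"]]), arm)
})

test_that("terminator absent and first-hit rules", {
  s <- strrep("AC", 600)
  expect_error(find_terminator(seq_record("u", s), 100L), "no terminator")
  # two qualifying sites: 5'-most wins
  arm <- "GATCGA"
  site <- paste0(strrep("T", 6), "CC", arm, "AA", revcomp(arm))
  s2 <- paste0(strrep("CA", 50), site, strrep("CA", 50), site, strrep("CA", 50))
  term <- find_terminator(seq_record("u", s2), 0L)
  expect_equal(term$start, 100L)
})

test_that("promoter search ranks by mismatches then position", {
  set.seed(54)
  bg <- random_dna(400, 0.35)
  motif <- PROMOTER_MOTIF
  exact <- paste0(substr(bg, 1, 100), motif, substr(bg, 120, 400))
  hits <- locate_promoter(exact, motif)
  expect_equal(hits$position[1], 100L)
  expect_equal(hits$mismatches[1], 0L)

  one_off <- sub("TTGCTCCGC", "TTGATCCGC", exact, fixed = TRUE)
  h2 <- locate_promoter(one_off, motif)
  expect_equal(h2$mismatches[1], 1L)
  expect_equal(h2$position[1], 100L)

  none <- locate_promoter(strrep("A", 100), motif, max_mismatch = 4L)
  expect_equal(nrow(none), 0L)  # 13 non-A bases in the motif
  expect_error(locate_promoter("ACGT", ""), "motif")
})

test_that("with max_mismatch = motif length every window position is a hit", {
  set.seed(55)
  s <- random_dna(80, 0.5)
  m <- "ACGTACGT"
  hits <- locate_promoter(s, m, max_mismatch = nchar(m))
  expect_equal(sort(hits$position), 0:(80 - 8))
})

test_that("annotate_unit chains transfer, TSS, terminator and promoter", {
  truth <- generate_unit(coturnix_preset(seed = 6))
  cov <- generate_coverage(truth, depth = 60, noise_sd = 5, seed = 2)
  feats <- annotate_unit(truth$unit, truth$unit,
                         truth$features[truth$features$type %in% region_order(), ],
                         track = cov, promoter_motif = PROMOTER_MOTIF)
  expect_setequal(setdiff(unique(feats$type), region_order()),
                  c("TSS", "TERMINATOR", "PROMOTER"))
  tt <- truth$features[truth$features$type == "TERMINATOR", ]
  got <- feats[feats$type == "TERMINATOR", ]
  expect_equal(got$start, tt$start)
  pp <- truth$features[truth$features$type == "PROMOTER", ]
  gp <- feats[feats$type == "PROMOTER", ]
  expect_equal(gp$start, pp$start)
})
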