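test_that("gc_content matches hand computations and excludes N", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_error(gc_content("NNN"), "all N")
  set.seed(7)
  for (t in 1:10) {
    s <- rdna(100, runif(1, .2, .8))
    expect_equal(gc_content(s) + (1 - gc_content(s)), 1)
  }
})

test_that("constructed hairpins are found and poly-A yields nothing", {
  ir <- find_inverted_repeats("GGGAAACCC", min_arm = 3, max_loop = 5,
                              max_mismatch = 0)
  expect_equal(nrow(ir), 1L)
  expect_equal(unlist(ir[1, 1:4]), c(arm1_start = 1L, arm1_end = 3L,
                                     arm2_start = 7L, arm2_end = 9L))
  expect_equal(ir$loop_len, 3L)
  expect_equal(nrow(find_inverted_repeats(strrep("A", 10), 3, 5, 0)), 0L)
})

test_that("inverted-repeat finder agrees with exhaustive enumeration", {
  set.seed(11)
  for (t in 1:25) {
    s <- rdna(sample(40:90, 1), runif(1, .3, .7))
    min_arm <- sample(3:6, 1); max_loop <- sample(0:12, 1)
    max_mm <- sample(0:2, 1)
    got <- find_inverted_repeats(s, min_arm, max_loop, max_mm)
    ref <- oracle_inverted_repeats(s, min_arm, max_loop, max_mm)
    expect_equal(as.data.frame(got), ref, ignore_attr = TRUE)
  }
})

test_that("every reported inverted repeat verifies by direct comparison", {
  set.seed(12)
  s <- rdna(300, 0.5)
  ir <- find_inverted_repeats(s, 4, 30, 1)
  for (r in seq_len(nrow(ir))) {
    arm1 <- substr(s, ir$arm1_start[r], ir$arm1_end[r])
    arm2 <- substr(s, ir$arm2_start[r], ir$arm2_end[r])
    mm <- sum(strsplit(arm1, "")[[1]] != strsplit(revcomp(arm2), "")[[1]])
    expect_equal(mm, ir$mismatches[r])
    expect_lte(mm, 1)
  }
})

test_that("stem score matches known folds and its invariants", {
  expect_equal(stem_score("GGGAAACCC"), 3)
  expect_equal(stem_score("AAAA"), 0)
  set.seed(13)
  for (t in 1:15) {
    s <- rdna(sample(10:80, 1), runif(1, .3, .7))
    sc <- stem_score(s)
    expect_equal(sc, stem_score(revcomp(s)))
    expect_lte(sc, floor(nchar(s) / 2))
  }
  expect_error(stem_score(strrep("A", 5001)), "5000")
})

test_that("motif scanning matches the naive oracle over random cases", {
  set.seed(14)
  pats <- c("TTATCCCNNTTATCCC", "AGGAGG", "TTGACA", "RYSWKM", "TATAAT")
  for (t in 1:40) {
    s <- rdna(sample(50:300, 1), runif(1, .25, .75))
    pat <- sample(pats, 1)
    mm <- sample(0:2, 1)
    got <- scan_motif(s, pat, mm, "both")
    ref <- oracle_scan_motif(s, pat, mm, "both")
    expect_equal(got$start, ref$start)
    expect_equal(got$strand, ref$strand)
    expect_equal(got$mismatches, ref$mismatches)
  }
})

test_that("dual-motif scan behaves as specified on planted operators", {
  s <- paste0(strrep("A", 10), "TTATCCCGGTTATCCC", strrep("A", 74))
  hit <- scan_motif(s, DM_PATTERN, 0, "+")
  expect_equal(hit$start, 11L)
  expect_equal(hit$strand, "+")
  ## one substitution in the first heptamer
  s2 <- sub("TTATCCCGG", "TAATCCCGG", s)
  expect_equal(nrow(scan_motif(s2, DM_PATTERN, 0, "+")), 0L)
  h2 <- scan_motif(s2, DM_PATTERN, 1, "+")
  expect_equal(h2$mismatches, 1L)
  ## minus-strand count equals plus-strand count on the reverse complement
  set.seed(15)
  for (t in 1:10) {
    s3 <- rdna(200, .5)
    expect_equal(nrow(scan_motif(s3, "TTATCCC", 1, "-")),
                 nrow(scan_motif(revcomp(s3), "TTATCCC", 1, "+")))
  }
  expect_error(scan_motif("ACGT", "AXGT"), "IUPAC")
})

test_that("sigma-A promoter calls match the brute-force pairing oracle", {
  s <- paste0(rdna(10, .5), "TTGACA", strrep("A", 17), "TATAAT", rdna(20, .5))
  call <- find_sigmaA_promoters(s)
  expect_true(any(call$spacer == 17 & call$score == 0))
  s25 <- paste0(rdna(10, .5), "TTGACA", strrep("A", 25), "TATAAT")
  direct <- find_sigmaA_promoters(s25)
  expect_false(any(direct$minus35_start == 11 & direct$minus10_start == 42))
  set.seed(16)
  for (t in 1:20) {
    sr <- rdna(500, runif(1, .3, .6))
    got <- find_sigmaA_promoters(sr, 3L)
    ref <- oracle_promoters(sr, 3)
    expect_equal(got$minus35_start, ref$minus35_start)
    expect_equal(got$minus10_start, ref$minus10_start)
    expect_equal(got$score, ref$score)
  }
})

test_that("GC z-score separates planted islands from an AT-rich backbone", {
  sim <- generate_plasmid(generator_config(seed = 33))
  tr <- sim$truth$islands
  z <- gc_zscore(sim$record, tr$start[1], tr$end[1],
                 exclude = tr[, c("start", "end")])
  expect_gt(z$z_score, 3)
  expect_lt(abs(z$background_gc - 0.377), 0.02)
  bg_z <- gc_zscore(sim$record, 100, 600, exclude = tr[, c("start", "end")])
  expect_lt(abs(bg_z$z_score), 3)
})

test_that("motif files load and drive the scanner", {
  mf <- read_motif_file(system.file("extdata", "motifs.tsv",
                                    package = "egers"))
  expect_setequal(mf$name, c("DM", "RBS", "minus35", "minus10"))
  dm <- mf[mf$name == "DM", ]
  s <- paste0(strrep("T", 5), "TTATCCCAGTTATCCC", strrep("G", 20))
  expect_equal(nrow(scan_motif(s, dm$pattern, dm$budget, "+")), 1L)
})
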