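test_that("generator is byte-identical for identical seeds", {
  s1 <- generate_plasmid(generator_config(seed = 5))
  s2 <- generate_plasmid(generator_config(seed = 5))
  expect_identical(s1$record$sequence, s2$record$sequence)
  expect_identical(s1$truth$islands, s2$truth$islands)
  expect_identical(s1$truth$genes, s2$truth$genes)
  s3 <- generate_plasmid(generator_config(seed = 6))
  expect_false(identical(s1$record$sequence, s3$record$sequence))
})

test_that("realized GC matches the configured background and island levels", {
  sim <- generate_plasmid(generator_config(seed = 1))
  rec <- sim$record
  tr <- sim$truth$islands
  expect_lt(abs(gc_content(rec$sequence) - 0.377), 0.02)
  pooled <- paste(vapply(seq_len(nrow(tr)), function(i)
    subsequence(rec, tr$start[i], tr$end[i]), ""), collapse = "")
  expect_lt(abs(gc_content(pooled) - 0.514), 0.02)
})

test_that("truth tables are structurally sound and inside the sequence", {
  cfg <- generator_config(seed = 7)
  sim <- generate_plasmid(cfg)
  rec <- sim$record
  tr <- sim$truth
  expect_equal(nrow(tr$islands), cfg$n_islands)
  expect_equal(sum(tr$islands$has_dup), 1L)
  expect_true(all(tr$islands$end <= rec$length))
  expect_true(all(tr$genes$end <= rec$length))
  expect_true(all(tr$motifs$end <= rec$length))
  validate_plasmid_record(rec)
  ## islands within the configured length band (+ duplication allowance)
  len <- tr$islands$end - tr$islands$start + 1L
  lo <- cfg$island_length_range[1L]
  hi <- cfg$island_length_range[2L] + cfg$internal_duplication +
    cfg$duplication_extra
  expect_true(all(len >= lo & len <= hi))
})

test_that("planted motifs are present verbatim at their truth coordinates", {
  sim <- generate_plasmid(generator_config(seed = 8))
  rec <- sim$record
  mot <- sim$truth$motifs
  for (r in seq_len(nrow(mot))) {
    s <- subsequence(rec, mot$start[r], mot$end[r], mot$strand[r])
    ref <- switch(mot$kind[r], RBS = "AGGAGG", minus35 = "TTGACA",
                  minus10 = "TATAAT", DM = NA)
    if (mot$kind[r] == "DM") {
      expect_equal(substr(s, 1, 7), "TTATCCC")
      expect_equal(substr(s, 10, 16), "TTATCCC")
    } else expect_equal(s, ref)
  }
})

test_that("copy divergence is controllable within three identity points", {
  set.seed(9)
  for (t in 1:20) {
    anc <- rdna(sample(400:750, 1), 0.514)
    target <- runif(1, 62, 95)
    v <- strsplit(anc, "")[[1]]
    d <- round((1 - target / 100) * length(v))
    pos <- sample(length(v), d)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    al <- global_align(anc, paste(v, collapse = ""))
    expect_lte(abs(al$identity - target), 3)
  }
})

test_that("packing failures are caught before any sequence is drawn", {
  cfg <- generator_config(seed = 10, plasmid_length = 5000L, n_islands = 5L)
  expect_error(generate_plasmid(cfg), "infeasible packing")
})

test_that("simulation truth round-trips through GenBank and GFF3 on disk", {
  sim <- generate_plasmid(generator_config(seed = 11, plasmid_length = 20000,
                                           n_islands = 2))
  dir <- withr::local_tempdir()
  paths <- suppressWarnings(write_simulation(sim, dir))
  expect_true(all(file.exists(paths)))
  back <- read_plasmid(paths[["genbank"]])
  expect_equal(back$sequence, sim$record$sequence)
  isl <- read.delim(paths[["islands"]])
  expect_equal(isl$start, sim$truth$islands$start)
  ## truth coordinates survive the GFF3 annotation round trip
  gr <- rtracklayer::import(paths[["gff"]], format = "gff3")
  expect_equal(sort(GenomicRanges::start(gr)),
               sort(sim$truth$genes$start))
})

test_that("family panels have the requested universal-family structure", {
  pan <- generate_family_panel(5, 2, generator_config(seed = 12))
  counts <- table(pan$truth$family)
  expect_equal(unname(counts[c("U1", "U2")]), c(5L, 5L), ignore_attr = TRUE)
  accessory <- grep("^F", names(counts), value = TRUE)
  expect_true(all(counts[accessory] >= 2 & counts[accessory] < 5))
  pan0 <- generate_family_panel(4, 0, generator_config(seed = 13))
  expect_false(any(table(pan0$truth$family) == 4))
})
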