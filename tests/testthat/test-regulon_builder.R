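toy_operon_record <- function(gaps = c(20L, 20L), strand = "+",
                              extra = NULL) {
  ## three genes of 90 bp with configurable intergenic gaps
  set.seed(61)
  lens <- rep(90L, 3L)
  starts <- 100L + cumsum(c(0L, lens[1:2] + gaps))
  genes <- gene_features(name = paste0("g", 1:3), start = starts,
                         end = starts + lens - 1L, strand = strand)
  if (!is.null(extra)) genes <- rbind(genes, extra)
  genes <- genes[order(genes$start), ]
  plasmid_record("toy", rdna(3000), genes = genes)
}

test_that("operon assembly extends over small gaps and stops at large ones", {
  rec <- toy_operon_record(gaps = c(20L, 20L))
  expect_equal(assemble_operon(rec, "g1")$genes, c("g1", "g2", "g3"))
  rec2 <- toy_operon_record(gaps = c(500L, 20L))
  expect_equal(assemble_operon(rec2, "g1")$genes, "g1")
  expect_equal(assemble_operon(rec2, "g2")$genes, c("g2", "g3"))
  expect_error(assemble_operon(rec, "nope"), "not found")
})

test_that("operon assembly stops at a strand switch", {
  extra <- gene_features("rev1", 330L, 420L, "-")
  rec <- toy_operon_record(gaps = c(20L, 1000L), extra = extra)
  expect_equal(assemble_operon(rec, "g1")$genes, c("g1", "g2"))
})

test_that("minus-strand operons extend downstream in transcription order", {
  set.seed(62)
  starts <- c(500L, 380L, 260L)
  genes <- gene_features(name = paste0("m", 1:3), start = starts,
                         end = starts + 90L, strand = "-")
  rec <- plasmid_record("toy", rdna(1000), genes = genes)
  expect_equal(assemble_operon(rec, "m1")$genes, c("m1", "m2", "m3"))
})

test_that("classification separates planted type-1 and type-2 islands", {
  hit1 <- 0L; hit2 <- 0L; n1 <- 0L; n2 <- 0L
  for (s in 63:65) {
    sim <- generate_plasmid(generator_config(seed = s))
    tr <- sim$truth$islands
    for (i in seq_len(nrow(tr))) {
      call <- classify_egers(sim$record, tr$start[i], tr$end[i],
                             strand = tr$strand[i],
                             all_islands = tr[, c("start", "end")])
      if (tr$type[i] == 1L) {
        n1 <- n1 + 1L
        if (identical(call$type, 1L)) hit1 <- hit1 + 1L
      } else {
        n2 <- n2 + 1L
        if (identical(call$type, 2L)) hit2 <- hit2 + 1L
      }
    }
  }
  expect_equal(hit1, n1)
  expect_equal(hit2, n2)
})

test_that("a promoter with no adjacent dual motif forces unclassified", {
  ## strong promoter, no DM: fails type 2, and the promoter bars type 1
  set.seed(66)
  core <- paste0(rdna(250, 0.52), "TTGACA", strrep("A", 17), "TATAAT",
                 rdna(250, 0.52))
  bg <- rdna(20000, 0.377)
  s <- paste0(substr(bg, 1, 5000), core, substr(bg, 5001 + nchar(core), 20000))
  rec <- plasmid_record("u", s)
  call <- classify_egers(rec, 5001L, 5000L + nchar(core))
  expect_true(is.na(call$type))
  expect_gte(nrow(call$promoters), 1L)
  expect_equal(nrow(call$dm_hits), 0L)
})

test_that("regulons match the generator truth end to end", {
  for (s in 67:69) {
    sim <- generate_plasmid(generator_config(seed = s))
    an <- analyse_plasmid(sim$record)
    tr <- sim$truth$islands
    reg <- an$regulons$regulons
    expect_equal(nrow(reg), nrow(tr))
    expect_equal(nrow(an$regulons$unpaired), 0L)
    ## regulon genes partition: no gene in two regulons, totals agree
    allg <- unlist(reg$genes)
    expect_equal(anyDuplicated(allg), 0L)
    truth_genes <- sim$truth$genes$name[!is.na(sim$truth$genes$operon)]
    expect_setequal(allg, truth_genes)
    ## per-island gene lists exactly match truth
    for (i in seq_len(nrow(tr))) {
      ri <- which.max(vapply(seq_len(nrow(reg)), function(j)
        egers:::interval_jaccard(tr$start[i], tr$end[i],
                                 reg$island_start[j], reg$island_end[j]),
        numeric(1)))
      tg <- sim$truth$genes$name[
        !is.na(sim$truth$genes$operon) & sim$truth$genes$operon == tr$label[i]]
      expect_setequal(reg$genes[[ri]], tg)
    }
  }
})

test_that("an island with no downstream gene in range stays unpaired", {
  set.seed(70)
  genes <- gene_features("far", 5000L, 5300L, "+")
  rec <- plasmid_record("u", rdna(8000), genes = genes)
  call <- classify_egers(rec, 1000L, 1500L, strand = "+")
  reg <- build_regulons(rec, list(call))
  expect_equal(nrow(reg$regulons), 0L)
  expect_equal(nrow(reg$unpaired), 1L)
})

test_that("classification is deterministic and order-equivariant", {
  sim <- generate_plasmid(generator_config(seed = 71))
  tr <- sim$truth$islands
  calls <- lapply(seq_len(nrow(tr)), function(i)
    classify_egers(sim$record, tr$start[i], tr$end[i], tr$strand[i],
                   all_islands = tr[, c("start", "end")]))
  reg1 <- build_regulons(sim$record, calls)
  reg2 <- build_regulons(sim$record, rev(calls))
  expect_equal(reg1$regulons, reg2$regulons)
})
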