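test_that("planted island groups are recovered with accurate boundaries", {
  ## five copies around 85% mutual identity
  sim <- generate_plasmid(generator_config(seed = 41,
                                           copy_identity_range = c(80, 90)))
  isl <- find_self_repeats(sim$record)
  tr <- sim$truth$islands
  expect_equal(nrow(isl$islands), nrow(tr))
  expect_equal(length(unique(isl$islands$group)), 1L)
  for (i in seq_len(nrow(tr))) {
    jac <- max(vapply(seq_len(nrow(isl$islands)), function(j)
      egers:::interval_jaccard(tr$start[i], tr$end[i],
                               isl$islands$start[j], isl$islands$end[j]),
      numeric(1)))
    expect_gte(jac, 0.8)
  }
})

test_that("a seeded random sequence yields no repeat groups", {
  set.seed(42)
  rec <- plasmid_record("rand", rdna(60000, 0.377))
  isl <- find_self_repeats(rec)
  expect_equal(nrow(isl$islands), 0L)
})

test_that("small-instance discovery agrees with an all-window oracle", {
  set.seed(43)
  for (t in 1:4) {
    n <- 1500
    bg <- rdna(n, 0.4)
    plant <- t %% 2 == 0
    if (plant) {
      core <- rdna(400, 0.5)
      copy <- local({  # ~85% identical copy
        v <- strsplit(core, "")[[1]]
        pos <- sample(400, 60)
        v[pos] <- vapply(v[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        paste(v, collapse = "")
      })
      s <- paste0(substr(bg, 1, 200), core, substr(bg, 201, 600), copy,
                  substr(bg, 601, 700))
      stopifnot(nchar(s) == n)
    } else s <- bg
    rec <- plasmid_record("w", s, is_circular = FALSE)
    got <- nrow(find_self_repeats(rec, min_len = 300)$islands) > 0
    ref <- oracle_has_repeat(s, 300, 60, step = 75)
    expect_equal(got, ref, info = paste("instance", t))
  }
})

test_that("pairwise island identities are symmetric and within bounds", {
  sim <- generate_plasmid(generator_config(seed = 44))
  isl <- find_self_repeats(sim$record)
  idm <- isl$identity
  expect_true(all(abs(idm - t(idm)) < 1e-9, na.rm = TRUE))
  off <- idm[upper.tri(idm)]
  off <- off[!is.na(off)]
  expect_true(all(off >= isl$params$min_identity - 2 & off <= 100))
})

test_that("island discovery is invariant to rotation of the origin", {
  sim <- generate_plasmid(generator_config(seed = 45, plasmid_length = 20000,
                                           n_islands = 3, n_decoy_genes = 0))
  rec <- sim$record
  base <- find_self_repeats(rec)$islands
  L <- rec$length
  for (off in c(5000L, 13211L)) {
    rot <- plasmid_record("rot", paste0(substr(rec$sequence, off + 1L, L),
                                        substr(rec$sequence, 1L, off)))
    got <- find_self_repeats(rot)$islands
    expect_equal(nrow(got), nrow(base))
    for (i in seq_len(nrow(base))) {
      es <- egers:::wrap_pos(base$start[i] - off, L)
      jac <- max(vapply(seq_len(nrow(got)), function(j) {
        ds <- got$start[j]
        egers:::interval_jaccard(es, es + base$length[i] - 1L,
                                 ds, ds + got$length[j] - 1L)
      }, numeric(1)))
      expect_gte(jac, 0.9)
    }
  }
})

test_that("short records return an empty result with a warning", {
  rec <- plasmid_record("tiny", rdna(400))
  expect_warning(isl <- find_self_repeats(rec), "shorter")
  expect_equal(nrow(isl$islands), 0L)
})

test_that("internal duplications are detected at the planted length", {
  found <- 0L
  for (s in c(51, 52, 53)) {
    sim <- generate_plasmid(generator_config(seed = s))
    tr <- sim$truth$islands
    di <- which(tr$has_dup)
    dup <- find_internal_duplication(sim$record, tr$start[di], tr$end[di])
    expect_gte(nrow(dup), 1L)
    expect_lte(abs(dup$length[1] - tr$dup_len[di]), 5)
    expect_gte(dup$identity[1], 90)
    ## an island without a duplication reports none
    clean <- setdiff(seq_len(nrow(tr)), di)[1]
    dup0 <- find_internal_duplication(sim$record, tr$start[clean],
                                      tr$end[clean])
    expect_equal(nrow(dup0), 0L)
    found <- found + 1L
  }
  expect_equal(found, 3L)
})

test_that("reference panel matching finds planted copies and nothing else", {
  sim <- generate_plasmid(generator_config(seed = 54))
  tr <- sim$truth$islands
  anc <- subsequence(sim$record, tr$start[1], tr$end[1], tr$strand[1])
  hits <- match_reference_panel(sim$record, c(refA = anc))
  expect_equal(nrow(hits), nrow(tr))
  ## a 70%-identity planted copy in a fresh backbone
  set.seed(55)
  copy <- local({
    v <- strsplit(anc, "")[[1]]
    pos <- sample(length(v), round(0.3 * length(v)))
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  })
  bg <- rdna(30000, 0.377)
  rec <- plasmid_record("p", paste0(substr(bg, 1, 9000), copy,
                                    substr(bg, 9001 + nchar(copy), 30000)))
  h <- match_reference_panel(rec, c(refA = anc))
  expect_equal(nrow(h), 1L)
  expect_lte(abs(h$identity - 70), 3)
  ## no planted copy -> no hits
  rec0 <- plasmid_record("q", rdna(30000, 0.377))
  expect_equal(nrow(match_reference_panel(rec0, c(refA = anc))), 0L)
})

test_that("inverted-orientation repeats are reported separately", {
  set.seed(56)
  bg <- rdna(12000, 0.4)
  core <- rdna(450, 0.5)
  s <- paste0(substr(bg, 1, 2000), core, substr(bg, 2001, 7000),
              revcomp(core), substr(bg, 7001, 12000))
  rec <- plasmid_record("inv", s)
  isl <- find_self_repeats(rec)
  expect_equal(nrow(isl$islands), 0L)  # never grouped as direct repeats
  expect_gte(nrow(isl$inverted), 1L)
  expect_gte(max(isl$inverted$identity), 95)
})
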