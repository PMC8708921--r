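mutate_frac <- function(s, d) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), round(d * length(v)))
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

test_that("progressive alignment handles the basic contracts", {
  a <- progressive_align(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_equal(a$aligned, c("ACGTACGT", "ACGTACGT"))  # gap-free
  b <- progressive_align(c(x = "ACGTACGT", y = "ACGACGT"))
  expect_equal(b$ncols, 8L)                            # exactly one gap column
  expect_equal(sum(strsplit(b$aligned[2], "")[[1]] == "-"), 1L)
  single <- progressive_align(c(z = "ACGT"))
  expect_equal(single$aligned, "ACGT")
})

test_that("ungapping any alignment row returns the input sequence", {
  set.seed(91)
  for (t in 1:20) {
    n <- sample(3:6, 1)
    anc <- rdna(sample(100:300, 1), 0.5)
    seqs <- setNames(vapply(1:n, function(i) mutate_frac(anc, runif(1, 0, .3)),
                            ""), paste0("s", 1:n))
    aln <- progressive_align(seqs)
    for (nm in names(seqs))
      expect_equal(ungap_row(aln, nm), seqs[[nm]])
  }
})

test_that("K2P distance matches its closed form and ape's implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  ## 100 sites, P = 0.1, Q = 0: d = -log(0.8)/2
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8))
  set.seed(92)
  for (t in 1:10) {
    x <- rdna(300); y <- mutate_frac(x, runif(1, 0.05, 0.4))
    expect_equal(k2p_distance(x, y), k2p_distance(y, x))
    mat <- rbind(tolower(strsplit(x, "")[[1]]), tolower(strsplit(y, "")[[1]]))
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(k2p_distance(x, y), ref)
  }
  ## saturation: log argument <= 0 -> capped and flagged
  sat <- k2p_distance(strrep("A", 10), strrep("G", 10))
  expect_equal(as.numeric(sat), 5)
  expect_true(attr(sat, "saturated"))
  ## gap/N columns are pairwise-deleted
  expect_equal(k2p_distance("AC-GN", "ACTGA"), 0)
})

test_that("NJ reproduces 3-taxon closed form and additive 4-taxon trees", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cm <- ape::cophenetic.phylo(tr)
  expect_equal(cm[rownames(D), colnames(D)], D, tolerance = 1e-9)
  ## additive matrix from a known 4-leaf tree: ((a:1,b:2):1.5,(c:1,d:3));
  D4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 1, b = 2, c = 1, d = 3); mid <- 1.5
  for (x in letters[1:4]) for (y in letters[1:4]) {
    if (x == y) next
    same <- (x %in% c("a", "b")) == (y %in% c("a", "b"))
    D4[x, y] <- bl[x] + bl[y] + if (same) 0 else mid
  }
  tr4 <- nj_tree(D4)
  cm4 <- ape::cophenetic.phylo(tr4)
  expect_equal(cm4[rownames(D4), colnames(D4)], D4, tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
})

test_that("NJ agrees with an independent plain-R implementation", {
  set.seed(93)
  for (t in 1:25) {
    n <- sample(5:8, 1)
    pts <- matrix(runif(n * 4), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    got <- nj_tree(D)
    ref <- ape::read.tree(text = oracle_nj_newick(D))
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    cg <- ape::cophenetic.phylo(got); cr <- ape::cophenetic.phylo(ref)
    expect_equal(cg[rownames(D), colnames(D)], cr[rownames(D), colnames(D)],
                 tolerance = 1e-6)
  }
})

test_that("bootstrap supports are reproducible and detect clan structure", {
  set.seed(94)
  anc1 <- rdna(600, 0.5); anc2 <- mutate_frac(anc1, 0.30)
  seqs <- c(a1 = mutate_frac(anc1, .05), a2 = mutate_frac(anc1, .05),
            a3 = mutate_frac(anc1, .05), b1 = mutate_frac(anc2, .05),
            b2 = mutate_frac(anc2, .05), b3 = mutate_frac(anc2, .05))
  aln <- progressive_align(seqs)
  tr1 <- bootstrap_supports(aln, n_reps = 200, seed = 7)
  tr2 <- bootstrap_supports(aln, n_reps = 200, seed = 7)
  expect_identical(tr1$node.label, tr2$node.label)
  ## the central split (a* vs b*) must be near-unanimous
  split_support <- function(tree) {
    rooted <- midpoint_root(tree)
    labs <- suppressWarnings(as.numeric(rooted$node.label))
    max(labs, na.rm = TRUE)
  }
  expect_gte(split_support(tr1), 95)
  expect_error(bootstrap_supports(aln, n_reps = 10), "seed")
})

test_that("midpoint rooting preserves leaf-to-leaf path lengths", {
  set.seed(95)
  tr <- ape::rtree(7, rooted = FALSE)
  before <- ape::cophenetic.phylo(tr)
  rooted <- midpoint_root(tr)
  after <- ape::cophenetic.phylo(rooted)
  expect_equal(after[rownames(before), colnames(before)], before,
               tolerance = 1e-9)
  ## 2-leaf tree: root at half the branch
  t2 <- ape::read.tree(text = "(a:0.6,b:0.4);")
  r2 <- midpoint_root(t2)
  expect_equal(sort(r2$edge.length), c(0.5, 0.5))
  ## caterpillar: root bisects the longest path
  cat_tree <- ape::read.tree(text = "(((a:5,b:1):1,c:1):1,(d:1,e:3):1);")
  rc <- midpoint_root(ape::unroot(cat_tree))
  cc <- ape::cophenetic.phylo(rc)
  dmax <- max(cc)
  root_depths <- ape::node.depth.edgelength(rc)[seq_along(rc$tip.label)]
  expect_equal(max(root_depths), dmax / 2, tolerance = 1e-9)
})

test_that("island phylogenies separate two planted reference clades", {
  ## two island ancestors, copies planted on one plasmid each
  set.seed(96)
  cfgA <- generator_config(seed = 97, plasmid_length = 30000, n_islands = 3,
                           egers_type_mix = c(type1 = 1, type2 = 0))
  cfgB <- generator_config(seed = 98, plasmid_length = 30000, n_islands = 3,
                           egers_type_mix = c(type1 = 1, type2 = 0))
  simA <- generate_plasmid(cfgA); simB <- generate_plasmid(cfgB)
  grab <- function(sim, tag) {
    tr <- sim$truth$islands
    setNames(lapply(seq_len(nrow(tr)), function(i)
      subsequence(sim$record, tr$start[i], tr$end[i], tr$strand[i])),
      paste0(tag, tr$label))
  }
  seqs <- unlist(c(grab(simA, "A_"), grab(simB, "B_")))
  aln <- progressive_align(seqs)
  tre <- bootstrap_supports(aln, n_reps = 100, seed = 5)
  rooted <- midpoint_root(tre)
  ## monophyly of each source plasmid's islands
  a_tips <- grep("^A_", rooted$tip.label)
  expect_true(ape::is.monophyletic(rooted, rooted$tip.label[a_tips]))
})
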