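test_that("identical proteins align at full identity and coverage", {
  p <- rprot(100)
  h <- protein_align(p, p)
  expect_equal(h$identity, 100)
  expect_equal(h$coverage_a, 100)
  expect_equal(h$coverage_b, 100)
  expect_lt(h$e_value, 1e-30)
  expect_error(protein_align("", p), "empty")
})

test_that("e-value decreases monotonically with raw score at fixed lengths", {
  set.seed(81)
  scores <- numeric(); evals <- numeric()
  anc <- rprot(150)
  for (d in c(0, 10, 30, 60, 90)) {
    v <- strsplit(anc, "")[[1]]
    if (d > 0) {
      pos <- sample(150, d)
      v[pos] <- vapply(v[pos], function(x)
        sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
    }
    h <- protein_align(anc, paste(v, collapse = ""))
    scores <- c(scores, h$score); evals <- c(evals, h$e_value)
  }
  ord <- order(scores)
  expect_true(all(diff(evals[ord]) <= 0))
})

test_that("local alignment score equals an independent Smith-Waterman DP", {
  set.seed(82)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  for (t in 1:20) {
    a <- rprot(sample(40:70, 1)); b <- rprot(sample(40:70, 1))
    got <- protein_align(a, b)$score
    ref <- oracle_sw_score(a, b, B62)
    expect_equal(got, ref)
  }
})

test_that("shared families cluster; unrelated proteins stay singletons", {
  set.seed(83)
  anc <- rprot(180)
  mut <- function(p, d) {
    v <- strsplit(p, "")[[1]]
    pos <- sample(length(v), round(d * length(v)))
    v[pos] <- vapply(v[pos], function(x)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
    paste(v, collapse = "")
  }
  prot <- data.frame(
    plasmid = c(paste0("p", 1:7), paste0("p", 1:7)),
    gene = c(rep("fam", 7), rep("uniq", 7)),
    sequence = c(vapply(1:7, function(i) mut(anc, 0.2), ""),
                 vapply(1:7, function(i) rprot(150), "")))
  cl <- cluster_homologs(prot)
  sizes <- table(cl$clusters$cluster_id)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE)[1], 7L)
  expect_equal(sum(sizes == 1L), 7L)
  pa <- presence_absence(cl)
  expect_equal(sum(attr(pa, "row_sums") == 7L), 1L)
})

test_that("a half-length shared domain fails the both-coverage rule", {
  set.seed(84)
  domain <- rprot(100)
  a <- paste0(domain, rprot(100))
  b <- paste0(rprot(100), domain)
  prot <- data.frame(plasmid = c("p1", "p2"), gene = c("x", "y"),
                     sequence = c(a, b))
  cl <- cluster_homologs(prot, min_coverage = 75)
  expect_equal(cl$n_clusters, 2L)
  ## at permissive coverage the pair joins: threshold monotonicity
  cl2 <- cluster_homologs(prot, min_coverage = 40)
  expect_equal(cl2$n_clusters, 1L)
})

test_that("clustering is invariant to input order", {
  set.seed(85)
  pan <- generate_family_panel(4, 1, generator_config(seed = 85))
  prot <- proteins_from_records(pan$records)
  cl1 <- cluster_homologs(prot)
  cl2 <- cluster_homologs(prot[rev(seq_len(nrow(prot))), ])
  m1 <- cl1$clusters[order(cl1$clusters$plasmid, cl1$clusters$gene), ]
  m2 <- cl2$clusters[order(cl2$clusters$plasmid, cl2$clusters$gene), ]
  expect_equal(m1$cluster_id, m2$cluster_id)
  ## every cluster pair is connected through passing edges
  for (cid in unique(cl1$clusters$cluster_id)) {
    members <- with(cl1$clusters, paste(plasmid, gene, sep = "|")[
      cluster_id == cid])
    if (length(members) < 2) next
    edges <- cl1$edges
    reach <- members[1]
    repeat {
      nxt <- unique(c(edges$subject[edges$query %in% reach],
                      edges$query[edges$subject %in% reach]))
      nxt <- setdiff(intersect(nxt, members), reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    expect_setequal(reach, members)
  }
})

test_that("family panel recovers the ardC/reg-style universal pattern", {
  pan <- generate_family_panel(7, 2, generator_config(seed = 86))
  prot <- proteins_from_records(pan$records)
  cl <- cluster_homologs(prot)
  pa <- presence_absence(cl)
  expect_equal(sum(attr(pa, "row_sums") == 7L), 2L)
  ## recovered partition equals the planted family partition
  key <- paste(pan$truth$plasmid, pan$truth$gene)
  fam <- setNames(pan$truth$family, key)
  got <- setNames(cl$clusters$cluster_id,
                  paste(cl$clusters$plasmid, cl$clusters$gene))
  tab <- table(fam[names(got)], got)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})
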