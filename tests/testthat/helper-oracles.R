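## Independent brute-force oracles.  Each reimplements an operation in the
## most transparent way possible (plain dynamic programs and exhaustive
## enumeration) and must stay independent of the package code paths it
## checks.

rdna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rprot <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

## Gotoh global alignment score with affine gaps (penalties positive).
oracle_nw_score <- function(a, b, match = 2, mismatch = -2, go = 10,
                            ge = 0.5, submat = NULL) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sub <- function(x, y) {
    if (!is.null(submat)) return(submat[x, y])
    if (x == y && x != "N") match else mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -go - ge * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -go - ge * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best + sub(av[i - 1], bv[j - 1])
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge,
                     Y[i, j - 1] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Smith-Waterman local score, affine gaps, arbitrary substitution matrix.
oracle_sw_score <- function(a, b, submat, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- X
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) +
                       submat[av[i - 1], bv[j - 1]])
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      best <- max(best, M[i, j])
    }
  }
  best
}

## Exhaustive maximal inverted repeats: enumerate every (arm1, loop, arm)
## placement, keep those within the mismatch budget, drop non-maximal
## ones (extendable outward or inward within the budget).
oracle_inverted_repeats <- function(seq, min_arm, max_loop, max_mismatch) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "*")
  pairs_ok <- function(a1s, a1e, a2s, a2e) {
    arm1 <- v[a1s:a1e]; arm2 <- v[a2s:a2e]
    sum(comp[arm1] != rev(arm2))
  }
  rows <- list()
  for (a1s in 1:n) for (a1e in a1s:n) {
    arm <- a1e - a1s + 1
    if (arm < min_arm) next
    for (loop in 0:max_loop) {
      a2s <- a1e + loop + 1; a2e <- a2s + arm - 1
      if (a2e > n) break
      mm <- pairs_ok(a1s, a1e, a2s, a2e)
      if (mm > max_mismatch) next
      ## outward extension
      if (a1s > 1 && a2e < n &&
          mm + (comp[v[a1s - 1]] != v[a2e + 1]) <= max_mismatch) next
      ## inward extension (needs loop >= 2 left afterwards)
      if (loop >= 2 &&
          mm + (comp[v[a1e + 1]] != v[a2s - 1]) <= max_mismatch) next
      rows[[length(rows) + 1]] <- data.frame(
        arm1_start = a1s, arm1_end = a1e, arm2_start = a2s, arm2_end = a2e,
        arm_len = arm, loop_len = loop, mismatches = mm)
    }
  }
  if (!length(rows))
    return(data.frame(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      arm_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  df <- do.call(rbind, rows)
  df <- df[order(df$arm1_start, df$arm2_start, df$arm1_end), ]
  rownames(df) <- NULL
  df
}

## Naive per-position motif comparison (IUPAC pattern, both strands).
oracle_scan_motif <- function(seq, pattern, max_mismatch,
                              strands = "both") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T", "N"))
  one_strand <- function(s) {
    sv <- strsplit(s, "")[[1]]; pv <- strsplit(pattern, "")[[1]]
    m <- length(pv); hits <- NULL
    if (length(sv) < m) return(hits)
    for (pos in 1:(length(sv) - m + 1)) {
      mm <- 0
      for (t in 1:m) if (!(sv[pos + t - 1] %in% iupac[[pv[t]]])) mm <- mm + 1
      if (mm <= max_mismatch) hits <- rbind(hits, c(pos = pos, mm = mm))
    }
    hits
  }
  res <- list()
  rc <- function(s) paste(rev(chartr("ACGTN", "TGCAN",
                                     strsplit(s, "")[[1]])), collapse = "")
  if (strands %in% c("both", "+")) {
    h <- one_strand(seq)
    if (!is.null(h))
      res$fwd <- data.frame(start = h[, "pos"], strand = "+",
                            mismatches = h[, "mm"])
  }
  if (strands %in% c("both", "-")) {
    h <- one_strand(rc(seq))
    if (!is.null(h))
      res$rev <- data.frame(
        start = nchar(seq) - (h[, "pos"] + nchar(pattern) - 1) + 1,
        strand = "-", mismatches = h[, "mm"])
  }
  if (!length(res))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

## Brute-force promoter pairing: all -35 x -10 combinations.
oracle_promoters <- function(seq, budget = 3, spacer = c(16, 19)) {
  h35 <- oracle_scan_motif(seq, "TTGACA", budget, "+")
  h10 <- oracle_scan_motif(seq, "TATAAT", budget, "+")
  out <- NULL
  for (i in seq_len(nrow(h35))) for (j in seq_len(nrow(h10))) {
    sp <- h10$start[j] - (h35$start[i] + 6)
    sc <- h35$mismatches[i] + h10$mismatches[j]
    if (sp >= spacer[1] && sp <= spacer[2] && sc <= budget)
      out <- rbind(out, data.frame(minus35_start = h35$start[i],
                                   minus10_start = h10$start[j],
                                   spacer = sp, score = sc))
  }
  if (is.null(out))
    return(data.frame(minus35_start = integer(), minus10_start = integer(),
                      spacer = integer(), score = integer()))
  out <- out[order(out$minus35_start, out$minus10_start), ]
  rownames(out) <- NULL
  out
}

## Plain-R canonical neighbor joining; returns a Newick string.  Ties in
## the Q criterion resolve to the first (lowest-index) pair, which is
## unique on the random matrices used in tests.
oracle_nj_newick <- function(D) {
  labs <- rownames(D)
  nodes <- as.list(labs)
  D <- as.matrix(D)
  while (nrow(D) > 2) {
    r <- nrow(D)
    net <- rowSums(D)
    Q <- (r - 2) * D - outer(net, net, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    vi <- D[i, j] / 2 + (net[i] - net[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    node <- sprintf("(%s:%.10f,%s:%.10f)", nodes[[i]], vi, nodes[[j]], vj)
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nodes <- c(nodes[keep], node)
    D <- D2
    rownames(D) <- colnames(D) <- seq_len(nrow(D))
  }
  sprintf("(%s:%.10f,%s:0.0);", nodes[[1]], D[1, 2], nodes[[2]])
}

## All-window-pair repeat oracle for small sequences: is there any pair of
## windows (length win, offset by >= win) whose global-alignment identity
## reaches the floor?
oracle_has_repeat <- function(seq, win, min_identity, step = 25) {
  n <- nchar(seq)
  if (n < 2 * win) return(FALSE)
  starts <- seq(1, n - win + 1, by = step)
  for (i in starts) for (j in starts) {
    if (j - i < win) next
    al <- egers::global_align(substr(seq, i, i + win - 1),
                              substr(seq, j, j + win - 1))
    if (al$identity >= min_identity) return(TRUE)
  }
  FALSE
}
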