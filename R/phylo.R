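## Island phylogenetics: progressive multiple alignment, Kimura
## two-parameter distances, neighbor-joining with nonparametric bootstrap,
## and midpoint rooting.  Trees are `ape::phylo` objects throughout;
## Newick is the interchange format.

#' Progressive multiple alignment of DNA sequences
#'
#' Greedy guide ordering from shared k-mer distances followed by
#' profile-profile Needleman-Wunsch merges (column-frequency profiles,
#' +1/-1 expected match score, linear gap penalty).  Deterministic for a
#' fixed input order: ties in the guide ordering are broken by the pair
#' with the smallest member indices, and the traceback prefers diagonal,
#' then up, then left.
#'
#' @param seqs Character vector of DNA sequences (named; names become row
#'   names).
#' @param k Word size for guide distances.
#' @param gap Linear gap penalty for the profile merge.
#' @return An object of class `msa`: `names`, `aligned` (equal-length
#'   gapped strings), `ncols`.
#' @export
progressive_align <- function(seqs, k = 6L, gap = 2) {
  n <- length(seqs)
  if (n < 1L) stop("need at least one sequence", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  seqs <- vapply(seqs, check_dna, character(1))
  if (n == 1L)
    return(structure(list(names = names(seqs), aligned = unname(seqs),
                          ncols = nchar(seqs[[1L]])), class = "msa"))
  ## guide distances: 1 - shared k-mer fraction
  ksets <- lapply(seqs, function(s) unique(kmer_vector(s, k)))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- length(intersect(ksets[[i]], ksets[[j]])) /
      max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
    D[i, j] <- D[j, i] <- 1 - sh
  }
  ## greedy agglomeration (average linkage over original distances)
  clusters <- lapply(seq_len(n), function(i)
    list(rows = i, aln = unname(seqs[i])))
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL; best_d <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      u <- active[ai]; v <- active[bi]
      dd <- mean(D[clusters[[u]]$rows, clusters[[v]]$rows])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(u, v) }
    }
    u <- best[1L]; v <- best[2L]
    merged <- merge_alignments(clusters[[u]]$aln, clusters[[v]]$aln, gap)
    clusters[[u]] <- list(rows = c(clusters[[u]]$rows, clusters[[v]]$rows),
                          aln = merged)
    active <- setdiff(active, v)
  }
  final <- clusters[[active]]
  ord <- order(final$rows)
  structure(list(names = names(seqs)[final$rows[ord]],
                 aligned = final$aln[ord],
                 ncols = nchar(final$aln[1L])), class = "msa")
}

## Merge two alignments (character vectors of equal-width gapped strings)
## via the compiled profile aligner.
merge_alignments <- function(alnA, alnB, gap) {
  profile_of <- function(aln) {
    rows <- lapply(aln, chars)
    L <- length(rows[[1L]])
    m <- matrix(0, 5L, L)
    code <- c(A = 1L, C = 2L, G = 3L, T = 4L, "-" = 5L, N = 5L)
    for (r in rows) {
      idx <- code[r]
      for (t in seq_len(L)) m[idx[t], t] <- m[idx[t], t] + 1
    }
    m / length(rows)
  }
  maps <- cpp_profile_align(profile_of(alnA), profile_of(alnB), gap)
  apply_map <- function(aln, map) {
    vapply(aln, function(s) {
      cs <- chars(s)
      paste(ifelse(map == 0L, "-", cs[pmax(map, 1L)]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(apply_map(alnA, maps$map_a), apply_map(alnB, maps$map_b))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$names), x$ncols))
  invisible(x)
}

#' Ungap one row of an alignment
#' @param msa An `msa` object.
#' @param i Row index or name.
#' @return The input sequence without gaps.
#' @export
ungap_row <- function(msa, i) {
  if (is.character(i)) i <- match(i, msa$names)
  gsub("-", "", msa$aligned[i], fixed = TRUE)
}

#' Kimura two-parameter distance between two aligned rows
#'
#' Columns where either row carries a gap or N are excluded (pairwise
#' deletion).  With transition proportion P and transversion proportion Q
#' over the usable columns, `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`.  When the
#' logarithm is undefined (saturation) the distance is capped at `cap`
#' substitutions/site and flagged via the `"saturated"` attribute.
#'
#' @param a,b Gapped sequences of equal length.
#' @param cap Saturation cap (default 5 substitutions/site).
#' @return Numeric distance (>= 0), possibly with attribute
#'   `saturated = TRUE`.
#' @examples
#' # P = 0.1, Q = 0 over 100 sites: -0.5 * log(0.8)
#' @export
k2p_distance <- function(a, b, cap = 5) {
  ca <- chars(toupper(a)); cb <- chars(toupper(b))
  if (length(ca) != length(cb)) stop("rows differ in length", call. = FALSE)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no usable columns", call. = FALSE)
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  diff <- ca != cb
  purA <- ca %in% c("A", "G"); purB <- cb %in% c("A", "G")
  transitions <- sum(diff & (purA == purB))
  transversions <- sum(diff & (purA != purB))
  P <- transitions / n; Q <- transversions / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    d <- cap
    attr(d, "saturated") <- TRUE
    return(d)
  }
  -0.5 * log(arg1 * sqrt(arg2))
}

#' K2P distance matrix of a multiple alignment
#'
#' @param msa An `msa` object (or list with `names`, `aligned`).
#' @param cap Saturation cap passed to [k2p_distance()].
#' @return A symmetric numeric matrix with zero diagonal; saturated cells
#'   are listed in the `"saturated_pairs"` attribute.
#' @export
k2p_matrix <- function(msa, cap = 5) {
  n <- length(msa$names)
  D <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
  sat <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- k2p_distance(msa$aligned[i], msa$aligned[j], cap = cap)
    if (isTRUE(attr(d, "saturated")))
      sat[[length(sat) + 1L]] <- c(msa$names[i], msa$names[j])
    D[i, j] <- D[j, i] <- as.numeric(d)
  }
  if (length(sat)) attr(D, "saturated_pairs") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Q-criterion agglomeration, via
#' \code{\link[ape]{nj}}); negative branch-length estimates are clamped to
#' zero (a message reports how many).  The result is unrooted.
#'
#' @param D Symmetric distance matrix with >= 3 taxa.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  tr <- ape::nj(as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Nonparametric bootstrap supports for the NJ tree of an alignment
#'
#' Columns are resampled with replacement `n_reps` times; each replicate is
#' run through K2P + NJ, and the support of each internal edge of the
#' full-data tree is the percentage of replicates containing that
#' bipartition.  Supports are stored as internal `node.label`s.
#'
#' @param msa An `msa` object with >= 4 usable columns.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed (required; the resampling is the only source of
#'   randomness).
#' @param cap Saturation cap for K2P.
#' @return The full-data NJ `phylo` tree with `node.label` = support
#'   percentages (root label empty).
#' @export
bootstrap_supports <- function(msa, n_reps = 1000L, seed, cap = 5) {
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  mat <- do.call(rbind, lapply(msa$aligned, chars))
  rownames(mat) <- msa$names
  usable <- colSums(matrix(mat %in% c("A", "C", "G", "T"), nrow(mat))) ==
    nrow(mat)
  if (sum(usable) < 4L)
    stop("alignment has fewer than 4 usable columns", call. = FALSE)
  dist_of <- function(m) {
    rows <- apply(m, 1L, paste, collapse = "")
    k2p_matrix(list(names = rownames(m), aligned = rows), cap = cap)
  }
  full <- nj_tree(dist_of(mat))
  counts <- withr::with_seed(seed,
    ape::boot.phylo(full, mat, function(m) nj_tree(dist_of(m)),
                    B = n_reps, quiet = TRUE))
  supports <- round(100 * counts / n_reps, 1)
  supports[1L] <- NA  # root pseudo-node
  full$node.label <- ifelse(is.na(supports), "", as.character(supports))
  full
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via \code{\link[phangorn]{midpoint}}); leaf-to-leaf path lengths are
#' preserved.
#'
#' @param tree An `ape::phylo` tree.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 2L) {
    tree$root.edge <- 0
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, length(tree$edge.length))
    return(tree)
  }
  if (sum(tree$edge.length) == 0) {
    message("zero-length tree; root left at the first internal node")
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Write / read alignments as FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  ss <- Biostrings::BStringSet(setNames(msa$aligned, msa$names))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  structure(list(names = names(ss), aligned = as.character(ss),
                 ncols = unique(nchar(ss))[1L]), class = "msa")
}
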