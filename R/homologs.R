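## All-vs-all protein comparison and single-linkage clustering into
## homologous protein clusters, with Karlin-Altschul bitscores/e-values.
## The e-values are documented approximations of BLAST's (ungapped
## BLOSUM62 constants, search space = product of sequence lengths);
## cluster membership, not e-value equality, is the quantity the pipeline
## relies on.

## Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
## (the values distributed with BLAST for this scheme).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local protein alignment with Karlin-Altschul statistics
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1).  The bitscore is `(lambda*S - ln K) / ln 2` and the
#' e-value `m*n*2^-bitscore` with `m`, `n` the full sequence lengths.
#' Coverage is the aligned span over the full length, per sequence.
#'
#' @param a,b Amino-acid strings (20-letter alphabet plus X; X scores 0).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `pairwise_hit`: `score` (raw), `bitscore`,
#'   `e_value`, `identity` (percent of alignment columns), `coverage_a`,
#'   `coverage_b` (percent), aligned strings.
#' @export
protein_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nchar(a) || !nchar(b)) stop("empty protein sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend)
  hit_from_alignment(aln, nchar(a), nchar(b))
}

hit_from_alignment <- function(aln, na, nb) {
  s <- Biostrings::score(aln)
  bits <- (KA_LAMBDA * s - log(KA_K)) / log(2)
  ev <- na * nb * 2^(-bits)
  pa <- Biostrings::pattern(aln); sb <- Biostrings::subject(aln)
  ga <- as.character(pa); gb <- as.character(sb)
  cols <- nchar(ga)
  nmatch <- Biostrings::nmatch(aln)
  structure(list(score = s, bitscore = bits, e_value = ev,
                 identity = if (cols) 100 * nmatch / cols else 0,
                 coverage_a = 100 * (Biostrings::end(pa) -
                                       Biostrings::start(pa) + 1L) / na,
                 coverage_b = 100 * (Biostrings::end(sb) -
                                       Biostrings::start(sb) + 1L) / nb,
                 aligned_a = ga, aligned_b = gb),
            class = "pairwise_hit")
}

#' @export
print.pairwise_hit <- function(x, ...) {
  cat(sprintf("<pairwise_hit> score %.0f bits %.1f E %.2g id %.1f%% cov %.0f/%.0f%%\n",
              x$score, x$bitscore, x$e_value, x$identity, x$coverage_a,
              x$coverage_b))
  invisible(x)
}

## BLOSUM62 from Biostrings, loaded once.
blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Cluster proteins into homologous families
#'
#' All-vs-all local alignment; an edge joins two proteins when coverage on
#' BOTH sequences reaches `min_coverage` percent and the e-value is at most
#' `max_e` (the both-sequence rule prevents domain-only chaining).
#' Clusters are the connected components (single linkage).  Cluster ids are
#' assigned deterministically from the lexicographically smallest member.
#'
#' @param proteins Data frame with columns `plasmid`, `gene`, `sequence`.
#' @param min_coverage Coverage threshold, percent (default 75).
#' @param max_e E-value threshold (default 1e-10).
#' @return An object of class `protein_clusters`: `$clusters` (data frame
#'   `cluster_id`, `plasmid`, `gene`, `is_singleton`), `$edges` (passing
#'   pairwise hits), `$n_clusters`, `$n_multi` (clusters with >= 2
#'   members).
#' @export
cluster_homologs <- function(proteins, min_coverage = 75, max_e = 1e-10) {
  stopifnot(is.data.frame(proteins),
            all(c("plasmid", "gene", "sequence") %in% colnames(proteins)),
            nrow(proteins) >= 1L)
  n <- nrow(proteins)
  ids <- paste(proteins$plasmid, proteins$gene, sep = "|")
  if (anyDuplicated(ids)) stop("duplicate (plasmid, gene) entries",
                               call. = FALSE)
  lens <- nchar(proteins$sequence)
  uf <- uf_new(n)
  edges <- list()
  if (n >= 2L) {
    aa <- Biostrings::AAStringSet(proteins$sequence)
    for (qi in seq_len(n - 1L)) {
      subj <- (qi + 1L):n
      alns <- Biostrings::pairwiseAlignment(
        aa[subj], aa[[qi]], type = "local",
        substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(alns)
      bits <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
      ev <- lens[qi] * lens[subj] * 2^(-bits)
      pa <- Biostrings::pattern(alns); sb <- Biostrings::subject(alns)
      cov_s <- 100 * (Biostrings::end(pa) - Biostrings::start(pa) + 1L) /
        lens[subj]
      cov_q <- 100 * (Biostrings::end(sb) - Biostrings::start(sb) + 1L) /
        lens[qi]
      pass <- which(ev <= max_e & cov_q >= min_coverage &
                      cov_s >= min_coverage)
      for (t in pass) {
        uf <- uf_union(uf, qi, subj[t])
        edges[[length(edges) + 1L]] <- data.frame(
          query = ids[qi], subject = ids[subj[t]], score = sc[t],
          bitscore = bits[t], e_value = ev[t],
          query_coverage = cov_q[t], subject_coverage = cov_s[t],
          stringsAsFactors = FALSE)
      }
    }
  }
  comp <- uf_components(uf)
  ## deterministic ids: order components by their smallest member id
  rep_id <- vapply(split(ids, comp), min, character(1))
  remap <- match(names(sort(rep_id)), names(rep_id))
  newcomp <- match(comp, remap)
  sizes <- table(newcomp)
  clusters <- data.frame(
    cluster_id = sprintf("HPC%03d", newcomp),
    plasmid = proteins$plasmid, gene = proteins$gene,
    is_singleton = as.integer(sizes[as.character(newcomp)]) == 1L,
    stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id, clusters$plasmid,
                             clusters$gene), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters,
                 edges = if (length(edges)) do.call(rbind, edges)
                         else data.frame(),
                 n_clusters = length(unique(newcomp)),
                 n_multi = sum(sizes >= 2L),
                 params = list(min_coverage = min_coverage, max_e = max_e)),
            class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat(sprintf("<protein_clusters> %d proteins -> %d clusters (%d with >= 2 members)\n",
              nrow(x$clusters), x$n_clusters, x$n_multi))
  invisible(x)
}

#' Presence/absence matrix of clusters across plasmids
#'
#' @param clusters A `protein_clusters` object.
#' @param plasmids Optional plasmid ordering (defaults to sorted unique).
#' @return Binary matrix, clusters x plasmids, with `row_sums` and
#'   `col_sums` attributes.
#' @export
presence_absence <- function(clusters, plasmids = NULL) {
  cl <- clusters$clusters
  plasmids <- plasmids %||% sort(unique(cl$plasmid))
  cids <- sort(unique(cl$cluster_id))
  m <- matrix(0L, length(cids), length(plasmids),
              dimnames = list(cids, plasmids))
  for (r in seq_len(nrow(cl)))
    m[cl$cluster_id[r], cl$plasmid[r]] <- 1L
  attr(m, "row_sums") <- rowSums(m)
  attr(m, "col_sums") <- colSums(m)
  m
}

#' Extract the protein complement of plasmid records
#'
#' @param records A list of `plasmid_record` objects.
#' @param genes Optional character vector restricting to given gene names.
#' @return Data frame `plasmid`, `gene`, `sequence` (translations; genes
#'   without a translation are skipped).
#' @export
proteins_from_records <- function(records, genes = NULL) {
  if (inherits(records, "plasmid_record")) records <- list(records)
  out <- lapply(records, function(r) {
    g <- r$genes
    g <- g[!is.na(g$translation), , drop = FALSE]
    if (!is.null(genes)) g <- g[g$name %in% genes, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(plasmid = r$id, gene = g$name, sequence = g$translation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read proteins from a multi-FASTA with `plasmid|gene` headers
#'
#' @param path FASTA path.
#' @return Data frame `plasmid`, `gene`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("[[:space:]].*$", "", names(ss)), "|", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("FASTA headers must be 'plasmid|gene': ",
         paste(names(ss)[bad][1:min(3, sum(bad))], collapse = ", "),
         call. = FALSE)
  data.frame(plasmid = vapply(parts, `[`, "", 1L),
             gene = vapply(parts, `[`, "", 2L),
             sequence = as.character(ss), stringsAsFactors = FALSE)
}
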