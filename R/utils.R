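## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Complements over the alphabet `{A,C,G,T,N}` (N stays N) and reverses.
#'
#' @param seq A DNA string.
#' @return The reverse-complemented string.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Split a string into a character vector of single letters.
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

## Draw an i.i.d. DNA string at a given GC fraction (uses the current RNG
## stream; callers are responsible for seeding).
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Validate a sequence over {A,C,G,T,N}; returns the upper-cased string or
## stops with an informative error (ambiguity codes other than N are
## rejected on purpose: they participate in no match, motif or base pair).
check_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    stop(sprintf("%s contains letters outside {A,C,G,T,N}: '%s'",
                 what, substr(bad, 1L, 10L)), call. = FALSE)
  }
  seq
}

## Maximum-sum contiguous segment (Kadane, vectorised via prefix sums);
## returns c(from, to, sum) or NULL when no positive segment exists.
max_segment <- function(x) {
  cs <- cumsum(x)
  prev <- cummin(c(0, cs[-length(cs)]))   # min prefix strictly before t
  gain <- cs - prev
  to <- which.max(gain)
  if (gain[to] <= 0) return(NULL)
  from <- which(c(0, cs)[seq_len(to)] == prev[to])[1L]
  c(from = from, to = to, sum = gain[to])
}

## Minimal union-find used by single-linkage groupings.
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}
uf_components <- function(uf) {
  roots <- vapply(seq_along(uf), function(i) uf_find(uf, i), integer(1))
  match(roots, sort(unique(roots)))
}
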