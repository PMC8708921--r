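#' Plasmid records
#'
#' A `plasmid_record` is the container every stage of the pipeline operates
#' on: a (usually circular) replicon sequence together with its gene
#' annotations.  All coordinates are 1-based inclusive, following the
#' GenBank/GFF convention.  Gene features are kept in a data frame sorted by
#' start coordinate.
#'
#' @param id Accession or free-form name.
#' @param sequence DNA string over `{A,C,G,T,N}` (ambiguity codes other than
#'   N are rejected; N takes part in no match, motif or base pair).
#' @param genes A data frame of gene features as built by [gene_features()],
#'   or `NULL` for an unannotated record.
#' @param is_circular Logical; plasmids default to circular.
#' @param source Free-text provenance note.
#' @return An object of class `plasmid_record` with elements `id`,
#'   `sequence`, `length`, `is_circular`, `genes`, `source`.
#' @examples
#' rec <- plasmid_record("toy", "ACGTACGTACGT")
#' rec$length
#' @export
plasmid_record <- function(id, sequence, genes = NULL, is_circular = TRUE,
                           source = "") {
  sequence <- check_dna(sequence, what = sprintf("record '%s'", id))
  genes <- genes %||% gene_features()
  rec <- structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence), is_circular = isTRUE(is_circular),
         genes = genes, source = source),
    class = "plasmid_record")
  validate_plasmid_record(rec)
}

#' Build a gene-feature table
#'
#' @param name Locus labels (e.g. `"82c"`).
#' @param start,end 1-based inclusive coordinates; for non-wrapping features
#'   `start <= end`.  Features that wrap the replication origin carry
#'   `wraps = TRUE` and `end` beyond the plasmid length.
#' @param strand `"+"` or `"-"`.
#' @param product Free-text product description.
#' @param translation Optional amino-acid string.
#' @param wraps Logical flag for origin-wrapping features.
#' @return A data frame with one row per feature, sorted by `start`.
#' @export
gene_features <- function(name = character(), start = integer(),
                          end = integer(), strand = character(),
                          product = NA_character_,
                          translation = NA_character_, wraps = FALSE) {
  n <- length(name)
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   product = rep_len(as.character(product), n),
                   translation = rep_len(as.character(translation), n),
                   wraps = rep_len(as.logical(wraps), n),
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Validate a plasmid record
#'
#' Checks the structural invariants: sequence length bookkeeping, gene
#' intervals inside `[1, length]` (after circular normalisation), gene order
#' and translation lengths.
#'
#' @param rec A `plasmid_record`.
#' @return The record, invisibly unchanged, or an error.
#' @export
validate_plasmid_record <- function(rec) {
  stopifnot(inherits(rec, "plasmid_record"))
  if (rec$length != nchar(rec$sequence))
    stop("length field disagrees with sequence length", call. = FALSE)
  g <- rec$genes
  if (nrow(g)) {
    if (any(g$start < 1L))
      stop("gene start below 1: ", paste(g$name[g$start < 1L], collapse = ","),
           call. = FALSE)
    nonwrap <- !g$wraps
    if (any(nonwrap & (g$start > g$end)))
      stop("non-wrapping gene with start > end: ",
           paste(g$name[nonwrap & g$start > g$end], collapse = ","),
           call. = FALSE)
    if (any(nonwrap & (g$end > rec$length)))
      stop("gene interval beyond sequence end: ",
           paste(g$name[nonwrap & g$end > rec$length], collapse = ","),
           call. = FALSE)
    if (any(g$wraps) && !rec$is_circular)
      stop("wrapping feature on a linear record", call. = FALSE)
    span <- g$end - g$start + 1L
    tl <- ifelse(is.na(g$translation), 0L, nchar(g$translation))
    if (any(tl * 3L > span + 3L))
      stop("translation longer than feature span allows: ",
           paste(g$name[tl * 3L > span + 3L], collapse = ","), call. = FALSE)
    if (is.unsorted(g$start))
      stop("gene table must be sorted by start", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.plasmid_record <- function(x, ...) {
  cat(sprintf("<plasmid_record> %s: %s bp, %s, %d genes\n", x$id,
              format(x$length, big.mark = ","),
              if (x$is_circular) "circular" else "linear", nrow(x$genes)))
  invisible(x)
}

#' Extract a (possibly wrapping) subsequence
#'
#' Returns the 1-based inclusive slice `[start, end]`.  On circular records
#' `end` may exceed the length, in which case the slice wraps across the
#' replication origin.  Strand `"-"` returns the reverse complement.
#'
#' @param record A `plasmid_record`.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= length`.
#' @param strand `"+"` (default) or `"-"`.
#' @return A DNA string.
#' @examples
#' rec <- plasmid_record("toy", "ACGT")
#' subsequence(rec, 4, 5)   # wraps: "TA"
#' @export
subsequence <- function(record, start, end, strand = "+") {
  stopifnot(inherits(record, "plasmid_record"))
  L <- record$length
  if (start < 1L || start > L)
    stop(sprintf("start %d outside [1, %d]", start, L), call. = FALSE)
  if (end < start) stop("end < start", call. = FALSE)
  if (end > L) {
    if (!record$is_circular)
      stop("wraparound slice requested on a linear record", call. = FALSE)
    if (end - start + 1L > L)
      stop("slice longer than the plasmid", call. = FALSE)
    s <- paste0(substr(record$sequence, start, L),
                substr(record$sequence, 1L, end - L))
  } else {
    s <- substr(record$sequence, start, end)
  }
  if (strand == "-") s <- revcomp(s)
  s
}

## Normalise a 1-based position onto [1, L].
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L
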