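## FASTA + GFF3 input/output.  FASTA goes through Biostrings; GFF3 through
## rtracklayer, so the files interoperate with the usual genome-browser
## tooling.

#' Read a plasmid sequence with annotations
#'
#' Front end dispatching on format: either a GenBank flat file, or a FASTA
#' file paired with a GFF3 annotation.  With `format = "auto"` the file
#' extension decides (`.gb`, `.gbk`, `.genbank` vs `.fa`, `.fasta`, `.fna`).
#'
#' @param path Path to the GenBank or FASTA file.
#' @param format `"auto"`, `"genbank"` or `"fasta"`.
#' @param gff Path to the GFF3 companion (required for FASTA input when the
#'   record is annotated).
#' @param is_circular Topology for FASTA input (GenBank carries its own);
#'   plasmids default to circular.
#' @return A [plasmid_record()].
#' @export
read_plasmid <- function(path, format = c("auto", "genbank", "fasta"),
                         gff = NULL, is_circular = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "genbank") return(read_genbank(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA, found ", length(ss), " records",
         call. = FALSE)
  id <- strsplit(names(ss)[1L], "[[:space:]]+")[[1L]][1L]
  genes <- if (!is.null(gff)) read_genes_gff3(gff) else gene_features()
  plasmid_record(id, as.character(ss[[1L]]), genes = genes,
                 is_circular = is_circular,
                 source = paste("fasta:", path))
}

## CDS features from a GFF3 file -> gene_features() data frame.
read_genes_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  if (!length(gr)) return(gene_features())
  ## prefer CDS when both feature types are present
  if (any(as.character(gr$type) == "CDS"))
    gr <- gr[as.character(gr$type) == "CDS"]
  meta <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% colnames(meta))
    as.character(meta[[col]]) else rep(NA_character_, length(gr))
  name <- pick("Name")
  name[is.na(name)] <- pick("ID")[is.na(name)]
  name[is.na(name)] <- sprintf("cds_%d", which(is.na(name)))
  gene_features(name = name,
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                                "-", "+"),
                product = pick("product"),
                translation = pick("translation"))
}

#' Write a plasmid record as FASTA + GFF3
#'
#' @param record A `plasmid_record`.
#' @param fasta,gff Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_plasmid <- function(record, fasta = NULL, gff = NULL) {
  stopifnot(inherits(record, "plasmid_record"))
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(setNames(record$sequence, record$id))
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(gff)) {
    g <- record$genes
    gr <- GenomicRanges::GRanges(
      seqnames = record$id,
      ranges = IRanges::IRanges(start = g$start,
                                end = pmin(g$end, record$length)),
      strand = g$strand)
    gr$type <- "CDS"
    gr$source <- "egers"
    gr$phase <- 0L
    gr$Name <- g$name
    gr$product <- g$product
    gr$translation <- g$translation
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(c(fasta = fasta, gff = gff))
}

#' Write discovered islands as GFF3 and/or TSV
#'
#' Islands are emitted as `type=region` features with `group`, `label` and
#' mean-identity attributes, so they can be loaded next to the annotation in
#' any GFF3-aware browser.
#'
#' @param islands An island set from [find_self_repeats()], or its `$islands`
#'   data frame.
#' @param record The host `plasmid_record` (names the seqid).
#' @param gff,tsv Output paths; either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_islands <- function(islands, record, gff = NULL, tsv = NULL) {
  df <- if (is.data.frame(islands)) islands else islands$islands
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff)) {
    gr <- GenomicRanges::GRanges(
      seqnames = record$id,
      ranges = IRanges::IRanges(start = df$start,
                                end = pmin(df$end, record$length)),
      strand = df$strand %||% "+")
    gr$type <- "region"
    gr$source <- "egers"
    gr$Name <- df$label
    gr$group <- as.character(df$group)
    if (!is.null(df$mean_identity)) gr$identity <- df$mean_identity
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(c(gff = gff, tsv = tsv))
}

#' Write assembled regulons as GFF3 and/or TSV
#'
#' Each regulon contributes a `region` feature for its island and an
#' `operon` feature spanning its gene run.
#'
#' @param regulons A regulon set from [build_regulons()].
#' @param record The host `plasmid_record`.
#' @param gff,tsv Output paths; either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_regulons <- function(regulons, record, gff = NULL, tsv = NULL) {
  df <- regulons$regulons
  if (!is.null(tsv)) {
    flat <- df
    flat$genes <- vapply(df$genes, paste, character(1), collapse = ",")
    write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gff) && nrow(df)) {
    mk <- function(start, end, strand, type, name, extra) {
      gr <- GenomicRanges::GRanges(record$id,
              IRanges::IRanges(pmin(start, end), pmax(start, end)), strand)
      gr$type <- type; gr$source <- "egers"; gr$Name <- name
      gr$egers_type <- extra
      gr
    }
    isl <- mk(df$island_start, pmin(df$island_end, record$length), df$strand,
              "region", paste0("EGeRS-", df$label), as.character(df$type))
    ops <- mk(df$operon_start, pmin(df$operon_end, record$length), df$strand,
              "operon", paste0("operon-", df$label), as.character(df$type))
    rtracklayer::export(c(isl, ops), gff, format = "gff3")
  }
  invisible(c(gff = gff, tsv = tsv))
}
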