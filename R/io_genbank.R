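## GenBank flat-file input/output.
##
## A deliberately small reader covering single-record plasmid files: LOCUS
## topology, CDS features with simple or complement() locations (plus
## two-part join() across the origin, flagged as wrapping), the qualifiers
## the pipeline uses, and the ORIGIN block.  Multi-record chromosome
## assemblies are out of scope.

#' Read a plasmid from a GenBank flat file
#'
#' Parses a single-record GenBank file into a [plasmid_record()].  Gene
#' features are taken from `CDS` entries; the gene name comes from the
#' `/gene`, `/locus_tag` or `/label` qualifier (first available).
#' Circularity is read from the LOCUS line topology field and defaults to
#' circular when absent (the files this package targets are plasmids).
#'
#' @param path Path to a GenBank file.
#' @return A `plasmid_record`.
#' @seealso [read_plasmid()] for the format-dispatching front end.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank file (no LOCUS line): ", path,
                           call. = FALSE)
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  id <- if (length(toks) >= 2L) toks[2L] else basename(path)
  is_circular <- !any(grepl("\\blinear\\b", locus[1L], ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN block: ", path,
                         call. = FALSE)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_from <- grep("^FEATURES", lines)
  genes <- gene_features()
  if (length(feat_from)) {
    block <- lines[(feat_from[1L] + 1L):(ori[1L] - 1L)]
    genes <- parse_genbank_features(block, path)
  }
  rec <- plasmid_record(id, sequence, genes = genes,
                        is_circular = is_circular,
                        source = paste("genbank:", path))
  validate_plasmid_record(rec)
  rec
}

## Parse the FEATURES block; returns a gene_features() data frame of CDSs.
parse_genbank_features <- function(block, path = "") {
  key_re <- "^ {1,10}([A-Za-z_'0-9-]+) {1,}(.*)$"
  is_key <- grepl(key_re, block) & !grepl("^ {12,}", block)
  idx <- which(is_key)
  out <- list()
  for (h in seq_along(idx)) {
    i <- idx[h]
    key <- sub(key_re, "\\1", block[i])
    if (key != "CDS") next
    to <- if (h < length(idx)) idx[h + 1L] - 1L else length(block)
    body <- c(sub(key_re, "\\2", block[i]), trimws(block[(i + 1L):to]))
    if (to < i + 1L) body <- body[1L]
    ## location may continue over lines until the first qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    parsed <- parse_genbank_location(loc)
    if (is.null(parsed))
      stop(sprintf("unsupported CDS location '%s' in %s", loc, path),
           call. = FALSE)
    quals <- paste(body, collapse = "\n")
    out[[length(out) + 1L]] <- data.frame(
      name = gb_qualifier(quals, c("gene", "locus_tag", "label")) %||%
        sprintf("cds_%d", length(out) + 1L),
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      product = gb_qualifier(quals, "product") %||% NA_character_,
      translation = gb_qualifier(quals, "translation", collapse = TRUE) %||%
        NA_character_,
      wraps = parsed$wraps, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(gene_features())
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

## Extract one qualifier value (first of `keys` found); translation values
## span lines, so optionally collapse whitespace out.
gb_qualifier <- function(text, keys, collapse = FALSE) {
  for (key in keys) {
    m <- regmatches(text, regexpr(sprintf('/%s="[^"]*"', key), text))
    if (length(m) && nchar(m)) {
      val <- sub(sprintf('^/%s="', key), "", sub('"$', "", m))
      if (collapse) val <- gsub("[[:space:]\n]", "", val)
      else val <- gsub("[\n]+[[:space:]]*", " ", val)
      return(val)
    }
    m2 <- regmatches(text, regexpr(sprintf("/%s=[^\"/\n]+", key), text))
    if (length(m2) && nchar(m2))
      return(trimws(sub(sprintf("^/%s=", key), "", m2)))
  }
  NULL
}

## Supported locations: a..b, complement(a..b), and two-part
## join(a..L,1..b) (origin wrap, flagged).  Returns NULL if unsupported.
parse_genbank_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  simple <- "^([0-9]+)\\.\\.([0-9]+)$"
  if (grepl(simple, loc)) {
    return(list(start = as.integer(sub(simple, "\\1", loc)),
                end = as.integer(sub(simple, "\\2", loc)),
                strand = strand, wraps = FALSE))
  }
  joinre <- "^join\\(([0-9]+)\\.\\.([0-9]+),([0-9]+)\\.\\.([0-9]+)\\)$"
  if (grepl(joinre, loc)) {
    a <- as.integer(sub(joinre, "\\1", loc)); b <- as.integer(sub(joinre, "\\2", loc))
    c2 <- as.integer(sub(joinre, "\\3", loc)); d <- as.integer(sub(joinre, "\\4", loc))
    if (c2 == 1L)  # wrap across the origin: end stored past the length
      return(list(start = a, end = b + d, strand = strand, wraps = TRUE))
  }
  NULL
}

#' Write a plasmid record as a GenBank flat file
#'
#' Emits a minimal standards-compliant flat file: LOCUS line with topology,
#' CDS features with `/gene`, `/product` and `/translation` qualifiers, and
#' the ORIGIN sequence block.
#'
#' @param record A `plasmid_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "plasmid_record"))
  con <- file(path, "w"); on.exit(close(con))
  topo <- if (record$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2000",
                     record$id, record$length, topo), con)
  writeLines(sprintf("DEFINITION  %s.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  g <- record$genes
  for (i in seq_len(nrow(g))) {
    loc <- if (g$wraps[i]) {
      sprintf("join(%d..%d,1..%d)", g$start[i], record$length,
              g$end[i] - record$length)
    } else sprintf("%d..%d", g$start[i], g$end[i])
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /gene="%s"', g$name[i]), con)
    if (!is.na(g$product[i]))
      writeLines(sprintf('                     /product="%s"', g$product[i]), con)
    if (!is.na(g$translation[i]))
      writeLines(wrap_qualifier("translation", g$translation[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    line <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- seq(1L, nchar(line), by = 10L)
    blocks <- substring(line, tens, pmin(tens + 9L, nchar(line)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

wrap_qualifier <- function(key, value) {
  text <- sprintf('/%s="%s"', key, value)
  pieces <- substring(text, seq(1L, nchar(text), by = 58L),
                      pmin(seq(1L, nchar(text), by = 58L) + 57L, nchar(text)))
  paste0("                     ", pieces)
}
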