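## Synthetic plasmid generator.  Emits circular plasmids with planted
## regulatory islands, operons, motifs and protein families, together with
## full ground-truth tables, so every pipeline stage can be exercised and
## scored without downloads.  Defaults emulate the measured structure of
## the pLS20-family establishment regions: AT-rich backbone (GC 37.7%),
## GC-rich islands (51.4%) of 400-750 bp in 62-95% mutual identity, each
## immediately upstream of an RBS and a co-directional operon of 2-6
## genes.

#' Generator configuration
#'
#' @param plasmid_length Plasmid size in bp.
#' @param background_gc Backbone GC fraction.
#' @param island_gc Island GC fraction.
#' @param n_islands Number of island copies planted.
#' @param island_length_range Island ancestor length range, bp.
#' @param copy_identity_range Target pairwise identity band between copies,
#'   percent (per-copy divergence from the ancestor is drawn so that
#'   pairwise identities fall in this band).
#' @param internal_duplication Length (bp) of the tandem duplication
#'   planted into one copy, or `NULL` to disable; `duplication_extra`
#'   random bp are appended to the duplicated segment.
#' @param duplication_extra See above.
#' @param egers_type_mix Named proportions for island types
#'   (`c(type1 = , type2 = )`).
#' @param operon_size_range Genes per operon.
#' @param gene_length_range Protein length range, amino acids.
#' @param n_protein_families Size of the family pool used by
#'   [generate_family_panel()].
#' @param n_decoy_genes Unrelated background genes planted outside the
#'   island blocks.
#' @param n_planted_irs Inverted repeats planted into the island ancestor.
#' @param min_margin Minimum background spacing around planted blocks, bp.
#' @param indel_mode Also introduce indels when diverging copies (off by
#'   default, so planted identities stay controllable).
#' @param seed Integer seed (mandatory; the generator is fully reproducible
#'   from it).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(plasmid_length = 60000L, background_gc = 0.377,
                             island_gc = 0.514, n_islands = 5L,
                             island_length_range = c(400L, 750L),
                             copy_identity_range = c(62, 95),
                             internal_duplication = 131L,
                             duplication_extra = 9L,
                             egers_type_mix = c(type1 = 0.5, type2 = 0.5),
                             operon_size_range = c(2L, 6L),
                             gene_length_range = c(80L, 250L),
                             n_protein_families = 8L,
                             n_decoy_genes = 4L, n_planted_irs = 4L,
                             min_margin = 400L, indel_mode = FALSE,
                             seed) {
  if (missing(seed)) stop("generator_config requires a seed", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(background_gc > 0, background_gc < 1,
            island_gc > 0, island_gc < 1,
            island_length_range[1L] <= island_length_range[2L],
            copy_identity_range[1L] <= copy_identity_range[2L],
            operon_size_range[1L] <= operon_size_range[2L],
            n_islands >= 1L)
  class(cfg) <- "generator_config"
  cfg
}

## -- low-level sequence edits --------------------------------------------

## Point-mutate a fraction of positions (each to a different base drawn
## uniformly); exact count, so divergence is controlled.
mutate_dna <- function(seq, divergence) {
  n <- nchar(seq)
  d <- round(divergence * n)
  if (d == 0L) return(seq)
  v <- chars(seq)
  pos <- sample.int(n, d)
  bases <- c("A", "C", "G", "T")
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(bases, b), 1L), character(1))
  paste(v, collapse = "")
}

mutate_protein <- function(seq, divergence) {
  aas <- chars("ACDEFGHIKLMNPQRSTVWY")
  n <- nchar(seq)
  d <- round(divergence * n)
  if (d == 0L) return(seq)
  v <- chars(seq)
  pos <- sample.int(n, d)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(aas, b), 1L), character(1))
  paste(v, collapse = "")
}

## AA -> sense codons (uniform usage; the pipeline never reads codon bias).
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      gc <- gc[gc != "*"]
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

random_protein <- function(n_aa) {
  aas <- chars("ACDEFGHIKLMNPQRSTVWY")
  paste(c("M", sample(aas, n_aa - 1L, replace = TRUE)), collapse = "")
}

## Codon choice is weighted by the host base composition (product of
## per-base probabilities at the target GC), so coding regions share the
## AT-rich backbone statistics instead of standing out as GC anomalies of
## their own.
reverse_translate <- function(protein, gc = 0.377) {
  tab <- codon_table()
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  wt <- lapply(tab, function(cods)
    vapply(cods, function(cd) prod(p[chars(cd)]), numeric(1)))
  paste(vapply(chars(protein), function(a)
    sample(tab[[a]], 1L, prob = wt[[a]]), character(1)), collapse = "")
}

## Plant inverted repeats into a sequence; returns list(seq, positions df).
plant_irs <- function(seq, n_ir, gc, arm_range = c(10L, 25L),
                      loop_range = c(5L, 40L)) {
  n <- nchar(seq)
  used <- data.frame(start = integer(), end = integer())
  rows <- list()
  v <- chars(seq)
  for (t in seq_len(n_ir)) {
    for (try in 1:100) {
      arm <- sample(arm_range[1L]:arm_range[2L], 1L)
      loop <- sample(loop_range[1L]:loop_range[2L], 1L)
      span <- 2L * arm + loop
      if (span + 2L >= n) next
      p <- sample.int(n - span - 1L, 1L)
      if (nrow(used) && any(pmax(used$start, p) <=
                              pmin(used$end, p + span - 1L))) next
      armseq <- random_dna(arm, gc)
      v[p:(p + arm - 1L)] <- chars(armseq)
      v[(p + arm + loop):(p + span - 1L)] <- chars(revcomp(armseq))
      used <- rbind(used, data.frame(start = p, end = p + span - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        arm1_start = p, arm1_end = p + arm - 1L,
        arm2_start = p + arm + loop, arm2_end = p + span - 1L,
        arm_len = arm, loop_len = loop)
      break
    }
  }
  list(seq = paste(v, collapse = ""),
       irs = if (length(rows)) do.call(rbind, rows) else NULL)
}

## sigma-A promoter + dual-motif operator cassette written into a copy near
## its 3' end; returns list(seq, motifs df with island-local coordinates).
plant_type2_cassette <- function(seq) {
  n <- nchar(seq)
  spacer <- sample(16:19, 1L)
  dm <- paste0("TTATCCC", random_dna(2L, 0.5), "TTATCCC")
  cassette <- paste0(dm, random_dna(3L, 0.5), "TTGACA",
                     random_dna(spacer, 0.3), "TATAAT")
  clen <- nchar(cassette)
  p <- n - clen - 60L  # leave room between promoter and the RBS/operon
  v <- chars(seq)
  v[p:(p + clen - 1L)] <- chars(cassette)
  motifs <- data.frame(
    kind = c("DM", "minus35", "minus10"),
    start = c(p, p + 19L, p + 25L + spacer),
    end = c(p + 15L, p + 24L, p + 30L + spacer))
  list(seq = paste(v, collapse = ""), motifs = motifs)
}

## -- plasmid generation ---------------------------------------------------

#' Generate a synthetic plasmid with planted islands and ground truth
#'
#' Draws an i.i.d. backbone at the background GC, plants `n_islands`
#' diverged copies of a GC-rich, inverted-repeat-rich island ancestor, each
#' followed by a ribosome binding site and a co-directional operon of
#' random ORFs, plus unrelated decoy genes.  Type-2 islands carry a
#' sigma-A promoter with an upstream dual-motif operator.  One copy
#' optionally receives an internal tandem duplication.  Fully reproducible
#' from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `egers_sim`: `$record` (a `plasmid_record`) and
#'   `$truth` (list of data frames `islands`, `genes`, `motifs`, plus the
#'   `config`).
#' @export
generate_plasmid <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_plasmid_impl(config))
}

generate_plasmid_impl <- function(config) {
  cfg <- config
  ## island ancestor
  ilen <- sample(cfg$island_length_range[1L]:cfg$island_length_range[2L], 1L)
  anc <- random_dna(ilen, cfg$island_gc)
  planted <- plant_irs(anc, cfg$n_planted_irs, cfg$island_gc)
  anc <- planted$seq

  strand <- sample(c("+", "-"), 1L)  # islands co-oriented with operons
  div_lo <- 1 - sqrt(cfg$copy_identity_range[2L] / 100)
  div_hi <- 1 - sqrt(cfg$copy_identity_range[1L] / 100)
  mix <- cfg$egers_type_mix / sum(cfg$egers_type_mix)
  dup_copy <- if (!is.null(cfg$internal_duplication) && cfg$n_islands >= 1L)
    min(3L, cfg$n_islands) else 0L

  blocks <- list()
  for (ci in seq_len(cfg$n_islands)) {
    div <- runif(1L, div_lo, div_hi)
    iseq <- mutate_dna(anc, div)
    type <- sample(c(1L, 2L), 1L, prob = c(mix[["type1"]], mix[["type2"]]))
    ## the tandem duplication goes in first; the promoter cassette is an
    ## in-place overwrite near the (longer) 3' end, so coordinates of both
    ## stay valid and never collide
    dup <- NULL
    if (ci == dup_copy) {
      dl <- cfg$internal_duplication
      o1 <- sample.int(nchar(iseq) - 2L * dl - cfg$duplication_extra - 20L,
                       1L) + 10L
      seg <- substr(iseq, o1, o1 + dl - 1L)
      insert <- paste0(mutate_dna(seg, 0.05),
                       random_dna(cfg$duplication_extra, cfg$island_gc))
      iseq <- paste0(substr(iseq, 1L, o1 + dl - 1L), insert,
                     substr(iseq, o1 + dl, nchar(iseq)))
      dup <- data.frame(offset1 = o1, offset2 = o1 + dl, dup_len = dl)
    }
    motifs <- NULL
    if (type == 2L) {
      cass <- plant_type2_cassette(iseq)
      iseq <- cass$seq
      motifs <- cass$motifs
    }
    ## operon
    n_genes <- sample(cfg$operon_size_range[1L]:cfg$operon_size_range[2L], 1L)
    prot_len <- sample(cfg$gene_length_range[1L]:cfg$gene_length_range[2L],
                       n_genes, replace = TRUE)
    prots <- vapply(prot_len, random_protein, character(1))
    orfs <- vapply(prots, function(p)
      paste0(reverse_translate(p, cfg$background_gc), "TAA"), character(1))
    spacer <- sample(4:8, 1L)
    parts <- c(iseq, random_dna(spacer, cfg$background_gc), "AGGAGG",
               random_dna(7L, cfg$background_gc))
    gene_local <- list()
    pos <- sum(nchar(parts)) + 1L
    for (gi in seq_len(n_genes)) {
      gene_local[[gi]] <- data.frame(
        idx = gi, start = pos, end = pos + nchar(orfs[gi]) - 1L,
        translation = prots[gi])
      parts <- c(parts, orfs[gi])
      pos <- pos + nchar(orfs[gi])
      if (gi < n_genes) {
        gap <- sample(20:80, 1L)
        parts <- c(parts, random_dna(gap, cfg$background_gc))
        pos <- pos + gap
      }
    }
    blocks[[length(blocks) + 1L]] <- list(
      kind = "island", seq = paste(parts, collapse = ""),
      island_len = nchar(iseq), type = type, divergence = div,
      genes = do.call(rbind, gene_local), motifs = motifs, dup = dup,
      rbs_start = nchar(iseq) + spacer + 1L)
  }
  for (di in seq_len(cfg$n_decoy_genes)) {
    p <- random_protein(sample(cfg$gene_length_range[1L]:
                                 cfg$gene_length_range[2L], 1L))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "decoy", seq = paste0(reverse_translate(p, cfg$background_gc), "TAA"),
      translation = p,
      strand_local = sample(c("+", "-"), 1L))
  }
  blocks <- blocks[sample.int(length(blocks))]

  ## placement: split the free backbone into gaps of at least min_margin
  blens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  free <- cfg$plasmid_length - sum(blens)
  ngap <- length(blocks) + 1L
  if (free < ngap * cfg$min_margin)
    stop("infeasible packing: planted features exceed the plasmid length",
         call. = FALSE)
  extra <- free - ngap * cfg$min_margin
  gaps <- cfg$min_margin +
    as.integer(stats::rmultinom(1L, extra, rep(1, ngap)))

  seq_parts <- character(0)
  islands_truth <- list(); genes_truth <- list(); motifs_truth <- list()
  offset <- 0L
  island_counter <- 0L; decoy_counter <- 0L
  for (t in seq_along(blocks)) {
    bg <- random_dna(gaps[t], cfg$background_gc)
    seq_parts <- c(seq_parts, bg)
    offset <- offset + gaps[t]
    b <- blocks[[t]]
    blen <- nchar(b$seq)
    if (b$kind == "island") {
      island_counter <- island_counter + 1L
      lab <- LETTERS[island_counter]
      flip <- strand == "-"
      bseq <- if (flip) revcomp(b$seq) else b$seq
      loc <- function(s, e) {  # local (forward-sense) -> global coords
        if (flip) c(offset + blen - e + 1L, offset + blen - s + 1L)
        else c(offset + s, offset + e)
      }
      isl <- loc(1L, b$island_len)
      islands_truth[[island_counter]] <- data.frame(
        label = lab, start = isl[1L], end = isl[2L], strand = strand,
        type = b$type, divergence = b$divergence,
        has_dup = !is.null(b$dup),
        dup_offset1 = if (!is.null(b$dup)) b$dup$offset1 else NA_integer_,
        dup_offset2 = if (!is.null(b$dup)) b$dup$offset2 else NA_integer_,
        dup_len = if (!is.null(b$dup)) b$dup$dup_len else NA_integer_,
        stringsAsFactors = FALSE)
      g <- b$genes
      for (gi in seq_len(nrow(g))) {
        gg <- loc(g$start[gi], g$end[gi])
        genes_truth[[length(genes_truth) + 1L]] <- data.frame(
          name = sprintf("%s%d", tolower(lab), g$idx[gi]),
          start = gg[1L], end = gg[2L], strand = strand, operon = lab,
          family = NA_character_, translation = g$translation[gi],
          product = "putative establishment protein",
          stringsAsFactors = FALSE)
      }
      rbs <- loc(b$rbs_start, b$rbs_start + 5L)
      motifs_truth[[length(motifs_truth) + 1L]] <- data.frame(
        kind = "RBS", island = lab, start = rbs[1L], end = rbs[2L],
        strand = strand, stringsAsFactors = FALSE)
      if (!is.null(b$motifs)) {
        for (mi in seq_len(nrow(b$motifs))) {
          mm <- loc(b$motifs$start[mi], b$motifs$end[mi])
          motifs_truth[[length(motifs_truth) + 1L]] <- data.frame(
            kind = b$motifs$kind[mi], island = lab, start = mm[1L],
            end = mm[2L], strand = strand, stringsAsFactors = FALSE)
        }
      }
      seq_parts <- c(seq_parts, bseq)
    } else {
      decoy_counter <- decoy_counter + 1L
      flip <- b$strand_local == "-"
      bseq <- if (flip) revcomp(b$seq) else b$seq
      genes_truth[[length(genes_truth) + 1L]] <- data.frame(
        name = sprintf("dec%d", decoy_counter), start = offset + 1L,
        end = offset + blen, strand = b$strand_local, operon = NA_character_,
        family = NA_character_, translation = b$translation,
        product = "hypothetical protein", stringsAsFactors = FALSE)
      seq_parts <- c(seq_parts, bseq)
    }
    offset <- offset + blen
  }
  seq_parts <- c(seq_parts, random_dna(cfg$plasmid_length - offset,
                                       cfg$background_gc))
  sequence <- paste(seq_parts, collapse = "")

  genes <- do.call(rbind, genes_truth)
  record <- plasmid_record(
    sprintf("sim%06d", cfg$seed %% 1000000L), sequence,
    genes = gene_features(name = genes$name, start = genes$start,
                          end = genes$end, strand = genes$strand,
                          product = genes$product,
                          translation = genes$translation),
    is_circular = TRUE, source = "egers synthetic generator")
  truth <- list(islands = do.call(rbind, islands_truth),
                genes = genes,
                motifs = do.call(rbind, motifs_truth),
                config = cfg)
  structure(list(record = record, truth = truth), class = "egers_sim")
}

#' @export
print.egers_sim <- function(x, ...) {
  cat(sprintf("<egers_sim> %s: %d planted islands, %d genes\n",
              x$record$id, nrow(x$truth$islands), nrow(x$truth$genes)))
  invisible(x)
}

#' Generate a panel of plasmids sharing protein families
#'
#' Emulates the conserved-core pattern of closely related plasmid clades:
#' every plasmid carries one diverged member (70-90% amino-acid identity
#' to the family ancestor) of each universal family (the ardC/reg
#' pattern), a draw from a pool of partially shared accessory families
#' (each on at least two plasmids), and one or two unique proteins.
#'
#' @param n_plasmids Number of plasmids.
#' @param universal_families Families present on every plasmid.
#' @param config A [generator_config()] (supplies the seed, family pool
#'   size, and gene length range).
#' @return List of class `egers_panel`: `$records`, `$truth` (data frame
#'   `plasmid`, `gene`, `family`).
#' @export
generate_family_panel <- function(n_plasmids = 7L, universal_families = 2L,
                                  config) {
  stopifnot(inherits(config, "generator_config"), universal_families >= 0L)
  withr::with_seed(config$seed, {
    cfg <- config
    n_acc <- max(0L, cfg$n_protein_families - universal_families)
    lens <- function(n) sample(cfg$gene_length_range[1L]:
                                 cfg$gene_length_range[2L], n, replace = TRUE)
    fam_anc <- c(
      setNames(vapply(lens(universal_families), random_protein, character(1)),
               if (universal_families) paste0("U", seq_len(universal_families))
               else character(0)),
      setNames(vapply(lens(n_acc), random_protein, character(1)),
               if (n_acc) paste0("F", seq_len(n_acc)) else character(0)))
    acc_names <- grep("^F", names(fam_anc), value = TRUE)
    acc_on <- lapply(acc_names, function(f)
      sort(sample.int(n_plasmids, sample(2:max(2L, n_plasmids - 1L), 1L))))
    names(acc_on) <- acc_names

    records <- list(); truth <- list()
    for (p in seq_len(n_plasmids)) {
      pid <- sprintf("panel%02d", p)
      fams <- c(names(fam_anc)[seq_len(universal_families)],
                acc_names[vapply(acc_on, function(v) p %in% v, logical(1))])
      prots <- character(0); famv <- character(0)
      for (f in fams) {
        div <- 1 - runif(1L, 0.70, 0.90)
        prots <- c(prots, mutate_protein(fam_anc[[f]], div))
        famv <- c(famv, f)
      }
      for (u in seq_len(sample(1:2, 1L))) {
        prots <- c(prots, random_protein(lens(1L)))
        famv <- c(famv, sprintf("S_%s_%d", pid, u))
      }
      ## lay the genes head-to-tail with 100 bp spacers
      orfs <- vapply(prots, function(x)
        paste0(reverse_translate(x, cfg$background_gc), "TAA"), character(1))
      gaps <- rep(100L, length(orfs))
      starts <- cumsum(c(200L, head(nchar(orfs) + gaps, -1L)))
      ends <- starts + nchar(orfs) - 1L
      seqlen <- ends[length(ends)] + 200L
      v <- chars(random_dna(seqlen, cfg$background_gc))
      for (gi in seq_along(orfs))
        v[starts[gi]:ends[gi]] <- chars(orfs[gi])
      gnames <- sprintf("p%02dg%02d", p, seq_along(orfs))
      records[[pid]] <- plasmid_record(
        pid, paste(v, collapse = ""),
        genes = gene_features(name = gnames, start = starts, end = ends,
                              strand = "+", product = famv,
                              translation = unname(prots)),
        is_circular = TRUE, source = "egers synthetic panel")
      truth[[pid]] <- data.frame(plasmid = pid, gene = gnames,
                                 family = famv, stringsAsFactors = FALSE)
    }
    structure(list(records = records, truth = do.call(rbind, truth)),
              class = "egers_panel")
  })
}

#' @export
print.egers_panel <- function(x, ...) {
  cat(sprintf("<egers_panel> %d plasmids, %d proteins, %d families\n",
              length(x$records), nrow(x$truth),
              length(unique(x$truth$family))))
  invisible(x)
}

#' Write a simulated plasmid and its truth tables to disk
#'
#' @param sim An `egers_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (GenBank, GFF3, truth TSVs and a
#'   JSON config echo).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "egers_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$record$id
  paths <- c(
    genbank = file.path(dir, paste0(id, ".gbk")),
    gff = file.path(dir, paste0(id, ".gff3")),
    islands = file.path(dir, paste0(id, ".truth_islands.tsv")),
    genes = file.path(dir, paste0(id, ".truth_genes.tsv")),
    motifs = file.path(dir, paste0(id, ".truth_motifs.tsv")),
    config = file.path(dir, paste0(id, ".config.json")))
  write_genbank(sim$record, paths[["genbank"]])
  write_plasmid(sim$record, gff = paths[["gff"]])
  write.table(sim$truth$islands, paths[["islands"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, paths[["genes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$motifs, paths[["motifs"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$truth$config
  cfg$egers_type_mix <- as.list(cfg$egers_type_mix)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}
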