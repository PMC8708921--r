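## End-to-end orchestration: islands -> features -> classification ->
## regulons per plasmid; protein clustering and island phylogenetics
## across plasmids.  Every stage writes a tabular artifact plus a JSON
## summary carrying the exact parameters and seed used.

#' Analyse one plasmid end to end
#'
#' Runs island discovery, computes classification evidence for every
#' island, and assembles the establishment regulons.
#'
#' @param record A `plasmid_record`.
#' @param k,min_len,min_identity,gap_tol Island discovery parameters (see
#'   [find_self_repeats()]).
#' @param thresholds Classification thresholds ([egers_thresholds()]).
#' @param max_rbs_distance,max_gap Regulon assembly parameters
#'   ([build_regulons()]).
#' @param min_dup Internal duplications of at least this many bp are
#'   searched for within every island.
#' @return A list of class `plasmid_analysis`: `$islands`
#'   (`repeat_islands`), `$calls` (list of `egers_call`), `$regulons`
#'   (`regulon_set`), `$duplications` (per-island data frames).
#' @export
analyse_plasmid <- function(record, k = 12L, min_len = 300L,
                            min_identity = 60, gap_tol = 100L,
                            thresholds = egers_thresholds(),
                            max_rbs_distance = 300L, max_gap = 150L,
                            min_dup = 100L) {
  isl <- find_self_repeats(record, k = k, min_len = min_len,
                           min_identity = min_identity, gap_tol = gap_tol)
  df <- isl$islands
  calls <- list(); dups <- list()
  for (t in seq_len(nrow(df))) {
    strand <- infer_island_strand(record, df$start[t], df$end[t],
                                  max_rbs_distance)
    calls[[df$label[t]]] <- classify_egers(
      record, df$start[t], df$end[t], strand = strand,
      thresholds = thresholds,
      all_islands = df[, c("start", "end")])
    dups[[df$label[t]]] <- find_internal_duplication(
      record, df$start[t], df$end[t], min_dup = min_dup,
      min_identity = min_identity)
  }
  reg <- build_regulons(record, calls, max_rbs_distance = max_rbs_distance,
                        max_gap = max_gap)
  structure(list(record_id = record$id, islands = isl, calls = calls,
                 regulons = reg, duplications = dups),
            class = "plasmid_analysis")
}

## Orientation of the operon an island feeds: the strand of the nearest
## annotated gene transcribed away from the island within `max_dist` bp
## (+ preferred on ties; "+" when no gene is in range).  `overlap_tol`
## absorbs boundary fuzziness of discovered islands, as in
## build_regulons().
infer_island_strand <- function(record, start, end, max_dist = 300L,
                                overlap_tol = 30L) {
  g <- record$genes
  if (!nrow(g)) return("+")
  fwd <- g[g$strand == "+" & g$start > end - overlap_tol &
             g$start - end - 1L <= max_dist, , drop = FALSE]
  rev <- g[g$strand == "-" & g$end < start + overlap_tol &
             start - g$end - 1L <= max_dist, , drop = FALSE]
  df <- if (nrow(fwd)) max(0L, min(fwd$start) - end - 1L) else NA_integer_
  dr <- if (nrow(rev)) max(0L, start - max(rev$end) - 1L) else NA_integer_
  if (is.na(dr) && is.na(df)) return("+")
  if (is.na(dr) || (!is.na(df) && df <= dr)) "+" else "-"
}

#' @export
print.plasmid_analysis <- function(x, ...) {
  cat(sprintf("<plasmid_analysis> %s: %d islands, %d regulons\n",
              x$record_id, nrow(x$islands$islands), nrow(x$regulons$regulons)))
  invisible(x)
}

#' Pipeline configuration
#'
#' A single validated configuration covering every stage; any unset block
#' keeps the per-stage documented defaults.
#'
#' @param inputs Character vector of input files (GenBank, or FASTA with a
#'   `.gff3` sibling); may be empty when `simulate` is set.
#' @param out_dir Output directory.
#' @param seed Integer seed (used by simulation and bootstrap stages).
#' @param simulate `NULL`, or a list of [generator_config()] arguments;
#'   generated plasmids are analysed in place of `inputs`.
#' @param stages Character subset of
#'   `c("islands", "regulons", "cluster", "phylo")`.
#' @param islands,classify,regulons,cluster,phylo Per-stage parameter
#'   lists overriding the defaults.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = character(), out_dir = "egers_out",
                            seed = 1L, simulate = NULL,
                            stages = c("islands", "regulons", "cluster",
                                       "phylo"),
                            islands = list(), classify = list(),
                            regulons = list(), cluster = list(),
                            phylo = list(), log_level = "info") {
  cfg <- as.list(environment())
  bad <- setdiff(stages, c("islands", "regulons", "cluster", "phylo"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ","),
                        call. = FALSE)
  if (!is.null(simulate) && !is.list(simulate))
    stop("config field 'simulate' must be a list of generator arguments",
         call. = FALSE)
  if (is.null(simulate)) {
    if (!length(inputs))
      stop("config field 'inputs' is empty and no simulation is requested",
           call. = FALSE)
    missing_files <- inputs[!file.exists(inputs)]
    if (length(missing_files))
      stop("config field 'inputs' names missing file(s): ",
           paste(missing_files, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_log <- function(cfg, level, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message(sprintf("[egers %s] ", level), ...)
}

#' Run the full pipeline
#'
#' Stages run in dependency order: input (or simulation) -> island
#' discovery -> classification -> regulons per plasmid; then protein
#' clustering and the island phylogeny across plasmids.  A failure on one
#' plasmid is logged and reported without aborting the batch.  Every
#' artifact is written under `config$out_dir` together with JSON summaries
#' recording parameters and seed.
#'
#' @param config A [pipeline_config()].
#' @return A report list: per-plasmid analyses, clustering, tree, paths of
#'   artifacts written, and any per-plasmid errors.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- list()
  if (!is.null(cfg$simulate)) {
    n_sim <- cfg$simulate$n_plasmids %||% 1L
    simargs <- cfg$simulate
    simargs$n_plasmids <- NULL
    for (t in seq_len(n_sim)) {
      simargs$seed <- (cfg$seed + t - 1L) %% .Machine$integer.max
      sim <- generate_plasmid(do.call(generator_config, simargs))
      records[[sim$record$id]] <- sim$record
      write_simulation(sim, file.path(cfg$out_dir, "simulated"))
    }
    pipe_log(cfg, "info", sprintf("simulated %d plasmid(s)", n_sim))
  }
  read_errors <- list()
  if (is.null(cfg$simulate)) {
    for (p in cfg$inputs) {
      gff <- sub("\\.(fa|fasta|fna)$", ".gff3", p, ignore.case = TRUE)
      rec <- tryCatch({
        if (grepl("\\.(fa|fasta|fna)$", p, ignore.case = TRUE) &&
              file.exists(gff))
          read_plasmid(p, "fasta", gff = gff) else read_plasmid(p)
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        read_errors[[basename(p)]] <- conditionMessage(rec)
        pipe_log(cfg, "info", sprintf("input %s failed: %s", p,
                                      conditionMessage(rec)))
        next
      }
      records[[rec$id]] <- rec
    }
    pipe_log(cfg, "info", sprintf("read %d plasmid(s)", length(records)))
  }

  analyses <- list(); errors <- read_errors
  if ("islands" %in% cfg$stages) {
    for (id in names(records)) {
      res <- tryCatch(
        do.call(analyse_plasmid, c(list(records[[id]]), cfg$islands)),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[id]] <- conditionMessage(res)
        pipe_log(cfg, "info", sprintf("plasmid %s failed: %s", id,
                                      conditionMessage(res)))
        next
      }
      analyses[[id]] <- res
      write_islands(res$islands, records[[id]],
                    gff = file.path(cfg$out_dir, paste0(id, ".islands.gff3")),
                    tsv = file.path(cfg$out_dir, paste0(id, ".islands.tsv")))
      if ("regulons" %in% cfg$stages)
        write_regulons(res$regulons, records[[id]],
                       gff = file.path(cfg$out_dir, paste0(id, ".regulons.gff3")),
                       tsv = file.path(cfg$out_dir, paste0(id, ".regulons.tsv")))
      pipe_log(cfg, "info", sprintf(
        "%s: %d islands, %d regulons", id, nrow(res$islands$islands),
        nrow(res$regulons$regulons)))
    }
  }

  clustering <- NULL
  if ("cluster" %in% cfg$stages) {
    prot <- proteins_from_records(records)
    if (!is.null(prot) && nrow(prot) >= 2L) {
      clustering <- do.call(cluster_homologs, c(list(prot), cfg$cluster))
      pa <- presence_absence(clustering)
      write.table(clustering$clusters,
                  file.path(cfg$out_dir, "clusters.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(cluster = rownames(pa), pa,
                             check.names = FALSE),
                  file.path(cfg$out_dir, "presence_absence.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      pipe_log(cfg, "info", sprintf("clustered %d proteins into %d clusters",
                                    nrow(prot), clustering$n_clusters))
    }
  }

  tree <- NULL
  if ("phylo" %in% cfg$stages && length(analyses)) {
    seqs <- character(0)
    for (id in names(analyses)) {
      idf <- analyses[[id]]$islands$islands
      for (t in seq_len(nrow(idf))) {
        strand <- analyses[[id]]$calls[[idf$label[t]]]$strand
        seqs[paste0(id, "_", idf$label[t])] <-
          subsequence(records[[id]], idf$start[t], idf$end[t], strand)
      }
    }
    if (length(seqs) >= 3L) {
      phy_args <- cfg$phylo
      n_reps <- phy_args$n_reps %||% 200L
      aln <- progressive_align(seqs)
      tree <- bootstrap_supports(aln, n_reps = n_reps, seed = cfg$seed)
      tree <- midpoint_root(tree)
      write_msa_fasta(aln, file.path(cfg$out_dir, "islands.aln.fasta"))
      ape::write.tree(tree, file.path(cfg$out_dir, "islands.nj.nwk"))
      pipe_log(cfg, "info", sprintf(
        "phylogeny over %d island sequences (%d bootstrap replicates)",
        length(seqs), n_reps))
    }
  }

  report <- list(
    parameters = unclass(cfg), seed = cfg$seed,
    n_plasmids = length(records),
    islands = lapply(analyses, function(a) a$islands$islands),
    regulons = lapply(analyses, function(a) a$regulons$regulons),
    clustering = if (!is.null(clustering))
      list(n_clusters = clustering$n_clusters,
           n_multi = clustering$n_multi) else NULL,
    tree_file = if (!is.null(tree))
      file.path(cfg$out_dir, "islands.nj.nwk") else NULL,
    errors = errors)
  summary_path <- file.path(cfg$out_dir, "pipeline_summary.json")
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         n_plasmids = length(records),
         n_islands = vapply(analyses, function(a)
           nrow(a$islands$islands), integer(1)),
         n_regulons = vapply(analyses, function(a)
           nrow(a$regulons$regulons), integer(1)),
         clustering = report$clustering,
         errors = errors,
         parameters = list(islands = cfg$islands, cluster = cfg$cluster,
                           phylo = cfg$phylo)),
    summary_path, auto_unbox = TRUE, null = "null", digits = NA)
  pipe_log(cfg, "info", "summary written to ", summary_path)
  invisible(c(report, list(analyses = analyses, clustering = clustering,
                           tree = tree)))
}
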