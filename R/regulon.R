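## Regulon assembly: islands joined to their downstream operons and
## classified as EGeRS type 1 (long, GC-rich, inverted-repeat-rich,
## promoterless) or type 2 (sigma-A promoter flanked by dual-heptamer Reg
## operators).

#' Classification thresholds for EGeRS calls
#'
#' @param gc_z Minimum GC z-score for a type-1 call.
#' @param n_ir Minimum number of inverted repeats for a type-1 call.
#' @param promoter_budget Mismatch budget used when scanning for promoters.
#' @param qualifying_score A promoter with at most this many consensus
#'   mismatches disqualifies a type-1 call (a near-consensus constitutive
#'   promoter; looser scores are too frequent in GC-rich background to be
#'   evidence on their own).
#' @param dm_budget Mismatch budget for the dual-motif operator scan.
#' @param dm_distance Maximum distance (bp) between a dual motif and the
#'   promoter boxes for the "operator flanks promoter" requirement of a
#'   type-2 call.
#' @param flank Context (bp) added on each side of the island before
#'   evidence is computed.
#' @param gc_window,gc_step Background window geometry for the GC null.
#' @param ir_min_arm,ir_max_loop,ir_max_mismatch Inverted-repeat scan
#'   parameters.
#' @return A named list of thresholds.
#' @export
egers_thresholds <- function(gc_z = 2, n_ir = 3L, promoter_budget = 3L,
                             qualifying_score = 1L, dm_budget = 1L,
                             dm_distance = 30L, flank = 100L,
                             gc_window = 500L, gc_step = 100L,
                             ir_min_arm = 8L, ir_max_loop = 150L,
                             ir_max_mismatch = 1L) {
  as.list(environment())
}

#' Classify an island as EGeRS type 1, type 2 or unclassified
#'
#' Evidence is computed on the island plus `flank` bp of context, on the
#' island strand.  The decision rule:
#' type 2 requires at least one dual motif adjacent to a sigma-A promoter
#' call (motif 3' end within `dm_distance` bp upstream of the -35 box, or
#' motif start within `dm_distance` bp downstream of the -10 box); type 1
#' requires GC z-score and inverted-repeat count above threshold and no
#' qualifying promoter; anything else is unclassified, never a guess.
#'
#' @param record Host `plasmid_record`.
#' @param start,end Island interval (1-based inclusive; `end` may wrap).
#' @param strand Island orientation (`"+"` or `"-"`): the strand of the
#'   downstream operon.
#' @param thresholds From [egers_thresholds()].
#' @param all_islands Optional data frame of every candidate island
#'   (`start`, `end`), excluded from the GC background.
#' @return An object of class `egers_call`: `type` (1, 2 or NA for
#'   unclassified), `gc_z`, `n_inverted_repeats`, `dm_hits`, `promoters`,
#'   `inverted_repeats`, and the interval.
#' @export
classify_egers <- function(record, start, end, strand = "+",
                           thresholds = egers_thresholds(),
                           all_islands = NULL) {
  th <- thresholds
  L <- record$length
  ctx_start <- max(1L, start - th$flank)
  ctx_end <- min(end + th$flank, if (record$is_circular) start + L - 1L else L)
  ctx_fwd <- subsequence(record, ctx_start, ctx_end)  # forward orientation
  ctx <- if (strand == "-") revcomp(ctx_fwd) else ctx_fwd

  gc <- gc_zscore(record, start, end, window = th$gc_window,
                  step = th$gc_step,
                  exclude = all_islands %||% data.frame(start = start, end = end))
  irs <- find_inverted_repeats(ctx, min_arm = th$ir_min_arm,
                               max_loop = th$ir_max_loop,
                               max_mismatch = th$ir_max_mismatch)
  dms <- scan_motif(ctx, DM_PATTERN, max_mismatch = th$dm_budget,
                    strands = "+", motif_name = "DM")
  prom <- find_sigmaA_promoters(ctx, max_total_mismatch = th$promoter_budget)

  ## operator-adjacent promoter => type 2
  type2 <- FALSE
  if (nrow(dms) && nrow(prom)) {
    for (pi in seq_len(nrow(prom))) {
      m35 <- prom$minus35_start[pi]
      m10e <- prom$minus10_start[pi] + 5L
      gap_up <- m35 - dms$end            # DM 3' end upstream of the -35 box
      gap_dn <- dms$start - m10e         # DM downstream of the -10 box
      if (any(gap_up >= 1L & gap_up <= th$dm_distance) ||
          any(gap_dn >= 1L & gap_dn <= th$dm_distance)) { type2 <- TRUE; break }
    }
  }
  qualifying <- nrow(prom) > 0L && min(prom$score) <= th$qualifying_score
  type <- if (type2) 2L
          else if (gc$z_score >= th$gc_z && nrow(irs) >= th$n_ir && !qualifying)
            1L else NA_integer_

  structure(list(plasmid_id = record$id, start = start, end = end,
                 strand = strand, type = type, gc_z = gc$z_score,
                 region_gc = gc$region_gc, background_gc = gc$background_gc,
                 n_inverted_repeats = nrow(irs), inverted_repeats = irs,
                 dm_hits = dms, promoters = prom,
                 thresholds = th),
            class = "egers_call")
}

#' @export
print.egers_call <- function(x, ...) {
  cat(sprintf(
    "<egers_call> %s:%d-%d(%s) type=%s gc_z=%.1f IRs=%d DMs=%d promoters=%d\n",
    x$plasmid_id, x$start, x$end, x$strand,
    if (is.na(x$type)) "unclassified" else x$type, x$gc_z,
    x$n_inverted_repeats, nrow(x$dm_hits), nrow(x$promoters)))
  invisible(x)
}

#' Assemble the operon downstream of an anchor gene
#'
#' Starting from `anchor_gene`, extends along its strand, adding
#' co-directional genes while the intergenic gap stays within `max_gap`;
#' stops at a strand switch or gap violation.
#'
#' @param record A `plasmid_record`.
#' @param anchor_gene Gene name present in `record$genes`.
#' @param max_gap Maximum intergenic gap in bp.
#' @return An object of class `operon`: `genes` (ordered names in
#'   transcription direction), `strand`, `first_gene_start`, `start`, `end`
#'   (bp span), `plasmid_id`.
#' @export
assemble_operon <- function(record, anchor_gene, max_gap = 150L) {
  g <- record$genes
  i <- which(g$name == anchor_gene)
  if (!length(i)) stop("anchor gene not found: ", anchor_gene, call. = FALSE)
  i <- i[1L]
  strand <- g$strand[i]
  members <- i
  repeat {
    cur <- members[length(members)]
    if (strand == "+") {
      nxt <- which(g$start > g$end[cur])
      nxt <- nxt[order(g$start[nxt])]
      if (!length(nxt)) break
      nxt <- nxt[1L]
      gap <- g$start[nxt] - g$end[cur] - 1L
    } else {
      nxt <- which(g$end < g$start[cur])
      nxt <- nxt[order(-g$end[nxt])]
      if (!length(nxt)) break
      nxt <- nxt[1L]
      gap <- g$start[cur] - g$end[nxt] - 1L
    }
    if (gap > max_gap || g$strand[nxt] != strand) break
    members <- c(members, nxt)
  }
  rows <- g[members, , drop = FALSE]
  structure(list(plasmid_id = record$id, genes = rows$name, strand = strand,
                 first_gene_start = g$start[i],
                 start = min(rows$start), end = max(rows$end),
                 table = rows),
            class = "operon")
}

#' @export
print.operon <- function(x, ...) {
  cat(sprintf("<operon> %s (%s): %s\n", x$plasmid_id, x$strand,
              paste(x$genes, collapse = "-")))
  invisible(x)
}

#' Join classified islands to their downstream operons
#'
#' Each island is paired with the nearest gene downstream on its own strand
#' (transcribed away from the island) within `max_rbs_distance` bp; the
#' operon is assembled from that gene and a ribosome-binding-site hit is
#' looked for in the gap.  Islands with no downstream gene in range are
#' reported unpaired.  Labels `A`, `B`, ... follow plasmid position.
#'
#' @param record A `plasmid_record`.
#' @param calls List of `egers_call` objects (or a `repeat_islands` object
#'   plus `strand`, classified internally with default thresholds).
#' @param max_rbs_distance Maximum island-to-gene distance, bp.
#' @param max_gap Operon extension gap, bp.
#' @param rbs_max_mismatch Mismatch budget for the RBS motif.
#' @param overlap_tol Discovered island boundaries are fuzzy by a few bp;
#'   a gene whose start lies up to this many bp inside the island 3' end
#'   still counts as downstream.
#' @return An object of class `regulon_set`: `$regulons` (data frame with
#'   `label`, `type`, island and operon coordinates, `genes` list-column,
#'   `n_genes`, `distance_to_rbs`) and `$unpaired` (island intervals left
#'   without an operon).
#' @export
build_regulons <- function(record, calls, max_rbs_distance = 300L,
                           max_gap = 150L, rbs_max_mismatch = 1L,
                           overlap_tol = 30L) {
  stopifnot(inherits(record, "plasmid_record"))
  if (inherits(calls, "egers_call")) calls <- list(calls)
  g <- record$genes
  used_genes <- character()
  rows <- list(); unpaired <- list()
  ord <- order(vapply(calls, function(x) x$start, numeric(1)))
  calls <- calls[ord]
  for (x in calls) {
    strand <- x$strand
    if (strand == "+") {
      cand <- which(g$strand == "+" & g$start > x$end - overlap_tol &
                      g$start - x$end - 1L <= max_rbs_distance)
      cand <- cand[order(g$start[cand])]
    } else {
      cand <- which(g$strand == "-" & g$end < x$start + overlap_tol &
                      x$start - g$end - 1L <= max_rbs_distance)
      cand <- cand[order(-g$end[cand])]
    }
    if (!length(cand)) {
      unpaired[[length(unpaired) + 1L]] <-
        data.frame(start = x$start, end = x$end, strand = strand)
      next
    }
    anchor <- cand[1L]
    op <- assemble_operon(record, g$name[anchor], max_gap = max_gap)
    ## RBS in the island-to-gene gap, island strand
    dist0 <- if (strand == "+") g$start[anchor] - x$end - 1L
             else x$start - g$end[anchor] - 1L
    gap_seq <- if (dist0 < 6L) ""
    else if (strand == "+")
      subsequence(record, x$end + 1L, g$start[anchor] - 1L, "+")
    else subsequence(record, g$end[anchor] + 1L, x$start - 1L, "-")
    rbs <- if (nchar(gap_seq) >= 6L)
      scan_motif(gap_seq, RBS_PATTERN, max_mismatch = rbs_max_mismatch,
                 strands = "+", motif_name = "RBS")
    else data.frame()
    dist <- if (strand == "+") g$start[anchor] - x$end - 1L
            else x$start - g$end[anchor] - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      plasmid_id = record$id, label = NA_character_,
      type = x$type, island_start = x$start, island_end = x$end,
      strand = strand, operon_start = op$start, operon_end = op$end,
      first_gene = op$genes[1L], n_genes = length(op$genes),
      distance_to_rbs = dist, has_rbs = nrow(rbs) > 0L,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$genes <- I(list(op$genes))
    used_genes <- c(used_genes, op$genes)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df$label <- LETTERS[seq_len(nrow(df))]
    ## no gene may appear in two regulons of one plasmid
    dup <- duplicated(unlist(df$genes))
    if (any(dup))
      warning("gene(s) shared between regulons: ",
              paste(unique(unlist(df$genes)[dup]), collapse = ","))
  } else {
    df <- data.frame(plasmid_id = character(), label = character(),
                     type = integer(), island_start = integer(),
                     island_end = integer(), strand = character(),
                     operon_start = integer(), operon_end = integer(),
                     first_gene = character(), n_genes = integer(),
                     distance_to_rbs = integer(), has_rbs = logical(),
                     stringsAsFactors = FALSE)
    df$genes <- I(list())
  }
  structure(list(regulons = df,
                 unpaired = if (length(unpaired)) do.call(rbind, unpaired)
                            else data.frame(start = integer(),
                                            end = integer(),
                                            strand = character())),
            class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("<regulon_set> %d regulons (%d genes), %d unpaired islands\n",
              nrow(x$regulons), sum(x$regulons$n_genes),
              nrow(x$unpaired)))
  invisible(x)
}
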