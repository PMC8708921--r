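## Island characterisation: GC anomaly, inverted repeats, a base-pairing
## stem score, and motif scans (RBS, sigma-A promoter, dual-heptamer
## operator).

#' Canonical motifs
#'
#' `DM_PATTERN` is the dual-heptamer repressor operator
#' `5'-TTATCCCnnTTATCCC-3'` bound co-operatively by the ribbon-helix-helix
#' repressor Reg; `RBS_PATTERN` is the Shine-Dalgarno consensus used for
#' ribosome-binding-site calls.
#' @name motifs
#' @export
DM_PATTERN <- "TTATCCCNNTTATCCC"

#' @rdname motifs
#' @export
RBS_PATTERN <- "AGGAGG"

#' GC content of a DNA string
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N is excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("GGCC")  # 1
#' @export
gc_content <- function(seq) {
  seq <- check_dna(seq)
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0L) stop("gc_content undefined: sequence is all N", call. = FALSE)
  unname((f[["G"]] + f[["C"]]) / tot)
}

#' Sliding-window GC profile of a plasmid
#'
#' Windows of `window` bp advanced by `step` bp over the full (circular)
#' plasmid; windows overlapping any `exclude` interval are dropped, so the
#' background distribution can be computed without candidate islands.
#'
#' @param record A `plasmid_record`.
#' @param window,step Window and step sizes in bp.
#' @param exclude Optional data frame with `start`, `end` columns (1-based
#'   inclusive; `end` may wrap past the length).
#' @return A data frame `start`, `end`, `gc`.
#' @export
gc_profile <- function(record, window = 500L, step = 100L, exclude = NULL) {
  L <- record$length
  s <- if (record$is_circular)
    paste0(record$sequence, substr(record$sequence, 1L, window)) else
      record$sequence
  v <- chars(s)
  isgc <- as.integer(v == "G" | v == "C")
  isbase <- as.integer(v != "N")
  cgc <- cumsum(isgc); cb <- cumsum(isbase)
  starts <- seq(1L, if (record$is_circular) L else L - window + 1L, by = step)
  ends <- starts + window - 1L
  gc <- (cgc[ends] - ifelse(starts > 1L, cgc[starts - 1L], 0)) /
    pmax(1L, cb[ends] - ifelse(starts > 1L, cb[starts - 1L], 0))
  df <- data.frame(start = starts, end = ends, gc = gc)
  if (!is.null(exclude) && nrow(exclude)) {
    hit <- rep(FALSE, nrow(df))
    for (r in seq_len(nrow(exclude))) {
      es <- exclude$start[r]; ee <- exclude$end[r]
      hit <- hit | (df$start <= ee & df$end >= es)
      if (ee > L)  # wrapping exclusion also masks the origin-proximal windows
        hit <- hit | (df$end >= 1L & df$start <= ee - L)
    }
    df <- df[!hit, , drop = FALSE]
  }
  df
}

#' GC z-score of a region against the host-plasmid background
#'
#' The background null is the sliding-window GC distribution of the host
#' plasmid (candidate islands excluded); the z-score is
#' `(region GC - mean) / sd` of that distribution.
#'
#' @param record A `plasmid_record`.
#' @param start,end Region, 1-based inclusive (may wrap on circular records).
#' @param window,step Background window geometry.
#' @param exclude Intervals excluded from the background (typically all
#'   candidate islands, including the one being scored).
#' @return A list with class `gc_profile_z`: `region_gc`, `background_gc`
#'   (mean), `background_sd`, `z_score`, `window`, `step`, `values`.
#' @export
gc_zscore <- function(record, start, end, window = 500L, step = 100L,
                      exclude = NULL) {
  prof <- gc_profile(record, window, step, exclude = exclude)
  if (nrow(prof) < 5L)
    stop("too few background windows for a GC null", call. = FALSE)
  region_gc <- gc_content(subsequence(record, start, end))
  mu <- mean(prof$gc); sdev <- sd(prof$gc)
  structure(list(window = window, step = step, values = prof$gc,
                 region_gc = region_gc, background_gc = mu,
                 background_sd = sdev,
                 z_score = (region_gc - mu) / sdev),
            class = "gc_profile_z")
}

#' Find maximal inverted repeats
#'
#' Enumerates every maximal inverted repeat: two arms whose sequences are
#' reverse complements within a mismatch budget, separated by a loop of at
#' most `max_loop` bp.  Maximality means the arms can be extended neither
#' outward nor inward (towards a smaller loop) without exceeding the
#' budget.  N pairs with nothing.
#'
#' @param seq DNA string.
#' @param min_arm Minimum arm length (>= 4).
#' @param max_loop Maximum loop length.
#' @param max_mismatch Mismatch budget across the arm pairing.
#' @return A data frame sorted by `arm1_start` with columns `arm1_start`,
#'   `arm1_end`, `arm2_start`, `arm2_end`, `arm_len`, `loop_len`,
#'   `mismatches` (1-based inclusive coordinates).
#' @examples
#' find_inverted_repeats("GGGAAACCC", min_arm = 3, max_loop = 5,
#'                       max_mismatch = 0)
#' @export
find_inverted_repeats <- function(seq, min_arm = 8L, max_loop = 150L,
                                  max_mismatch = 1L) {
  stopifnot(min_arm >= 3L, max_loop >= 0L, max_mismatch >= 0L)
  seq <- check_dna(seq)
  cpp_inverted_repeats(seq, as.integer(min_arm), as.integer(max_loop),
                       as.integer(max_mismatch))
}

#' Base-pair-maximisation stem score
#'
#' Maximum number of nested Watson-Crick pairs (G:C, A:T, minimum loop 3)
#' attainable by the sequence folding on itself (Nussinov recursion).  This
#' is a structure-richness proxy with no thermodynamic meaning: it counts
#' pairs, not free energy.
#'
#' @param seq DNA string, at most 5000 bp (the recursion is cubic).
#' @return Integer pair count; never exceeds `floor(nchar(seq)/2)`.
#' @examples
#' stem_score("GGGAAACCC")  # 3
#' @export
stem_score <- function(seq) {
  seq <- check_dna(seq)
  if (nchar(seq) > 5000L)
    stop("stem_score limited to 5000 bp (cubic algorithm)", call. = FALSE)
  cpp_stem_score(seq)
}

## IUPAC code -> set of plain bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

#' Scan a sequence for an IUPAC motif
#'
#' Reports every position where the motif matches with at most
#' `max_mismatch` mismatches.  `N` in the pattern matches anything at zero
#' cost; `N` in the sequence never matches a non-N pattern letter.  Minus
#' strand hits are reported with the forward coordinate of their leftmost
#' base and `strand = "-"`; `matched_text` is always the motif-orientation
#' text.
#'
#' @param seq DNA string.
#' @param pattern IUPAC motif.
#' @param max_mismatch Mismatch budget.
#' @param strands `"+"`, `"-"` or `"both"`.
#' @param motif_name Stored in the `motif` column.
#' @return Data frame `motif`, `start`, `end`, `strand`, `mismatches`,
#'   `matched_text`, sorted by `start`.
#' @export
scan_motif <- function(seq, pattern, max_mismatch = 0L,
                       strands = c("both", "+", "-"),
                       motif_name = pattern) {
  strands <- match.arg(strands)
  seq <- check_dna(seq)
  pattern <- toupper(pattern)
  pc <- chars(pattern)
  if (!all(pc %in% names(IUPAC_SETS)))
    stop("invalid IUPAC letter in pattern: ",
         paste(setdiff(pc, names(IUPAC_SETS)), collapse = ","), call. = FALSE)
  out <- list()
  if (strands %in% c("both", "+"))
    out[["+"]] <- scan_motif_fwd(seq, pc, max_mismatch)
  if (strands %in% c("both", "-"))
    out[["-"]] <- scan_motif_fwd(revcomp(seq), pc, max_mismatch)
  m <- length(pc); n <- nchar(seq)
  res <- list()
  if (!is.null(out[["+"]]) && nrow(out[["+"]])) {
    h <- out[["+"]]
    res[["+"]] <- data.frame(motif = motif_name, start = h$pos,
                             end = h$pos + m - 1L, strand = "+",
                             mismatches = h$mm,
                             matched_text = substring(seq, h$pos, h$pos + m - 1L),
                             stringsAsFactors = FALSE)
  }
  if (!is.null(out[["-"]]) && nrow(out[["-"]])) {
    h <- out[["-"]]
    start_fwd <- n - (h$pos + m - 1L) + 1L
    res[["-"]] <- data.frame(motif = motif_name, start = start_fwd,
                             end = start_fwd + m - 1L, strand = "-",
                             mismatches = h$mm,
                             matched_text = substring(revcomp(seq), h$pos,
                                                      h$pos + m - 1L),
                             stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df[order(df$start, df$strand), , drop = FALSE]
}

## Forward-strand scan: per-position mismatch counts by vectorised column
## comparison.  Returns data.frame(pos, mm).
scan_motif_fwd <- function(seq, pc, max_mismatch) {
  n <- nchar(seq); m <- length(pc)
  if (n < m) return(data.frame(pos = integer(), mm = integer()))
  sv <- chars(seq)
  npos <- n - m + 1L
  mm <- integer(npos)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[pc[j]]]
    mm <- mm + !(sv[j:(npos + j - 1L)] %in% allowed)
  }
  keep <- which(mm <= max_mismatch)
  data.frame(pos = keep, mm = mm[keep])
}

#' Call sigma-A promoters by consensus mismatch counting
#'
#' Pairs a -35 box match (consensus `TTGACA`) with a -10 box match
#' (consensus `TATAAT`) separated by a spacer within `spacer_range`, with
#' at most `max_total_mismatch` mismatches summed over both boxes.  All
#' qualifying (possibly overlapping) calls are reported.  The model counts
#' consensus mismatches rather than using a weight matrix: no promoter
#' training set exists for these plasmids.
#'
#' @param seq DNA string (scanned on its forward strand; feed the reverse
#'   complement for the other orientation).
#' @param max_total_mismatch Total mismatch budget over the two boxes.
#' @param spacer_range Integer `c(min, max)` spacer length in bp.
#' @return Data frame `minus35_start`, `minus10_start`, `spacer`, `score`
#'   (summed mismatches), `strand` (always `"+"`, relative to `seq`).
#' @export
find_sigmaA_promoters <- function(seq, max_total_mismatch = 3L,
                                  spacer_range = c(16L, 19L)) {
  seq <- check_dna(seq)
  h35 <- scan_motif_fwd(seq, chars("TTGACA"), max_total_mismatch)
  h10 <- scan_motif_fwd(seq, chars("TATAAT"), max_total_mismatch)
  out <- list()
  if (nrow(h35) && nrow(h10)) {
    for (i in seq_len(nrow(h35))) {
      sp_start <- h35$pos[i] + 6L
      cand <- h10[h10$pos - sp_start >= spacer_range[1L] &
                  h10$pos - sp_start <= spacer_range[2L] &
                  h10$mm + h35$mm[i] <= max_total_mismatch, , drop = FALSE]
      if (nrow(cand))
        out[[length(out) + 1L]] <- data.frame(
          minus35_start = h35$pos[i], minus10_start = cand$pos,
          spacer = cand$pos - sp_start, score = cand$mm + h35$mm[i],
          strand = "+", stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(minus35_start = integer(), minus10_start = integer(),
                      spacer = integer(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$minus35_start, df$minus10_start), , drop = FALSE]
}

#' Read a motif file
#'
#' Plain-text, tab-separated, three columns: motif name, IUPAC pattern,
#' mismatch budget.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Data frame `name`, `pattern`, `budget`.
#' @export
read_motif_file <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("motif file needs 3 columns: name, pattern, budget",
                          call. = FALSE)
  setNames(df[, 1:3], c("name", "pattern", "budget"))
}
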