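#' Kyte-Doolittle hydropathy indices
#'
#' The published per-residue hydropathy scale; `X` (unknown residue) is
#' assigned 0 so it neither creates nor destroys transmembrane calls.
#'
#' @return Named numeric vector over the 20 amino acids plus `X`.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Scan for a C-terminal PTS1-like tripeptide
#'
#' Tests the final three residues against three tiers: the canonical
#' peroxisome-targeting tripeptide SKL, a configurable list of tripeptides
#' functional in plants (default: AKI, AKV, ASL, SNL, SKV, SKI, SKF, SRI,
#' CKM, CKI), and optionally the loose pattern `[ASC][KRNS][LIVMF]`.
#' Classification uses the canonical and listed tiers only; the pattern
#' tier is off by default.
#'
#' @param sequence amino-acid string (length >= 3).
#' @param pts1_list accepted tripeptides beyond SKL.
#' @param enable_pattern logical; admit the loose pattern tier.
#' @return List with `present` (logical), `tripeptide` (the final three
#'   residues, or "" when absent), and `tier` (one of "canonical",
#'   "listed", "pattern", "none").
#' @export
#' @examples
#' scan_pts1("MAAAKI")$tier   # "listed"
#' scan_pts1("MAASKL")$tier   # "canonical"
scan_pts1 <- function(sequence,
                      pts1_list = mdar_config()$pts1_list,
                      enable_pattern = FALSE) {
  n <- nchar(sequence)
  if (n < 3) stop("sequence shorter than 3 residues")
  tri <- toupper(substr(sequence, n - 2L, n))
  tier <- if (tri == "SKL") {
    "canonical"
  } else if (tri %in% pts1_list) {
    "listed"
  } else if (enable_pattern && grepl("^[ASC][KRNS][LIVMF]$", tri)) {
    "pattern"
  } else {
    "none"
  }
  present <- tier != "none"
  list(present = present, tripeptide = if (present) tri else "", tier = tier)
}

#' Sliding-window mean hydropathy profile
#'
#' @param sequence amino-acid string.
#' @param window odd window size (residues), at most the sequence length.
#' @return Numeric vector of length `nchar(sequence)`; entry i is the mean
#'   Kyte-Doolittle index of the window centred at i, `NA` within
#'   `window %/% 2` of either end.
#' @export
hydropathy_profile <- function(sequence, window = 19L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  n <- nchar(sequence)
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  # indices are exact tenths, so window sums are accumulated as integers
  # (in tenths) to keep threshold comparisons free of summation-order error
  h10 <- as.integer(round(10 * kyte_doolittle()))[
    match(seq_chars(sequence), names(kyte_doolittle()))]
  if (anyNA(h10)) stop("sequence contains characters outside the alphabet")
  half <- window %/% 2L
  cs <- cumsum(c(0L, h10))
  prof <- rep(NA_real_, n)
  centers <- (half + 1L):(n - half)
  prof[centers] <- (cs[centers + half + 1L] - cs[centers - half]) /
    (10 * window)
  prof
}

#' Detect transmembrane-like spans
#'
#' Calls maximal runs of window centres whose mean hydropathy reaches the
#' threshold, merges runs separated by fewer than 3 positions, and reports
#' each as a span covering the full windows (clamped to the sequence).
#'
#' @param sequence amino-acid string.
#' @param window odd hydropathy window (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `mean_hydropathy` (mean profile value over the run centres), sorted by
#'   `start`; zero rows when nothing passes.
#' @export
detect_tm <- function(sequence, window = 19L, threshold = 1.6) {
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (n < window) return(empty)
  prof <- hydropathy_profile(sequence, window)
  half <- as.integer(window) %/% 2L
  hits <- which(!is.na(prof) & prof >= threshold)
  if (length(hits) == 0) return(empty)
  # maximal runs of consecutive centres, then merge runs < 3 apart
  breaks <- which(diff(hits) > 1L)
  run_start <- hits[c(1L, breaks + 1L)]
  run_end <- hits[c(breaks, length(hits))]
  merged_s <- run_start[1]
  merged_e <- run_end[1]
  if (length(run_start) > 1) {
    for (k in 2:length(run_start)) {
      gap <- run_start[k] - merged_e[length(merged_e)] - 1L
      if (gap < 3L) {
        merged_e[length(merged_e)] <- run_end[k]
      } else {
        merged_s <- c(merged_s, run_start[k])
        merged_e <- c(merged_e, run_end[k])
      }
    }
  }
  spans <- data.frame(
    start = pmax(1L, merged_s - half),
    end = pmin(n, merged_e + half),
    mean_hydropathy = mapply(function(s, e) mean(prof[s:e]), merged_s, merged_e)
  )
  spans[order(spans$start), , drop = FALSE]
}

#' Scan for a membrane peroxisome-targeting signal (mPTS)
#'
#' An mPTS is a C-terminal transmembrane span immediately followed by a
#' cluster of basic residues (the AthMDAR4 archetype ends TM + "RRRRRW").
#' A span counts as C-terminal when it ends within `cterm_margin` residues
#' of the sequence end. The basic-cluster search is anchored at the last
#' above-threshold hydropathy-window centre of that span (the reported span
#' end overshoots the hydrophobic stretch by half a window, which would
#' otherwise swallow a cluster sitting at the very C-terminus); within
#' `tail_window` residues of the anchor, a cluster is any 6-residue window
#' holding at least `min_basic` K/R. Among passing windows the one with the
#' most basic residues (ties: most C-terminal) is reported.
#'
#' @param sequence amino-acid string.
#' @param tm_spans output of [detect_tm()] on the same sequence.
#' @param cterm_margin,tail_window,min_basic thresholds; see [mdar_config()].
#' @param window the hydropathy window used to produce `tm_spans`.
#' @return List with `has_cterm_tm`, `tm` (one-row span data frame or NULL),
#'   `basic_cluster`, `cluster_seq`.
#' @export
scan_mpts <- function(sequence, tm_spans,
                      cterm_margin = 40L, tail_window = 10L,
                      min_basic = 4L, window = 19L) {
  n <- nchar(sequence)
  none <- list(has_cterm_tm = FALSE, tm = NULL,
               basic_cluster = FALSE, cluster_seq = "")
  if (is.null(tm_spans) || nrow(tm_spans) == 0) return(none)
  cterm <- tm_spans[tm_spans$end >= n - cterm_margin + 1L, , drop = FALSE]
  if (nrow(cterm) == 0) return(none)
  tm <- cterm[nrow(cterm), , drop = FALSE]
  half <- as.integer(window) %/% 2L
  anchor <- max(1L, min(tm$end - half, n))  # last above-threshold centre
  region_end <- min(anchor + tail_window, n)
  chars <- seq_chars(sequence)
  best_count <- -1L
  best_start <- NA_integer_
  s <- anchor
  while (s + 5L <= region_end) {
    cnt <- sum(chars[s:(s + 5L)] %in% c("K", "R"))
    if (cnt >= min_basic && cnt >= best_count) {
      best_count <- cnt
      best_start <- s
    }
    s <- s + 1L
  }
  if (is.na(best_start)) {
    return(list(has_cterm_tm = TRUE, tm = tm,
                basic_cluster = FALSE, cluster_seq = ""))
  }
  list(has_cterm_tm = TRUE, tm = tm, basic_cluster = TRUE,
       cluster_seq = substr(sequence, best_start, best_start + 5L))
}

# First non-gap column of an alignment row.
first_residue_col <- function(row_chars) {
  idx <- which(row_chars != "-")
  if (length(idx) == 0) stop("alignment row is all gaps")
  idx[1]
}

#' Measure an N-terminal extension relative to a cytosolic-core reference
#'
#' The extension is the set of query residues aligned strictly before the
#' first residue of the reference row (a cytosolic core, which has no
#' extension by definition). When the extension reaches `min_extension`
#' residues its composition is scored by [predict_organellar()].
#'
#' @param aligned an `mdar_alignment` containing both ids.
#' @param ref_id id of the reference (cytosolic core) row.
#' @param query_id id of the query row.
#' @param min_extension minimum length before the organellar heuristic runs.
#' @param organellar_threshold,head_len passed to [predict_organellar()].
#' @return List with `length`, `extension_seq`, `organellar_score`,
#'   `organellar`.
#' @export
detect_nterm_extension <- function(aligned, ref_id, query_id,
                                   min_extension = 30L,
                                   organellar_threshold = 0.05,
                                   head_len = 50L) {
  for (id in c(ref_id, query_id)) {
    if (!id %in% aligned$ids) stop("id not in alignment: ", id)
  }
  ref <- seq_chars(aligned$seqs[[ref_id]])
  qry <- seq_chars(aligned$seqs[[query_id]])
  ref_start <- first_residue_col(ref)
  before <- if (ref_start > 1) qry[seq_len(ref_start - 1L)] else character(0)
  ext <- before[before != "-"]
  ext_seq <- paste(ext, collapse = "")
  len <- length(ext)
  if (len >= min_extension) {
    org <- predict_organellar(ext_seq, head_len = head_len,
                              threshold = organellar_threshold)
    list(length = len, extension_seq = ext_seq,
         organellar_score = org$score, organellar = org$organellar)
  } else {
    score <- if (len > 0) {
      predict_organellar(ext_seq, head_len = head_len,
                         threshold = organellar_threshold)$score
    } else 0
    list(length = len, extension_seq = ext_seq,
         organellar_score = score, organellar = FALSE)
  }
}

#' Transit-peptide composition heuristic
#'
#' A deliberately simple, fully documented stand-in for dedicated targeting
#' predictors: chloroplast/mitochondrial transit peptides are enriched in
#' serine and arginine and depleted in acidic residues, so the score is
#' `freq(S) + freq(R) - freq(D) - freq(E)` over the first `head_len`
#' residues, and the extension is called organellar when the score exceeds
#' `threshold`. Both knobs are replaceable via [mdar_config()].
#'
#' @param extension_seq nonempty extension sequence.
#' @param head_len residues scored from the start (default 50).
#' @param threshold score above which the call is organellar (default 0.05).
#' @return List with `score` and `organellar`.
#' @export
#' @examples
#' predict_organellar("SSSSSRRRRR")  # score 1, organellar TRUE
predict_organellar <- function(extension_seq, head_len = 50L,
                               threshold = 0.05) {
  if (nchar(extension_seq) == 0) stop("empty extension sequence")
  head <- substr(extension_seq, 1L, min(head_len, nchar(extension_seq)))
  chars <- seq_chars(head)
  n <- length(chars)
  score <- (sum(chars == "S") + sum(chars == "R") -
            sum(chars == "D") - sum(chars == "E")) / n
  list(score = score, organellar = score > threshold)
}

#' Check the catalytic residues against a reference row
#'
#' MDAR activity requires specific residues (Arg320 and Tyr349 in rice
#' OsaMDAR3 numbering); candidates with a substitution or deletion at those
#' positions are demoted to "MDAR-like". For each labelled reference
#' position the alignment column holding that reference residue is located
#' and the query residue in that column is reported (`-` for a gap).
#'
#' @param aligned an `mdar_alignment`.
#' @param ref_id id of the reference row.
#' @param query_id id of the query row.
#' @param ref_positions named list of `list(pos, residue)` giving 1-based
#'   ungapped reference positions and expected residues; default
#'   `mdar_config()$catalytic_positions`.
#' @return List with `ok` (logical) and `residues_found` (named character:
#'   observed residue per label).
#' @export
check_catalytic <- function(aligned, ref_id, query_id,
                            ref_positions = mdar_config()$catalytic_positions) {
  for (id in c(ref_id, query_id)) {
    if (!id %in% aligned$ids) stop("id not in alignment: ", id)
  }
  ref <- seq_chars(aligned$seqs[[ref_id]])
  qry <- seq_chars(aligned$seqs[[query_id]])
  residue_cols <- which(ref != "-")
  found <- character(0)
  ok <- TRUE
  for (label in names(ref_positions)) {
    spec <- ref_positions[[label]]
    pos <- spec$pos
    if (pos > length(residue_cols)) {
      stop("reference '", ref_id, "' has only ", length(residue_cols),
           " residues; position ", pos, " (", label, ") out of range")
    }
    col <- residue_cols[pos]
    observed <- qry[col]
    found[label] <- observed
    if (observed != spec$residue) ok <- FALSE
  }
  list(ok = ok, residues_found = found)
}

#' Flag atypical sequences
#'
#' Two atypicality signals seen in real MDAR families: lengths outside the
#' typical 400-552 residue range, and grass-type tandem isoforms carrying
#' two complete catalytic cores (proxied by two distant matches of a
#' catalytic-context motif, since full domain search is out of scope).
#'
#' @param sequence amino-acid string.
#' @param typical_range inclusive length range, default `c(400, 552)`.
#' @param catalytic_context_motif optional fixed string (e.g. the 7-residue
#'   window around a catalytic residue); two non-overlapping matches at
#'   least `min_separation` apart set `dual_catalytic_core`.
#' @param min_separation minimum distance between the two matches.
#' @return List with `length_atypical`, `dual_catalytic_core`, `length`.
#' @export
detect_atypical <- function(sequence, typical_range = c(400L, 552L),
                            catalytic_context_motif = NULL,
                            min_separation = 300L) {
  len <- nchar(sequence)
  length_atypical <- len < typical_range[1] || len > typical_range[2]
  dual <- FALSE
  if (!is.null(catalytic_context_motif) && nzchar(catalytic_context_motif)) {
    hits <- gregexpr(catalytic_context_motif, sequence, fixed = TRUE)[[1]]
    if (hits[1] != -1 && length(hits) >= 2) {
      dual <- (max(hits) - min(hits)) >= min_separation
    }
  }
  list(length_atypical = length_atypical, dual_catalytic_core = dual,
       length = len)
}

#' Compute the full signal set for one sequence
#'
#' Bundles every scanner into the feature vector the classifier consumes.
#'
#' @param sequence ungapped amino-acid string.
#' @param aligned an `mdar_alignment` containing `ref_id` and `query_id`.
#' @param ref_id reference (cytosolic core) row id.
#' @param query_id the sequence's row id in the alignment.
#' @param config a configuration list from [mdar_config()].
#' @param catalytic_context_motif optional motif for [detect_atypical()].
#' @return List of class `mdar_signals` with components `pts1`, `tm_spans`,
#'   `mpts`, `nterm`, `catalytic`, `atypical`.
#' @export
scan_signals <- function(sequence, aligned, ref_id, query_id,
                         config = mdar_config(),
                         catalytic_context_motif = NULL) {
  pts1 <- scan_pts1(sequence, pts1_list = config$pts1_list,
                    enable_pattern = config$pts1_pattern_enabled)
  tm <- detect_tm(sequence, window = config$tm_window,
                  threshold = config$tm_threshold)
  mpts <- scan_mpts(sequence, tm,
                    cterm_margin = config$cterm_margin,
                    tail_window = config$tail_window,
                    min_basic = config$min_basic,
                    window = config$tm_window)
  nterm <- detect_nterm_extension(aligned, ref_id, query_id,
                                  min_extension = config$min_extension,
                                  organellar_threshold = config$organellar_threshold,
                                  head_len = config$organellar_head_len)
  catalytic <- check_catalytic(aligned, ref_id, query_id,
                               ref_positions = config$catalytic_positions)
  atypical <- detect_atypical(sequence,
                              typical_range = config$typical_length_range,
                              catalytic_context_motif = catalytic_context_motif)
  structure(list(pts1 = pts1, tm_spans = tm, mpts = mpts, nterm = nterm,
                 catalytic = catalytic, atypical = atypical),
            class = "mdar_signals")
}
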