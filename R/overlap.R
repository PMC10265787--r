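#' Overlap-detection configuration
#'
#' Scoring and thresholds for prior-guided pairwise overlap detection. The
#' candidate threshold `delta_d` limits alignment to read pairs whose prior
#' coordinates differ by less than it; when `NULL` it is derived per pair
#' from the reads' library SDs as `delta_d_mult * sqrt(v_i^2 + v_j^2)` with a
#' `delta_d_floor` bp floor (pseudo reads have SD 0).
#'
#' @param delta_d Fixed candidate-pair prior-distance threshold in bp, or
#'   `NULL` to derive it from library SDs.
#' @param delta_d_mult Multiplier on the combined SD (default 3).
#' @param delta_d_floor Floor in bp (default 10).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; penalties are
#'   given as negative values (defaults +1, -2, -4, -1; a gap of length L
#'   costs `|gap_open| + (L-1) |gap_extend|`).
#' @param min_score Significance threshold on the alignment score
#'   (default 15).
#' @param min_overlap Minimum aligned length in bp (default 15).
#' @param max_hang Maximum unaligned overhang on the inner side of each
#'   alignment end (default 5).
#' @param dedup_window Patterns within this many bp of a higher-scoring
#'   pattern's offset are suppressed (default 2).
#' @param max_patterns Cap on the number of suboptimal alignments enumerated
#'   per read pair (default 8).
#' @return An object of class `overlap_config`.
#' @export
overlap_config <- function(delta_d = NULL, delta_d_mult = 3,
                           delta_d_floor = 10,
                           match = 1, mismatch = -2, gap_open = -4,
                           gap_extend = -1, min_score = 15, min_overlap = 15,
                           max_hang = 5, dedup_window = 2,
                           max_patterns = 8) {
  stopifnot(is.null(delta_d) || delta_d > 0, min_overlap >= 1, min_score > 0)
  structure(list(delta_d = delta_d, delta_d_mult = delta_d_mult,
                 delta_d_floor = delta_d_floor, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 min_overlap = min_overlap, max_hang = max_hang,
                 dedup_window = dedup_window, max_patterns = max_patterns),
            class = "overlap_config")
}

#' Candidate read pairs by prior proximity
#'
#' Returns exactly the unordered pairs with `|p_i - p_j| < delta_d`, found by
#' sorting on the priors and sliding a window, so the work is linear in the
#' output size rather than quadratic in the read count. The all-against-all
#' pair count `choose(n, 2)` is attached as attribute `n_all_pairs` for
#' reporting how much work the prior restriction saves.
#'
#' @param p Numeric vector of prior coordinates.
#' @param delta_d Threshold in bp (strict inequality).
#' @return Two-column integer matrix of index pairs (`i < j`), with
#'   attribute `n_all_pairs`.
#' @export
candidate_pairs <- function(p, delta_d) {
  stopifnot(delta_d > 0, all(is.finite(p)))
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  out <- vector("list", n)
  lo <- 1L
  for (k in seq_len(n)) {
    while (ps[k] - ps[lo] >= delta_d) lo <- lo + 1L
    if (lo < k) {
      i <- ord[lo:(k - 1L)]
      j <- ord[k]
      out[[k]] <- cbind(pmin(i, j), pmax(i, j))
    }
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(0), ncol = 2)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  attr(m, "n_all_pairs") <- choose(n, 2)
  m
}

#' All significant overlap patterns between two reads
#'
#' Extended Smith-Waterman local alignment that enumerates, per implied
#' ending-base offset, the best alignment consistent with an
#' overlap/dovetail/containment configuration (see the C++ kernel for the
#' exact rules), then suppresses patterns within `dedup_window` bp of a
#' higher-scoring one. On tandem repeats this yields one pattern per unit
#' shift, which is what the prior-compatible selection chooses among.
#'
#' @param seq_i,seq_j The two read sequences (gap-axis orientation).
#' @param cfg An [overlap_config()].
#' @return Data.frame of patterns: `offset` (implied `beta_j - beta_i`),
#'   `score`, aligned spans `i1,i2,j1,j2` (1-based inclusive), ordered by
#'   decreasing score.
#' @export
align_pair <- function(seq_i, seq_j, cfg = overlap_config()) {
  stopifnot(nchar(seq_i) > 0, nchar(seq_j) > 0)
  pat <- sw_overlap_patterns(seq_i, seq_j, cfg$match, abs(cfg$mismatch),
                             abs(cfg$gap_open), abs(cfg$gap_extend),
                             cfg$min_score, cfg$min_overlap, cfg$max_hang,
                             cfg$max_patterns)
  if (!nrow(pat)) return(pat)
  pat <- pat[order(-pat$score, abs(pat$offset)), , drop = FALSE]
  keep <- logical(nrow(pat))
  acc <- numeric(0)
  for (k in seq_len(nrow(pat))) {
    if (!length(acc) || min(abs(acc - pat$offset[k])) > cfg$dedup_window) {
      keep[k] <- TRUE
      acc <- c(acc, pat$offset[k])
    }
  }
  pat <- pat[keep, , drop = FALSE]
  rownames(pat) <- NULL
  pat
}

#' Select the alignment most compatible with the prior positions
#'
#' Among significant patterns, returns the one minimising
#' `|offset - (p_j - p_i)|` — not the highest-scoring one. Ties go to the
#' higher score, then to the smaller absolute offset.
#'
#' @param patterns Data.frame from [align_pair()].
#' @param p_i,p_j Prior coordinates of the two reads.
#' @return One-row data.frame, or `NULL` when `patterns` is empty.
#' @export
select_alignment <- function(patterns, p_i, p_j) {
  if (is.null(patterns) || !nrow(patterns)) return(NULL)
  d <- abs(patterns$offset - (p_j - p_i))
  ord <- order(d, -patterns$score, abs(patterns$offset))
  patterns[ord[1], , drop = FALSE]
}

#' Build overlap observations for a set of placed reads
#'
#' Generates candidate pairs from the priors, aligns each pair, selects the
#' prior-compatible pattern, and emits one observation per selected pattern:
#' `y = offset` observed for `beta_j - beta_i`. With `use_lib_weights` the
#' initial weight of an observation is `(min_v / max(v_i, v_j))^2`, where
#' `min_v` is the smallest library SD present — tighter libraries give more
#' trusted observations; with a single library all weights are 1.
#'
#' @param placed Data.frame of placed reads (see [collect_gap_reads()]).
#' @param cfg An [overlap_config()].
#' @param use_lib_weights Enable per-library initial weights (default FALSE).
#' @return Data.frame of observations: `i`, `j` (row indices into `placed`),
#'   `y`, `score`, `weight`, `outlier` (all FALSE here).
#' @export
build_observations <- function(placed, cfg = overlap_config(),
                               use_lib_weights = FALSE) {
  n <- nrow(placed)
  empty <- data.frame(i = integer(), j = integer(), y = numeric(),
                      score = numeric(), weight = numeric(),
                      outlier = logical())
  if (n < 2) return(empty)
  v <- placed$v
  dmax <- if (is.null(cfg$delta_d))
    max(cfg$delta_d_floor, cfg$delta_d_mult * sqrt(2 * max(v)^2))
  else cfg$delta_d
  cand <- candidate_pairs(placed$p, dmax)
  if (!nrow(cand)) return(empty)
  if (is.null(cfg$delta_d)) {
    thr <- pmax(cfg$delta_d_floor,
                cfg$delta_d_mult * sqrt(v[cand[, 1]]^2 + v[cand[, 2]]^2))
    keep <- abs(placed$p[cand[, 1]] - placed$p[cand[, 2]]) < thr
    cand <- cand[keep, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  min_v <- {
    vv <- v[!placed$is_pseudo]
    if (length(vv)) min(vv) else 1
  }
  rows <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    sel <- select_alignment(align_pair(placed$seq[i], placed$seq[j], cfg),
                            placed$p[i], placed$p[j])
    if (is.null(sel)) next
    w <- 1
    if (use_lib_weights) {
      vmax <- max(v[i], v[j], min_v) # pseudo reads (v = 0) inherit min_v
      w <- (min_v / vmax)^2
    }
    rows[[k]] <- data.frame(i = i, j = j, y = sel$offset, score = sel$score,
                            weight = w, outlier = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
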