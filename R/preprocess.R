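#' Estimate library insert-size statistics from alignments
#'
#' Uses pairs with both mates uniquely mapped (MAPQ at or above `min_mapq`)
#' to the same scaffold in FR orientation. The insert size is the outer
#' distance, leftmost base of the forward read to rightmost base of the
#' reverse read. Location and scale are estimated robustly (median and
#' 1.4826 x MAD) so a minority of chimeric pairs cannot distort them; the SD
#' is floored at 1 bp.
#'
#' @param pairs Data.frame from [pair_alignments()].
#' @param min_pairs Minimum usable pair count (default 200); below it the
#'   caller must supply the statistics.
#' @param min_mapq MAPQ threshold operationalising "uniquely mapped"
#'   (default 20).
#' @param mu,v Optional user-supplied values; when both are given the
#'   estimator is bypassed.
#' @return A [lib_profile()].
#' @export
estimate_insert_stats <- function(pairs, min_pairs = 200, min_mapq = 20,
                                  mu = NULL, v = NULL) {
  if (!is.null(mu) && !is.null(v)) return(lib_profile(mu, v))
  ok <- pairs$mapped_1 & pairs$mapped_2 &
    pairs$rname_1 == pairs$rname_2 &
    pairs$mapq_1 >= min_mapq & pairs$mapq_2 >= min_mapq &
    pairs$strand_1 != pairs$strand_2
  ok[is.na(ok)] <- FALSE
  p <- pairs[ok, , drop = FALSE]
  if (!nrow(p)) stop("no usable pairs; supply mu and v")
  fwd_pos <- ifelse(p$strand_1 == "+", p$pos_1, p$pos_2)
  rev_pos <- ifelse(p$strand_1 == "+", p$pos_2, p$pos_1)
  rev_len <- ifelse(p$strand_1 == "+", nchar(p$seq_2), nchar(p$seq_1))
  ins <- rev_pos + rev_len - fwd_pos
  ins <- ins[ins > 0]
  if (length(ins) < min_pairs)
    stop("only ", length(ins), " usable pairs (< ", min_pairs,
         "); supply mu and v")
  lib_profile(median(ins), max(1, mad(ins)))
}

#' Estimate the size of one gap from spanning read pairs
#'
#' For every FR pair with its forward mate uniquely mapped on the left flank
#' and its reverse mate on the right flank, the gap size is observed as
#' `mu - d_L - d_R`, where `d_L`/`d_R` are each mate's outermost-base
#' distance to its breakpoint; the estimate is the median over pairs,
#' floored at 1. With no spanning pair the N-run length is returned.
#'
#' A pair can only be observed spanning when its insert exceeds the gap plus
#' both read lengths, so spanning inserts are size-biased upward and the raw
#' rule underestimates the gap, increasingly so for wide-insert libraries.
#' With `correct_bias = TRUE` (the pipeline default) the estimate is
#' debiased iteratively using the closed-form mean of a normal insert
#' conditioned on spanning, `E[S | span] = mu + v (1 - Phi(z)) /
#' (phi(z) - z (1 - Phi(z)))` with `z = (G + l1 + l2 - mu) / v`; with
#' `correct_bias = FALSE` the raw median rule is applied unchanged.
#'
#' @param gap One row of [find_gaps()] output.
#' @param pairs Data.frame from [pair_alignments()].
#' @param profile The library [lib_profile()].
#' @param min_mapq MAPQ threshold for unique mapping.
#' @param correct_bias Correct the spanning-insert size bias (default TRUE).
#' @return Gap-size estimate in bp.
#' @export
estimate_gap_size <- function(gap, pairs, profile, min_mapq = 20,
                              correct_bias = TRUE) {
  win <- profile$mu + 3 * profile$v
  ok <- pairs$mapped_1 & pairs$mapped_2 &
    pairs$rname_1 == gap$scaffold & pairs$rname_2 == gap$scaffold &
    pairs$mapq_1 >= min_mapq & pairs$mapq_2 >= min_mapq
  ok[is.na(ok)] <- FALSE
  p <- pairs[ok, , drop = FALSE]
  if (nrow(p)) {
    fwd_is_1 <- p$strand_1 == "+" & p$strand_2 == "-"
    rev_is_1 <- p$strand_1 == "-" & p$strand_2 == "+"
    keep <- fwd_is_1 | rev_is_1
    p <- p[keep, , drop = FALSE]
    fwd_is_1 <- fwd_is_1[keep]
    a <- ifelse(fwd_is_1, p$pos_1, p$pos_2)                       # fwd leftmost
    e <- ifelse(fwd_is_1, p$pos_2 + nchar(p$seq_2),
                p$pos_1 + nchar(p$seq_1)) - 1                     # rev rightmost
    d_l <- gap$start - a
    d_r <- e - gap$end + 1
    span <- d_l >= 1 & d_l <= win & d_r >= 1 & d_r <= win
    if (any(span)) {
      est <- profile$mu - d_l[span] - d_r[span]
      if (!correct_bias)
        return(max(1, round(median(est))))
      # read lengths set the minimum flank distances of a spanning pair
      l1 <- median(ifelse(fwd_is_1, nchar(p$seq_1), nchar(p$seq_2))[span])
      l2 <- median(ifelse(fwd_is_1, nchar(p$seq_2), nchar(p$seq_1))[span])
      base <- mean(est, trim = 0.1)
      G <- max(1, base)
      for (it in 1:6) {
        z <- (G + l1 + l2 - profile$mu) / profile$v
        denom <- stats::dnorm(z) - z * stats::pnorm(z, lower.tail = FALSE)
        if (denom < 1e-8) break # spanning essentially impossible: no update
        shift <- profile$v * stats::pnorm(z, lower.tail = FALSE) / denom
        G <- max(1, base + shift)
      }
      return(round(G))
    }
  }
  max(1, gap$reported_size)
}

# Internal: empty placed-read table.
empty_placed <- function() {
  data.frame(id = character(), seq = character(), qual = character(),
             p = numeric(), lib = character(), v = numeric(),
             is_pseudo = logical(), anchor = numeric(),
             stringsAsFactors = FALSE)
}

#' Collect the reads originating in a gap, with prior coordinates
#'
#' A pair contributes when one mate is uniquely mapped within `mu + 3 v`
#' of a breakpoint and oriented toward the gap: forward within the window
#' left of the gap, or reverse within the window right of it. The other mate
#' is then recruited onto the gap axis (origin 0 = last base of the left
#' flank; coordinates refer to a read's rightmost, "ending", base).
#' Priors: left-anchored recruits get `p = mu - d_anchor`; right-anchored
#' recruits get `p = gap_size - (mu - d_anchor) + read_len`, with `d_anchor`
#' the anchoring mate's outermost-base distance to its breakpoint.
#'
#' Recruits are oriented onto the (forward) gap axis: an unmapped recruit
#' whose anchor is forward on the left flank is the reverse-sequenced mate
#' and is reverse-complemented; an unmapped recruit anchored on the right
#' flank is already forward; mapped recruits keep their SAM (forward) bases.
#'
#' @param gap One row of [find_gaps()] output.
#' @param pairs Data.frame from [pair_alignments()].
#' @param profile [lib_profile()] of the pairs' library.
#' @param gap_size Gap-size estimate from [estimate_gap_size()].
#' @param min_mapq MAPQ threshold for the anchoring mate.
#' @param lib_id Library label stored with each recruit.
#' @return A data.frame of placed reads: `id`, `seq`, `qual` (gap-axis
#'   orientation), `p` (prior ending-base coordinate), `lib`, `v` (library
#'   SD), `is_pseudo`, `anchor` (NA for ordinary reads).
#' @export
collect_gap_reads <- function(gap, pairs, profile, gap_size,
                              min_mapq = 20, lib_id = "lib1") {
  win <- profile$mu + 3 * profile$v
  out <- list()
  grab <- function(anchor_mate) {
    s <- if (anchor_mate == 1) "_1" else "_2"
    o <- if (anchor_mate == 1) "_2" else "_1"
    av <- function(f) pairs[[paste0(f, s)]]
    ov <- function(f) pairs[[paste0(f, o)]]
    anch_ok <- av("mapped") & av("rname") == gap$scaffold &
      av("mapq") >= min_mapq
    anch_ok[is.na(anch_ok)] <- FALSE
    has_mate <- !is.na(ov("seq"))
    alen <- nchar(av("seq"))
    # left-flank anchor: forward strand, outermost = leftmost base
    d_left <- gap$start - av("pos")
    left <- anch_ok & has_mate & av("strand") == "+" &
      d_left >= 1 & d_left <= win
    left[is.na(left)] <- FALSE
    # right-flank anchor: reverse strand, outermost = rightmost base
    e <- av("pos") + alen - 1
    d_right <- e - gap$end + 1
    right <- anch_ok & has_mate & av("strand") == "-" &
      d_right >= 1 & d_right <= win
    right[is.na(right)] <- FALSE

    res <- list()
    if (any(left)) {
      sq <- ov("seq")[left]; ql <- ov("qual")[left]
      rmapped <- ov("mapped")[left]; rstrand <- ov("strand")[left]
      # orient onto the forward gap axis
      flip <- ifelse(rmapped, rstrand == "+", TRUE)
      # a mapped recruit stores forward bases already; the unmapped mate of a
      # forward anchor was sequenced in reverse, so RC its raw bases.
      flip[is.na(flip)] <- TRUE
      sq[flip & !rmapped] <- revcomp_many(sq[flip & !rmapped])
      ql[flip & !rmapped] <- vapply(ql[flip & !rmapped], function(x)
        paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1))
      res$left <- data.frame(
        id = paste0(pairs$qname[left], ifelse(o == "_1", "/1", "/2")),
        seq = sq, qual = ql,
        p = profile$mu - d_left[left],
        lib = lib_id, v = profile$v, is_pseudo = FALSE, anchor = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (any(right)) {
      sq <- ov("seq")[right]; ql <- ov("qual")[right]
      rmapped <- ov("mapped")[right]
      # unmapped mate of a reverse anchor was sequenced forward: keep as is;
      # mapped recruits are already forward.
      ell <- nchar(sq)
      res$right <- data.frame(
        id = paste0(pairs$qname[right], ifelse(o == "_1", "/1", "/2")),
        seq = sq, qual = ql,
        p = gap_size - (profile$mu - d_right[right]) + ell,
        lib = lib_id, v = profile$v, is_pseudo = FALSE, anchor = NA_real_,
        stringsAsFactors = FALSE)
    }
    res
  }
  out <- c(grab(1), grab(2))
  if (!length(out)) return(empty_placed())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!duplicated(res$id), , drop = FALSE]
}

#' Cut the two pseudo reads from the gap flanks
#'
#' The left pseudo read is the last `flank_len` non-N bases of the left
#' flank, anchored at coordinate 0 (its ending base defines the gap-axis
#' origin). The right pseudo read is the first `flank_len` bases of the
#' right flank with prior `gap_size + flank_len`; it is anchored only after
#' layout. Flanks shorter than `flank_len` are truncated to what is
#' available; a flank shorter than `min_flank` marks the gap unclosable from
#' that side (the pseudo read is omitted).
#'
#' @param gap One row of [find_gaps()] output.
#' @param scaffold_seq The scaffold's sequence.
#' @param gap_size Gap-size estimate.
#' @param flank_len Pseudo-read length (default 150).
#' @param min_flank Minimum acceptable flank (default 20).
#' @return Data.frame of 0, 1 or 2 placed pseudo reads (Phred 40
#'   qualities).
#' @export
make_pseudo_reads <- function(gap, scaffold_seq, gap_size, flank_len = 150,
                              min_flank = 20) {
  s <- scaffold_seq
  left_all <- substr(s, 1, gap$start)
  right_all <- substr(s, gap$end + 1, nchar(s))
  # flanks end at the nearest N (gaps further out belong to other intervals)
  left_ctg <- sub(".*[Nn]", "", left_all)
  right_ctg <- sub("[Nn].*", "", right_all)
  rows <- list()
  lf <- substr(left_ctg, nchar(left_ctg) - min(flank_len, nchar(left_ctg)) + 1,
               nchar(left_ctg))
  if (nchar(lf) >= min_flank)
    rows$left <- data.frame(id = "__pseudo_left", seq = lf,
                            qual = strrep("I", nchar(lf)), p = 0,
                            lib = "flank", v = 0, is_pseudo = TRUE,
                            anchor = 0, stringsAsFactors = FALSE)
  rf <- substr(right_ctg, 1, min(flank_len, nchar(right_ctg)))
  if (nchar(rf) >= min_flank)
    rows$right <- data.frame(id = "__pseudo_right", seq = rf,
                             qual = strrep("I", nchar(rf)),
                             p = gap_size + nchar(rf),
                             lib = "flank", v = 0, is_pseudo = TRUE,
                             anchor = NA_real_, stringsAsFactors = FALSE)
  if (!length(rows)) return(empty_placed())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
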