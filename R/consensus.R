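#' Build a multiple alignment from a fitted layout
#'
#' Reads are placed on the gap axis at their estimated ending-base
#' coordinates, in start order. Each incoming read is re-aligned to the
#' running consensus within a band of +/- `band` columns to absorb residual
#' 1-2 bp offsets left by rounding; the shift with the most matches wins
#' (ties prefer the unshifted placement, then the smaller shift). A read
#' whose best banded placement matches less than `min_identity` of the
#' consensus columns it overlaps (when it overlaps at least `min_overlap_cols`
#' called columns) is dropped and counted.
#'
#' @param layout Data.frame with columns `id`, `seq`, `qual`, `coord`
#'   (integer ending-base coordinate of each read).
#' @param band Banded re-alignment half-width in columns (default 3).
#' @param min_identity Identity floor for keeping a read (default 0.5).
#' @param min_overlap_cols Minimum overlapping called columns before the
#'   floor applies (default 10).
#' @return An object of class `gap_msa`: `bases` and `quals` (read x column
#'   character/integer matrices, NA off-read), `start` (gap-axis coordinate
#'   of column 1), `coord` (realigned ending-base coordinate per kept read),
#'   `ids`, `dropped` (ids of discarded reads).
#' @export
build_msa <- function(layout, band = 3, min_identity = 0.5,
                      min_overlap_cols = 10) {
  stopifnot(nrow(layout) >= 1)
  len <- nchar(layout$seq)
  start <- layout$coord - len + 1
  ord <- order(start, layout$coord)
  layout <- layout[ord, , drop = FALSE]
  len <- len[ord]; start <- start[ord]

  lo <- min(start) - band
  hi <- max(layout$coord) + band
  ncol_ <- hi - lo + 1
  n <- nrow(layout)
  bases <- matrix(NA_character_, n, ncol_)
  quals <- matrix(NA_integer_, n, ncol_)
  cons <- rep(NA_character_, ncol_)   # running majority call
  votes <- matrix(0L, 4, ncol_, dimnames = list(c("A", "C", "G", "T"), NULL))
  dropped <- character(0)
  keep <- logical(n)
  coord_out <- integer(n)

  for (k in seq_len(n)) {
    b <- strsplit(layout$seq[k], "")[[1]]
    q <- utf8ToInt(layout$qual[k]) - 33L
    col0 <- start[k] - lo + 1 # column of the read's first base, unshifted
    shifts <- c(0, as.vector(rbind(seq_len(band), -seq_len(band))))
    best <- NULL
    for (d in shifts) {
      cols <- col0 + d + seq_along(b) - 1
      ok <- cols >= 1 & cols <= ncol_
      cc <- cons[cols[ok]]
      cmp <- !is.na(cc)
      nover <- sum(cmp)
      nmatch <- sum(cc[cmp] == b[ok][cmp])
      score <- if (nover) nmatch / nover else 1
      if (is.null(best) || nmatch > best$nmatch) {
        best <- list(d = d, nover = nover, nmatch = nmatch, score = score)
      }
    }
    if (best$nover >= min_overlap_cols && best$score < min_identity) {
      dropped <- c(dropped, layout$id[k])
      next
    }
    keep[k] <- TRUE
    cols <- col0 + best$d + seq_along(b) - 1
    ok <- cols >= 1 & cols <= ncol_
    bases[k, cols[ok]] <- b[ok]
    quals[k, cols[ok]] <- q[ok]
    coord_out[k] <- layout$coord[k] + best$d
    # refresh the running consensus where this read voted
    bk <- b[ok]
    known <- bk %in% rownames(votes)
    idx <- cbind(match(bk[known], rownames(votes)), cols[ok][known])
    for (r in seq_len(nrow(idx)))
      votes[idx[r, 1], idx[r, 2]] <- votes[idx[r, 1], idx[r, 2]] + 1L
    touched <- unique(cols[ok])
    cons[touched] <- rownames(votes)[apply(votes[, touched, drop = FALSE],
                                           2, which.max)]
  }
  structure(list(bases = bases[keep, , drop = FALSE],
                 quals = quals[keep, , drop = FALSE],
                 start = lo, ids = layout$id[keep],
                 coord = coord_out[keep], dropped = dropped),
            class = "gap_msa")
}

#' Call a Phred-scored consensus from a multiple alignment
#'
#' Per column, a posterior over A/C/G/T with a uniform prior: each read base
#' contributes likelihood `1 - e` to its own base and `e/3` to the other
#' three, with `e` its Phred error probability (or a flat `err` when
#' `use_qualities = FALSE`). The consensus base is the posterior argmax (ties
#' broken lexicographically) and its quality is
#' `-10 log10(1 - posterior)` capped at 60. Columns with no coverage inside
#' the span are called `N` with Phred 0.
#'
#' @param msa A `gap_msa` from [build_msa()].
#' @param use_qualities Use per-base Phred scores (default) or a flat error
#'   rate.
#' @param err Flat per-base error probability for the count-based mode.
#' @return List: `sequence`, `phred` (integer vector), `qualities`
#'   (Phred+33 string), `start` (coordinate of the first column).
#' @export
call_consensus <- function(msa, use_qualities = TRUE, err = 0.01) {
  bs <- msa$bases; qs <- msa$quals
  ncol_ <- ncol(bs)
  nucs <- c("A", "C", "G", "T")
  loglik <- matrix(0, 4, ncol_, dimnames = list(nucs, NULL))
  cov <- integer(ncol_)
  for (k in seq_len(nrow(bs))) {
    cols <- which(!is.na(bs[k, ]))
    if (!length(cols)) next
    b <- bs[k, cols]
    e <- if (use_qualities) 10^(-qs[k, cols] / 10) else rep(err, length(b))
    e <- pmin(pmax(e, 1e-6), 0.75)
    valid <- b %in% nucs
    cols <- cols[valid]; b <- b[valid]; e <- e[valid]
    if (!length(cols)) next
    cov[cols] <- cov[cols] + 1L
    for (x in 1:4) {
      p <- ifelse(b == nucs[x], 1 - e, e / 3)
      loglik[x, cols] <- loglik[x, cols] + log(p)
    }
  }
  # trim uncovered margins, keep interior zero-coverage columns as N
  covered <- which(cov > 0)
  if (!length(covered))
    return(list(sequence = "", phred = integer(0), qualities = "",
                start = msa$start))
  span <- covered[1]:covered[length(covered)]
  seq_out <- character(length(span))
  phred <- integer(length(span))
  for (t in seq_along(span)) {
    j <- span[t]
    if (cov[j] == 0) { seq_out[t] <- "N"; phred[t] <- 0L; next }
    ll <- loglik[, j]
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    w <- which.max(post) # ties: which.max takes the first, i.e. lexicographic
    seq_out[t] <- nucs[w]
    phred[t] <- min(60L, as.integer(round(-10 * log10(max(1 - post[w],
                                                          1e-6)))))
  }
  list(sequence = paste(seq_out, collapse = ""), phred = phred,
       qualities = intToUtf8(phred + 33L, multiple = FALSE),
       start = msa$start + span[1] - 1)
}

#' Anchor fitted layouts into the gap and emit the result
#'
#' Applies the anchoring rules: if both pseudo reads land in one layout the
#' gap is closed and the consensus strictly between their anchor points (the
#' left pseudo's ending base and the right pseudo's first base) is spliced
#' in; if only one pseudo read is present, the consensus beyond it extends
#' the corresponding flank; layouts containing neither pseudo read are
#' discarded as unreliable. Pseudo reads found in inverted order (right
#' before left) yield `unfilled` with a diagnostic attribute.
#'
#' @param fit A `robust_fit` over the placed reads.
#' @param placed The placed-read data.frame the fit refers to.
#' @param band,min_identity,min_overlap_cols Passed to [build_msa()].
#' @param use_qualities Passed to [call_consensus()].
#' @return An object of class `gap_result`: `status` (`closed`,
#'   `left_extended`, `right_extended`, `unfilled`), `sequence`, `qualities`,
#'   `filled_length`, plus bookkeeping fields (`n_reads`, `n_observations`,
#'   `n_outliers`, `dropped`).
#' @export
anchor_and_emit <- function(fit, placed, band = 3, min_identity = 0.5,
                            min_overlap_cols = 10, use_qualities = TRUE) {
  unfilled <- function(note = NULL) {
    structure(list(status = "unfilled", sequence = "", qualities = "",
                   filled_length = 0, n_reads = nrow(placed),
                   n_observations = length(fit$residuals),
                   n_outliers = length(fit$outliers),
                   dropped = character(0), note = note),
              class = "gap_result")
  }
  il <- which(placed$id == "__pseudo_left")
  ir <- which(placed$id == "__pseudo_right")
  has_l <- length(il) == 1
  has_r <- length(ir) == 1
  if (!has_l && !has_r) return(unfilled("no pseudo read present"))

  comp <- fit$comp
  if (has_l && has_r && comp[il] == comp[ir]) {
    status0 <- "closed"
    pick <- comp[il]
  } else {
    # one-sided extension: when both pseudo reads survive in separate
    # components, extend from the side with the larger layout (tie: left)
    size_l <- if (has_l) sum(comp == comp[il]) else -1L
    size_r <- if (has_r) sum(comp == comp[ir]) else -1L
    if (size_l >= size_r) {
      status0 <- "left_extended"; pick <- comp[il]
    } else {
      status0 <- "right_extended"; pick <- comp[ir]
    }
  }
  members <- which(comp == pick)
  if (length(members) < 2 && status0 != "closed")
    return(unfilled("pseudo read isolated"))

  lay <- data.frame(id = placed$id[members], seq = placed$seq[members],
                    qual = placed$qual[members], coord = fit$beta[members],
                    stringsAsFactors = FALSE)
  msa <- build_msa(lay, band = band, min_identity = min_identity,
                   min_overlap_cols = min_overlap_cols)
  if (!length(msa$ids)) return(unfilled("all reads dropped in MSA"))
  cons <- call_consensus(msa, use_qualities = use_qualities)
  if (!nchar(cons$sequence)) return(unfilled("empty consensus"))

  # coordinates after banded re-alignment
  coord_of <- function(id) {
    k <- match(id, msa$ids)
    if (is.na(k)) NA_integer_ else msa$coord[k]
  }
  slice <- function(from, to) { # gap-axis [from, to] inclusive
    a <- from - cons$start + 1; b <- to - cons$start + 1
    a <- max(a, 1); b <- min(b, nchar(cons$sequence))
    if (a > b) return(list(seq = "", qual = ""))
    list(seq = substr(cons$sequence, a, b),
         qual = substr(cons$qualities, a, b))
  }

  if (status0 == "closed") {
    bl <- coord_of("__pseudo_left")
    br <- coord_of("__pseudo_right")
    if (is.na(bl) || is.na(br)) return(unfilled("pseudo read lost in MSA"))
    len_r <- nchar(placed$seq[ir])
    right_first <- br - len_r + 1
    if (right_first <= bl)
      return(unfilled("pseudo reads in inverted order"))
    s <- slice(bl + 1, right_first - 1)
    res <- structure(list(status = "closed", sequence = s$seq,
                          qualities = s$qual,
                          filled_length = nchar(s$seq),
                          n_reads = nrow(placed),
                          n_observations = length(fit$residuals),
                          n_outliers = length(fit$outliers),
                          dropped = msa$dropped, note = NULL),
                     class = "gap_result")
    return(res)
  }
  if (status0 == "left_extended") {
    bl <- coord_of("__pseudo_left")
    if (is.na(bl)) return(unfilled("pseudo read lost in MSA"))
    s <- slice(bl + 1, cons$start + nchar(cons$sequence) - 1)
    if (!nchar(s$seq)) return(unfilled("no extension beyond flank"))
    return(structure(list(status = "left_extended", sequence = s$seq,
                          qualities = s$qual, filled_length = nchar(s$seq),
                          n_reads = nrow(placed),
                          n_observations = length(fit$residuals),
                          n_outliers = length(fit$outliers),
                          dropped = msa$dropped, note = NULL),
                     class = "gap_result"))
  }
  br <- coord_of("__pseudo_right")
  if (is.na(br)) return(unfilled("pseudo read lost in MSA"))
  right_first <- br - nchar(placed$seq[ir]) + 1
  s <- slice(cons$start, right_first - 1)
  if (!nchar(s$seq)) return(unfilled("no extension beyond flank"))
  structure(list(status = "right_extended", sequence = s$seq,
                 qualities = s$qual, filled_length = nchar(s$seq),
                 n_reads = nrow(placed),
                 n_observations = length(fit$residuals),
                 n_outliers = length(fit$outliers),
                 dropped = msa$dropped, note = NULL),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> %s, %d bp filled (%s reads, %s obs, %s outliers)\n",
              x$status, x$filled_length, x$n_reads, x$n_observations,
              x$n_outliers))
  invisible(x)
}
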