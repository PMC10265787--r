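# Minimal hand-built pair tables for arithmetic checks.
mk_pairs <- function(pos1, strand1, pos2, strand2, len = 100,
                     rname = "s", mapq = 60) {
  n <- length(pos1)
  data.frame(qname = sprintf("q%03d", seq_len(n)),
             mate_1 = 1L, mapped_1 = !is.na(pos1), rname_1 = rname,
             pos_1 = pos1, strand_1 = strand1, mapq_1 = mapq,
             seq_1 = strrep("A", len), qual_1 = strrep("I", len),
             mate_2 = 2L, mapped_2 = !is.na(pos2), rname_2 = rname,
             pos_2 = pos2, strand_2 = strand2, mapq_2 = mapq,
             seq_2 = strrep("A", len), qual_2 = strrep("I", len),
             stringsAsFactors = FALSE)
}

test_that("insert statistics are estimated robustly from proper pairs", {
  g <- simulate_genome(60000, seed = 81)
  tr <- make_draft(g, list(c(30000, 30150)))
  dir <- withr::local_tempdir()
  sim <- simulate_paired_reads(tr, lib_profile(500, 50), read_len = 100,
                               coverage = 25, err_rate = 0, seed = 83,
                               dir = dir)
  pairs <- pair_alignments(read_alignments(sim$paths$sam))
  prof <- estimate_insert_stats(pairs)
  n <- sum(pairs$mapped_1 & pairs$mapped_2)
  expect_lt(abs(prof$mu - 500), 3 * 50 / sqrt(n) + 2)
  expect_lt(abs(prof$v - 50), 10) # MAD-based scale, truncation shrinks a bit

  # degenerate: identical inserts give v floored at 1
  p <- mk_pairs(pos1 = rep(0, 300), strand1 = "+",
                pos2 = rep(300, 300), strand2 = "-")
  prof2 <- estimate_insert_stats(p)
  expect_equal(prof2$mu, 400)
  expect_equal(prof2$v, 1)

  # user-supplied values bypass the estimator entirely
  prof3 <- estimate_insert_stats(data.frame(), mu = 415, v = 105)
  expect_equal(prof3$mu, 415)
  expect_equal(prof3$v, 105)

  expect_error(estimate_insert_stats(p[1:10, ]), "supply mu and v")
})

test_that("gap size follows the spanning-pair rule with fallbacks", {
  gap <- data.frame(scaffold = "s", start = 1000, end = 1350,
                    reported_size = 350, stringsAsFactors = FALSE)
  # one spanning pair: d_L = 100, d_R = 115, mu = 415 -> 415 - 100 - 115 = 200
  p <- mk_pairs(pos1 = 900, strand1 = "+", pos2 = 1465 - 1, strand2 = "-")
  # reverse rightmost = pos2 + 100 - 1 = 1563? set pos so e - end + 1 = 115
  p$pos_2 <- 1350 + 115 - 100 # e = pos + 99 -> d_R = e - 1350 + 1 = 115
  est <- estimate_gap_size(gap, p, lib_profile(415, 105),
                           correct_bias = FALSE)
  expect_equal(est, 200)

  # no spanning pair: fall back to the N-run length
  p2 <- mk_pairs(pos1 = 900, strand1 = "+", pos2 = 1100, strand2 = "-")
  expect_equal(estimate_gap_size(gap, p2, lib_profile(415, 105)), 350)

  # floor at 1
  p3 <- p; p3$pos_1 <- 1000 - 300; p3$pos_2 <- 1350 + 300 - 99
  expect_equal(estimate_gap_size(gap, p3, lib_profile(415, 105),
                                 correct_bias = FALSE), 1)
})

test_that("bias-corrected gap size concentrates near the truth", {
  g <- simulate_genome(40000, seed = 91)
  tr <- make_draft(g, list(c(20000, 20080)))
  dir <- withr::local_tempdir()
  sim <- simulate_paired_reads(tr, lib_profile(400, 40), read_len = 100,
                               coverage = 60, err_rate = 0, seed = 93,
                               dir = dir)
  pairs <- pair_alignments(read_alignments(sim$paths$sam))
  prof <- estimate_insert_stats(pairs)
  gap <- find_gaps(stats::setNames(tr$draft, "scaffold1"))[1, ]
  est <- estimate_gap_size(gap, pairs, prof)
  # median concentration: within 3 v / sqrt(n_span) plus a small slack for
  # the residual truncation-bias of the correction
  expect_lt(abs(est - 80), 3 * prof$v / sqrt(50) + 5)
})

test_that("read collection recruits only window-anchored pairs with correct priors", {
  prof <- lib_profile(415, 105)
  expect_equal(prof$mu + 3 * prof$v, 730) # the S. aureus recruitment window

  gap <- data.frame(scaffold = "s", start = 1000, end = 1200,
                    reported_size = 200, stringsAsFactors = FALSE)
  # anchor forward at d_anchor = 200 -> mate recruited with p = mu - 200
  p <- mk_pairs(pos1 = c(800, 1000 - 731), strand1 = "+",
                pos2 = c(NA, NA), strand2 = NA)
  p$seq_2 <- strrep("C", 100); p$mapped_2 <- FALSE
  got <- collect_gap_reads(gap, p, prof, gap_size = 200)
  expect_equal(nrow(got), 1) # the beyond-window anchor recruits nothing
  expect_equal(got$p, 415 - 200)
  # unmapped mate of a forward anchor is reverse-complemented onto the axis
  expect_equal(got$seq, strrep("G", 100))

  # right-flank anchor: reverse read ending at e, d_anchor = e - end + 1
  p2 <- mk_pairs(pos1 = c(NA), strand1 = NA, pos2 = c(1240), strand2 = "-")
  p2$mapped_1 <- FALSE; p2$seq_1 <- strrep("T", 100)
  got2 <- collect_gap_reads(gap, p2, prof, gap_size = 180)
  expect_equal(nrow(got2), 1)
  d_anchor <- (1240 + 99) - 1200 + 1
  expect_equal(got2$p, 180 - (415 - d_anchor) + 100)
  expect_equal(got2$seq, strrep("T", 100)) # kept as sequenced
})

test_that("priors track truth coordinates on a noiseless fixture", {
  fx <- fig1b_fixture()
  prof <- fx$profile
  gap <- find_gaps(fx$draft)[1, ]
  gs <- estimate_gap_size(gap, fx$pairs, prof)
  pl <- collect_gap_reads(gap, fx$pairs, prof, gs)
  truthco <- stats::setNames(fx$sim$read_truth$end - (fx$gap_true[1] - 1),
                             fx$sim$read_truth$id)
  err <- pl$p - truthco[pl$id]
  expect_lt(mean(abs(err)), 3 * prof$v)
  # every prior lies within the recruitment bounds
  win <- prof$mu + 3 * prof$v
  expect_true(all(pl$p >= -(win) & pl$p <= gs + win + 100))

  # enlarging the window never removes a recruit
  prof_wide <- lib_profile(prof$mu, prof$v * 1.3)
  pl_wide <- collect_gap_reads(gap, fx$pairs, prof_wide, gs)
  expect_true(all(pl$id %in% pl_wide$id))
})

test_that("pseudo reads are cut from the flanks with anchored coordinates", {
  gap <- data.frame(scaffold = "s", start = 8, end = 21, reported_size = 13,
                    stringsAsFactors = FALSE)
  sc <- paste0("TTTTACGT", strrep("N", 13), "TTGCAAAA")
  ps <- make_pseudo_reads(gap, sc, gap_size = 13, flank_len = 4,
                          min_flank = 2)
  expect_equal(ps$seq, c("ACGT", "TTGC"))
  expect_equal(ps$p, c(0, 17)) # right pseudo prior = G + flank_len
  expect_equal(ps$anchor, c(0, NA))

  # a flank below the minimum is omitted
  sc2 <- paste0("AC", strrep("N", 13), "TTGCAAAA")
  gap2 <- data.frame(scaffold = "s", start = 2, end = 15, reported_size = 13,
                     stringsAsFactors = FALSE)
  ps2 <- make_pseudo_reads(gap2, sc2, gap_size = 13, flank_len = 4,
                           min_flank = 3)
  expect_equal(ps2$id, "__pseudo_right")
})
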