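mk_layout <- function(seqs, coords, quals = NULL, ids = NULL) {
  data.frame(id = ids %||% sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = quals %||% strrep("I", nchar(seqs)), coord = coords,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical stacked reads give unanimous columns", {
  lay <- mk_layout(rep("ACGTACGT", 3), rep(8, 3))
  msa <- build_msa(lay)
  expect_length(msa$dropped, 0)
  for (col in which(colSums(!is.na(msa$bases)) > 0))
    expect_equal(length(unique(msa$bases[, col])), 1)
  cons <- call_consensus(msa)
  expect_equal(cons$sequence, "ACGTACGT")
})

test_that("offset reads concatenate without conflict columns", {
  lay <- mk_layout(c("AAAACCCC", "CCCCGGGG"), c(8, 12))
  msa <- build_msa(lay)
  cons <- call_consensus(msa)
  expect_equal(cons$sequence, "AAAACCCCGGGG")
  # no column holds two different base calls
  conflict <- apply(msa$bases, 2, function(x) length(unique(stats::na.omit(x))))
  expect_true(all(conflict <= 1))
})

test_that("a read incompatible with the running consensus is dropped", {
  lay <- mk_layout(c(strrep("A", 30), strrep("A", 30), strrep("C", 30)),
                   c(30, 30, 30))
  msa <- build_msa(lay)
  expect_equal(msa$dropped, "r3")
  expect_equal(nrow(msa$bases), 2)
})

test_that("consensus posteriors follow the quality model", {
  # three A's at Q30: posterior ~ 1, Phred capped at 60
  lay <- mk_layout(rep("A", 3), rep(1, 3), quals = rep("?", 3)) # '?' = Q30
  cons <- call_consensus(build_msa(lay, min_overlap_cols = 100))
  expect_equal(cons$sequence, "A")
  expect_equal(cons$phred, 60L)

  # equal-quality A/C tie resolves lexicographically to A
  lay2 <- mk_layout(c("A", "C"), c(1, 1))
  cons2 <- call_consensus(build_msa(lay2, min_overlap_cols = 100))
  expect_equal(cons2$sequence, "A")
  expect_equal(cons2$phred, 3L) # posterior 1/2 -> -10 log10(1/2) = 3.01

  # zero-coverage interior columns are N with Phred 0
  lay3 <- mk_layout(c("AAAA", "TTTT"), c(4, 12))
  cons3 <- call_consensus(build_msa(lay3))
  expect_equal(cons3$sequence, "AAAANNNNTTTT")
  expect_equal(cons3$phred[5:8], rep(0L, 4))
})

test_that("consensus error rate at 30x / 1% errors is below 1e-4", {
  set.seed(29)
  L <- 12000
  truth <- sample(c("A", "C", "G", "T"), L, TRUE)
  cov <- 30
  q <- 20L # Phred 20 = 1% error
  bases <- matrix(NA_character_, cov, L)
  for (r in seq_len(cov)) {
    b <- truth
    hit <- which(stats::runif(L) < 0.01)
    if (length(hit))
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    bases[r, ] <- b
  }
  msa <- structure(list(bases = bases,
                        quals = matrix(q, cov, L), start = 1,
                        ids = sprintf("r%d", seq_len(cov)),
                        coord = rep(L, cov), dropped = character(0)),
                   class = "gap_msa")
  cons <- call_consensus(msa)
  err <- mean(strsplit(cons$sequence, "")[[1]] != truth)
  expect_lt(err, 1e-4)
})

test_that("anchoring closes the Fig-1b-style tandem-repeat gap exactly", {
  fx <- fig1b_fixture()
  libs <- list(list(pairs = fx$pairs, profile = fx$profile))
  res <- close_all_gaps(fx$draft, libs, run_config())
  expect_equal(res$report$status, "closed")
  r <- res$results[[1]]
  want <- substr(fx$genome, fx$gap_true[1] + 1, fx$gap_true[2])
  expect_true(closed_correctly(r$sequence, want))
  # the triple tandem repeat is recovered with the right copy number
  region <- res$genome[["scaffold1"]]
  expect_equal(count_copies(substr(region, 1990, 2035), "GAACCCT"), 3)
  # closed length equals the true gap length on the noiseless fixture
  expect_equal(r$filled_length, diff(fx$gap_true))
  # and the whole genome is restored byte-for-byte
  expect_identical(region, fx$genome)
})

test_that("gaps with no surviving pseudo-read layout stay unfilled", {
  placed <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                       qual = c("IIII", "IIII"), p = c(0, 0),
                       lib = "lib1", v = 10, is_pseudo = FALSE,
                       anchor = NA_real_, stringsAsFactors = FALSE)
  fit <- structure(list(beta = c(0, 0), residuals = numeric(0),
                        outliers = integer(0), comp = c(1, 1)),
                   class = "robust_fit")
  res <- anchor_and_emit(fit, placed)
  expect_equal(res$status, "unfilled")
})

test_that("inverted pseudo reads yield a diagnosed unfilled result", {
  flank <- strrep("ACGT", 10)
  placed <- data.frame(
    id = c("__pseudo_left", "__pseudo_right"),
    seq = c(flank, flank), qual = strrep("I", 40), p = c(0, 20),
    lib = "flank", v = 0, is_pseudo = TRUE, anchor = c(0, NA),
    stringsAsFactors = FALSE)
  # fitted so the right pseudo sits entirely left of the left pseudo's end
  fit <- structure(list(beta = c(0, 10), residuals = 0, outliers = integer(0),
                        comp = c(1, 1)), class = "robust_fit")
  res <- anchor_and_emit(fit, placed)
  expect_equal(res$status, "unfilled")
  expect_match(res$note, "inverted|lost")
})
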