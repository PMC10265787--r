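test_that("incidence rows have exactly two non-zeros, -1 and +1", {
  obs <- data.frame(i = 1L, j = 2L, y = 5, score = 1, weight = 1,
                    outlier = FALSE)
  pr <- build_problem(obs, 2, priors = c(0, 5), anchors = c(0, NA))
  X <- as.matrix(pr$X)
  expect_equal(X, matrix(c(-1, 1), 1))
  expect_equal(pr$anchors$read, 1)
  expect_equal(pr$anchors$coord, 0)

  inst <- random_instance(n = 12, m = 30, out_frac = 0, seed = 7)
  Xd <- as.matrix(inst$X)
  expect_true(all(rowSums(Xd != 0) == 2))
  expect_true(all(rowSums(Xd) == 0))
  expect_true(all(Xd %in% c(-1, 0, 1)))
})

test_that("per-component incidence rank is n_k - 1 (dense oracle)", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:15, 1)
    m <- sample(n:(3 * n), 1)
    i <- sample(n, m, TRUE)
    j <- sapply(i, function(a) sample(setdiff(seq_len(n), a), 1))
    obs <- data.frame(i = pmin(i, j), j = pmax(i, j), y = 0, score = 1,
                      weight = 1, outlier = FALSE)
    obs <- obs[obs$i != obs$j, , drop = FALSE]
    pr <- build_problem(obs, n, priors = seq_len(n))
    X <- as.matrix(pr$X)
    for (cc in unique(pr$comp)) {
      members <- which(pr$comp == cc)
      rows <- which(obs$i %in% members | obs$j %in% members)
      if (!length(rows)) next # isolated read: 0 x 1 block, rank 0 = n_k - 1
      blk <- X[rows, members, drop = FALSE]
      expect_equal(qr(blk)$rank, length(members) - 1)
    }
  }
})

test_that("Huber closed forms hold exactly", {
  expect_equal(huber_weight(69, 2), 2 / 69)
  expect_equal(huber_weight(1.5, 2), 1)
  # continuity at the knot: both branches give c^2 / 2
  c0 <- 2
  expect_equal(huber_rho(c0, c0), c0^2 / 2)
  expect_equal(huber_rho(c0 + 1e-12, c0), c0^2 / 2, tolerance = 1e-9)
  expect_equal(huber_rho(0, 2), 0)
})

test_that("a single anchored chain solves in one iteration", {
  obs <- data.frame(i = 1L, j = 2L, y = 5, score = 1, weight = 1,
                    outlier = FALSE)
  pr <- build_problem(obs, 2, priors = c(0, 5), anchors = c(0, NA))
  fit <- huber_irls(pr)
  expect_equal(fit$beta, c(0, 5))
  expect_equal(fit$residuals, 0)
  expect_equal(fit$iterations, 1)
  expect_true(fit$converged)
})

test_that("IRLS matches a generic convex minimizer and descends monotonically", {
  for (s in 1:12) {
    inst <- random_instance(n = sample(8:20, 1), m = sample(20:60, 1),
                            out_frac = runif(1, 0, 0.3), seed = 1000 + s)
    cfg <- robust_config(alpha = 1e-7, max_iter = 500)
    fit <- huber_irls(inst, cfg)
    expect_true(all(diff(fit$objective) <= 1e-8))
    oracle <- huber_oracle(inst)
    expect_lt(max(abs(fit$beta - oracle)), 1e-4)
    # and the objective at the M-estimate never exceeds the OLS start
    ols <- ols_fit(inst)
    expect_lte(objective(inst, fit$beta), objective(inst, ols$beta) + 1e-9)
  }
})

test_that("two-step fit resists unit-offset outliers where OLS fails", {
  cp <- chain_problem(n = 25, links = 6, out_frac = 0.2, u = 7, seed = 11)
  pr <- build_problem(cp$obs, length(cp$truth), priors = cp$truth,
                      anchors = c(0, rep(NA_real_, length(cp$truth) - 1)))
  # the trimming threshold must sit below the smallest gross-error
  # magnitude, and the IRLS stopping tolerance below the trimming margin;
  # for a 7 bp unit the defaults (r_o = 10, alpha = 2) cannot separate
  # single-unit outliers
  fit <- two_step_fit(pr, robust_config(r_o = 5, alpha = 0.1))
  expect_equal(as.numeric(fit$beta), as.numeric(cp$truth))
  # every planted false overlap is flagged (step 1 may conservatively trim
  # a few borderline clean rows as well; their final residuals are zero)
  expect_true(all(cp$out_rows %in% fit$outliers))
  kept <- setdiff(seq_len(nrow(cp$obs)), fit$outliers)
  expect_true(all(abs(fit$residuals[kept]) < 1e-8))
  expect_true(all(abs(fit$residuals[cp$out_rows]) %in% c(7, 14)))

  ols <- ols_fit(pr)
  expect_gte(max(abs(ols$beta - cp$truth)), 7 / 4)
})

test_that("noiseless layouts are recovered exactly with no outliers", {
  cp <- chain_problem(n = 20, links = 2, out_frac = 0, seed = 13)
  pr <- build_problem(cp$obs, length(cp$truth), priors = cp$truth,
                      anchors = c(0, rep(NA_real_, length(cp$truth) - 1)))
  fit <- two_step_fit(pr)
  expect_equal(as.numeric(fit$beta), as.numeric(cp$truth))
  expect_length(fit$outliers, 0)
})

test_that("trimming a bridge splits the component and refits each part", {
  # two cliques joined only by a pair of contradictory bridge observations
  # (a lone consistent bridge would be unidentifiable -- the far clique
  # simply absorbs the shift); the conflict leaves both bridge residuals
  # beyond r_o, so trimming disconnects the component
  truth <- c(0, 5, 10, 100, 105, 110)
  obs <- data.frame(
    i = c(1, 1, 2, 4, 4, 5, 3, 3),
    j = c(2, 3, 3, 5, 6, 6, 4, 4),
    y = c(5, 10, 5, 5, 10, 5, 90, 90 + 69), # duplicated bridge, one false
    score = 1, weight = 1, outlier = FALSE)
  pr <- build_problem(obs, 6, priors = truth,
                      anchors = c(0, rep(NA_real_, 5)))
  fit <- two_step_fit(pr)
  expect_setequal(fit$outliers, c(7L, 8L))
  expect_equal(length(unique(fit$comp)), 2)
  # each part is internally consistent
  expect_equal(diff(fit$beta[1:3]), c(5, 5))
  expect_equal(diff(fit$beta[4:6]), c(5, 5))
})

test_that("anchor shift equivariance holds", {
  cp <- chain_problem(n = 15, links = 2, out_frac = 0.15, u = 7, seed = 17)
  n <- length(cp$truth)
  pr0 <- build_problem(cp$obs, n, priors = cp$truth,
                       anchors = c(0, rep(NA_real_, n - 1)))
  pr1 <- build_problem(cp$obs, n, priors = cp$truth,
                       anchors = c(1000, rep(NA_real_, n - 1)))
  f0 <- two_step_fit(pr0)
  f1 <- two_step_fit(pr1)
  expect_equal(f1$beta, f0$beta + 1000)
})

test_that("outlier influence on the M-estimate is bounded", {
  cp <- chain_problem(n = 15, links = 3, out_frac = 0, seed = 19)
  n <- length(cp$truth)
  one <- function(delta) {
    obs <- cp$obs
    obs$y[10] <- obs$y[10] + delta
    pr <- build_problem(obs, n, priors = cp$truth,
                        anchors = c(0, rep(NA_real_, n - 1)))
    huber_irls(pr, robust_config(alpha = 1e-7, max_iter = 500))$beta
  }
  b69 <- one(69)
  b138 <- one(138)
  # doubling the outlier's magnitude barely moves the estimate
  expect_lt(max(abs(b138 - b69)), 2)
})

test_that("rounding is to nearest with ties away from zero", {
  expect_equal(regapcloser:::round_half_away(c(1.4, 1.5, -1.5, -2.5, 0)),
               c(1, 2, -2, -3, 0))
})

test_that("degenerate problems are handled", {
  # no observations at all: coordinates fall back to anchors / priors
  obs <- data.frame(i = integer(), j = integer(), y = numeric(),
                    score = numeric(), weight = numeric(),
                    outlier = logical())
  pr <- build_problem(obs, 3, priors = c(5, 10, 15),
                      anchors = c(0, NA, NA))
  fit <- two_step_fit(pr)
  expect_equal(as.numeric(fit$beta), c(0, 10, 15))
})
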