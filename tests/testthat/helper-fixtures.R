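# Shared fixtures, all generated in code at test time.

# A small genome with one gap spanning a triple 7-bp tandem repeat
# ("GAACCCT" x 3), simulated error-free reads, and paired alignments.
fig1b_fixture <- function(coverage = 40, v = 20, seed = 5) {
  g <- simulate_genome(4000, list(repeat_spec("GAACCCT", 3, 2000)), seed = 3)
  tr <- make_draft(g, list(c(1995, 2025)))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_paired_reads(tr, lib_profile(300, v), read_len = 100,
                               coverage = coverage, err_rate = 0,
                               seed = seed, dir = dir)
  pairs <- pair_alignments(read_alignments(sim$paths$sam))
  list(genome = g, truth = tr, sim = sim, pairs = pairs,
       profile = estimate_insert_stats(pairs),
       draft = stats::setNames(tr$draft, "scaffold1"),
       gap_true = c(1995, 2025))
}

# A 69-bp unit repeated 2.9 times (span 200 bp); the gap starts at base 32 of
# the first unit and ends at the repeat end. Tight-insert library so the
# prior noise stays below half the unit size.
fig3a_fixture <- function(coverage = 80, seed = 13) {
  set.seed(9)
  unit <- paste(sample(c("A", "C", "G", "T"), 69, TRUE), collapse = "")
  g <- simulate_genome(6000, list(repeat_spec(unit, 2.9, 3000)), seed = 11)
  tr <- make_draft(g, list(c(3031, 3200)))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_paired_reads(tr, lib_profile(300, 15), read_len = 101,
                               coverage = coverage, err_rate = 0,
                               seed = seed, dir = dir)
  pairs <- pair_alignments(read_alignments(sim$paths$sam))
  list(genome = g, truth = tr, sim = sim, pairs = pairs, unit = unit,
       profile = estimate_insert_stats(pairs),
       draft = stats::setNames(tr$draft, "scaffold1"),
       gap_true = c(3031, 3200))
}

# Chain layout regression problem: n reads on a line, each overlapping its
# next `links` neighbours (the tiling density of a 30-80x short-read gap);
# a fraction of observations is offset by the repeat unit u. Outlier
# placement respects the identifiability conditions under which robust
# recovery is possible at all: true overlaps must dominate every graph cut
# (a majority-corrupted cut is observationally equivalent to a genuinely
# shifted placement) and every read's incident edges (a vertex whose
# corrupted edges rival its clean ones can come to rest a full unit away).
chain_problem <- function(n = 25, links = 6, out_frac = 0.2, u = 7,
                          seed = 1) {
  set.seed(seed)
  truth <- cumsum(c(0, sample(5:15, n - 1, TRUE)))
  i <- rep(seq_len(n - 1), each = links)
  j <- i + rep(seq_len(links), n - 1)
  keep <- j <= n
  i <- i[keep]; j <- j[keep]
  obs <- data.frame(i = i, j = j, y = truth[j] - truth[i], score = 1,
                    weight = 1, outlier = FALSE)
  m <- nrow(obs)
  n_out <- floor(out_frac * m)
  # candidate outlier rows: never the single i -> i+1 edge guarding a cut,
  # and no cut may have half or more of its crossing edges corrupted --
  # recovery is only identifiable when true overlaps dominate every cut
  # (a majority-corrupted cut looks like a genuine shifted placement)
  guard <- match(paste(seq_len(n - 1), 2:n), paste(obs$i, obs$j))
  cand <- setdiff(seq_len(m), guard)
  placement_ok <- function(rows) {
    for (t in seq_len(n - 1)) {
      cross <- which(obs$i <= t & obs$j > t)
      if (sum(cross %in% rows) >= length(cross) / 2) return(FALSE)
    }
    for (vv in seq_len(n)) {
      inc <- which(obs$i == vv | obs$j == vv)
      if (sum(inc %in% rows) > length(inc) / 3) return(FALSE)
    }
    TRUE
  }
  repeat {
    out_rows <- sort(sample(cand, min(n_out, length(cand))))
    if (placement_ok(out_rows)) break
  }
  signs <- sample(c(-1, 1), length(out_rows), TRUE)
  mult <- sample(1:2, length(out_rows), TRUE)
  obs$y[out_rows] <- obs$y[out_rows] + signs * mult * u
  list(obs = obs, truth = truth, out_rows = out_rows, u = u)
}

# Random connected regression instance for oracle comparisons. Outliers are
# confined to the extra random edges: the two clean low-noise spanning chains
# guarantee that every graph cut keeps edges in the quadratic zone of the
# Huber loss at the optimum, so the minimizer is unique and a per-coordinate
# comparison against the oracle is well-posed (a cut crossed only by
# linear-zone residuals with balanced signs would give a flat valley of
# equal-objective solutions).
random_instance <- function(n = 15, m = 40, out_frac = 0.2, seed = 1) {
  set.seed(seed)
  truth <- cumsum(c(0, sample(3:20, n - 1, TRUE)))
  gi <- c(seq_len(n - 1), seq_len(max(n - 2, 1)))
  gj <- c(2:n, seq_len(max(n - 2, 1)) + 2)
  keep <- gj <= n & gi != gj
  gi <- gi[keep]; gj <- gj[keep]
  guard <- data.frame(i = gi, j = gj,
                      y = truth[gj] - truth[gi] + rnorm(length(gi), 0, 0.5),
                      score = 1, weight = 1, outlier = FALSE)
  i <- sample(n, m, TRUE)
  j <- sapply(i, function(a) sample(setdiff(seq_len(n), a), 1))
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  extra <- data.frame(i = i, j = j,
                      y = truth[j] - truth[i] + rnorm(length(i)),
                      score = 1, weight = 1, outlier = FALSE)
  n_out <- floor(out_frac * nrow(extra))
  if (n_out > 0) {
    rows <- sample(nrow(extra), n_out)
    extra$y[rows] <- extra$y[rows] + sample(c(-1, 1), n_out, TRUE) * 50
  }
  obs <- rbind(guard, extra)
  build_problem(obs, n, priors = truth, anchors = c(0, rep(NA_real_, n - 1)))
}

# Generic convex-minimizer oracle for the Huber objective (BFGS with exact
# gradient), independent of the IRLS path.
huber_oracle <- function(problem, cfg = robust_config(), reltol = 1e-14) {
  n <- problem$n
  anchor <- problem$anchors$read[1]
  a_val <- problem$anchors$coord[1]
  free <- setdiff(seq_len(n), anchor)
  X <- as.matrix(problem$X)
  fn <- function(b) {
    beta <- numeric(n); beta[anchor] <- a_val; beta[free] <- b
    objective(problem, beta, cfg)
  }
  gr <- function(b) {
    beta <- numeric(n); beta[anchor] <- a_val; beta[free] <- b
    r <- problem$Y - as.vector(X %*% beta)
    psi <- ifelse(abs(r) <= cfg$c, r, cfg$c * sign(r))
    as.vector(-t(X[, free, drop = FALSE]) %*% (problem$w0 * psi))
  }
  start <- problem$priors[free]
  o <- stats::optim(start, fn, gr, method = "BFGS",
                    control = list(maxit = 5000, reltol = reltol))
  beta <- numeric(n); beta[anchor] <- a_val; beta[free] <- o$par
  beta
}

# Correctness criterion for a closed gap: the filled sequence must match the
# true gap sequence allowing a 15-bp soft clip on both ends.
closed_correctly <- function(filled, want, clip = 15) {
  if (is.null(filled) || nchar(filled) == 0) return(FALSE)
  if (nchar(want) <= 2 * clip) return(abs(nchar(filled) - nchar(want)) <= clip)
  core <- substr(want, clip + 1, nchar(want) - clip)
  grepl(core, filled, fixed = TRUE) &&
    abs(nchar(filled) - nchar(want)) <= 2 * clip
}

# Count tandem-repeat copies of `unit` in the reconstructed repeat region:
# longest run of consecutive unit matches (allowing the final partial copy),
# divided by the unit length.
count_copies <- function(seqn, unit) {
  u <- nchar(unit)
  best <- 0
  starts <- gregexpr(unit, seqn, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(0)
  for (s in starts) {
    pos <- s
    len <- 0
    while (substr(seqn, pos, pos + u - 1) == unit) {
      len <- len + u
      pos <- pos + u
    }
    # extend by the trailing partial copy
    tail_ <- substr(seqn, pos, nchar(seqn))
    part <- 0
    while (part < u &&
           substr(tail_, part + 1, part + 1) == substr(unit, part + 1,
                                                       part + 1))
      part <- part + 1
    best <- max(best, len + part)
  }
  best / u
}
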