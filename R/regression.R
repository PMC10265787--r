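#' Robust-regression configuration
#'
#' @param c Huber tuning constant in bp (default 2): residuals within `c`
#'   contribute quadratically to the loss, larger ones linearly. Smaller
#'   values resist outliers harder at the cost of statistical efficiency.
#' @param r_o Residual threshold in bp (default 10) above which an
#'   observation is declared a potential outlier after the M-step.
#' @param alpha IRLS convergence threshold on the max coordinate change in
#'   bp (default 2).
#' @param max_iter IRLS iteration cap (default 100).
#' @return An object of class `robust_config`.
#' @export
robust_config <- function(c = 2, r_o = 10, alpha = 2, max_iter = 100) {
  stopifnot(c > 0, r_o > 0, alpha > 0, max_iter >= 1)
  structure(list(c = c, r_o = r_o, alpha = alpha, max_iter = max_iter),
            class = "robust_config")
}

#' Huber loss and weight functions
#'
#' `huber_rho(e, c)` is `e^2/2` for `|e| <= c` and `c|e| - c^2/2` beyond
#' (continuous at the knot); `huber_weight(e, c)` is its induced IRLS weight,
#' 1 inside the knot and `c/|e|` outside.
#'
#' @param e Residual(s).
#' @param c Huber tuning constant.
#' @return Numeric vector.
#' @export
huber_rho <- function(e, c = 2) {
  ifelse(abs(e) <= c, e^2 / 2, c * abs(e) - c^2 / 2)
}

#' @rdname huber_rho
#' @export
huber_weight <- function(e, c = 2) {
  ifelse(abs(e) <= c, 1, c / abs(e))
}

#' Build the sparse incidence regression problem
#'
#' Encodes overlap observations as rows of an oriented incidence matrix:
#' row k has -1 in column `i_k` and +1 in column `j_k`, and the response is
#' the observed ending-base distance `y_k`. Weakly connected components of
#' the overlap graph are identified; each component gets one anchor that
#' pins its coordinate frame: the member with a fixed coordinate when
#' present (the left pseudo read at 0 takes precedence by having the
#' smallest anchor value), otherwise the member with the smallest prior,
#' anchored at that prior. Duplicate `(i, j)` observations are kept as
#' independent rows.
#'
#' @param obs Data.frame from [build_observations()] (`i`, `j`, `y`,
#'   `weight`).
#' @param n Number of reads; indices in `obs` must be in `1..n`.
#' @param priors Numeric vector of prior coordinates (length n); used to
#'   anchor components without a fixed-coordinate member.
#' @param anchors Numeric vector (length n): fixed coordinate of a read or
#'   NA. Pseudo reads typically carry 0 (left) and `gap_size + flank_len`
#'   (right; used only when the right pseudo's component lacks the left one).
#' @return An object of class `regression_problem`: `n`, `m`, `X` (sparse
#'   m x n), `Y`, `w0`, `comp` (component membership per read), `anchors`
#'   (data.frame `comp`, `read`, `coord`), `priors`, `fixed`.
#' @export
build_problem <- function(obs, n, priors = rep(0, n),
                          anchors = rep(NA_real_, n)) {
  stopifnot(n >= 1, all(obs$i >= 1), all(obs$j <= n), all(obs$i != obs$j))
  m <- nrow(obs)
  X <- Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(obs$i, obs$j),
                            x = c(rep(-1, m), rep(1, m)), dims = c(m, n))
  g <- igraph::graph_from_edgelist(cbind(obs$i, obs$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g, mode = "weak")$membership
  anc <- component_anchors(comp, priors, anchors)
  structure(list(n = n, m = m, X = X, Y = obs$y, w0 = obs$weight,
                 comp = comp, anchors = anc, priors = priors,
                 fixed = anchors, obs = obs),
            class = "regression_problem")
}

# Internal: one anchor per component. Fixed-coordinate members win (smallest
# coordinate first, so a left pseudo read at 0 beats the right one); else the
# member with the smallest prior is pinned at that prior.
component_anchors <- function(comp, priors, fixed) {
  rows <- lapply(sort(unique(comp)), function(cc) {
    members <- which(comp == cc)
    fx <- members[!is.na(fixed[members])]
    if (length(fx)) {
      r <- fx[which.min(fixed[fx])]
      data.frame(comp = cc, read = r, coord = fixed[r])
    } else {
      r <- members[which.min(priors[members])]
      data.frame(comp = cc, read = r, coord = priors[r])
    }
  })
  do.call(rbind, rows)
}

# Internal: weighted least squares on the anchored incidence system.
# Anchored coordinates are eliminated (moved to the right-hand side), so the
# anchor holds exactly and the reduced normal equations are nonsingular; the
# sparse system is solved by Matrix's Cholesky factorization.
solve_wls <- function(X, Y, w, anchor_read, anchor_coord, n) {
  beta <- rep(NA_real_, n)
  beta[anchor_read] <- anchor_coord
  # only columns that actually appear in a row are estimable; isolated
  # reads stay NA for the caller to fill from anchors/priors
  deg <- Matrix::colSums(abs(X))
  free <- setdiff(which(deg > 0), anchor_read)
  if (!length(free)) return(beta)
  Xf <- X[, free, drop = FALSE]
  rhs_adj <- Y - as.vector(X[, anchor_read, drop = FALSE] %*% anchor_coord)
  W <- Matrix::Diagonal(x = w)
  M <- Matrix::crossprod(Xf, W %*% Xf)
  b <- Matrix::crossprod(Xf, W %*% rhs_adj)
  beta[free] <- as.vector(Matrix::solve(M, b))
  beta
}

#' Huber M-estimate of read coordinates by IRLS
#'
#' Starts from the (initially weighted) least-squares solution and iterates
#' weighted normal-equation solves `X' W X beta = X' W Y` with
#' `W = w0 * w_H(residual)` until the coordinates move less than `alpha` in
#' the max norm or the iteration cap is reached. The Huber objective is
#' convex, so the iteration converges to the global minimum; residuals are
#' used in raw bp (no robust-scale standardisation — the tuning constant is
#' in the data's units).
#'
#' Reads in components with no observations keep their anchor coordinate.
#'
#' @param problem A [build_problem()] result.
#' @param cfg A [robust_config()].
#' @return List: `beta` (length n, real-valued), `residuals` (length m),
#'   `iterations`, `converged`, `objective` (trace, one value per iterate).
#' @export
huber_irls <- function(problem, cfg = robust_config()) {
  n <- problem$n; m <- problem$m
  beta <- rep(NA_real_, n)
  # isolated components (no incident rows) sit at their anchor
  deg <- if (m) Matrix::colSums(abs(problem$X)) else rep(0, n)
  for (k in seq_len(nrow(problem$anchors)))
    beta[problem$anchors$read[k]] <- problem$anchors$coord[k]
  if (m == 0) {
    idx <- which(is.na(beta))
    beta[idx] <- problem$priors[idx]
    return(list(beta = beta, residuals = numeric(0), iterations = 0,
                converged = TRUE, objective = numeric(0)))
  }
  active <- deg > 0
  # solve each connected part jointly: eliminate all anchors of active comps
  acomp <- unique(problem$comp[active])
  anc <- problem$anchors[problem$anchors$comp %in% acomp, , drop = FALSE]

  w0 <- problem$w0
  fit <- solve_wls(problem$X, problem$Y, w0, anc$read, anc$coord, n)
  beta_cur <- fit
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(cfg$max_iter)) {
    resid <- problem$Y - as.vector(problem$X %*% ifelse(is.na(beta_cur), 0,
                                                        beta_cur))
    obj <- c(obj, sum(w0 * huber_rho(resid, cfg$c)))
    w <- w0 * huber_weight(resid, cfg$c)
    beta_new <- solve_wls(problem$X, problem$Y, w, anc$read, anc$coord, n)
    delta <- max(abs(beta_new - beta_cur), na.rm = TRUE)
    beta_cur <- beta_new
    if (delta < cfg$alpha) { converged <- TRUE; break }
  }
  resid <- problem$Y - as.vector(problem$X %*% ifelse(is.na(beta_cur), 0,
                                                      beta_cur))
  obj <- c(obj, sum(w0 * huber_rho(resid, cfg$c)))
  # isolated non-anchor reads keep their prior
  idx <- which(is.na(beta_cur))
  beta_cur[idx] <- ifelse(!is.na(problem$fixed[idx]), problem$fixed[idx],
                          problem$priors[idx])
  list(beta = beta_cur, residuals = resid, iterations = iter,
       converged = converged, objective = obj)
}

#' Huber objective of the incidence model
#'
#' `sum_k w0_k * rho_H(y_k - (beta_j - beta_i))`; reduces to the plain Huber
#' loss sum when all initial weights are 1.
#'
#' @param problem A [build_problem()] result.
#' @param beta Coordinate vector of length n.
#' @param cfg A [robust_config()].
#' @return Scalar loss value.
#' @export
objective <- function(problem, beta, cfg = robust_config()) {
  if (problem$m == 0) return(0)
  resid <- problem$Y - as.vector(problem$X %*% beta)
  sum(problem$w0 * huber_rho(resid, cfg$c))
}

#' Plain (initially weighted) least-squares fit, for contrast
#'
#' The non-robust estimate the two-step procedure improves upon: one
#' weighted normal-equation solve with the initial weights only. A single
#' gross outlier can displace every coordinate in its component.
#'
#' @inheritParams huber_irls
#' @return List with `beta` and `residuals`.
#' @export
ols_fit <- function(problem) {
  fit <- huber_irls(problem, robust_config(c = Inf, max_iter = 1,
                                           alpha = Inf))
  list(beta = fit$beta, residuals = fit$residuals)
}

#' Two-step robust fit: Huber IRLS then trimmed OLS
#'
#' Step 1 computes the Huber M-estimate and flags observations whose
#' absolute residual exceeds `r_o` as potential outliers. Step 2 refits by
#' ordinary least squares on the remaining rows. Removing rows can
#' disconnect a component; each resulting sub-component is re-anchored (a
#' fixed-coordinate member when present, else the smallest-prior member at
#' its prior) and fitted on its own rows. Final coordinates are rounded to
#' the nearest integer, ties away from zero. A component reduced to a
#' single read keeps its anchor (or prior) as its coordinate.
#'
#' @inheritParams huber_irls
#' @return An object of class `robust_fit`: `beta` (integer coordinates),
#'   `beta_real`, `beta_m` (step-1 estimate), `residuals` (all m rows at the
#'   final estimate), `outliers` (index set I_o), `iterations`, `converged`,
#'   `comp` (final component membership per read).
#' @export
two_step_fit <- function(problem, cfg = robust_config()) {
  n <- problem$n; m <- problem$m
  s1 <- huber_irls(problem, cfg)
  if (m == 0) {
    beta <- round_half_away(s1$beta)
    return(structure(list(beta = beta, beta_real = s1$beta,
                          beta_m = s1$beta, residuals = numeric(0),
                          outliers = integer(0), iterations = 0,
                          converged = TRUE, comp = problem$comp),
                     class = "robust_fit"))
  }
  I_o <- which(abs(s1$residuals) > cfg$r_o)
  keep <- setdiff(seq_len(m), I_o)

  # re-derive components on the trimmed overlap graph
  obs_k <- problem$obs[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(obs_k$i, obs_k$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp2 <- igraph::components(g, mode = "weak")$membership
  anc2 <- component_anchors(comp2, problem$priors, problem$fixed)

  beta <- rep(NA_real_, n)
  if (length(keep)) {
    Xk <- problem$X[keep, , drop = FALSE]
    deg <- Matrix::colSums(abs(Xk))
    acomp <- unique(comp2[deg > 0])
    anc_active <- anc2[anc2$comp %in% acomp, , drop = FALSE]
    beta <- solve_wls(Xk, problem$Y[keep], problem$w0[keep],
                      anc_active$read, anc_active$coord, n)
  }
  # singleton / row-less components: anchor or prior
  idx <- which(is.na(beta))
  beta[idx] <- ifelse(!is.na(problem$fixed[idx]), problem$fixed[idx],
                      problem$priors[idx])
  # final residuals are reported at the rounded (integer) coordinates the
  # layout actually uses
  resid <- problem$Y - as.vector(problem$X %*% round_half_away(beta))
  structure(list(beta = round_half_away(beta), beta_real = beta,
                 beta_m = s1$beta, residuals = resid, outliers = I_o,
                 iterations = s1$iterations, converged = s1$converged,
                 comp = comp2),
            class = "robust_fit")
}

# Rounding with ties away from zero (documented: 0.5 -> 1, -0.5 -> -1).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "<robust_fit> %d reads, %d observations, %d outliers, %d IRLS iterations%s\n",
    length(x$beta), length(x$residuals), length(x$outliers), x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}
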