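# Constrained linear attribution of Purkinje-cell activity to granule-cell
# and inferior-olive cluster regressors:
#
#   PC_i(t) = offset_i + sum_j GCcoeff_ij GCreg_j(t) + sum_k IONcoeff_ik IONreg_k(t)
#
# with offset in [-5, 5], coefficients in [0, 1000], an L1 penalty on the
# coefficients (linear in them, since they are nonnegative), leave-one-out
# lambda cross-validation, a regressor-wise shuffle null on the test cost,
# and a GC/ION contribution index.

#' Build kernel-matched cluster regressors
#'
#' Upstream cluster mean responses are deconvolved with the indicator
#' kernel they were recorded under and re-convolved with the Purkinje
#' cells' (slower) indicator kernel so all traces live on a common sensor
#' timescale. Each matched trace is then shifted so its minimum sits at
#' epsilon above zero (epsilon = `epsilon_frac` of its range) and scaled so
#' its integral (sum x frame_period) is 1.
#'
#' @param gc_means,ion_means cluster x frames matrices of cluster mean
#'   responses on a common frame grid.
#' @param kernel_from indicator kernel of the recorded populations.
#' @param kernel_to indicator kernel of the target population.
#' @param frame_period seconds per frame.
#' @param epsilon_frac positivity margin as a fraction of each trace's
#'   range (default 1e-3).
#' @return object of class `cluster_regressors`: `gc` (frames x J), `ion`
#'   (frames x K), `names`, `frame_period`.
#' @export
build_cluster_regressors <- function(gc_means, ion_means, kernel_from,
                                     kernel_to, frame_period,
                                     epsilon_frac = 1e-3) {
  match_one <- function(x) {
    if (stats::sd(x) == 0) stop("cluster mean is constant")
    y <- convolve_kernel(deconvolve_kernel(x, kernel_from), kernel_to)
    rng <- diff(range(y))
    y <- y - min(y) + epsilon_frac * rng
    y / (sum(y) * frame_period)
  }
  gc <- apply(rbind(gc_means), 1, match_one)
  ion <- apply(rbind(ion_means), 1, match_one)
  structure(
    list(gc = gc, ion = ion,
         names = c(paste0("GC", seq_len(ncol(gc))),
                   paste0("ION", seq_len(ncol(ion)))),
         frame_period = frame_period),
    class = "cluster_regressors"
  )
}

#' Preprocess Purkinje-cell trials for model fitting
#'
#' Each trial is z-scored, high-pass filtered at 1/80 Hz (first-order
#' Butterworth applied forward-backward, so slow drifts are removed with
#' zero phase) and smoothed with a centered 3-point boxcar. Two trials are
#' held out (seeded draw) as the test set; the rest are fit trials.
#'
#' @param trials trials x frames matrix (>= 6 trials).
#' @param frame_period seconds per frame.
#' @param seed seed for the test-trial draw.
#' @param cutoff_hz high-pass cutoff (default 1/80 Hz).
#' @param n_test held-out trials (default 2).
#' @return object of class `pc_prep`: `values` (trials x frames,
#'   processed), `fit_trials`, `test_trials`, `degenerate` (flags trials
#'   that were constant before z-scoring).
#' @export
preprocess_pc <- function(trials, frame_period, seed = 0L,
                          cutoff_hz = 1 / 80, n_test = 2L) {
  trials <- rbind(trials)
  n_trials <- nrow(trials)
  if (n_trials < 6) stop("preprocessing requires >= 6 trials (4 fit + 2 test)")
  degenerate <- apply(trials, 1, function(x) stats::sd(x, na.rm = TRUE) == 0)
  z <- t(apply(trials, 1, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x))
    else (x - mean(x, na.rm = TRUE)) / s
  }))
  nyquist <- 1 / (2 * frame_period)
  bf <- signal::butter(1, cutoff_hz / nyquist, type = "high")
  hp <- t(apply(z, 1, function(x) signal::filtfilt(bf, x)))
  sm <- t(apply(hp, 1, function(x) {
    stats::filter(x, rep(1 / 3, 3), sides = 2) |>
      (\(y) { y[1] <- x[1]; y[length(y)] <- x[length(x)]; as.numeric(y) })()
  }))
  test_trials <- local({ set.seed(seed); sort(sample(n_trials, n_test)) })
  structure(
    list(values = sm, fit_trials = setdiff(seq_len(n_trials), test_trials),
         test_trials = test_trials, frame_period = frame_period,
         degenerate = degenerate),
    class = "pc_prep"
  )
}

# Design matrix [1 | GC | ION] for one trial's frames.
pc_design <- function(regs) {
  cbind(offset = 1, regs$gc, regs$ion)
}

# Minimize 1/2 t(th) H th + g . th subject to lower <= th <= upper, for
# positive semidefinite H: active-set iterations in the style of
# Lawson-Hanson NNLS. Variables pinned at a bound are released when their
# KKT multiplier points inward; free variables are solved exactly, so
# solutions are accurate to the conditioning of H (no first-order
# optimizer tolerance).
solve_box_qp <- function(H, g, lower, upper, max_iter = 200L, tol = 1e-10) {
  p <- length(g)
  th <- pmin(pmax(rep(0, p), lower), upper)
  at_lo <- th <= lower + tol
  at_up <- th >= upper - tol
  for (it in seq_len(max_iter)) {
    fixed <- at_lo | at_up
    free <- which(!fixed)
    if (length(free) > 0) {
      rhs <- -(g[free] + H[free, fixed, drop = FALSE] %*% th[fixed])
      sol <- tryCatch(
        solve(H[free, free, drop = FALSE], rhs),
        error = function(e) qr.solve(H[free, free, drop = FALSE], rhs)
      )
      th_free <- drop(sol)
      # clip any free variable that left the box and pin it
      out_lo <- th_free < lower[free]
      out_up <- th_free > upper[free]
      th[free] <- pmin(pmax(th_free, lower[free]), upper[free])
      if (any(out_lo) || any(out_up)) {
        at_lo[free[out_lo]] <- TRUE
        at_up[free[out_up]] <- TRUE
        next
      }
    }
    grad <- drop(H %*% th + g)
    release_lo <- at_lo & grad < -tol
    release_up <- at_up & grad > tol
    if (!any(release_lo) && !any(release_up)) break
    # release the single worst violator (Lawson-Hanson rule)
    viol <- pmax(ifelse(at_lo, -grad, 0), ifelse(at_up, grad, 0))
    k <- which.max(viol)
    at_lo[k] <- FALSE
    at_up[k] <- FALSE
  }
  # values a rounding error away from a bound are the bound
  snap <- 1e-9
  th <- ifelse(th - lower < snap, lower, th)
  th <- ifelse(upper - th < snap, upper, th)
  th
}

#' Fit the constrained Purkinje-cell model at a fixed penalty
#'
#' Minimizes the mean squared error between the concatenated fit trials
#' and `offset + GC/ION regressor mixture`, plus `lambda` times the sum of
#' the coefficients (their L1 norm — they are bound to be nonnegative),
#' subject to offset in \[-5, 5\] and coefficients in \[0, 1000\]. The
#' penalty is linear in the coefficients on the feasible box, so the
#' objective is a convex quadratic, solved deterministically by exact
#' active-set iterations from an all-zero start.
#'
#' @param prep a `pc_prep` for one cell.
#' @param regs a `cluster_regressors`.
#' @param lambda L1 penalty weight (>= 0).
#' @param fit_trials trials to fit on (default `prep$fit_trials`).
#' @return object of class `pc_fit`: `offset`, `gc_coeffs`, `ion_coeffs`,
#'   `lambda`, `fit_cost` (penalized MSE at the solution).
#' @export
fit_pc <- function(prep, regs, lambda, fit_trials = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(fit_trials)) fit_trials <- prep$fit_trials
  y <- as.vector(t(prep$values[fit_trials, , drop = FALSE]))
  D1 <- pc_design(regs)
  D <- do.call(rbind, rep(list(D1), length(fit_trials)))
  n <- length(y)
  J <- ncol(regs$gc); K <- ncol(regs$ion)
  p <- 1 + J + K
  DtD <- crossprod(D) / n
  Dty <- crossprod(D, y) / n
  yty <- sum(y^2) / n
  pen <- c(0, rep(lambda, J + K))  # offset unpenalized
  # objective = th' DtD th - 2 Dty' th + yty + pen' th, a box QP
  th <- solve_box_qp(H = 2 * DtD, g = -2 * drop(Dty) + pen,
                     lower = c(-5, rep(0, J + K)),
                     upper = c(5, rep(1000, J + K)))
  fit_cost <- drop(yty - 2 * crossprod(th, Dty) +
                     crossprod(th, DtD %*% th)) + sum(pen * th)
  structure(
    list(offset = th[1], gc_coeffs = th[1 + seq_len(J)],
         ion_coeffs = th[1 + J + seq_len(K)], lambda = lambda,
         fit_cost = fit_cost),
    class = "pc_fit"
  )
}

#' Leave-one-out cross-validation of the L1 penalty
#'
#' For each lambda on a logarithmic sweep (1e-7 to 1e-2 by default), the
#' model is trained on all fit trials but one and its unpenalized MSE on
#' the held-out trial is averaged over folds; returns the cost-minimizing
#' lambda. Across a population, use [average_lambda()] and refit all cells
#' with the shared value.
#'
#' @param prep a `pc_prep`.
#' @param regs a `cluster_regressors`.
#' @param grid lambda candidates.
#' @return list with `lambda` (the winner), `grid`, `cv_cost` per lambda.
#' @export
crossval_lambda <- function(prep, regs,
                            grid = 10^seq(-7, -2, length.out = 11)) {
  ft <- prep$fit_trials
  if (length(ft) < 2) stop("lambda cross-validation needs >= 2 fit trials")
  D1 <- pc_design(regs)
  cv_cost <- vapply(grid, function(lam) {
    errs <- vapply(ft, function(held) {
      f <- fit_pc(prep, regs, lam, fit_trials = setdiff(ft, held))
      pred <- drop(D1 %*% c(f$offset, f$gc_coeffs, f$ion_coeffs))
      mean((prep$values[held, ] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # ties (e.g. every lambda past the all-zero point) resolve toward the
  # strongest regularization
  best <- max(grid[cv_cost <= min(cv_cost) + 1e-12])
  list(lambda = best, grid = grid, cv_cost = cv_cost)
}

#' Population-level penalty: geometric mean of per-cell lambdas
#'
#' The per-cell cross-validated lambdas live on a logarithmic sweep, so
#' their population average is taken on the log scale; the shared value is
#' then used to refit every cell, making fitted weights comparable across
#' cells.
#'
#' @param lambdas per-cell cross-validated penalties.
#' @export
average_lambda <- function(lambdas) {
  exp(mean(log(lambdas[is.finite(lambdas) & lambdas > 0])))
}

#' Model prediction for one trial
#' @param fit a `pc_fit`.
#' @param regs the `cluster_regressors` it was fit with.
#' @export
predict_pc <- function(fit, regs) {
  drop(pc_design(regs) %*% c(fit$offset, fit$gc_coeffs, fit$ion_coeffs))
}

#' Test cost of a fitted cell
#'
#' Mean squared error between the model prediction and the average of the
#' held-out test trials.
#'
#' @param fit a `pc_fit`.
#' @param prep the cell's `pc_prep`.
#' @param regs the `cluster_regressors`.
#' @export
evaluate_test_cost <- function(fit, prep, regs) {
  test_avg <- colMeans(prep$values[prep$test_trials, , drop = FALSE])
  mean((test_avg - predict_pc(fit, regs))^2)
}

#' Regressor-wise shuffle null for fit quality
#'
#' All cells' fitted weights form a cells x regressors matrix; in each
#' shuffle every regressor's column of weights is permuted independently
#' across cells, and each cell's intercept is refit to its own fit trials
#' (the regressors are all positive, so a draw's total weight would
#' otherwise shift the prediction mean and penalize every recombination
#' regardless of shape). Test costs of all shuffled fits are pooled into
#' one null distribution and the threshold is its 5th percentile, so only
#' 5% of random recombinations across the population could beat it. A
#' cell's fit is better than chance when its true test cost is strictly
#' below the threshold.
#'
#' @param fits list of `pc_fit` (one per cell, shared regressors/lambda).
#' @param preps list of `pc_prep`, parallel to `fits`.
#' @param regs the shared `cluster_regressors`.
#' @param n_shuffles number of random recombinations (default 100).
#' @param seed RNG seed.
#' @return list with `threshold` (scalar, 5th percentile of the pooled
#'   null), `test_cost` (per cell), `better_than_chance` (logical),
#'   `shuffle_costs` (cells x shuffles).
#' @export
shuffle_null <- function(fits, preps, regs, n_shuffles = 100L, seed = 0L) {
  n_cells <- length(fits)
  if (n_cells < 2) stop("shuffle null requires >= 2 cells")
  W <- cbind(
    offset = vapply(fits, `[[`, numeric(1), "offset"),
    t(vapply(fits, function(f) c(f$gc_coeffs, f$ion_coeffs),
             numeric(length(fits[[1]]$gc_coeffs) +
                       length(fits[[1]]$ion_coeffs))))
  )
  D1 <- pc_design(regs)
  test_avg <- t(vapply(preps, function(p) {
    colMeans(p$values[p$test_trials, , drop = FALSE])
  }, numeric(nrow(D1))))
  true_cost <- vapply(seq_len(n_cells), function(i) {
    mean((test_avg[i, ] - drop(D1 %*% W[i, ]))^2)
  }, numeric(1))
  fit_mean <- vapply(preps, function(p) {
    mean(p$values[p$fit_trials, , drop = FALSE])
  }, numeric(1))
  set.seed(seed)
  shuffle_costs <- matrix(NA_real_, n_cells, n_shuffles)
  for (s in seq_len(n_shuffles)) {
    Ws <- W
    for (j in 2:ncol(W)) Ws[, j] <- W[sample(n_cells), j]
    pred <- D1[, -1, drop = FALSE] %*% t(Ws[, -1, drop = FALSE])
    # per-cell intercept refit on the fit trials
    offs <- pmin(pmax(fit_mean - colMeans(pred), -5), 5)
    pred <- sweep(pred, 2, offs, "+")
    shuffle_costs[, s] <- colMeans((t(test_avg) - pred)^2)
  }
  threshold <- stats::quantile(as.vector(shuffle_costs), probs = 0.05,
                               names = FALSE)
  list(threshold = threshold, test_cost = true_cost,
       better_than_chance = true_cost < threshold,
       shuffle_costs = shuffle_costs)
}

#' GC/ION contribution index
#'
#' `(sum GC coefficients - sum ION coefficients) / (sum of all
#' coefficients)`: +1 when only granule-cell clusters carry weight, -1
#' when only inferior-olive clusters do, NA when all weights are zero.
#'
#' @param fit a `pc_fit`.
#' @export
gc_ion_index <- function(fit) {
  sg <- sum(fit$gc_coeffs); si <- sum(fit$ion_coeffs)
  if (sg + si == 0) return(NA_real_)
  (sg - si) / (sg + si)
}

#' Spearman correlation between reliability and GC/ION index
#'
#' Tests whether Purkinje cells dominated by granule-cell input respond
#' more reliably than cells dominated by inferior-olive input.
#'
#' @param indices per-cell GC/ION indices.
#' @param reliabilities per-cell reliability scores.
#' @return list with `rho` and `p` (two-sided).
#' @export
reliability_vs_index <- function(indices, reliabilities) {
  ok <- is.finite(indices) & is.finite(reliabilities)
  if (sum(ok) < 4) stop("need >= 4 paired finite values")
  if (length(unique(indices[ok])) < 2 ||
      length(unique(reliabilities[ok])) < 2) {
    stop("ties-only input: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(reliabilities[ok], indices[ok], method = "spearman",
                    exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}
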