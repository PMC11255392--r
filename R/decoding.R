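# Decoding instantaneous luminance (RBF support-vector regression) and time
# since stimulus onset (ridge regression) from per-frame population vectors.
#
# Population vectors are assembled from trial-wise traces with each cell
# potentially drawn from a different recording, so noise correlations
# between cells are not represented — decoding quantifies single-cell
# information content, not joint-population structure.

#' Train/test trial split for decoding
#'
#' Draws 10 training and 2 test trials uniformly at random (seeded); only
#' cells with data from at least 12 trials are eligible.
#'
#' @param tensor a `trial_tensor`.
#' @param seed integer RNG seed.
#' @param n_train,n_test trials per role (defaults 10 and 2).
#' @return list with `train_trials`, `test_trials`, `eligible_cells`.
#' @export
make_split <- function(tensor, seed, n_train = 10L, n_test = 2L) {
  v <- tensor$values
  n_trials <- dim(v)[2]
  need <- n_train + n_test
  trials_per_cell <- apply(v, 1, function(cell) {
    sum(apply(cell, 1, function(tr) any(!is.na(tr))))
  })
  eligible <- which(trials_per_cell >= need)
  if (n_trials < need) stop("need at least ", need, " trials")
  if (length(eligible) == 0) stop("no cell has data from >= ", need, " trials")
  rng <- local({ set.seed(seed); sample(n_trials, need) })
  list(train_trials = sort(rng[seq_len(n_train)]),
       test_trials = sort(rng[n_train + seq_len(n_test)]),
       eligible_cells = eligible)
}

# Closed-form ridge regression with intercept; features standardized with
# training-set statistics. Returns a predict(newX) closure.
ridge_fit <- function(X, y, lambda) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ybar <- mean(y)
  p <- ncol(Z)
  beta <- solve(crossprod(Z) + diag(lambda, p), crossprod(Z, y - ybar))
  function(newX) {
    Zn <- sweep(sweep(newX, 2, mu), 2, sdv, "/")
    drop(Zn %*% beta) + ybar
  }
}

r_squared <- function(truth, pred) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

# Stack selected trials of eligible cells into a frames x cells feature
# matrix plus per-frame targets.
pool_frames <- function(tensor, cells, trials, frames, target) {
  v <- tensor$values
  X <- do.call(rbind, lapply(trials, function(tr) {
    arr <- v[cells, tr, frames, drop = FALSE]
    t(matrix(arr, length(cells), length(frames)))
  }))
  list(X = X, y = rep(target, length(trials)),
       trial = rep(trials, each = length(frames)))
}

#' Decode time since stimulus onset with ridge regression
#'
#' Frames within `onset_window` are labelled with seconds elapsed since the
#' window start; a ridge regressor maps per-frame population vectors to
#' that label. The ridge penalty is chosen by leave-one-trial-out grid
#' search over a 9-point logarithmic grid (1e-4 to 1e4) on the training
#' trials, and performance is the coefficient of determination (1 -
#' SSE/SST) on pooled test frames.
#'
#' @param tensor a `trial_tensor`.
#' @param split a split from [make_split()].
#' @param onset_window frame indices within a trial (>= 2 frames).
#' @param lambda_grid ridge penalty candidates.
#' @return list with `predictions`, `truth`, `r2`, `model_kind = "ridge"`,
#'   `regularization`, `n_cells`, and `model` (the trained predictor, a
#'   function of a frames x cells matrix).
#' @export
decode_time <- function(tensor, split, onset_window,
                        lambda_grid = 10^seq(-4, 4, length.out = 9)) {
  if (length(onset_window) < 2) stop("onset window is degenerate")
  cells <- split$eligible_cells
  target <- (seq_along(onset_window) - 1) * tensor$frame_period
  train <- pool_frames(tensor, cells, split$train_trials, onset_window, target)
  cv_err <- vapply(lambda_grid, function(lam) {
    errs <- vapply(split$train_trials, function(held) {
      in_tr <- train$trial != held
      fit <- ridge_fit(train$X[in_tr, , drop = FALSE], train$y[in_tr], lam)
      mean((train$y[!in_tr] - fit(train$X[!in_tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv_err)]
  fit <- ridge_fit(train$X, train$y, lambda)
  test <- pool_frames(tensor, cells, split$test_trials, onset_window, target)
  pred <- fit(test$X)
  list(predictions = pred, truth = test$y, r2 = r_squared(test$y, pred),
       model_kind = "ridge", regularization = lambda,
       n_cells = length(cells), model = fit)
}

#' Decode instantaneous luminance with RBF support-vector regression
#'
#' Per-frame population vectors are mapped to the displayed luminance with
#' an epsilon-SVR and radial-basis kernel (via `e1071`); the single cost
#' parameter is grid-searched leave-one-trial-out on the training trials.
#'
#' @param tensor a `trial_tensor` whose `trial_stimulus` labels each frame.
#' @param split a split from [make_split()].
#' @param frames frame indices within a trial to decode (default all).
#' @param cost_grid SVR cost candidates (9-point log grid, 1e-2 to 1e2).
#' @return list with `predictions`, `truth`, `r2`, `by_level` (mean
#'   prediction per true level), `model_kind = "svr"`, `regularization`,
#'   `n_cells`.
#' @export
decode_luminance <- function(tensor, split, frames = NULL,
                             cost_grid = 10^seq(-2, 2, length.out = 9)) {
  cells <- split$eligible_cells
  if (is.null(frames)) frames <- seq_along(tensor$trial_stimulus)
  target <- tensor$trial_stimulus[frames]
  train <- pool_frames(tensor, cells, split$train_trials, frames, target)
  mu <- colMeans(train$X); sdv <- apply(train$X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  Ztr <- std(train$X)
  cv_err <- vapply(cost_grid, function(cost) {
    errs <- vapply(split$train_trials, function(held) {
      in_tr <- train$trial != held
      m <- e1071::svm(Ztr[in_tr, , drop = FALSE], train$y[in_tr],
                      type = "eps-regression", kernel = "radial",
                      cost = cost, scale = FALSE)
      mean((train$y[!in_tr] -
              stats::predict(m, Ztr[!in_tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  cost <- cost_grid[which.min(cv_err)]
  model <- e1071::svm(Ztr, train$y, type = "eps-regression",
                      kernel = "radial", cost = cost, scale = FALSE)
  test <- pool_frames(tensor, cells, split$test_trials, frames, target)
  pred <- stats::predict(model, std(test$X))
  list(predictions = pred, truth = test$y, r2 = r_squared(test$y, pred),
       by_level = tapply(pred, test$y, mean),
       model_kind = "svr", regularization = cost, n_cells = length(cells))
}

#' Repeated decoding on random cell subsets
#'
#' Runs the decoding analysis on `n_iterations` seeded random subsets of
#' `n_cells` cells (e.g. granule cells downsampled to match the inferior
#' olive population size) and summarizes the R2 distribution.
#'
#' @param tensor a `trial_tensor`.
#' @param n_cells subset size.
#' @param n_iterations number of seeded subsets.
#' @param seed base RNG seed; iteration i uses `seed + i`.
#' @param task `"time"` or `"luminance"`.
#' @param ... passed to the task's decoder (e.g. `onset_window`).
#' @return list with `results` (per-iteration decoder outputs), `r2`
#'   vector, `mean_r2`, `sd_r2`.
#' @export
subsample_decode <- function(tensor, n_cells, n_iterations, seed,
                             task = c("time", "luminance"), ...) {
  task <- match.arg(task)
  n_pop <- dim(tensor$values)[1]
  if (n_cells > n_pop) stop("n_cells exceeds the population size")
  results <- lapply(seq_len(n_iterations), function(i) {
    set.seed(seed + i)
    sub <- sort(sample(n_pop, n_cells))
    sub_tensor <- tensor
    sub_tensor$values <- tensor$values[sub, , , drop = FALSE]
    split <- make_split(sub_tensor, seed = seed + i)
    if (task == "time") decode_time(sub_tensor, split, ...)
    else decode_luminance(sub_tensor, split, ...)
  })
  r2 <- vapply(results, `[[`, numeric(1), "r2")
  list(results = results, r2 = r2, mean_r2 = mean(r2), sd_r2 = stats::sd(r2))
}
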