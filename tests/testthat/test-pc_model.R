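# Constrained nonnegative L1 model of Purkinje-cell activity.

# Shared fixture: kernel-matched cluster regressors on a coarse steps grid.
pc_regs <- local({
  stim <- NULL
  function() {
    if (is.null(stim)) {
      stim <<- sample_protocol(build_steps_protocol(n_repetitions = 1), 0.5)
    }
    kf <- make_kernel("GCaMP6fEF05", 0.5)
    ks <- make_kernel("GCaMP6s", 0.5)
    recipe <- default_population_recipe()
    n_fr <- length(stim$luminance)
    gc_m <- t(vapply(recipe$gc, template_response, numeric(n_fr),
                     stimulus = stim, kernel = kf))
    ion_m <- t(vapply(recipe$ion, template_response, numeric(n_fr),
                      stimulus = stim, kernel = kf))
    build_cluster_regressors(gc_m, ion_m, kf, ks, 0.5)
  }
})

test_that("cluster regressors are strictly positive with unit integral", {
  regs <- pc_regs()
  expect_equal(ncol(regs$gc), 8)
  expect_equal(ncol(regs$ion), 6)
  cols <- cbind(regs$gc, regs$ion)
  expect_true(all(cols > 0))
  expect_equal(unname(colSums(cols) * 0.5), rep(1, 14), tolerance = 1e-9)
  expect_error(build_cluster_regressors(matrix(1, 1, 10), matrix(1, 1, 10),
                                        make_kernel("GCaMP6fEF05", 0.5),
                                        make_kernel("GCaMP6s", 0.5), 0.5),
               "constant")
})

test_that("kernel matching to a slower sensor slows transients", {
  kf <- make_kernel("GCaMP6fEF05", 0.1)
  ks <- make_kernel("GCaMP6s", 0.1)
  imp <- c(rep(0, 5), 1, rep(0, 194))
  fast <- convolve_kernel(imp, kf)
  matched <- convolve_kernel(deconvolve_kernel(fast, kf), ks)
  half_time <- function(x) {
    pk <- which.max(x)
    which(x[pk:length(x)] <= max(x) / 2)[1]
  }
  expect_gt(half_time(matched), half_time(fast))
  # roundtrip with identical kernels is the positivity-shifted input
  regs_rt <- build_cluster_regressors(rbind(fast), rbind(fast), kf, kf, 0.1)
  expect_equal(cor(regs_rt$gc[, 1], fast), 1, tolerance = 1e-6)
})

test_that("preprocessing z-scores, filters and smooths trials", {
  set.seed(31)
  n_fr <- 400
  fp <- 0.25
  tr <- matrix(rnorm(6 * n_fr, mean = 5, sd = 2), 6)
  prep <- preprocess_pc(tr, fp, seed = 1)
  expect_length(prep$fit_trials, 4)
  expect_length(prep$test_trials, 2)
  expect_error(preprocess_pc(tr[1:5, ], fp), ">= 6 trials")
  # constant trial flagged, mapped to an all-zero row
  tr2 <- tr; tr2[3, ] <- 7
  prep2 <- preprocess_pc(tr2, fp, seed = 1)
  expect_true(prep2$degenerate[3])
  expect_equal(prep2$values[3, ], rep(0, n_fr))
})

test_that("the high-pass removes slow drifts but keeps fast structure", {
  fp <- 0.25
  n_fr <- 1600
  t_s <- (seq_len(n_fr) - 1) * fp
  gain_of <- function(period) {
    x <- sin(2 * pi * t_s / period)
    tr <- rbind(x, x, x, x, x, x)
    prep <- preprocess_pc(tr, fp, seed = 1)
    # amplitude ratio via regression on the original sinusoid
    sum(prep$values[1, ] * x) / sum(x * x)
  }
  expect_lte(gain_of(200), 0.2)  # 1/200 Hz attenuated by >= 80%
  expect_gte(gain_of(10), 0.8)   # 1/10 Hz attenuated by <= 20%
})

test_that("exact mixtures are recovered at lambda 0", {
  regs <- pc_regs()
  w <- rep(0, 14); w[3] <- 2
  g <- gen_pc_traces(regs, matrix(w, 1), offsets = 0.5, n_trials = 6,
                     noise_sd = 0, seed = 32)
  # fit the raw trials (no preprocessing: the planted signal is the model)
  prep <- structure(list(values = g$trials[[1]], fit_trials = 1:4,
                         test_trials = 5:6, frame_period = 0.5),
                    class = "pc_prep")
  fit <- fit_pc(prep, regs, lambda = 0)
  expect_equal(fit$offset, 0.5, tolerance = 1e-3)
  expect_equal(fit$gc_coeffs[3], 2, tolerance = 1e-3)
  expect_lt(max(abs(fit$gc_coeffs[-3])), 1e-4)
  expect_lt(max(abs(fit$ion_coeffs)), 1e-4)
  expect_error(fit_pc(prep, regs, lambda = -1), ">= 0")
})

test_that("a huge penalty zeroes all coefficients", {
  regs <- pc_regs()
  set.seed(33)
  n_fr <- nrow(regs$gc)
  trials <- matrix(rnorm(6 * n_fr, mean = 0.7), 6)
  prep <- structure(list(values = trials, fit_trials = 1:4,
                         test_trials = 5:6, frame_period = 0.5),
                    class = "pc_prep")
  fit <- fit_pc(prep, regs, lambda = 10)
  expect_equal(unname(c(fit$gc_coeffs, fit$ion_coeffs)), rep(0, 14),
               tolerance = 1e-6)
  y <- as.vector(t(trials[1:4, ]))
  expect_equal(fit$offset, mean(y), tolerance = 1e-3)
})

test_that("bounds are enforced exactly and the solution is locally optimal", {
  regs <- pc_regs()
  set.seed(34)
  w <- runif(14, 0, 3)
  g <- gen_pc_traces(regs, matrix(w, 1), offsets = -1, n_trials = 6,
                     noise_sd = 0.3, seed = 35)
  prep <- structure(list(values = g$trials[[1]], fit_trials = 1:4,
                         test_trials = 5:6, frame_period = 0.5),
                    class = "pc_prep")
  fit <- fit_pc(prep, regs, lambda = 1e-4)
  th <- c(fit$offset, fit$gc_coeffs, fit$ion_coeffs)
  expect_true(all(th[-1] >= 0 & th[-1] <= 1000))
  expect_true(th[1] >= -5 && th[1] <= 5)
  # random feasible perturbations never beat the solution (local optimality)
  y <- as.vector(t(g$trials[[1]][1:4, ]))
  D <- do.call(rbind, rep(list(cbind(1, regs$gc, regs$ion)), 4))
  cost <- function(v) mean((y - D %*% v)^2) + 1e-4 * sum(v[-1])
  c0 <- cost(th)
  for (i in 1:50) {
    v <- th + rnorm(15, sd = 1e-3)
    v[-1] <- pmin(pmax(v[-1], 0), 1000)
    v[1] <- min(max(v[1], -5), 5)
    expect_gte(cost(v), c0 - 1e-6)
  }
})

test_that("lambda cross-validation picks extremes for pure cases", {
  regs <- pc_regs()
  grid <- 10^seq(-7, -2, length.out = 11)
  expect_equal(range(grid), c(1e-7, 1e-2))
  w <- rep(0, 14); w[2] <- 1; w[10] <- 0.5
  g <- gen_pc_traces(regs, matrix(w, 1), offsets = 0, n_trials = 6,
                     noise_sd = 0, seed = 36)
  prep <- structure(list(values = g$trials[[1]], fit_trials = 1:4,
                         test_trials = 5:6, frame_period = 0.5),
                    class = "pc_prep")
  cv <- crossval_lambda(prep, regs, grid)
  expect_equal(cv$lambda, grid[1])  # representable exactly: no penalty
  set.seed(37)
  noise_prep <- structure(
    list(values = matrix(rnorm(6 * nrow(regs$gc)), 6), fit_trials = 1:4,
         test_trials = 5:6, frame_period = 0.5), class = "pc_prep")
  cv0 <- crossval_lambda(noise_prep, regs, grid)
  expect_equal(cv0$lambda, grid[length(grid)])  # pure noise: shrink away
  expect_equal(average_lambda(c(1e-6, 1e-4)), 1e-5)
})

test_that("test cost equals the brute-force L2 computation", {
  regs <- pc_regs()
  set.seed(38)
  w <- rep(0, 14); w[c(1, 9)] <- c(1, 1)
  g <- gen_pc_traces(regs, matrix(w, 1), offsets = 0, n_trials = 6,
                     noise_sd = 0.2, seed = 39)
  prep <- structure(list(values = g$trials[[1]], fit_trials = 1:4,
                         test_trials = 5:6, frame_period = 0.5),
                    class = "pc_prep")
  fit <- fit_pc(prep, regs, lambda = 1e-5)
  cost <- evaluate_test_cost(fit, prep, regs)
  pred <- fit$offset + drop(cbind(regs$gc, regs$ion) %*%
                              c(fit$gc_coeffs, fit$ion_coeffs))
  test_avg <- colMeans(g$trials[[1]][5:6, ])
  expect_equal(cost, mean((test_avg - pred)^2))
  # a perfect model on noiseless data has zero cost
  g0 <- gen_pc_traces(regs, matrix(w, 1), offsets = 0, n_trials = 6,
                      noise_sd = 0, seed = 40)
  prep0 <- structure(list(values = g0$trials[[1]], fit_trials = 1:4,
                          test_trials = 5:6, frame_period = 0.5),
                     class = "pc_prep")
  fit0 <- fit_pc(prep0, regs, lambda = 0)
  expect_lt(evaluate_test_cost(fit0, prep0, regs), 1e-8)
})

test_that("gc_ion_index hits its symmetry anchors", {
  f <- function(gc, ion) {
    structure(list(offset = 0, gc_coeffs = gc, ion_coeffs = ion),
              class = "pc_fit")
  }
  expect_equal(gc_ion_index(f(c(1, 2), c(0, 0))), 1)
  expect_equal(gc_ion_index(f(c(0, 0), c(3, 0))), -1)
  expect_equal(gc_ion_index(f(c(1, 1), c(2, 0))), 0)
  expect_true(is.na(gc_ion_index(f(c(0, 0), c(0, 0)))))
})

test_that("the shuffle null separates true mixtures from noise cells", {
  regs <- pc_regs()
  n_mix <- 20; n_noise <- 20
  set.seed(41)
  W <- matrix(0, n_mix, 14)
  for (i in seq_len(n_mix)) W[i, sample(14, 3)] <- runif(3, 10, 50)
  g <- gen_pc_traces(regs, W, offsets = rep(0, n_mix), n_trials = 6,
                     noise_sd = 0.3, seed = 42)
  n_fr <- nrow(regs$gc)
  zscore <- function(tr) t(apply(tr, 1, function(x) (x - mean(x)) / sd(x)))
  preps <- c(
    lapply(g$trials, function(tr) {
      structure(list(values = zscore(tr), fit_trials = 1:4,
                     test_trials = 5:6,
                     frame_period = 0.5), class = "pc_prep")
    }),
    lapply(seq_len(n_noise), function(i) {
      structure(list(values = zscore(matrix(rnorm(6 * n_fr, sd = 0.5), 6)),
                     fit_trials = 1:4, test_trials = 5:6,
                     frame_period = 0.5), class = "pc_prep")
    })
  )
  fits <- lapply(preps, fit_pc, regs = regs, lambda = 1e-4)
  sn <- shuffle_null(fits, preps, regs, n_shuffles = 200, seed = 43)
  expect_gte(mean(sn$better_than_chance[seq_len(n_mix)]), 0.9)
  expect_lte(mean(sn$better_than_chance[n_mix + seq_len(n_noise)]), 0.15)
  # reproducible under the same seed
  sn2 <- shuffle_null(fits, preps, regs, n_shuffles = 200, seed = 43)
  expect_identical(sn$threshold, sn2$threshold)
  expect_error(shuffle_null(fits[1], preps[1], regs), ">= 2 cells")
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  set.seed(44)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  res <- reliability_vs_index(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)))
  expect_equal(reliability_vs_index(1:10, (1:10)^3)$rho, 1)
  set.seed(45)
  null <- reliability_vs_index(rnorm(300), rnorm(300))
  expect_lt(abs(null$rho), 0.2)
  expect_error(reliability_vs_index(rep(1, 10), 1:10), "ties")
  expect_error(reliability_vs_index(1:3, 1:3), ">= 4")
})
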