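# Reliability gating, Otsu threshold, clustering, regressor
# classification and center-of-mass timing.

# Exhaustive between-class-variance maximizer: independent oracle for the
# histogram threshold.
otsu_oracle <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bcv <- rep(-Inf, n_bins - 1)
  for (k in seq_len(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    bcv[k] <- w0 * w1 * (m0 - m1)^2
  }
  at_max <- which(bcv == max(bcv))  # plateau across an empty valley
  edges[at_max[ceiling(length(at_max) / 2)] + 1L]
}

test_that("trial splitting respects repetition boundaries", {
  stim <- steps_stim(n_repetitions = 6, frame_period = 0.5)
  n_fr <- length(stim$luminance)
  per <- n_fr / 6
  traces <- matrix(rnorm(3 * n_fr), 3)
  tt <- split_trials(traces, stim)
  expect_equal(dim(tt$values), c(3, 6, per))
  expect_equal(tt$values[2, 3, ], traces[2, (2 * per + 1):(3 * per)])
  # one repetition is not splittable
  stim1 <- steps_stim(n_repetitions = 1)
  expect_error(split_trials(matrix(rnorm(length(stim1$luminance)), 1), stim1),
               "2 complete repetitions")
})

test_that("a ragged trailing repetition is dropped", {
  stim <- steps_stim(n_repetitions = 6, frame_period = 0.5)
  n_fr <- length(stim$luminance)
  # four stray frames of a seventh repetition
  stim$luminance <- c(stim$luminance, rep(0, 4))
  stim$repetition_index <- c(stim$repetition_index, rep(6L, 4))
  traces <- matrix(rnorm(2 * (n_fr + 4)), 2)
  tt <- split_trials(traces, stim)
  expect_equal(dim(tt$values)[2], 6)
})

test_that("reliability is 1 for identical trials, ~0 for noise", {
  stim <- steps_stim()
  n_fr <- length(stim$luminance)
  one <- rnorm(n_fr)
  vals <- array(NA_real_, c(2, 6, n_fr))
  for (tr in 1:6) vals[1, tr, ] <- one
  set.seed(21)
  for (tr in 1:6) vals[2, tr, ] <- rnorm(n_fr)
  tt <- structure(list(values = vals, frame_period = 0.5,
                       trial_stimulus = stim$luminance),
                  class = "trial_tensor")
  ri <- reliability_index(tt)
  expect_equal(ri[1], 1)
  expect_lt(abs(ri[2]), 0.1)
})

test_that("reliability equals the brute-force mean over all trial pairs", {
  set.seed(22)
  vals <- array(rnorm(4 * 3 * 50), c(4, 3, 50))
  tt <- structure(list(values = vals, frame_period = 0.5,
                       trial_stimulus = rep(0, 50)), class = "trial_tensor")
  ri <- reliability_index(tt)
  oracle <- vapply(1:4, function(i) {
    mean(c(cor(vals[i, 1, ], vals[i, 2, ]),
           cor(vals[i, 1, ], vals[i, 3, ]),
           cor(vals[i, 2, ], vals[i, 3, ])))
  }, numeric(1))
  expect_equal(ri, oracle)
  # symmetric under trial permutation
  perm <- tt
  perm$values <- vals[, c(3, 1, 2), ]
  expect_equal(reliability_index(perm), ri)
})

test_that("constant trials give a missing reliability score", {
  vals <- array(1, c(1, 3, 40))
  tt <- structure(list(values = vals, frame_period = 0.5,
                       trial_stimulus = rep(0, 40)), class = "trial_tensor")
  expect_true(is.na(reliability_index(tt)))
})

test_that("Otsu threshold matches the exhaustive oracle on random data", {
  set.seed(23)
  for (i in 1:100) {
    x <- switch(1 + i %% 4,
      c(rnorm(80, 0, 0.05), rnorm(40, 0.7, 0.05)),
      runif(60),
      c(rnorm(50, -1), rnorm(50, 2, 0.3)),
      rbeta(100, 2, 5))
    expect_identical(otsu_threshold(x), otsu_oracle(x))
  }
})

test_that("Otsu threshold separates a bimodal mixture", {
  set.seed(24)
  x <- c(rnorm(300, 0, 0.05), rnorm(200, 0.7, 0.05))
  th <- otsu_threshold(x)
  expect_gt(th, 0.2); expect_lt(th, 0.5)
  expect_gt(otsu_threshold(c(0, 1)), 0)
  expect_lt(otsu_threshold(c(0, 1)), 1)
  expect_equal(otsu_threshold(c(x, NA, Inf)), th)  # non-finite ignored
  expect_error(otsu_threshold(rep(0.3, 10)), "distinct")
})

test_that("trial averaging is a missing-aware elementwise mean", {
  set.seed(25)
  vals <- array(rnorm(2 * 6 * 30), c(2, 6, 30))
  vals[1, 2, 5] <- NA
  tt <- structure(list(values = vals, frame_period = 0.5,
                       trial_stimulus = rep(0, 30)), class = "trial_tensor")
  avg <- trial_average(tt)
  expect_equal(avg[1, 5], mean(vals[1, -2, 5]))
  expect_equal(avg[2, ], colMeans(vals[2, , ]))
  expect_equal(trial_average(tt, 1)[2, ], vals[2, 1, ])
  expect_error(trial_average(tt, integer(0)), "non-empty")
})

test_that("Ward clustering recovers two well-separated waveforms", {
  set.seed(26)
  t1 <- sin(2 * pi * (1:80) / 40)
  t2 <- c(rep(0, 40), rep(1, 40))
  m <- rbind(
    t(replicate(20, t1 + rnorm(80, sd = 0.1))),
    t(replicate(20, t2 + rnorm(80, sd = 0.1)))
  )
  cl <- cluster_responses(m, cut_height = 10)
  expect_equal(max(cl$labels), 2)
  expect_true(all(cl$labels[1:20] == cl$labels[1]))
  expect_true(all(cl$labels[21:40] == cl$labels[21]))
  expect_equal(dim(cl$cluster_means), c(2, 80))
  expect_equal(cl$cluster_means[cl$labels[1], ],
               colMeans(m[1:20, ]))
})

test_that("degenerate cuts behave as specified", {
  set.seed(27)
  m <- matrix(rnorm(10 * 30), 10)
  root <- cluster_responses(m, cut_height = 1e6)
  expect_equal(max(root$labels), 1)
  each <- cluster_responses(m, cut_height = 0)
  expect_equal(max(each$labels), 10)
  # duplicated rows merge at height zero
  dup <- cluster_responses(rbind(m, m[1, ]), cut_height = 1e-9)
  expect_equal(dup$labels[1], dup$labels[11])
})

test_that("cells equal to a regressor correlate at +/-1 with it", {
  stim <- steps_stim(n_repetitions = 2)
  bank <- build_regressor_bank(stim)
  m <- rbind(bank$matrix[, 3], -bank$matrix[, 5])
  rc <- regressor_correlations(m, bank)
  expect_equal(unname(rc$r[1, 3]), 1)
  expect_equal(unname(rc$r[2, 5]), -1)
  expect_equal(unname(rc$best[1]), bank$names[3])
})

test_that("planted transient and sustained cells classify into their groups", {
  stim <- steps_stim(n_repetitions = 2)
  kernel <- make_kernel("GCaMP6fEF05", stim$frame_period)
  set.seed(28)
  sustained <- t(replicate(30, template_response(
    response_class("sustained_on"), stim, kernel) + rnorm(length(stim$luminance), sd = 0.05)))
  transient <- t(replicate(30, template_response(
    response_class("transient_both"), stim, kernel) + rnorm(length(stim$luminance), sd = 0.05)))
  bank <- build_regressor_bank(stim)
  rc <- regressor_correlations(rbind(sustained, transient), bank)
  cls <- classify_by_best_regressor(rc)
  expect_gte(mean(cls[1:30] == "luminance"), 0.95)
  expect_gte(mean(cls[31:60] == "transition"), 0.95)
  # planted 50/50 population recovers fractions within 5%
  frac <- mean(cls == "transition")
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("exact correlation ties classify as luminance", {
  rc <- list(best_luminance = c(0.9, 0.5), best_transition = c(0.3, 0.5))
  expect_equal(classify_by_best_regressor(rc), c("luminance", "luminance"))
})

test_that("center of mass matches analytic cases", {
  fp <- 0.1
  # impulse at (0-based) frame k
  tr <- rep(0, 100); tr[31] <- 1
  expect_equal(center_of_mass(tr, 1:100, fp), 30 * fp)
  # symmetric boxcar centered in the window
  box <- rep(0, 100); box[41:60] <- 1
  expect_lt(abs(center_of_mass(box, 1:100, fp) - 49.5 * fp), fp)
  # linear ramp over [0, T]: COM = T / sqrt(2)
  n <- 400
  ramp <- seq(0, 1, length.out = n)
  T_dur <- (n - 1) * fp
  expect_lt(abs(center_of_mass(ramp, 1:n, fp) - T_dur / sqrt(2)), fp)
  # nonpositive mass is undefined
  expect_true(is.na(center_of_mass(rep(0, 50), 1:50, fp)))
})

test_that("COM is equivariant under time shifts", {
  fp <- 0.2
  base <- dnorm(1:200, mean = 60, sd = 8)
  com0 <- center_of_mass(base, 1:200, fp)
  for (shift in c(10, 25, 40)) {
    shifted <- c(rep(0, shift), base)[1:200]
    expect_lt(abs(center_of_mass(shifted, 1:200, fp) - (com0 + shift * fp)),
              fp + 1e-9)
  }
})

test_that("COM subtracts the pre-window baseline", {
  fp <- 0.5
  tr <- c(rep(2, 10), rep(2, 50))  # flat at baseline level: no mass
  expect_true(is.na(center_of_mass(tr, 11:60, fp)))
  tr2 <- c(rep(2, 10), rep(2, 20), rep(5, 30))
  com <- center_of_mass(tr2, 11:60, fp)
  # all mass sits in the last 30 frames of the window
  expect_gt(com, 19 * fp)
})

test_that("cross-validated COM orders ramp after transient in both halves", {
  stim <- flashes_stim(frame_period = 0.25)
  kernel <- make_kernel("GCaMP6fEF05", 0.25)
  n_fr <- length(stim$luminance)
  ramp <- template_response(response_class("ramp", tau_ramp = 8), stim, kernel)
  trans <- template_response(response_class("transient_on"), stim, kernel)
  vals <- array(NA_real_, c(2, 6, n_fr))
  for (tr in 1:6) { vals[1, tr, ] <- ramp; vals[2, tr, ] <- trans }
  tt <- structure(list(values = vals, frame_period = 0.25,
                       trial_stimulus = stim$luminance),
                  class = "trial_tensor")
  # window: the 21 s flash
  lv <- stim$luminance
  w_start <- which(diff(c(0, lv)) > 0)[3]
  window <- w_start:(w_start + round(21 / 0.25) - 1)
  cv <- crossval_com(tt, window)
  expect_equal(cv$com_a, cv$com_b)  # identical trials
  expect_gt(cv$com_a[1], cv$com_a[2])
  expect_equal(sort_by_com(cv), c(2, 1))
})

test_that("COM sorting places missing values last and is stable", {
  com <- list(com_a = c(3, 1, NA, 2, 1))
  expect_equal(sort_by_com(com), c(2, 5, 4, 1, 3))
})
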