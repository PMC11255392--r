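# Trial reliability gating, clustering, regressor classification and
# center-of-mass timing of mean responses.

#' Reshape traces into a trials x frames tensor
#'
#' Uses the stimulus `repetition_index` to cut each cell's trace into
#' trials; a ragged final trial (movie stopped mid-repetition) is dropped,
#' and all trials are truncated to the shortest complete repetition.
#'
#' @param traces cells x frames matrix aligned to `stimulus`.
#' @param stimulus the `sampled_stimulus` the traces were recorded under.
#' @return object of class `trial_tensor`: `values` (cells x trials x
#'   frames), `frame_period`, `trial_stimulus` (single-repetition luminance).
#' @export
split_trials <- function(traces, stimulus) {
  traces <- rbind(traces)
  reps <- split(seq_along(stimulus$repetition_index),
                stimulus$repetition_index)
  # a final repetition much shorter than the rest is ragged: require at
  # least 90% of the longest repetition's frames to count as a trial
  full_len <- max(lengths(reps))
  keep <- which(lengths(reps) >= 0.9 * full_len)
  len <- min(lengths(reps)[keep])
  if (length(keep) < 2) stop("need at least 2 complete repetitions")
  vals <- array(NA_real_, c(nrow(traces), length(keep), len))
  for (j in seq_along(keep)) {
    vals[, j, ] <- traces[, reps[[keep[j]]][seq_len(len)], drop = FALSE]
  }
  structure(
    list(values = vals, frame_period = stimulus$frame_period,
         trial_stimulus = stimulus$luminance[reps[[keep[1]]][seq_len(len)]]),
    class = "trial_tensor"
  )
}

#' Trial-to-trial reliability index
#'
#' For each cell, the mean Pearson correlation over all unordered pairs of
#' trials (the between-presentation correlation of its responses). Frames
#' missing in either trial of a pair are excluded pairwise; pairs with
#' fewer than 3 shared valid frames are skipped. A cell whose trials are
#' all constant gets NA.
#'
#' @param tensor a `trial_tensor` with >= 2 trials.
#' @return numeric vector, one score in \[-1, 1\] per cell.
#' @export
reliability_index <- function(tensor) {
  v <- tensor$values
  n_trials <- dim(v)[2]
  if (n_trials < 2) stop("reliability requires >= 2 trials")
  pairs <- utils::combn(n_trials, 2)
  apply(v, 1, function(cell) {
    rs <- apply(pairs, 2, function(p) {
      a <- cell[p[1], ]; b <- cell[p[2], ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(a[ok], b[ok]))
    })
    if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  })
}

#' Otsu threshold of a score distribution
#'
#' Builds a 256-bin histogram over the finite range of the scores and
#' returns the bin edge that maximizes the between-class variance of the
#' two-class split (the classic histogram-thresholding criterion). Used to
#' separate the near-zero reliability peak from the responsive tail.
#'
#' @param scores numeric vector; NA ignored.
#' @param n_bins histogram resolution (default 256).
#' @return the threshold value (a bin edge).
#' @export
otsu_threshold <- function(scores, n_bins = 256L) {
  x <- scores[is.finite(scores)]
  if (length(unique(x)) < 2) stop("Otsu threshold needs >= 2 distinct values")
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for a cut after bin k (classes [1..k], [k+1..n])
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  # the criterion is flat across an empty valley between modes: take the
  # middle of the maximal plateau so the cut sits mid-valley
  at_max <- which(bcv == max(bcv))
  edges[at_max[ceiling(length(at_max) / 2)] + 1L]
}

#' Gate cells by reliability with an automatic threshold
#'
#' @param tensor a `trial_tensor`.
#' @param threshold optional fixed threshold; by default
#'   [otsu_threshold()] of the scores.
#' @return list with `score`, `threshold`, `responsive` (score > threshold;
#'   NA scores are not responsive).
#' @export
gate_responsive <- function(tensor, threshold = NULL) {
  score <- reliability_index(tensor)
  if (is.null(threshold)) threshold <- otsu_threshold(score)
  responsive <- !is.na(score) & score > threshold
  list(score = score, threshold = threshold, responsive = responsive)
}

#' Mean response over selected trials
#'
#' @param tensor a `trial_tensor`.
#' @param trials trial indices to average (default all).
#' @return cells x frames matrix of missing-aware trial means.
#' @export
trial_average <- function(tensor, trials = NULL) {
  v <- tensor$values
  if (is.null(trials)) trials <- seq_len(dim(v)[2])
  if (length(trials) == 0) stop("trial subset must be non-empty")
  apply(v[, trials, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
}

#' Ward clustering of mean responses
#'
#' Mean responses are z-scored per cell (so clusters group response shapes,
#' not amplitudes) and clustered by Ward linkage on Euclidean distance; the
#' tree is cut at `cut_height`. Cluster ids are renumbered by decreasing
#' size, tie-broken by first-occurring member, so labels are stable for a
#' fixed input order.
#'
#' @param mean_responses cells x frames matrix (>= 2 cells).
#' @param cut_height height at which to cut the dendrogram; a value <= 0
#'   puts each cell in its own cluster.
#' @param standardize z-score rows before linkage (default TRUE).
#' @return list with `linkage` (an `hclust`), `cut_height`, `labels`,
#'   `cluster_means` (cluster x frames, means of member cells' responses).
#' @export
cluster_responses <- function(mean_responses, cut_height,
                              standardize = TRUE) {
  m <- rbind(mean_responses)
  if (nrow(m) < 2) stop("clustering requires >= 2 cells")
  z <- if (standardize) t(scale(t(m))) else m
  z[is.na(z)] <- 0  # constant cells: flat profile
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- if (cut_height <= 0) seq_len(nrow(m))
         else stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(relabel[as.character(raw)])
  k <- max(labels)
  cluster_means <- t(vapply(seq_len(k), function(c) {
    colMeans(m[labels == c, , drop = FALSE])
  }, numeric(ncol(m))))
  list(linkage = hc, cut_height = cut_height, labels = labels,
       cluster_means = cluster_means)
}

#' Dendrogram height that yields a given number of clusters
#'
#' The cut is placed midway between the two merge heights that bracket
#' `k` clusters — a convenience for reproducing a manual tree cut at a
#' known cluster count.
#'
#' @param linkage an `hclust` (e.g. from [cluster_responses()]).
#' @param k desired number of clusters.
#' @export
cut_height_for_k <- function(linkage, k) {
  h <- sort(linkage$height)
  n <- length(h) + 1
  if (k >= n) return(0)
  if (k <= 1) return(max(h) * 1.01)
  (h[n - k] + h[n - k + 1]) / 2
}

#' Correlate cells against the regressor bank
#'
#' Pearson correlation of every cell's mean response with every regressor,
#' plus the per-cell best regressor and the best correlation within each
#' group (luminance vs transition). Constant cells get an NA row.
#'
#' @param mean_responses cells x frames matrix.
#' @param bank a `regressor_bank` sampled on the same frames.
#' @return list with `r` (cells x regressors), `best` (regressor name per
#'   cell), `best_luminance`, `best_transition` (per-cell best r within
#'   each group).
#' @export
regressor_correlations <- function(mean_responses, bank) {
  m <- rbind(mean_responses)
  stopifnot(ncol(m) == nrow(bank$matrix))
  r <- suppressWarnings(stats::cor(t(m), bank$matrix,
                                   use = "pairwise.complete.obs"))
  colnames(r) <- bank$names
  best <- apply(r, 1, function(ri) {
    if (all(is.na(ri))) NA_character_ else bank$names[which.max(ri)]
  })
  lum <- bank$group == "luminance"
  list(
    r = r,
    best = best,
    best_luminance = apply(r[, lum, drop = FALSE], 1,
                           function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    best_transition = apply(r[, !lum, drop = FALSE], 1,
                            function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    group = bank$group
  )
}

#' Classify cells by their best regressor's group
#'
#' A cell is labelled by the group (luminance or transition) of its highest
#' correlated regressor; exact ties go to luminance.
#'
#' @param correlations output of [regressor_correlations()].
#' @return character vector, `"luminance"` / `"transition"` / NA per cell.
#' @export
classify_by_best_regressor <- function(correlations) {
  bl <- correlations$best_luminance
  bt <- correlations$best_transition
  ifelse(is.na(bl) & is.na(bt), NA_character_,
         ifelse(is.na(bt) | (!is.na(bl) & bl >= bt),
                "luminance", "transition"))
}

#' Center of mass of a response within a window
#'
#' Baseline (the mean of the 1 s preceding the window) is subtracted, the
#' trace is floored at zero, and the COM is the first time at which the
#' cumulative sum reaches half of the total, linearly interpolated between
#' frames. Returns seconds from the window start; NA when the windowed
#' trace carries no positive mass.
#'
#' @param trace numeric vector (one cell, full trial).
#' @param window integer frame range (indices into `trace`).
#' @param frame_period seconds per frame.
#' @param baseline_duration seconds of pre-window baseline (default 1).
#' @export
center_of_mass <- function(trace, window, frame_period,
                           baseline_duration = 1) {
  w0 <- min(window)
  n_base <- max(1L, round(baseline_duration / frame_period))
  base_idx <- seq(max(1L, w0 - n_base), max(1L, w0 - 1L))
  baseline <- if (w0 > 1) mean(trace[base_idx], na.rm = TRUE) else 0
  x <- pmax(trace[window] - baseline, 0)
  x[is.na(x)] <- 0
  total <- sum(x)
  if (total <= 0) return(NA_real_)
  cs <- cumsum(x)
  half <- total / 2
  k <- which(cs >= half)[1]
  prev <- if (k == 1) 0 else cs[k - 1]
  frac <- (half - prev) / (cs[k] - prev)
  # frame j's sample sits at time (j-1)*frame_period from window start;
  # its mass accrues over the half-frame on either side
  max(0, (k - 1.5 + frac) * frame_period)
}

#' Cross-validated center of mass
#'
#' Trials are split into two fixed halves (even and odd indices); the COM
#' is computed on each half's trial average. Half A (odd trials) is meant
#' for sorting, half B (even trials) for display, so the ordering is not
#' fit to the plotted data.
#'
#' @param tensor a `trial_tensor` with >= 2 trials.
#' @param window frame range within a trial.
#' @param baseline_duration seconds of pre-window baseline.
#' @return list with `com_a`, `com_b` (seconds per cell) and `half_split`.
#' @export
crossval_com <- function(tensor, window, baseline_duration = 1) {
  n_trials <- dim(tensor$values)[2]
  if (n_trials < 2) stop("cross-validated COM requires >= 2 trials")
  half_a <- seq(1, n_trials, by = 2)
  half_b <- seq(2, n_trials, by = 2)
  avg_a <- trial_average(tensor, half_a)
  avg_b <- trial_average(tensor, half_b)
  com_of <- function(avg) {
    apply(avg, 1, center_of_mass, window = window,
          frame_period = tensor$frame_period,
          baseline_duration = baseline_duration)
  }
  list(com_a = com_of(avg_a), com_b = com_of(avg_b),
       half_split = list(a = half_a, b = half_b))
}

#' Sort cells by their (held-out) center of mass
#'
#' Ascending order of the half-A COM; cells with NA COM go last; ties keep
#' their input order.
#'
#' @param com output of [crossval_com()].
#' @return integer permutation of cell indices.
#' @export
sort_by_com <- function(com) {
  order(com$com_a, na.last = TRUE)
}
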