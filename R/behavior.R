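# Swim-bout extraction from velocity traces and the bootstrap test for
# bout-probability suppression after luminance-OFF transitions.

#' Detect swim bouts by thresholding speed
#'
#' Larval zebrafish swim in discrete bouts; a bout is a maximal run of
#' samples with speed above `threshold`. Runs separated by less than
#' `min_gap` seconds are merged into one bout.
#'
#' @param velocity numeric speed trace (arbitrary units, >= 0).
#' @param rate sampling rate in Hz.
#' @param threshold speed threshold.
#' @param min_gap merge gap in seconds (default 0.1).
#' @return data.frame with `onset`, `offset` (seconds) and `peak_speed`.
#' @export
detect_bouts <- function(velocity, rate, threshold, min_gap = 0.1) {
  stopifnot(rate > 0)
  above <- !is.na(velocity) & velocity > threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_speed = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1) / rate
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  data.frame(
    onset = (merged$start - 1) / rate,
    offset = merged$end / rate,
    peak_speed = vapply(seq_len(nrow(merged)), function(i) {
      max(velocity[merged$start[i]:merged$end[i]])
    }, numeric(1))
  )
}

#' Stimulus-aligned bout-time histogram
#'
#' Bout onsets are folded to their time within a protocol repetition and
#' binned; `probability` is the count per bin divided by the number of
#' repetitions (expected bouts per bin per presentation). The repetition
#' is divided into equal bins of width as close to `bin_width` as
#' possible, so no bin is a ragged remainder.
#'
#' @param bouts data.frame from [detect_bouts()].
#' @param stimulus a `sampled_stimulus` giving the repetition structure.
#' @param bin_width seconds per bin (default 0.25).
#' @return list with `bin_edges`, `counts`, `n_repetitions`, `probability`.
#' @export
bout_histogram <- function(bouts, stimulus, bin_width = 0.25) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  protocol <- stimulus$protocol
  rep_dur <- sum(protocol$epochs$duration)
  n_rep <- protocol$n_repetitions
  phase <- bouts$onset %% rep_dur
  n_bins <- max(1L, round(rep_dur / bin_width))
  edges <- seq(0, rep_dur, length.out = n_bins + 1)
  counts <- tabulate(findInterval(phase, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  list(bin_edges = edges, counts = counts, n_repetitions = n_rep,
       probability = counts / n_rep)
}

#' Bootstrap test for bout suppression after OFF transitions
#'
#' The observed statistic is the mean bout probability in the bins within
#' `window` seconds after each luminance-OFF transition. Under the null
#' that bout timing carries no relation to the transitions, the
#' histogram's total count is resampled multinomially over bins
#' (probabilities proportional to a uniform placement) `n_boot` times with
#' the windowed mean evaluated at random window placements; suppression is
#' significant when the observed value falls below the bootstrap
#' distribution's first percentile.
#'
#' @param hist output of [bout_histogram()].
#' @param off_times OFF-transition times (seconds within a repetition).
#' @param window seconds after each transition (default 1.5).
#' @param n_boot bootstrap samples (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `percentile1`, `significant`.
#' @export
offset_suppression_test <- function(hist, off_times, window = 1.5,
                                    n_boot = 1000L, seed = 0L) {
  if (sum(hist$counts) == 0) stop("no bouts: suppression test undefined")
  edges <- hist$bin_edges
  n_bins <- length(hist$counts)
  rep_dur <- edges[length(edges)]
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  window_bins <- function(starts) {
    unique(unlist(lapply(starts, function(t0) {
      w <- which(mids > t0 & mids <= t0 + window)
      if (t0 + window > rep_dur) {  # wrap into the next repetition
        w <- c(w, which(mids <= (t0 + window) %% rep_dur))
      }
      w
    })))
  }
  obs_bins <- window_bins(off_times)
  if (any(off_times + window > rep_dur)) {
    warning("suppression window extends past the repetition end; wrapped")
  }
  observed <- mean(hist$probability[obs_bins])
  n_win <- length(obs_bins)
  total <- sum(hist$counts)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    cnt <- as.vector(stats::rmultinom(1, total, rep(1 / n_bins, n_bins)))
    start <- sample(n_bins, 1)
    bins <- ((start - 1 + seq_len(n_win) - 1) %% n_bins) + 1
    mean(cnt[bins] / hist$n_repetitions)
  }, numeric(1))
  percentile1 <- stats::quantile(boot, 0.01, names = FALSE)
  list(observed = observed, percentile1 = percentile1,
       significant = observed < percentile1)
}
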