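# Luminance protocols, calcium kernels and the regressor bank.

#' Create a piecewise-constant luminance protocol
#'
#' A protocol is an ordered list of epochs, each holding a constant relative
#' luminance in \[0, 1\] for a positive duration, repeated `n_repetitions`
#' times back to back.
#'
#' @param epochs data.frame with columns `duration` (seconds, > 0) and
#'   `level` (relative luminance in \[0, 1\]).
#' @param n_repetitions number of back-to-back presentations of the epoch
#'   sequence.
#' @param name protocol label.
#' @return object of class `luminance_protocol`.
#' @export
luminance_protocol <- function(epochs, n_repetitions = 1L, name = "custom") {
  stopifnot(is.data.frame(epochs), all(c("duration", "level") %in% names(epochs)))
  if (any(epochs$duration <= 0)) stop("all epoch durations must be > 0")
  if (any(epochs$level < 0 | epochs$level > 1)) {
    stop("all luminance levels must lie in [0, 1]")
  }
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  structure(
    list(
      epochs = epochs[, c("duration", "level")],
      n_repetitions = as.integer(n_repetitions),
      name = name
    ),
    class = "luminance_protocol"
  )
}

#' @export
print.luminance_protocol <- function(x, ...) {
  cat(sprintf(
    "<luminance_protocol '%s'>: %d epochs x %d repetitions, %.1f s total\n",
    x$name, nrow(x$epochs), x$n_repetitions, protocol_duration(x)
  ))
  invisible(x)
}

#' Total duration of a protocol in seconds (all repetitions)
#' @param protocol a `luminance_protocol`.
#' @export
protocol_duration <- function(protocol) {
  sum(protocol$epochs$duration) * protocol$n_repetitions
}

#' The "steps" protocol: 5 s luminance steps covering all level transitions
#'
#' Steps of 5 s at 5%, 20% and 100% of maximal luminance, separated by 7 s
#' interstimulus intervals at the baseline level. The step order is a fixed
#' deterministic sequence chosen so that every ordered pair of distinct
#' levels among \{baseline, 0.05, 0.2, 1\} occurs as a direct transition at
#' least once within a single repetition: the sequence walks an Eulerian
#' circuit over the 12 ordered level pairs, with the baseline epochs serving
#' as the 7 s intervals.
#'
#' @param n_repetitions repetitions of the full sequence (default 6, one per
#'   imaging plane acquisition).
#' @param baseline interstimulus luminance level (default 0).
#' @param step_duration seconds per step (default 5).
#' @param interstim_duration seconds per interstimulus interval (default 7).
#' @return a `luminance_protocol`.
#' @export
build_steps_protocol <- function(n_repetitions = 6L, baseline = 0,
                                 step_duration = 5, interstim_duration = 7) {
  b <- baseline
  # Eulerian circuit over directed K4 on levels {b, 0.05, 0.2, 1}: every
  # ordered pair of distinct levels appears exactly once as a transition.
  seq_levels <- c(b, 0.05, 0.2, 1, b, 0.2, 0.05, 1, 0.2, b, 1, 0.05, b)
  durations <- ifelse(seq_levels == b, interstim_duration, step_duration)
  luminance_protocol(
    data.frame(duration = durations, level = seq_levels),
    n_repetitions = n_repetitions, name = "steps"
  )
}

#' The "flashes" protocol: full-brightness flashes of 3, 7 and 21 s
#'
#' Each flash is at maximal luminance and is preceded and followed by 7 s of
#' darkness.
#'
#' @inheritParams build_steps_protocol
#' @export
build_flashes_protocol <- function(n_repetitions = 6L, baseline = 0,
                                   interstim_duration = 7) {
  durations <- c(interstim_duration, 3, interstim_duration, 7,
                 interstim_duration, 21, interstim_duration)
  levels <- c(baseline, 1, baseline, 1, baseline, 1, baseline)
  luminance_protocol(
    data.frame(duration = durations, level = levels),
    n_repetitions = n_repetitions, name = "flashes"
  )
}

#' Ordered luminance transitions of a protocol (single repetition)
#'
#' @param protocol a `luminance_protocol`.
#' @return data.frame with columns `from`, `to`, one row per epoch boundary
#'   where the level changes.
#' @export
protocol_transitions <- function(protocol) {
  lv <- protocol$epochs$level
  from <- lv[-length(lv)]
  to <- lv[-1]
  keep <- from != to
  data.frame(from = from[keep], to = to[keep])
}

#' Sample a protocol on an imaging clock
#'
#' Frame `i` (0-based) carries the level active at time `(i + 0.5) *
#' frame_period` (midpoint sampling of the piecewise-constant schedule,
#' epochs half-open on the right). A `repetition_index` vector marks which
#' repetition each frame belongs to, starting at 0.
#'
#' @param protocol a `luminance_protocol`.
#' @param frame_period imaging frame period in seconds.
#' @return object of class `sampled_stimulus` with fields `luminance`,
#'   `frame_period`, `repetition_index`, `protocol`.
#' @export
sample_protocol <- function(protocol, frame_period) {
  stopifnot(frame_period > 0)
  if (frame_period > min(protocol$epochs$duration)) {
    stop("frame_period longer than the shortest epoch: sampling would alias")
  }
  rep_dur <- sum(protocol$epochs$duration)
  total <- rep_dur * protocol$n_repetitions
  n_frames <- floor(total / frame_period)
  t_mid <- (seq_len(n_frames) - 0.5) * frame_period
  rep_idx <- pmin(floor(t_mid / rep_dur), protocol$n_repetitions - 1)
  t_in_rep <- t_mid - rep_idx * rep_dur
  edges <- cumsum(protocol$epochs$duration)
  epoch_of <- findInterval(t_in_rep, c(0, edges), rightmost.closed = TRUE,
                           left.open = TRUE)
  epoch_of <- pmin(epoch_of, nrow(protocol$epochs))
  structure(
    list(
      luminance = protocol$epochs$level[epoch_of],
      frame_period = frame_period,
      repetition_index = as.integer(rep_idx),
      protocol = protocol
    ),
    class = "sampled_stimulus"
  )
}

#' Gamma-transform a luminance trace
#'
#' Elementwise power transform `x^gamma`; used to build regressors mimicking
#' responses with different thresholds and saturation points.
#'
#' @param luminance numeric vector in \[0, 1\].
#' @param gamma positive exponent.
#' @export
gamma_transform <- function(luminance, gamma) {
  stopifnot(gamma > 0)
  if (any(luminance < 0, na.rm = TRUE)) stop("luminance must be nonnegative")
  luminance^gamma
}

#' Impulse train at luminance transitions
#'
#' Unit impulses at frames where the sampled luminance increases (`on`),
#' decreases (`off`), or changes in either direction (`both`).
#'
#' @param stimulus a `sampled_stimulus`.
#' @param mode one of `"on"`, `"off"`, `"both"`.
#' @export
transition_train <- function(stimulus, mode = c("on", "off", "both")) {
  mode <- match.arg(mode)
  d <- diff(stimulus$luminance)
  hit <- switch(mode, on = d > 0, off = d < 0, both = d != 0)
  c(0, as.numeric(hit))
}

#' Calcium indicator impulse-response kernel
#'
#' Single-exponential causal decay, unit area, truncated where the amplitude
#' falls below 1e-4 of the peak. Default time constants are 0.85 s for
#' GCaMP6fEF05 and 1.25 s for GCaMP6s (midpoints of the indicators' reported
#' 0.7–1 s and 1–1.5 s ranges). `max_support` caps the kernel length: the
#' 3 s regressor-analysis kernel is the GCaMP6fEF05 kernel truncated at 3 s.
#'
#' @param sensor `"GCaMP6fEF05"` or `"GCaMP6s"`, or `"custom"` with `tau`.
#' @param frame_period seconds per frame.
#' @param tau decay time constant override in seconds.
#' @param max_support optional cap on kernel support, seconds.
#' @return object of class `calcium_kernel` with fields `sensor`,
#'   `waveform`, `frame_period`, `tau`.
#' @export
make_kernel <- function(sensor = c("GCaMP6fEF05", "GCaMP6s", "custom"),
                        frame_period, tau = NULL, max_support = NULL) {
  sensor <- match.arg(sensor)
  stopifnot(frame_period > 0)
  if (is.null(tau)) {
    tau <- switch(sensor,
      GCaMP6fEF05 = 0.85,
      GCaMP6s = 1.25,
      custom = stop("sensor 'custom' requires tau")
    )
  }
  stopifnot(tau > 0)
  t_max <- -tau * log(1e-4)  # amplitude < 1e-4 of peak beyond this lag
  if (!is.null(max_support)) t_max <- min(t_max, max_support)
  n <- max(1L, ceiling(t_max / frame_period))
  lag <- (seq_len(n) - 1) * frame_period
  w <- exp(-lag / tau)
  w <- w / sum(w)
  structure(
    list(sensor = sensor, waveform = w, frame_period = frame_period, tau = tau),
    class = "calcium_kernel"
  )
}

#' Causal convolution with a calcium kernel
#'
#' Linear convolution of a trace with the kernel waveform, truncated to the
#' input length. A unit-area kernel preserves the integral of padded inputs.
#'
#' @param trace numeric vector.
#' @param kernel a `calcium_kernel`.
#' @export
convolve_kernel <- function(trace, kernel) {
  w <- kernel$waveform
  out <- stats::convolve(trace, rev(w), type = "open")
  out[seq_along(trace)]
}

#' Deconvolution by a calcium kernel
#'
#' Exactly inverts [convolve_kernel()]: the truncated causal convolution
#' is a lower-triangular Toeplitz system, solved by forward substitution
#' `x[i] = (y[i] - sum_j w[j] x[i-j+1]) / w[1]`. The noiseless roundtrip
#' is therefore exact to machine precision; on noisy traces the error is
#' bounded by the noise amplitude times the norm of the inverse filter,
#' which stays moderate for the decaying indicator kernels used here
#' (their leading tap dominates).
#'
#' @param trace numeric vector.
#' @param kernel a `calcium_kernel`.
#' @export
deconvolve_kernel <- function(trace, kernel) {
  w <- kernel$waveform
  if (all(w == 0)) stop("kernel waveform is all zero")
  n <- length(trace)
  m <- length(w)
  x <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq(2, min(m, i))
    acc <- if (i >= 2) sum(w[j] * x[i - j + 1]) else 0
    x[i] <- (trace[i] - acc) / w[1]
  }
  x
}

#' Build the luminance/transition regressor bank
#'
#' Seven kernel-convolved predictors: gamma-corrected luminance profiles
#' (gamma 1, 1/2, 2), the gamma2 - gamma1 difference (mimicking
#' intermediate-luminance tuning), and ON / OFF / ON+OFF transition impulse
#' trains. The first four are labelled group `"luminance"`, the last three
#' `"transition"`. Columns are standardized to zero mean and unit variance
#' (Pearson correlation downstream is scale-free).
#'
#' @param stimulus a `sampled_stimulus`.
#' @param kernel a `calcium_kernel`; defaults to the 3 s-truncated
#'   GCaMP6fEF05 kernel at the stimulus frame period.
#' @return object of class `regressor_bank` with fields `matrix`
#'   (frames x 7), `names`, `group`, `frame_period`.
#' @export
build_regressor_bank <- function(stimulus, kernel = NULL) {
  if (is.null(kernel)) {
    kernel <- make_kernel("GCaMP6fEF05", stimulus$frame_period,
                          max_support = 3)
  }
  lum <- stimulus$luminance
  raw <- cbind(
    gamma1 = gamma_transform(lum, 1),
    gamma0.5 = gamma_transform(lum, 0.5),
    gamma2 = gamma_transform(lum, 2),
    gamma2_minus_gamma1 = gamma_transform(lum, 2) - gamma_transform(lum, 1),
    on = transition_train(stimulus, "on"),
    off = transition_train(stimulus, "off"),
    on_off = transition_train(stimulus, "both")
  )
  conv <- apply(raw, 2, convolve_kernel, kernel = kernel)
  if (any(apply(conv, 2, stats::sd) == 0)) {
    stop("a regressor column is constant for this stimulus")
  }
  structure(
    list(
      matrix = scale(conv),
      names = colnames(raw),
      group = c(rep("luminance", 4), rep("transition", 3)),
      frame_period = stimulus$frame_period
    ),
    class = "regressor_bank"
  )
}

#' Serialize a protocol to JSON
#' @param protocol a `luminance_protocol`.
#' @param path output file path.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(
    list(
      name = protocol$name,
      n_repetitions = protocol$n_repetitions,
      epochs = protocol$epochs
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a protocol from JSON
#' @param path file written by [write_protocol_json()].
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  luminance_protocol(x$epochs, n_repetitions = x$n_repetitions, name = x$name)
}
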