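# Seeded generators for every input the pipeline consumes, with planted
# ground truth: response-class templates, trial-repeated populations,
# two-photon-like movies with known footprints and drift, Purkinje traces
# as known regressor mixtures, and swim-bout velocity traces.

#' Response-class template specification
#'
#' @param kind one of `"sustained_on"`, `"sustained_off"`,
#'   `"intermediate_tuned"`, `"transient_on"`, `"transient_off"`,
#'   `"transient_both"`, `"ramp"`, `"suppressed_then_ramp"`.
#' @param threshold,saturation luminance operating range of sustained
#'   responses (drive ramps linearly from 0 at `threshold` to 1 at
#'   `saturation`).
#' @param tau_ramp ramp time constant in seconds (ramp kinds).
#' @param amplitude response amplitude (arbitrary fluorescence units).
#' @param gamma luminance exponent applied before thresholding.
#' @param peak,width center and width of the intermediate-luminance bump.
#' @param delay onset delay of the post-suppression ramp, seconds.
#' @param adaptation fraction of the sustained drive that decays away with
#'   time constant `tau_adapt` (0 = none; 0.9 models the strongly adapting
#'   sustained responses seen in the inferior olive).
#' @param tau_adapt adaptation time constant, seconds.
#' @param transient_weight additional transition-impulse drive added on
#'   top of the base kind (models cells combining sustained tuning with
#'   transition transients).
#' @param transient_mode which transitions the additive component marks.
#' @export
response_class <- function(kind, threshold = 0, saturation = 1,
                           tau_ramp = 5, amplitude = 1, gamma = 1,
                           peak = 0.2, width = 0.12, delay = 2,
                           adaptation = 0, tau_adapt = 2,
                           transient_weight = 0,
                           transient_mode = c("off", "on", "both")) {
  kinds <- c("sustained_on", "sustained_off", "intermediate_tuned",
             "transient_on", "transient_off", "transient_both", "ramp",
             "suppressed_then_ramp")
  if (!kind %in% kinds) stop("unknown response class kind: ", kind)
  if (threshold >= saturation) stop("threshold must be below saturation")
  if (tau_ramp <= 0) stop("tau_ramp must be > 0")
  structure(
    list(kind = kind, threshold = threshold, saturation = saturation,
         tau_ramp = tau_ramp, amplitude = amplitude, gamma = gamma,
         peak = peak, width = width, delay = delay,
         adaptation = adaptation, tau_adapt = tau_adapt,
         transient_weight = transient_weight,
         transient_mode = match.arg(transient_mode)),
    class = "response_class"
  )
}

# Exact first-order low-pass of a sampled trace.
lowpass <- function(x, tau, frame_period) {
  a <- exp(-frame_period / tau)
  stats::filter(x * (1 - a), a, method = "recursive") |> as.numeric()
}

#' Noiseless template response of a class to a stimulus
#'
#' The class-specific luminance drive (saturating, bump-tuned, transient
#' or ramping) is evaluated on the sampled stimulus, optionally adapted
#' and mixed with an additive transition-transient component, convolved
#' with the indicator kernel, and scaled so its peak absolute value equals
#' the class amplitude (interpretable as peak dF/F).
#'
#' @param spec a [response_class()].
#' @param stimulus a `sampled_stimulus`.
#' @param kernel a `calcium_kernel`; defaults to GCaMP6fEF05 at the
#'   stimulus frame period.
#' @export
template_response <- function(spec, stimulus, kernel = NULL) {
  if (is.null(kernel)) {
    kernel <- make_kernel("GCaMP6fEF05", stimulus$frame_period)
  }
  lum <- stimulus$luminance
  fp <- stimulus$frame_period
  sat_drive <- function(l) {
    g <- gamma_transform(l, spec$gamma)
    pmin(pmax((g - spec$threshold) / (spec$saturation - spec$threshold), 0), 1)
  }
  drive <- switch(spec$kind,
    sustained_on = sat_drive(lum),
    sustained_off = sat_drive(1 - lum),
    intermediate_tuned = {
      b <- exp(-(lum - spec$peak)^2 / (2 * spec$width^2))
      pmax(b - exp(-(0 - spec$peak)^2 / (2 * spec$width^2)), 0)
    },
    transient_on = transition_train(stimulus, "on"),
    transient_off = transition_train(stimulus, "off"),
    transient_both = transition_train(stimulus, "both"),
    ramp = lowpass(lum, spec$tau_ramp, fp),
    suppressed_then_ramp = {
      lag <- round(spec$delay / fp)
      delayed <- c(rep(lum[1], lag), lum)[seq_along(lum)]
      lowpass(delayed, spec$tau_ramp, fp) -
        0.5 * transition_train(stimulus, "both")
    }
  )
  if (spec$adaptation > 0) {
    drive <- drive - spec$adaptation * lowpass(drive, spec$tau_adapt, fp)
  }
  if (spec$transient_weight != 0) {
    drive <- drive +
      spec$transient_weight * transition_train(stimulus, spec$transient_mode)
  }
  out <- convolve_kernel(drive, kernel)
  pk <- max(abs(out))
  if (pk > 0) out <- out / pk
  spec$amplitude * out
}

#' Default synthetic population recipe
#'
#' Mirrors the empirically observed composition: eight granule-cell-like
#' classes (sustained ON/OFF at different thresholds and saturations,
#' intermediate-luminance-tuned cells, and slow ramps) and six inferior-
#' olive-like classes (ON / OFF / combined transients, a strongly adapting
#' sustained class and intermediate-tuned variants). Classes additionally
#' differ in their adaptation dynamics — as the recorded clusters do — so
#' no class is a linear combination of others and the downstream
#' regressor bank is full rank.
#'
#' @return named list with `gc` and `ion` lists of [response_class()].
#' @export
default_population_recipe <- function() {
  list(
    gc = list(
      GC1 = response_class("sustained_on", saturation = 0.05,
                           adaptation = 0.25, tau_adapt = 6),
      GC2 = response_class("sustained_on", threshold = 0.5),
      GC3 = response_class("sustained_on", saturation = 0.3,
                           adaptation = 0.45, tau_adapt = 3),
      GC4 = response_class("sustained_off", adaptation = 0.25,
                           tau_adapt = 8),
      GC5 = response_class("intermediate_tuned", peak = 0.1, width = 0.07),
      GC6 = response_class("intermediate_tuned", peak = 0.3, width = 0.15,
                           adaptation = 0.5, tau_adapt = 4),
      GC7 = response_class("ramp", tau_ramp = 4),
      GC8 = response_class("suppressed_then_ramp", tau_ramp = 10, delay = 2)
    ),
    ion = list(
      ION1 = response_class("transient_off"),
      ION2 = response_class("sustained_on", threshold = 0.3,
                            adaptation = 0.9, tau_adapt = 2),
      ION3 = response_class("transient_on"),
      ION4 = response_class("transient_both", adaptation = 0.6,
                            tau_adapt = 1),
      ION5 = response_class("intermediate_tuned", peak = 0.12, width = 0.1,
                            adaptation = 0.7, tau_adapt = 3),
      ION6 = response_class("intermediate_tuned", peak = 0.15, width = 0.1,
                            transient_weight = 2, transient_mode = "off")
    )
  )
}

#' Generate a trial-repeated synthetic population
#'
#' Responsive cells are a class template plus i.i.d. Gaussian noise per
#' trial; unresponsive cells are noise only (optionally with slow AR(1)
#' drift). Class labels cycle through `classes` across responsive cells.
#'
#' @param classes list of [response_class()] templates.
#' @param stimulus single-repetition `sampled_stimulus` defining one trial.
#' @param n_cells population size.
#' @param n_trials stimulus repetitions per cell.
#' @param responsive_fraction fraction of cells carrying a template.
#' @param noise_sd per-frame Gaussian noise sd.
#' @param drift_ar AR(1) coefficient for slow drift in unresponsive cells
#'   (0 disables).
#' @param seed RNG seed.
#' @param kernel indicator kernel for the templates.
#' @return list with `tensor` (a `trial_tensor`), `truth` (data.frame:
#'   `cell`, `class`, `responsive`), `templates` (class x frames matrix).
#' @export
gen_population <- function(classes, stimulus, n_cells, n_trials,
                           responsive_fraction = 0.5, noise_sd = 0.3,
                           drift_ar = 0, seed = 0L, kernel = NULL) {
  stopifnot(responsive_fraction >= 0, responsive_fraction <= 1)
  set.seed(seed)
  n_frames <- length(stimulus$luminance)
  templates <- t(vapply(classes, template_response, numeric(n_frames),
                        stimulus = stimulus, kernel = kernel))
  n_resp <- round(responsive_fraction * n_cells)
  class_of <- rep(NA_integer_, n_cells)
  if (n_resp > 0) {
    class_of[seq_len(n_resp)] <- rep_len(seq_along(classes), n_resp)
  }
  vals <- array(NA_real_, c(n_cells, n_trials, n_frames))
  for (i in seq_len(n_cells)) {
    base <- if (is.na(class_of[i])) rep(0, n_frames)
            else templates[class_of[i], ]
    for (tr in seq_len(n_trials)) {
      noise <- stats::rnorm(n_frames, sd = noise_sd)
      if (is.na(class_of[i]) && drift_ar > 0) {
        noise <- noise + as.numeric(stats::filter(
          stats::rnorm(n_frames, sd = noise_sd), drift_ar,
          method = "recursive"))
      }
      vals[i, tr, ] <- base + noise
    }
  }
  tensor <- structure(
    list(values = vals, frame_period = stimulus$frame_period,
         trial_stimulus = stimulus$luminance),
    class = "trial_tensor"
  )
  truth <- data.frame(
    cell = seq_len(n_cells),
    class = ifelse(is.na(class_of), NA, names(classes)[class_of]),
    responsive = !is.na(class_of)
  )
  list(tensor = tensor, truth = truth, templates = templates, seed = seed)
}

#' Generate a single-plane movie with planted footprints and drift
#'
#' Frame t is `background + sum_i footprint_i * trace_i[t]`, rigidly rolled
#' by `drift_shifts[t, ]`, plus Gaussian noise.
#'
#' @param footprint_labels y x x integer matrix, 0 = background, i > 0 =
#'   cell i's pixels.
#' @param traces cells x frames matrix of fluorescence time courses.
#' @param background y x x baseline image (default flat 100 counts).
#' @param drift_shifts frames x 2 integer (dy, dx) drift per frame.
#' @param noise_sd Gaussian noise sd per pixel per frame.
#' @param frame_period,pixel_size movie metadata.
#' @param seed RNG seed.
#' @return list with `movie` (a `plane_movie`) and `truth` (labels,
#'   drift, traces).
#' @export
gen_movie <- function(footprint_labels, traces, background = NULL,
                      drift_shifts = NULL, noise_sd = 1,
                      frame_period = 0.25, pixel_size = 1, seed = 0L) {
  set.seed(seed)
  ny <- nrow(footprint_labels); nx <- ncol(footprint_labels)
  n_t <- ncol(traces)
  if (is.null(background)) background <- matrix(100, ny, nx)
  if (is.null(drift_shifts)) drift_shifts <- matrix(0L, n_t, 2)
  frames <- array(NA_real_, c(n_t, ny, nx))
  n_cells <- max(footprint_labels)
  for (t in seq_len(n_t)) {
    img <- background
    for (i in seq_len(n_cells)) {
      img[footprint_labels == i] <- img[footprint_labels == i] + traces[i, t]
    }
    img <- roll2d(img, drift_shifts[t, 1], drift_shifts[t, 2])
    frames[t, , ] <- img + stats::rnorm(ny * nx, sd = noise_sd)
  }
  list(
    movie = plane_movie(frames, frame_period, pixel_size),
    truth = list(labels = footprint_labels, drift = drift_shifts,
                 traces = traces, seed = seed)
  )
}

#' Generate Purkinje-cell traces as known regressor mixtures
#'
#' Each cell's trial is `offset + regressors %*% weights + noise`, the
#' forward model of the constrained fit, so recovery can be scored against
#' the planted weights.
#'
#' @param regs a `cluster_regressors`.
#' @param true_weights cells x (J + K) nonnegative matrix within the fit
#'   bounds.
#' @param offsets per-cell offsets in \[-5, 5\].
#' @param n_trials trials per cell.
#' @param noise_sd per-frame Gaussian noise sd.
#' @param seed RNG seed.
#' @return list with `trials` (list of trials x frames matrices per cell)
#'   and `truth` (weights, offsets, gc_dominant flag).
#' @export
gen_pc_traces <- function(regs, true_weights, offsets, n_trials = 6L,
                          noise_sd = 0.3, seed = 0L) {
  true_weights <- rbind(true_weights)
  if (any(true_weights < 0) || any(true_weights > 1000)) {
    stop("true weights must lie in [0, 1000]")
  }
  if (any(abs(offsets) > 5)) stop("offsets must lie in [-5, 5]")
  set.seed(seed)
  D <- cbind(regs$gc, regs$ion)
  J <- ncol(regs$gc)
  n_frames <- nrow(D)
  trials <- lapply(seq_len(nrow(true_weights)), function(i) {
    clean <- offsets[i] + drop(D %*% true_weights[i, ])
    t(vapply(seq_len(n_trials), function(tr) {
      clean + stats::rnorm(n_frames, sd = noise_sd)
    }, numeric(n_frames)))
  })
  gc_sum <- rowSums(true_weights[, seq_len(J), drop = FALSE])
  ion_sum <- rowSums(true_weights[, -seq_len(J), drop = FALSE])
  list(trials = trials,
       truth = list(weights = true_weights, offsets = offsets,
                    gc_sum = gc_sum, ion_sum = ion_sum,
                    true_index = ifelse(gc_sum + ion_sum == 0, NA,
                                        (gc_sum - ion_sum) / (gc_sum + ion_sum)),
                    seed = seed))
}

#' OFF-transition times of a protocol (single repetition)
#' @param protocol a `luminance_protocol`.
#' @return seconds from repetition start at which luminance decreases.
#' @export
off_transition_times <- function(protocol) {
  lv <- protocol$epochs$level
  edges <- cumsum(protocol$epochs$duration)
  edges[-length(edges)][diff(lv) < 0]
}

#' Generate a velocity trace with bouts suppressed after OFF transitions
#'
#' Bout onsets follow an inhomogeneous Poisson process at `baseline_rate`,
#' multiplied by `1 - suppression` within `suppression_window` seconds
#' after every luminance-OFF transition. Each bout is rendered as a 0.2 s
#' rectangular speed pulse of amplitude 2 on a zero baseline (so a
#' threshold of 1 recovers the bouts exactly).
#'
#' @param protocol a `luminance_protocol` (its `n_repetitions` sets the
#'   session length).
#' @param baseline_rate bouts per second outside suppression windows.
#' @param suppression fractional rate drop in \[0, 1\].
#' @param suppression_window seconds after each OFF transition.
#' @param sample_rate velocity sampling rate in Hz (default 50).
#' @param refractory minimal gap between bout onsets, seconds (default
#'   0.5; swimming bouts are discrete events).
#' @param seed RNG seed.
#' @return list with `velocity`, `rate`, `truth` (planted onset times).
#' @export
gen_bout_train <- function(protocol, baseline_rate = 0.8, suppression = 0.8,
                           suppression_window = 1.5, sample_rate = 50,
                           refractory = 0.5, seed = 0L) {
  stopifnot(suppression >= 0, suppression <= 1)
  set.seed(seed)
  rep_dur <- sum(protocol$epochs$duration)
  total <- rep_dur * protocol$n_repetitions
  off_rep <- off_transition_times(protocol)
  # homogeneous Poisson in continuous time, thinned inside the
  # suppression windows
  n_max <- stats::qpois(1 - 1e-9, baseline_rate * total) + 10
  gaps <- stats::rexp(n_max, rate = baseline_rate)
  onsets <- cumsum(gaps)
  onsets <- onsets[onsets < total]
  phase <- onsets %% rep_dur
  in_window <- Reduce(`|`, c(list(rep(FALSE, length(onsets))),
                             lapply(off_rep, function(o) {
                               phase > o & phase <= o + suppression_window
                             })))
  keep <- !in_window | stats::runif(length(onsets)) >= suppression
  onsets <- onsets[keep]
  if (refractory > 0 && length(onsets) > 1) {
    accepted <- onsets[1]
    for (o in onsets[-1]) {
      if (o - accepted[length(accepted)] >= refractory) {
        accepted <- c(accepted, o)
      }
    }
    onsets <- accepted
  }
  velocity <- numeric(ceiling(total * sample_rate))
  pulse_len <- max(1L, round(0.2 * sample_rate))
  for (o in onsets) {
    i0 <- floor(o * sample_rate) + 1
    velocity[i0:min(length(velocity), i0 + pulse_len - 1)] <- 2
  }
  list(velocity = velocity, rate = sample_rate,
       truth = list(onsets = onsets, seed = seed))
}
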