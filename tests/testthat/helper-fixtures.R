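# Shared fixtures built in code: small planted-footprint movies and the
# populations used across modules.

# Disc-shaped footprint label matrix: n_cells discs of radius r on a grid.
make_footprints <- function(ny = 48, nx = 48, centers, radius = 2.5) {
  lb <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(centers))) {
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      if ((y - centers[i, 1])^2 + (x - centers[i, 2])^2 <= radius^2) {
        lb[y, x] <- i
      }
    }
  }
  lb
}

# A grid of well-separated disc centers.
grid_centers <- function(n, ny = 48, nx = 48, spacing = 10, margin = 6) {
  pos <- expand.grid(y = seq(margin, ny - margin, by = spacing),
                     x = seq(margin, nx - margin, by = spacing))
  as.matrix(pos[seq_len(n), ])
}

# Movie with planted coherent cells responding to a shared slow signal,
# independent per-cell phases, on a noisy background.
planted_movie <- function(n_cells = 6, n_frames = 300, amplitude = 30,
                          noise_sd = 4, drift = NULL, seed = 1,
                          ny = 48, nx = 48) {
  set.seed(seed)
  centers <- grid_centers(n_cells, ny, nx)
  lb <- make_footprints(ny, nx, centers)
  traces <- t(vapply(seq_len(n_cells), function(i) {
    # smooth positive activity, distinct per cell
    amplitude * pmax(sin(2 * pi * (seq_len(n_frames) / 40 + i / n_cells)), 0) +
      amplitude * 0.3 * sin(2 * pi * seq_len(n_frames) / (15 + 3 * i))
  }, numeric(n_frames)))
  # static anatomical texture so rigid alignment is well-posed
  bg <- matrix(100 + rnorm(ny * nx, sd = amplitude / 2), ny, nx)
  gen_movie(lb, traces, background = bg, drift_shifts = drift,
            noise_sd = noise_sd, frame_period = 0.25, pixel_size = 1,
            seed = seed)
}

# Steps stimulus for one repetition at a coarse frame period (fast tests).
steps_stim <- function(n_repetitions = 1, frame_period = 0.5) {
  sample_protocol(build_steps_protocol(n_repetitions = n_repetitions),
                  frame_period)
}

flashes_stim <- function(n_repetitions = 1, frame_period = 0.5) {
  sample_protocol(build_flashes_protocol(n_repetitions = n_repetitions),
                  frame_period)
}
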