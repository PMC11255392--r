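# Plane-wise rigid motion correction, neighbour-correlation maps, seeded
# ROI growing, and fluorescence trace extraction.

#' Construct a single-plane movie
#'
#' @param frames numeric array time x y x x (fluorescence counts; NA marks
#'   missing pixels/frames).
#' @param frame_period seconds per frame.
#' @param pixel_size microns per pixel.
#' @param plane_index 0-based plane position, dorsal to ventral.
#' @param plane_spacing microns between consecutive planes.
#' @return object of class `plane_movie`.
#' @export
plane_movie <- function(frames, frame_period, pixel_size,
                        plane_index = 0L, plane_spacing = 1.5) {
  stopifnot(length(dim(frames)) == 3, frame_period > 0, pixel_size > 0)
  structure(
    list(frames = frames, frame_period = frame_period,
         pixel_size = pixel_size, plane_index = as.integer(plane_index),
         plane_spacing = plane_spacing),
    class = "plane_movie"
  )
}

# Cross-correlation peak between two equally sized images; returns the
# integer (dy, dx) by which `img` is displaced relative to `ref`.
# Wrap-around FFT cross-correlation on mean-subtracted images; peak offsets
# beyond half the image size are interpreted as negative shifts.
xcorr_shift <- function(ref, img) {
  ref <- ref - mean(ref)
  img <- img - mean(img)
  ny <- nrow(ref); nx <- ncol(ref)
  cc <- Re(stats::fft(Conj(stats::fft(ref)) * stats::fft(img), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy = as.integer(dy), dx = as.integer(dx))
}

# Integer circular roll of a 2D image by (dy, dx).
roll2d <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  if (dy %% ny != 0) img <- img[((seq_len(ny) - 1 - dy) %% ny) + 1, , drop = FALSE]
  if (dx %% nx != 0) img <- img[, ((seq_len(nx) - 1 - dx) %% nx) + 1, drop = FALSE]
  img
}

#' Rigid plane-wise motion correction
#'
#' The reference is the mean of 50 frames (by default the first 50). Each
#' frame's displacement is the peak of its cross-correlation against the
#' reference; frames are corrected by integer-pixel rigid translation (no
#' subpixel interpolation, preserving counts). Frames whose displacement
#' exceeds `rejection_radius` microns are motion artifacts: they are set to
#' NA in place, never dropped, so the frame count is preserved.
#'
#' @param movie a `plane_movie` with at least 50 frames.
#' @param rejection_radius maximal believable displacement in microns
#'   (default 10).
#' @param reference_start 0-based index of the first reference frame.
#' @return list with `movie` (aligned) and `alignment` (fields `shifts`
#'   frames x 2, `rejected` logical, `reference` image).
#' @export
align_plane <- function(movie, rejection_radius = 10, reference_start = 0L) {
  fr <- movie$frames
  n_t <- dim(fr)[1]
  if (n_t < 50) stop("alignment requires at least 50 frames")
  idx <- reference_start + seq_len(50)
  reference <- apply(fr[idx, , , drop = FALSE], c(2, 3), mean)
  shifts <- matrix(0L, n_t, 2, dimnames = list(NULL, c("dy", "dx")))
  rejected <- logical(n_t)
  out <- fr
  for (t in seq_len(n_t)) {
    s <- xcorr_shift(reference, fr[t, , ])
    shifts[t, ] <- s
    if (sqrt(sum(s^2)) * movie$pixel_size > rejection_radius) {
      rejected[t] <- TRUE
      out[t, , ] <- NA_real_
    } else {
      out[t, , ] <- roll2d(fr[t, , ], -s[1], -s[2])
    }
  }
  movie$frames <- out
  list(
    movie = movie,
    alignment = list(shifts = shifts, rejected = rejected,
                     reference = reference)
  )
}

#' Cumulative rigid shifts across planes
#'
#' Chains cross-correlations between consecutive plane-average images and
#' accumulates them, so each plane's shift is expressed relative to plane 0.
#'
#' @param plane_averages list of y x x images, one per plane, dorsal to
#'   ventral.
#' @return matrix planes x 2 of cumulative (dy, dx) shifts.
#' @export
align_across_planes <- function(plane_averages) {
  n <- length(plane_averages)
  shifts <- matrix(0L, n, 2, dimnames = list(NULL, c("dy", "dx")))
  if (n < 2) return(shifts)
  for (p in 2:n) {
    shifts[p, ] <- shifts[p - 1, ] +
      xcorr_shift(plane_averages[[p - 1]], plane_averages[[p]])
  }
  shifts
}

#' Neighbour-correlation map of a movie
#'
#' Each pixel is assigned the Pearson correlation over time between its own
#' fluorescence and the average fluorescence of its eight neighbour pixels
#' (border pixels use their existing neighbours only). Frames rejected in
#' alignment are NA and excluded pairwise. Pixels with a constant
#' time-series get NA.
#'
#' @param movie a `plane_movie` with at least 2 valid frames.
#' @return y x x matrix of correlations in \[-1, 1\], class
#'   `correlation_map`.
#' @export
correlation_map <- function(movie) {
  fr <- movie$frames
  n_t <- dim(fr)[1]; ny <- dim(fr)[2]; nx <- dim(fr)[3]
  valid <- !apply(is.na(fr), 1, all)
  if (sum(valid) < 2) stop("correlation map requires >= 2 valid frames")
  fr <- fr[valid, , , drop = FALSE]
  n_t <- dim(fr)[1]
  # neighbour sums by shifting the y/x axes; count existing neighbours.
  nb_sum <- array(0, dim(fr))
  nb_cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    nb_sum[, which(oky), which(okx)] <- nb_sum[, which(oky), which(okx)] +
      fr[, ys[oky], xs[okx], drop = FALSE]
    nb_cnt[which(oky), which(okx)] <- nb_cnt[which(oky), which(okx)] + 1
  }
  X <- matrix(aperm(fr, c(2, 3, 1)), ny * nx, n_t)      # pixels x time
  Nm <- matrix(aperm(nb_sum, c(2, 3, 1)), ny * nx, n_t) / as.vector(nb_cnt)
  r <- vapply(seq_len(ny * nx), function(i) {
    suppressWarnings(stats::cor(X[i, ], Nm[i, ], use = "pairwise.complete.obs"))
  }, numeric(1))
  structure(matrix(r, ny, nx), class = "correlation_map")
}

#' Grow ROIs from correlation-map seeds
#'
#' Iteratively picks the unassigned pixel with the highest correlation-map
#' value (at least `seed_floor`) as a seed, then evaluates the ROI's
#' 4-connected unassigned neighbours in decreasing map order, adding a pixel
#' when the Pearson correlation between its time-series and the mean
#' time-series of the ROI grown so far reaches `grow_threshold` and it lies
#' within `max_radius` microns of the seed. An ROI is finalized when no
#' neighbour qualifies; ROIs smaller than `min_pixels` are discarded (their
#' pixels are consumed — not re-seedable — so the procedure terminates).
#' Ties in map value are broken in row-major pixel order.
#'
#' @param map a `correlation_map`.
#' @param movie the `plane_movie` the map was computed from.
#' @param seed_floor minimal map value for a seed (default 0.3).
#' @param grow_threshold minimal trace correlation to join an ROI
#'   (default 0.35).
#' @param max_radius maximal distance from seed in microns (default 5).
#' @param min_pixels minimal ROI size in pixels (default 4).
#' @return object of class `roi_set`: `labels` (y x x integer, 0 =
#'   background), `roi_ids`, `plane_membership`, `source`.
#' @export
grow_rois <- function(map, movie, seed_floor = 0.3, grow_threshold = 0.35,
                      max_radius = 5, min_pixels = 4L) {
  ny <- nrow(map); nx <- ncol(map)
  fr <- movie$frames
  valid <- !apply(is.na(fr), 1, all)
  X <- matrix(aperm(fr[valid, , , drop = FALSE], c(2, 3, 1)), ny * nx,
              sum(valid))
  mp <- unclass(map)
  labels <- matrix(0L, ny, nx)
  consumed <- is.na(mp)  # pixels never eligible again
  max_radius_px <- max_radius / movie$pixel_size
  next_id <- 0L
  # row-major order: R matrices are column-major, so order on (row, col)
  # explicitly for deterministic tie-breaks.
  lin <- function(y, x) (x - 1L) * ny + y
  repeat {
    cand <- which(!consumed & labels == 0 & mp >= seed_floor)
    if (length(cand) == 0) break
    ord <- cand[order(-mp[cand], ((cand - 1L) %% ny) + 1L,
                      ((cand - 1L) %/% ny) + 1L)]
    seed <- ord[1]
    sy <- ((seed - 1L) %% ny) + 1L; sx <- ((seed - 1L) %/% ny) + 1L
    roi <- seed
    roi_sum <- X[seed, ]
    tested <- logical(ny * nx)
    tested[seed] <- TRUE
    repeat {
      nbrs <- integer(0)
      for (p in roi) {
        py <- ((p - 1L) %% ny) + 1L; px <- ((p - 1L) %/% ny) + 1L
        if (py > 1) nbrs <- c(nbrs, lin(py - 1L, px))
        if (py < ny) nbrs <- c(nbrs, lin(py + 1L, px))
        if (px > 1) nbrs <- c(nbrs, lin(py, px - 1L))
        if (px < nx) nbrs <- c(nbrs, lin(py, px + 1L))
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[!tested[nbrs] & !consumed[nbrs] & labels[nbrs] == 0 &
                     !is.na(mp[nbrs])]
      if (length(nbrs) == 0) break
      nbrs <- nbrs[order(-mp[nbrs], ((nbrs - 1L) %% ny) + 1L,
                         ((nbrs - 1L) %/% ny) + 1L)]
      added <- FALSE
      mean_trace <- roi_sum / length(roi)
      for (p in nbrs) {
        tested[p] <- TRUE
        py <- ((p - 1L) %% ny) + 1L; px <- ((p - 1L) %/% ny) + 1L
        if (sqrt((py - sy)^2 + (px - sx)^2) > max_radius_px) next
        r <- suppressWarnings(stats::cor(X[p, ], mean_trace,
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r >= grow_threshold) {
          roi <- c(roi, p)
          roi_sum <- roi_sum + X[p, ]
          added <- TRUE
          break  # re-rank neighbours against the updated ROI mean
        }
      }
      if (!added) break
    }
    consumed[roi] <- TRUE
    if (length(roi) >= min_pixels) {
      next_id <- next_id + 1L
      labels[roi] <- next_id
    }
  }
  roi_ids <- seq_len(next_id)
  structure(
    list(labels = labels, roi_ids = roi_ids,
         plane_membership = stats::setNames(
           lapply(roi_ids, function(i) movie$plane_index),
           as.character(roi_ids)),
         source = "automatic"),
    class = "roi_set"
  )
}

#' Merge ROIs across adjacent planes
#'
#' ROIs in adjacent planes are merged into one multi-plane ROI when their
#' spatial footprints overlap by at least `overlap_fraction` (intersection
#' over the smaller footprint) and their mean traces correlate by at least
#' `trace_correlation`; merging is transitive along planes. Planes must
#' already be registered with [align_across_planes()].
#'
#' @param rois_by_plane list of single-plane `roi_set`s, dorsal to ventral.
#' @param traces_by_plane list of cells x frames matrices, rows matching
#'   `roi_ids` of the corresponding plane.
#' @param overlap_fraction minimal footprint overlap (default 0.5).
#' @param trace_correlation minimal mean-trace Pearson r (default 0.5).
#' @return a multi-plane `roi_set`: `labels` is a list of per-plane masks;
#'   `plane_membership` maps merged roi_id to its planes; `members` maps
#'   merged roi_id to per-plane original ids.
#' @export
merge_rois_across_planes <- function(rois_by_plane, traces_by_plane,
                                     overlap_fraction = 0.5,
                                     trace_correlation = 0.5) {
  n_planes <- length(rois_by_plane)
  nodes <- do.call(rbind, lapply(seq_len(n_planes), function(p) {
    ids <- rois_by_plane[[p]]$roi_ids
    if (length(ids) == 0) return(NULL)
    data.frame(plane = p, id = ids)
  }))
  if (is.null(nodes) || nrow(nodes) == 0) {
    return(structure(list(labels = lapply(rois_by_plane, `[[`, "labels"),
                          roi_ids = integer(0),
                          plane_membership = list(), members = list(),
                          source = "automatic"), class = "roi_set"))
  }
  parent <- seq_len(nrow(nodes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  node_idx <- function(p, id) which(nodes$plane == p & nodes$id == id)
  if (n_planes > 1) {
    for (p in seq_len(n_planes - 1)) {
      la <- rois_by_plane[[p]]$labels; lb <- rois_by_plane[[p + 1]]$labels
      for (ida in rois_by_plane[[p]]$roi_ids) {
        fa <- la == ida
        for (idb in rois_by_plane[[p + 1]]$roi_ids) {
          fb <- lb == idb
          ov <- sum(fa & fb) / min(sum(fa), sum(fb))
          if (ov < overlap_fraction) next
          r <- suppressWarnings(stats::cor(
            traces_by_plane[[p]][ida, ], traces_by_plane[[p + 1]][idb, ],
            use = "pairwise.complete.obs"))
          if (!is.na(r) && r >= trace_correlation) {
            union_(node_idx(p, ida), node_idx(p + 1, idb))
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(nrow(nodes)), find, integer(1))
  comp <- match(roots, sort(unique(roots)))
  merged_ids <- sort(unique(comp))
  members <- lapply(merged_ids, function(ci) nodes[comp == ci, , drop = FALSE])
  labels <- lapply(seq_len(n_planes), function(p) {
    lb <- rois_by_plane[[p]]$labels
    out <- matrix(0L, nrow(lb), ncol(lb))
    for (ci in merged_ids) {
      m <- members[[ci]]
      for (k in which(m$plane == p)) out[lb == m$id[k]] <- ci
    }
    out
  })
  structure(
    list(labels = labels, roi_ids = merged_ids,
         plane_membership = stats::setNames(
           lapply(members, function(m) sort(unique(m$plane)) - 1L),
           as.character(merged_ids)),
         members = stats::setNames(members, as.character(merged_ids)),
         source = "automatic"),
    class = "roi_set"
  )
}

#' Extract per-ROI fluorescence traces
#'
#' Each ROI's trace is the mean over its pixels per frame; frames rejected
#' during alignment propagate as NA. For multi-plane ROI sets produced by
#' [merge_rois_across_planes()] use [extract_traces_multiplane()], which
#' concatenates the per-plane protocol repetitions along the repetition
#' axis.
#'
#' @param movie a `plane_movie`.
#' @param rois a single-plane `roi_set` on the same field of view.
#' @return cells x frames matrix, rows named by roi_id.
#' @export
extract_traces <- function(movie, rois) {
  lb <- rois$labels
  if (is.list(lb)) stop("multi-plane roi_set: use extract_traces_multiplane()")
  fr <- movie$frames
  n_t <- dim(fr)[1]
  X <- matrix(aperm(fr, c(2, 3, 1)), length(lb), n_t)
  out <- matrix(NA_real_, length(rois$roi_ids), n_t,
                dimnames = list(rois$roi_ids, NULL))
  for (i in seq_along(rois$roi_ids)) {
    px <- which(lb == rois$roi_ids[i])
    if (length(px) == 0) stop("ROI with 0 pixels: ", rois$roi_ids[i])
    out[i, ] <- colMeans(X[px, , drop = FALSE])
  }
  out
}

#' Extract traces for multi-plane ROIs as stacked repetitions
#'
#' A cell spanning several planes was recorded once per plane, so its
#' per-plane traces are additional repetitions of the same protocol: this
#' returns, per merged ROI, a trials x frames-per-trial matrix concatenating
#' the repetitions observed in every member plane.
#'
#' @param movies_by_plane list of `plane_movie`s.
#' @param rois multi-plane `roi_set` from [merge_rois_across_planes()].
#' @param stimulus the `sampled_stimulus` shared by all planes.
#' @return list of trials x frames matrices, named by merged roi_id.
#' @export
extract_traces_multiplane <- function(movies_by_plane, rois, stimulus) {
  reps <- split(seq_along(stimulus$repetition_index),
                stimulus$repetition_index)
  len <- min(lengths(reps))
  lapply(stats::setNames(as.character(rois$roi_ids), rois$roi_ids),
         function(id) {
    m <- rois$members[[id]]
    do.call(rbind, lapply(seq_len(nrow(m)), function(k) {
      p <- m$plane[k]
      lb1 <- rois$labels[[p]]
      px <- which(lb1 == as.integer(id))
      fr <- movies_by_plane[[p]]$frames
      X <- matrix(aperm(fr, c(2, 3, 1)), length(lb1), dim(fr)[1])
      tr <- colMeans(X[px, , drop = FALSE])
      t(vapply(reps, function(ix) tr[ix[seq_len(len)]], numeric(len)))
    }))
  })
}

#' Load a manually drawn ROI mask
#'
#' Reads an integer-labelled mask (16-bit TIFF via the `tiff` package, or a
#' plain-text matrix of integer labels) into a `roi_set` with
#' `source = "manual"`. A label appearing in several disconnected blobs is
#' treated as a single ROI spanning those blobs.
#'
#' @param mask_file path to a labelled-mask TIFF or whitespace-delimited
#'   text matrix.
#' @param plane_index 0-based plane the mask belongs to.
#' @export
load_manual_rois <- function(mask_file, plane_index = 0L) {
  if (grepl("\\.tiff?$", mask_file, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF masks requires the 'tiff' package")
    }
    img <- tiff::readTIFF(mask_file, as.is = TRUE)
    if (is.list(img)) img <- img[[1]]
    m <- round(img)
    if (max(abs(img - m)) > 1e-9) stop("mask is not integer-labelled")
  } else {
    m <- as.matrix(utils::read.table(mask_file))
    dimnames(m) <- NULL
    if (any(m != round(m))) stop("mask is not integer-labelled")
  }
  storage.mode(m) <- "integer"
  ids <- sort(setdiff(unique(as.vector(m)), 0L))
  structure(
    list(labels = m, roi_ids = ids,
         plane_membership = stats::setNames(
           lapply(ids, function(i) plane_index), as.character(ids)),
         source = "manual"),
    class = "roi_set"
  )
}
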