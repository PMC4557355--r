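#' Sample ground-truth particles for a synthetic field of view
#'
#' Draws a set of immobile diffraction-limited particles. Each particle gets a
#' true oligomeric size `true_n` from `species_probs`, a labelled-subunit
#' count `labelled_m ~ Binomial(true_n, label_p)` (the binomial thinning that
#' the labelling correction later inverts), one brightness draw from
#' Normal(`mu1`, `sigma1`) per labelled fluorophore (redrawn if non-positive)
#' and one exponential bleaching lifetime per labelled fluorophore. Positions
#' are uniform over the usable field with a minimum pairwise separation so
#' that spots do not overlap.
#'
#' @param n_particles Number of particles to place.
#' @param species_probs Named numeric vector of probabilities over true sizes
#'   N; names are the sizes (e.g. `c("2" = 0.45, "4" = 0.35, "6" = 0.20)`).
#'   Must sum to 1.
#' @param label_p Labelling probability in (0, 1].
#' @param optics An [optics_model()].
#' @param photo A [photophysics_model()].
#' @param min_separation_px Minimum pairwise distance between particle
#'   centres, in pixels.
#' @param border_px Margin kept free of particles on every side.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @param max_tries Placement attempts per particle before giving up.
#' @return A data frame of class `ground_truth` with one row per particle:
#'   `x`, `y` (0-based pixel-centre coordinates), `true_n`, `labelled_m`, and
#'   list columns `bleach_frames` and `per_fluor_brightness` (each of length
#'   `labelled_m`).
#' @export
sample_ground_truth <- function(n_particles, species_probs, label_p = 0.8,
                                optics = optics_model(),
                                photo = photophysics_model(),
                                min_separation_px = 6, border_px = 5,
                                seed = NULL, max_tries = 200L) {
  stopifnot(n_particles >= 1, label_p > 0, label_p <= 1)
  probs <- as.numeric(species_probs)
  sizes <- as.integer(names(species_probs))
  if (any(is.na(sizes))) stop("species_probs must be named by integer sizes")
  if (abs(sum(probs) - 1) > 1e-9) stop("species_probs must sum to 1")
  if (any(probs < 0)) stop("species_probs must be nonnegative")
  if (!is.null(seed)) set.seed(seed)

  lo <- border_px
  hi <- optics$fov_px - 1 - border_px
  if (hi <= lo) stop("field of view too small for the requested border")
  # crude capacity check: disks of radius min_sep/2 must fit in the free area
  if (n_particles * pi * (min_separation_px / 2)^2 > 0.7 * (hi - lo)^2)
    stop("field of view too crowded for min_separation_px")

  xs <- ys <- numeric(n_particles)
  placed <- 0L
  while (placed < n_particles) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      px <- stats::runif(1, lo, hi)
      py <- stats::runif(1, lo, hi)
      if (placed == 0L ||
          min((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2) >=
            min_separation_px^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("field of view too crowded: placement failed after retries")
    placed <- placed + 1L
    xs[placed] <- px
    ys[placed] <- py
  }

  true_n <- sizes[sample.int(length(sizes), n_particles, replace = TRUE,
                             prob = probs)]
  labelled_m <- stats::rbinom(n_particles, true_n, label_p)

  bleach <- vector("list", n_particles)
  bright <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    m <- labelled_m[i]
    if (m > 0) {
      bleach[[i]] <- stats::rexp(m, rate = 1 / photo$bleach_mean_frames)
      b <- stats::rnorm(m, photo$mu1, photo$sigma1)
      while (any(b <= 0)) {
        bad <- b <= 0
        b[bad] <- stats::rnorm(sum(bad), photo$mu1, photo$sigma1)
      }
      bright[[i]] <- b
    } else {
      bleach[[i]] <- numeric(0)
      bright[[i]] <- numeric(0)
    }
  }

  out <- data.frame(particle_id = seq_len(n_particles),
                    x = xs, y = ys, true_n = true_n, labelled_m = labelled_m)
  out$bleach_frames <- bleach
  out$per_fluor_brightness <- bright
  class(out) <- c("ground_truth", "data.frame")
  attr(out, "label_p") <- label_p
  attr(out, "seed") <- seed
  out
}

#' Noise-free initial brightness of each particle
#'
#' Sum of the per-fluorophore brightness draws of the labelled fluorophores;
#' the expected level of the first trace frames before any bleaching.
#' Unlabelled (m = 0) particles are dropped: they are dark and unobservable.
#'
#' @param truth A `ground_truth` data frame from [sample_ground_truth()].
#' @return Numeric vector of per-particle brightnesses (counts).
#' @export
true_brightness <- function(truth) {
  v <- vapply(truth$per_fluor_brightness, sum, numeric(1))
  v[truth$labelled_m > 0]
}

#' Render a synthetic fluorescence movie
#'
#' Forward model of the measurement: per frame, each still-fluorescent
#' labelled fluorophore deposits a 2D Gaussian PSF whose integrated intensity
#' equals its per-fluorophore brightness; the pixel value is
#' Poisson(signal + background) plus Gaussian read noise, clipped at zero.
#' A fluorophore is on for frames strictly below its bleaching lifetime and
#' contributes nothing afterwards.
#'
#' @param truth Particles from [sample_ground_truth()].
#' @param optics An [optics_model()].
#' @param photo A [photophysics_model()].
#' @param n_frames Number of frames (default 500).
#' @param seed Optional seed for the noise draws.
#' @return A `frame_stack`: numeric array `fov x fov x n_frames`, with the
#'   optics/photophysics models and frame interval attached as attributes.
#' @export
render_movie <- function(truth, optics = optics_model(),
                         photo = photophysics_model(), n_frames = 500,
                         seed = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nf <- as.integer(n_frames)
  w <- optics$fov_px
  s <- optics$psf_sigma_px
  half <- ceiling(4 * s)

  # per-particle PSF pixel weights on a local window (integrated per pixel
  # via the error function so the deposited volume equals the brightness)
  stack <- array(photo$background_rate, dim = c(w, w, nf))
  np <- nrow(truth)
  if (np > 0) {
    for (i in seq_len(np)) {
      m <- truth$labelled_m[i]
      if (m == 0) next
      x0 <- truth$x[i]; y0 <- truth$y[i]
      cx <- round(x0); cy <- round(y0)
      ix <- max(0, cx - half):min(w - 1, cx + half)
      iy <- max(0, cy - half):min(w - 1, cy + half)
      # pixel j covers [j-0.5, j+0.5] (pixel-centre convention)
      fx <- stats::pnorm(ix + 0.5, x0, s) - stats::pnorm(ix - 0.5, x0, s)
      fy <- stats::pnorm(iy + 0.5, y0, s) - stats::pnorm(iy - 0.5, y0, s)
      psf <- outer(fx, fy)  # rows = x, cols = y
      on_frames <- pmin(nf, pmax(0L, floor(truth$bleach_frames[[i]])))
      br <- truth$per_fluor_brightness[[i]]
      # total deposited brightness per frame = sum of brightness of
      # fluorophores still on at that frame
      if (any(on_frames > 0)) {
        lvl <- numeric(nf)
        for (k in seq_len(m)) if (on_frames[k] > 0)
          lvl[seq_len(on_frames[k])] <- lvl[seq_len(on_frames[k])] + br[k]
        nz <- which(lvl > 0)
        for (t in nz)
          stack[ix + 1, iy + 1, t] <- stack[ix + 1, iy + 1, t] + lvl[t] * psf
      }
    }
  }
  noisy <- stats::rpois(length(stack), stack)
  if (photo$read_noise_sd > 0)
    noisy <- noisy + stats::rnorm(length(stack), 0, photo$read_noise_sd)
  stack <- array(pmax(0, noisy), dim = dim(stack))
  structure(stack, class = "frame_stack", optics = optics, photo = photo,
            frame_interval_s = photo$frame_interval_s, seed = seed)
}

#' Synthesize intensity traces directly from ground truth
#'
#' Image-free fast path: the trace value at frame t is the summed brightness
#' of the fluorophores whose bleaching lifetime exceeds t, plus i.i.d.
#' Gaussian noise. Exactly `labelled_m` downward steps exist in the noiseless
#' signal (lifetimes falling in the same frame merge into one step).
#'
#' @param truth Particles from [sample_ground_truth()].
#' @param photo A [photophysics_model()].
#' @param n_frames Trace length in frames.
#' @param noise_sd Additive Gaussian noise s.d. (counts).
#' @param seed Optional seed.
#' @param drop_dark Drop particles with `labelled_m == 0` (they are never
#'   detected experimentally). Default TRUE.
#' @return A list of class `trace_set`; each element is an `intensity_trace`
#'   (numeric vector with attributes `particle_id` and `frame_interval_s`).
#' @export
synthesize_traces <- function(truth, photo = photophysics_model(),
                              n_frames = 500, noise_sd = 0, seed = NULL,
                              drop_dark = TRUE) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nf <- as.integer(n_frames)
  keep <- if (drop_dark) which(truth$labelled_m > 0) else seq_len(nrow(truth))
  traces <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    lvl <- numeric(nf)
    m <- truth$labelled_m[i]
    if (m > 0) {
      on_frames <- pmin(nf, pmax(0L, floor(truth$bleach_frames[[i]])))
      br <- truth$per_fluor_brightness[[i]]
      for (k in seq_len(m)) if (on_frames[k] > 0)
        lvl[seq_len(on_frames[k])] <- lvl[seq_len(on_frames[k])] + br[k]
    }
    if (noise_sd > 0) lvl <- lvl + stats::rnorm(nf, 0, noise_sd)
    traces[[j]] <- structure(lvl, class = "intensity_trace",
                             particle_id = truth$particle_id[i],
                             frame_interval_s = photo$frame_interval_s)
  }
  structure(traces, class = "trace_set", truth_index = keep, seed = seed)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing index-aligned ground truth, traces and
#' (optionally) a rendered movie under a single seed.
#'
#' @inheritParams sample_ground_truth
#' @inheritParams synthesize_traces
#' @param render Also render the movie (slower). Default FALSE.
#' @param n_frames Number of frames for traces/movie.
#' @return List of class `synthetic_dataset` with elements `truth`, `traces`,
#'   `stack` (or NULL) and `seed`.
#' @export
synthetic_dataset <- function(n_particles, species_probs, label_p = 0.8,
                              optics = optics_model(),
                              photo = photophysics_model(),
                              n_frames = 500, noise_sd = photo$mu1 / 3,
                              min_separation_px = 6, render = FALSE,
                              seed = 1L) {
  set.seed(seed)
  truth <- sample_ground_truth(n_particles, species_probs, label_p,
                               optics = optics, photo = photo,
                               min_separation_px = min_separation_px,
                               seed = NULL)
  traces <- synthesize_traces(truth, photo, n_frames, noise_sd, seed = NULL)
  stack <- if (render) render_movie(truth, optics, photo, n_frames,
                                    seed = NULL) else NULL
  structure(list(truth = truth, traces = traces, stack = stack, seed = seed,
                 label_p = label_p, optics = optics, photo = photo),
            class = "synthetic_dataset")
}

# ---- plain-text I/O ---------------------------------------------------------

#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers (clipped at 65535).
#' @param stack A `frame_stack`.
#' @param path Output file path.
#' @export
write_movie_tiff <- function(stack, path) {
  nf <- dim(stack)[3]
  pages <- lapply(seq_len(nf), function(t) {
    # tiff stores rows = y; transpose and scale to [0,1] 16-bit
    t(pmin(stack[, , t], 65535)) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_interval_s Frame interval to attach on read (seconds).
#' @export
read_movie_tiff <- function(path, frame_interval_s = 0.091) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  w <- ncol(pages[[1]]); h <- nrow(pages[[1]])
  stack <- array(0, dim = c(w, h, length(pages)))
  for (t in seq_along(pages)) stack[, , t] <- t(pages[[t]]) * 65535
  structure(stack, class = "frame_stack", frame_interval_s = frame_interval_s)
}

#' Write / read traces as long-format CSV (particle_id, frame, intensity)
#' @param traces A `trace_set`.
#' @param path Output CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(particle_id = attr(tr, "particle_id"),
               frame = seq_along(tr) - 1L, intensity = as.numeric(tr))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_interval_s Frame interval attached to each trace (seconds).
#' @export
read_traces_csv <- function(path, frame_interval_s = 0.091) {
  df <- utils::read.csv(path)
  ids <- unique(df$particle_id)
  traces <- lapply(ids, function(id) {
    sub <- df[df$particle_id == id, ]
    structure(sub$intensity[order(sub$frame)], class = "intensity_trace",
              particle_id = id, frame_interval_s = frame_interval_s)
  })
  structure(traces, class = "trace_set")
}

#' Write ground truth (and seed) as a JSON sidecar
#' @param truth A `ground_truth` data frame.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(seed = attr(truth, "seed"), label_p = attr(truth, "label_p"),
              particles = lapply(seq_len(nrow(truth)), function(i) list(
                particle_id = truth$particle_id[i],
                x = truth$x[i], y = truth$y[i],
                true_n = truth$true_n[i], labelled_m = truth$labelled_m[i],
                bleach_frames = truth$bleach_frames[[i]],
                per_fluor_brightness = truth$per_fluor_brightness[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
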