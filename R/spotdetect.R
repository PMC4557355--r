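#' Spot-detection parameters
#'
#' @param smoothing_sigma_px Gaussian smoothing s.d. before peak finding
#'   (match the PSF width).
#' @param threshold Counts above local background a smoothed peak must reach.
#' @param min_separation_px Minimum distance between accepted peaks; the
#'   brighter peak wins ties.
#' @param fit_window_px Odd side length of the fitting window; should cover
#'   at least +/- 3 PSF sigmas.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma_px = 1.2, threshold,
                             min_separation_px = 5, fit_window_px = 11) {
  stopifnot(smoothing_sigma_px > 0, threshold > 0, min_separation_px >= 1,
            fit_window_px >= 5, fit_window_px %% 2 == 1)
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold = threshold,
                 min_separation_px = min_separation_px,
                 fit_window_px = as.integer(fit_window_px)),
            class = "detection_params")
}

# separable Gaussian smoothing with edge renormalization
.gauss_smooth <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

#' Detect candidate spots in a single frame
#'
#' Smooths the frame with a Gaussian, finds local maxima exceeding
#' `threshold` counts above the local background (median of the smoothed
#' frame — valid for sparse emitters), enforces the minimum pairwise
#' separation keeping brighter peaks, and drops candidates too close to the
#' border to be fitted.
#'
#' @param frame 2D numeric matrix of counts (x = rows, y = columns, 0-based
#'   pixel-centre coordinates in the output).
#' @param params A [detection_params()].
#' @return Data frame with columns `x`, `y` (0-based integer pixel
#'   positions), `peak` (smoothed peak height above background). May have
#'   zero rows.
#' @export
detect_spots <- function(frame, params) {
  stopifnot(is.matrix(frame))
  w <- nrow(frame); h <- ncol(frame)
  if (w < params$fit_window_px || h < params$fit_window_px)
    stop("frame smaller than the fitting window")
  sm <- .gauss_smooth(frame, params$smoothing_sigma_px)
  bg <- stats::median(sm)
  excess <- sm - bg

  # 3x3 local maxima above threshold
  cand <- which(excess > params$threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 1):min(w, r + 1)
    cc <- max(1, c - 1):min(h, c + 1)
    keep[i] <- sm[r, c] >= max(sm[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0)))

  # border exclusion
  halfw <- params$fit_window_px %/% 2
  inb <- cand[, 1] > halfw & cand[, 1] <= w - halfw &
         cand[, 2] > halfw & cand[, 2] <= h - halfw
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0)))

  # min-separation: greedy by brightness
  pk <- excess[cand]
  ord <- order(pk, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) ||
        min((cand[sel, 1] - cand[i, 1])^2 + (cand[sel, 2] - cand[i, 2])^2) >=
          params$min_separation_px^2)
      sel <- c(sel, i)
  }
  sel <- sel[order(cand[sel, 1], cand[sel, 2])]
  data.frame(x = cand[sel, 1] - 1, y = cand[sel, 2] - 1, peak = pk[sel])
}

# bin-integrated 2D Gaussian PSF weights over a pixel window (0-based coords)
.psf_weights <- function(ix, iy, x0, y0, sigma) {
  fx <- stats::pnorm(ix + 0.5, x0, sigma) - stats::pnorm(ix - 0.5, x0, sigma)
  fy <- stats::pnorm(iy + 0.5, y0, sigma) - stats::pnorm(iy - 0.5, y0, sigma)
  outer(fx, fy)
}

#' Refine a spot by Poisson maximum-likelihood 2D Gaussian fitting
#'
#' Maximizes the Poisson likelihood of the model
#' `background + brightness * Gaussian(x0, y0, sigma)` (bin-integrated over
#' pixels) on a square window around the seed position. The fitted
#' `brightness` is the integrated spot volume, equal to
#' `2 * pi * amplitude * sigma^2` for peak amplitude `amplitude`.
#'
#' @param image 2D count matrix.
#' @param x,y Seed position (0-based pixel coordinates).
#' @param window Odd window side (pixels); must fit inside the image.
#' @param psf_sigma Initial PSF sigma (pixels).
#' @return List of class `spot_fit`: `x`, `y`, `sigma_fit`, `brightness`,
#'   `amplitude`, `background`, `ok` (FALSE when the optimizer failed or the
#'   window carries no signal), `loglik`.
#' @export
fit_spot_mle <- function(image, x, y, window = 11, psf_sigma = 1.2) {
  stopifnot(window %% 2 == 1)
  half <- window %/% 2
  cx <- round(x); cy <- round(y)
  if (cx - half < 0 || cy - half < 0 ||
      cx + half > nrow(image) - 1 || cy + half > ncol(image) - 1)
    stop("window extends beyond the image")
  ix <- (cx - half):(cx + half)
  iy <- (cy - half):(cy + half)
  sub <- image[ix + 1, iy + 1]
  if (any(!is.finite(sub))) stop("non-finite pixel values in window")

  flat_fit <- list(x = x, y = y, sigma_fit = psf_sigma, brightness = 0,
                   amplitude = 0, background = mean(sub), ok = FALSE,
                   loglik = NA_real_)
  if (max(sub) - min(sub) < .Machine$double.eps) {
    flat_fit$ok <- FALSE
    class(flat_fit) <- "spot_fit"
    return(flat_fit)
  }

  bg0 <- max(stats::median(sub), 0.1)
  A0 <- max(sum(sub - bg0), 1)
  nll <- function(par) {
    mu <- par[5] + par[4] * .psf_weights(ix, iy, par[1], par[2], par[3])
    if (any(mu <= 0)) return(1e12)
    sum(mu - sub * log(mu))
  }
  opt <- tryCatch(
    stats::optim(c(x, y, psf_sigma, A0, bg0), nll, method = "L-BFGS-B",
                 lower = c(cx - half, cy - half, 0.3, 0, 1e-6),
                 upper = c(cx + half, cy + half, half, Inf, Inf),
                 control = list(maxit = 1000, factr = 10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    class(flat_fit) <- "spot_fit"
    return(flat_fit)
  }
  p <- opt$par
  structure(list(x = p[1], y = p[2], sigma_fit = p[3], brightness = p[4],
                 amplitude = p[4] / (2 * pi * p[3]^2), background = p[5],
                 ok = opt$convergence == 0, loglik = -opt$value),
            class = "spot_fit")
}

#' Detect and measure immobile particles in a movie
#'
#' Particles are assumed immobile: positions are detected and MLE-fitted once
#' on the average of the first `n_avg` frames, then the brightness is refit
#' per frame at the fixed position and PSF width by linear least squares on
#' (brightness, background). The result is one brightness trace per particle
#' plus a spot table.
#'
#' @param stack A `frame_stack` (array x, y, frame).
#' @param params A [detection_params()].
#' @param psf_sigma Initial PSF sigma for the MLE fit.
#' @param n_avg Frames averaged for detection/localization (default 5).
#' @return List with `spots` (data frame: particle_id, x, y, sigma_fit,
#'   brightness, background) and `traces` (a `trace_set` of per-frame fitted
#'   brightness).
#' @export
measure_movie <- function(stack, params, psf_sigma = 1.2, n_avg = 5) {
  nf <- dim(stack)[3]
  n_avg <- min(n_avg, nf)
  avg <- apply(stack[, , seq_len(n_avg), drop = FALSE], c(1, 2), mean)
  cand <- detect_spots(avg, params)
  fits <- list()
  for (i in seq_len(nrow(cand))) {
    f <- fit_spot_mle(avg, cand$x[i], cand$y[i],
                      window = params$fit_window_px, psf_sigma = psf_sigma)
    if (f$ok) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits))
    return(list(spots = data.frame(), traces = structure(list(),
                                                         class = "trace_set")))
  spots <- data.frame(particle_id = seq_along(fits),
                      x = vapply(fits, `[[`, 0, "x"),
                      y = vapply(fits, `[[`, 0, "y"),
                      sigma_fit = vapply(fits, `[[`, 0, "sigma_fit"),
                      brightness = vapply(fits, `[[`, 0, "brightness"),
                      background = vapply(fits, `[[`, 0, "background"))

  half <- params$fit_window_px %/% 2
  interval <- attr(stack, "frame_interval_s")
  if (is.null(interval)) interval <- 0.091
  traces <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    cx <- round(spots$x[i]); cy <- round(spots$y[i])
    ix <- (cx - half):(cx + half)
    iy <- (cy - half):(cy + half)
    g <- as.numeric(.psf_weights(ix, iy, spots$x[i], spots$y[i],
                                 spots$sigma_fit[i]))
    # per frame solve min ||I - b - A g||^2 in (A, b)
    gc <- g - mean(g)
    denom <- sum(gc^2)
    vals <- numeric(nf)
    for (t in seq_len(nf)) {
      I <- as.numeric(stack[ix + 1, iy + 1, t])
      vals[t] <- sum(gc * I) / denom
    }
    traces[[i]] <- structure(vals, class = "intensity_trace",
                             particle_id = spots$particle_id[i],
                             frame_interval_s = interval)
  }
  list(spots = spots, traces = structure(traces, class = "trace_set"))
}

#' Pre-bleach brightness of each particle
#'
#' The per-particle brightness used for histogram fitting: the mean fitted
#' brightness over the frames before the first detected bleaching event
#' (the first plateau of the filtered trace).
#'
#' @param traces A `trace_set` of per-frame brightness values.
#' @param params A [ck_params()].
#' @param monomer_step_counts Optional absolute step threshold (counts);
#'   when missing a noise-derived threshold is used.
#' @return Numeric vector, one value per trace.
#' @export
initial_brightness <- function(traces, params = ck_params(),
                               monomer_step_counts = NULL) {
  vapply(traces, function(tr) {
    x <- as.numeric(tr)
    # traces shorter than the filter support: no bleaching segmentation
    if (length(x) <= 2 * params$window_frames + 1) return(mean(x))
    filt <- ck_filter(x, params)
    if (is.null(monomer_step_counts)) {
      noise_sd <- stats::mad(diff(x)) / sqrt(2)
      thr_abs <- 4 * noise_sd / sqrt(params$window_frames)
      if (thr_abs <= 0) thr_abs <- .Machine$double.eps
    } else {
      thr_abs <- params$min_step_fraction * monomer_step_counts
    }
    m <- max(filt)
    if (m <= 0) return(mean(x))
    seg <- .segment_steps(filt / m, thr_abs / m, x / m)
    seg$levels[1] * m
  }, numeric(1))
}
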