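#' Parameters of the Chung-Kennedy filter and step census
#'
#' @param window_frames Predictor window K in frames (default 4; typical
#'   values 3-4).
#' @param weight_exponent Exponent applied to each predictor's inverse
#'   mean-squared prediction error when forming the convex weights. Large
#'   values give sharp switching between the forward and backward predictors
#'   at an edge; 10 is a standard choice.
#' @param min_step_fraction Smallest accepted level drop, as a fraction of
#'   the (normalized) monomer step. Default 0.5 splits the ambiguity between
#'   "one step" and "no step" symmetrically.
#' @return Object of class `ck_params`.
#' @export
ck_params <- function(window_frames = 4, weight_exponent = 10,
                      min_step_fraction = 0.5) {
  stopifnot(window_frames >= 2, weight_exponent > 0,
            min_step_fraction > 0, min_step_fraction < 1)
  structure(list(window_frames = as.integer(window_frames),
                 weight_exponent = weight_exponent,
                 min_step_fraction = min_step_fraction),
            class = "ck_params")
}

#' Forward-backward Chung-Kennedy nonlinear filter
#'
#' Edge-preserving smoother for piecewise-constant signals. The output at
#' frame t is a convex combination of a forward predictor (mean of the K
#' preceding frames) and a backward predictor (mean of the K following
#' frames), weighted by the inverse of each predictor's locally averaged
#' squared prediction error raised to `weight_exponent`. Away from a step
#' both predictors agree and the filter behaves like a running mean; at a
#' step the predictor that straddles the edge has a large prediction error
#' and is switched off, so edges are not smeared. At the trace ends only the
#' available one-sided predictor is used.
#'
#' @param trace Numeric vector (an `intensity_trace` or plain numeric).
#' @param params A [ck_params()].
#' @return Numeric vector of the same length.
#' @export
ck_filter <- function(trace, params = ck_params()) {
  x <- as.numeric(trace)
  n <- length(x)
  K <- params$window_frames
  if (n <= 2 * K) stop("trace too short for the chosen window")
  if (any(!is.finite(x))) stop("trace contains non-finite values")

  csum <- cumsum(c(0, x))
  idx <- seq_len(n)
  # forward predictor: mean of up to K preceding frames
  lo_f <- pmax(idx - K, 1)
  nf <- idx - lo_f
  f <- ifelse(nf > 0, (csum[idx] - csum[lo_f]) / pmax(nf, 1), NA_real_)
  # backward predictor: mean of up to K following frames
  hi_b <- pmin(idx + K, n)
  nb <- hi_b - idx
  b <- ifelse(nb > 0, (csum[hi_b + 1] - csum[idx + 1]) / pmax(nb, 1), NA_real_)

  ef <- (x - f)^2
  eb <- (x - b)^2
  # average the squared prediction errors over a K-frame one-sided window
  run_mean_back <- function(e) {
    e[is.na(e)] <- 0
    cs <- cumsum(c(0, e))
    lo <- pmax(idx - K + 1, 1)
    (cs[idx + 1] - cs[lo]) / (idx - lo + 1)
  }
  run_mean_fwd <- function(e) {
    e[is.na(e)] <- 0
    cs <- cumsum(c(0, e))
    hi <- pmin(idx + K - 1, n)
    (cs[hi + 1] - cs[idx]) / (hi - idx + 1)
  }
  Ef <- run_mean_back(ef)
  Eb <- run_mean_fwd(eb)

  p <- params$weight_exponent
  eps <- .Machine$double.xmin^(1 / (2 * p))
  wf <- (Ef + eps)^(-p)
  wb <- (Eb + eps)^(-p)
  wf[is.na(f)] <- 0
  wb[is.na(b)] <- 0
  # guard: both predictors exact (constant signal) -> equal weights
  tot <- wf + wb
  bad <- !is.finite(tot) | tot == 0
  if (any(bad)) {
    wf[bad] <- ifelse(is.na(f[bad]), 0, 1)
    wb[bad] <- ifelse(is.na(b[bad]), 0, 1)
    tot <- wf + wb
  }
  f[is.na(f)] <- 0
  b[is.na(b)] <- 0
  out <- (wf * f + wb * b) / tot
  attributes(out) <- attributes(trace)
  out
}

# Segment a (filtered) trace into plateaus separated by level changes of at
# least `thr`. A change must be sustained: candidate edges are scored on
# two-frame means on either side. Candidate positions are refined and
# plateau levels re-estimated on `raw` (the unfiltered trace when
# available), because the filter smears plateaus shorter than its window;
# edges whose raw level change falls below threshold are dropped.
# Returns list(change_points, levels): change_points are 1-based indices of
# the last frame of the preceding plateau.
.segment_steps <- function(y, thr, raw = y) {
  n <- length(y)
  if (n < 4) return(list(change_points = integer(0), levels = mean(raw)))
  t <- 2:(n - 2)
  d <- (y[t + 1] + y[t + 2]) / 2 - (y[t - 1] + y[t]) / 2
  # candidate stage uses a lower bar (hysteresis): the short-window score is
  # noisier than the plateau-level differences that decide acceptance, so
  # marginal steps would otherwise be lost before they can be confirmed
  cand <- which(abs(d) >= 0.5 * thr)
  cps <- integer(0)
  if (length(cand)) {
    runs <- split(cand, cumsum(c(1, diff(cand) > 2)))
    for (r in runs) {
      # strongest scores within the run, at least 2 frames apart
      dr <- abs(d[r])
      ord <- r[order(dr, decreasing = TRUE)]
      keep <- integer(0)
      for (j in ord)
        if (!length(keep) || min(abs(keep - j)) >= 2) keep <- c(keep, j)
      cps <- c(cps, sort(keep))
    }
  }
  cps <- sort(unique(cps + 1L))  # change point = last frame of old plateau

  # refine each change point on the raw trace (+- 3 frames), constrained so
  # neighbouring change points cannot collapse onto the same edge
  if (length(cps)) {
    score <- function(t0) {
      if (t0 < 2 || t0 > n - 2) return(0)
      abs(mean(raw[(t0 + 1):(t0 + 2)]) - mean(raw[(t0 - 1):t0]))
    }
    orig <- cps
    for (k in seq_along(cps)) {
      lo <- max(2L, orig[k] - 3L,
                if (k > 1) cps[k - 1] + 2L else -Inf)
      hi <- min(n - 2L, orig[k] + 3L,
                if (k < length(cps)) orig[k + 1] - 2L else Inf)
      if (lo > hi) next
      cands <- lo:hi
      cps[k] <- cands[which.max(vapply(cands, score, numeric(1)))]
    }
    cps <- sort(unique(cps))
    cps <- cps[c(TRUE, diff(cps) >= 2)]
  }

  repeat {
    bounds <- c(0L, cps, n)
    levels <- numeric(length(bounds) - 1)
    for (k in seq_along(levels)) {
      a <- bounds[k] + 1L
      bnd <- bounds[k + 1]
      # trim one frame at interior boundaries of long plateaus
      if (bnd - a + 1 > 2) {
        if (k > 1) a <- a + 1L
        if (k < length(levels)) bnd <- bnd - 1L
      }
      levels[k] <- mean(raw[a:bnd])
    }
    if (length(cps) == 0) break
    dl <- abs(diff(levels))
    if (all(dl >= thr)) {
      # prune transient excursions: a short plateau reached and left by
      # opposite-signed changes, with agreeing flanking levels, is a noise
      # spike, not bleaching (intensity never recovers)
      seg_len <- diff(c(0L, cps, n))
      dlev <- diff(levels)
      drop2 <- NA_integer_
      for (k in seq_along(levels)) {
        if (k > 1 && k < length(levels) && seg_len[k] <= 12 &&
            sign(dlev[k - 1]) != sign(dlev[k]) &&
            abs(levels[k + 1] - levels[k - 1]) < thr) {
          drop2 <- k
          break
        }
      }
      if (is.na(drop2)) break
      cps <- cps[-c(drop2 - 1L, drop2)]
      next
    }
    cps <- cps[-which.min(dl)]
  }

  # split pass: a level change much larger than the step threshold may be
  # two bleaching events a few frames apart whose intermediate plateau the
  # filter smeared away; refit such edges with two change points on the raw
  # trace and keep the split when it lowers the squared error and both
  # sub-steps clear the threshold
  if (length(cps)) {
    # acceptance penalty for the split pass: the best constrained 2-edge
    # refit of a pure-noise window rarely beats the 1-edge fit by more than
    # ~8 noise variances, while a real merged double (>= 2-frame gap) does
    sig2 <- (stats::mad(diff(raw)) / sqrt(2))^2
    penalty <- 8 * sig2
    repeat {
      improved <- FALSE
      bounds <- c(0L, cps, n)
      for (k in seq_along(cps)) {
        a <- bounds[k] + 1L
        b2 <- bounds[k + 2]
        cp <- cps[k]
        dlev <- mean(raw[(cp + 1L):b2]) - mean(raw[a:cp])
        if (abs(dlev) < 2.5 * thr) next
        seg_sse <- function(parts) {
          s <- 0
          for (pr in parts) s <- s + sum((raw[pr] - mean(raw[pr]))^2)
          s
        }
        sse1 <- seg_sse(list(a:cp, (cp + 1L):b2))
        best <- NULL
        for (p1 in max(a, cp - 6L):min(b2 - 2L, cp + 6L)) {
          for (p2 in (p1 + 1L):min(p1 + 8L, b2 - 1L)) {
            l1 <- mean(raw[a:p1])
            lm <- mean(raw[(p1 + 1L):p2])
            l2 <- mean(raw[(p2 + 1L):b2])
            d1 <- lm - l1; d2 <- l2 - lm
            if (sign(d1) != sign(dlev) || sign(d2) != sign(dlev)) next
            if (abs(d1) < thr || abs(d2) < thr) next
            sse2 <- seg_sse(list(a:p1, (p1 + 1L):p2, (p2 + 1L):b2))
            if (sse1 - sse2 > penalty && (is.null(best) || sse2 < best$sse))
              best <- list(p1 = p1, p2 = p2, sse = sse2)
          }
        }
        if (!is.null(best)) {
          cps <- sort(unique(c(cps[-k], best$p1, best$p2)))
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    # final level re-estimation
    bounds <- c(0L, cps, n)
    levels <- numeric(length(bounds) - 1)
    for (k in seq_along(levels)) {
      a <- bounds[k] + 1L
      bnd <- bounds[k + 1]
      if (bnd - a + 1 > 2) {
        if (k > 1) a <- a + 1L
        if (k < length(levels)) bnd <- bnd - 1L
      }
      levels[k] <- mean(raw[a:bnd])
    }
  }
  list(change_points = cps, levels = levels)
}

#' Count photobleaching steps in a filtered trace
#'
#' The trace is normalized by its maximum; change points are frames where
#' the filtered level drops by at least
#' `min_step_fraction * monomer_step` sustained for at least two frames.
#' Downward changes are counted as bleaching steps; upward changes (rare
#' noise artefacts) are recorded but excluded from the count.
#'
#' @param filtered A filtered trace (see [ck_filter()]); counting on the raw
#'   trace works but is noise-sensitive.
#' @param monomer_step Expected single-fluorophore drop on the same
#'   normalization (i.e. in units of the trace maximum).
#' @param params A [ck_params()].
#' @param raw Optional raw (unfiltered) trace; when given, change-point
#'   positions are refined and plateau levels estimated on it, which
#'   resolves steps separated by less than the filter window.
#' @return Object of class `step_result`: `filtered` (normalized),
#'   `change_points` (0-based frame indices), `n_steps`, `step_sizes`
#'   (positive drops, normalized units), `n_up`, `levels`.
#' @export
count_steps <- function(filtered, monomer_step, params = ck_params(),
                        raw = NULL) {
  if (monomer_step <= 0) stop("monomer_step must be positive")
  y <- as.numeric(filtered)
  m <- max(y)
  if (m <= 0) stop("all-zero trace")
  y <- y / m
  thr <- params$min_step_fraction * monomer_step
  yr <- if (is.null(raw)) y else as.numeric(raw) / m
  seg <- .segment_steps(y, thr, yr)
  dl <- diff(seg$levels)
  down <- dl < 0
  structure(list(filtered = y,
                 change_points = seg$change_points - 1L,
                 n_steps = sum(down),
                 step_sizes = -dl[down],
                 n_up = sum(!down & abs(dl) > 0),
                 levels = seg$levels,
                 # fully bleached: the trace ends below half a monomer unit
                 complete = seg$levels[length(seg$levels)] < thr,
                 max_value = m,
                 particle_id = attr(filtered, "particle_id")),
            class = "step_result")
}

#' @export
print.step_result <- function(x, ...) {
  cat(sprintf("Step census: %d downward step(s)", x$n_steps))
  if (x$n_up > 0) cat(sprintf(" (+%d upward change(s))", x$n_up))
  cat("\n")
  if (x$n_steps > 0)
    cat("  sizes (normalized):", paste(sprintf("%.3f", x$step_sizes),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Filter and count steps for a whole trace set
#'
#' @param traces A `trace_set` or list of numeric traces.
#' @param monomer_step_counts Expected single-fluorophore step in raw counts;
#'   converted per trace to the max-normalized scale.
#' @param params A [ck_params()].
#' @return List of `step_result` objects (class `step_result_set`).
#' @export
count_steps_traces <- function(traces, monomer_step_counts,
                               params = ck_params()) {
  res <- lapply(traces, function(tr) {
    filt <- ck_filter(tr, params)
    count_steps(filt, monomer_step_counts / max(as.numeric(filt)), params,
                raw = tr)
  })
  structure(res, class = "step_result_set")
}

#' Mean and s.d. of step sizes grouped by particle step count
#'
#' Checks that the per-fluorophore step size does not depend on the
#' oligomeric species: groups all step sizes by the particle's total step
#' count (1..6) and reports mean and s.d. per group.
#'
#' @param results List of `step_result` objects.
#' @param units `"counts"` (default) rescales each trace's normalized step
#'   sizes by its maximum so sizes are comparable across species;
#'   `"normalized"` keeps the per-trace max-normalized units.
#' @return Data frame with columns `n_steps`, `n_particles`, `n_sizes`,
#'   `mean_size`, `sd_size`. Empty groups are omitted.
#' @export
stepsize_table <- function(results, units = c("counts", "normalized")) {
  units <- match.arg(units)
  counts <- vapply(results, function(r) r$n_steps, numeric(1))
  sizes_of <- function(r) {
    s <- r$step_sizes
    if (units == "counts" && !is.null(r$max_value)) s <- s * r$max_value
    s
  }
  rows <- lapply(sort(unique(counts[counts >= 1 & counts <= 6])), function(k) {
    sizes <- unlist(lapply(results[counts == k], sizes_of))
    data.frame(n_steps = k, n_particles = sum(counts == k),
               n_sizes = length(sizes), mean_size = mean(sizes),
               sd_size = stats::sd(sizes))
  })
  do.call(rbind, rows)
}

# Level of the last non-zero plateau before complete bleaching, in raw
# counts; NULL when bleaching is incomplete or the plateau is too short.
# Threshold: supplied monomer step (counts) when available, otherwise a
# noise-derived floor (4 x filtered noise sd estimated from first
# differences).
last_level <- function(trace, params = ck_params(), min_plateau_frames = 4,
                       monomer_step_counts = NULL) {
  x <- as.numeric(trace)
  filt <- ck_filter(x, params)
  if (is.null(monomer_step_counts)) {
    noise_sd <- stats::mad(diff(x)) / sqrt(2)
    thr_abs <- 4 * noise_sd / sqrt(params$window_frames)
    if (thr_abs <= 0) thr_abs <- .Machine$double.eps
  } else {
    thr_abs <- params$min_step_fraction * monomer_step_counts
  }
  m <- max(filt)
  if (m <= 0) return(NULL)
  seg <- .segment_steps(filt / m, thr_abs / m, x / m)
  k <- length(seg$levels)
  if (k < 2) return(NULL)
  final <- seg$levels[k] * m
  lastp <- seg$levels[k - 1] * m
  # final plateau must be consistent with full bleaching (near zero)
  if (final > 0.5 * lastp) return(NULL)
  cps <- seg$change_points
  plateau_len <- cps[length(cps)] - if (k >= 3) cps[length(cps) - 1] else 0L
  if (plateau_len < min_plateau_frames) return(NULL)
  lastp - final
}
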