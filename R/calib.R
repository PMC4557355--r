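#' Calibrate single-fluorophore brightness from single-step particles
#'
#' Particles whose trace shows exactly one photobleaching step carry a single
#' fluorophore; the Gaussian fitted to their brightness histogram gives the
#' monomer brightness mean `mu1` and s.d. `sigma1` that anchor every N-mer
#' component downstream (mean `N*mu1`, s.d. `sqrt(N)*sigma1`). A maximum
#' resolvable size `n_max` is derived from the separation-over-width rule
#' (see [max_resolvable()]).
#'
#' The Gaussian is fitted to the histogram by least squares; when the fit is
#' degenerate (too few bins, zero spread) the sample mean and s.d. are used
#' instead and the calibration is flagged.
#'
#' @param brightnesses Positive brightness values of single-step particles.
#' @param min_n Minimum number of values required (default 30).
#' @param resolvability_c Separation factor for [max_resolvable()].
#' @param n_cap Hard cap on n_max (default 6).
#' @return Object of class `monomer_calibration`: `mu1`, `sigma1`, `n_used`,
#'   `n_max`, `resolvability_c`, `degenerate` flag.
#' @examples
#' set.seed(1)
#' calibrate_monomer(rnorm(500, 1000, 250))
#' @export
calibrate_monomer <- function(brightnesses, min_n = 30, resolvability_c = 2,
                              n_cap = 6) {
  b <- as.numeric(brightnesses)
  if (length(b) < min_n)
    stop(sprintf("need at least %d single-step particles, got %d",
                 min_n, length(b)))
  if (any(!is.finite(b)) || any(b <= 0))
    stop("brightness values must be positive and finite")

  degenerate <- FALSE
  if (stats::sd(b) < .Machine$double.eps^0.5 * mean(b)) {
    mu1 <- mean(b); sigma1 <- stats::sd(b)
    degenerate <- TRUE
  } else {
    # least-squares Gaussian fit to the histogram (Sturges-free rule:
    # bin width ~ sd/3 keeps the peak well sampled)
    bw <- stats::sd(b) / 3
    breaks <- seq(min(b) - bw, max(b) + bw, by = bw)
    h <- graphics::hist(b, breaks = breaks, plot = FALSE)
    fit <- tryCatch(
      stats::nls(counts ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
                 data = data.frame(counts = h$counts, mids = h$mids),
                 start = list(a = max(h$counts), mu = mean(b),
                              s = stats::sd(b))),
      error = function(e) NULL)
    if (is.null(fit)) {
      mu1 <- mean(b); sigma1 <- stats::sd(b)
      degenerate <- TRUE
    } else {
      cf <- stats::coef(fit)
      mu1 <- unname(cf["mu"]); sigma1 <- abs(unname(cf["s"]))
    }
  }
  if (sigma1 <= 0) {
    sigma1 <- max(stats::sd(b), .Machine$double.eps)
    degenerate <- TRUE
  }
  structure(list(mu1 = mu1, sigma1 = sigma1, n_used = length(b),
                 n_max = max_resolvable(mu1, sigma1, resolvability_c, n_cap),
                 resolvability_c = resolvability_c, degenerate = degenerate),
            class = "monomer_calibration")
}

#' Manually specify a monomer calibration
#' @param mu1,sigma1 Monomer brightness mean and s.d. (counts).
#' @inheritParams calibrate_monomer
#' @export
monomer_calibration <- function(mu1, sigma1, resolvability_c = 2, n_cap = 6) {
  stopifnot(mu1 > 0, sigma1 > 0)
  structure(list(mu1 = mu1, sigma1 = sigma1, n_used = NA_integer_,
                 n_max = max_resolvable(mu1, sigma1, resolvability_c, n_cap),
                 resolvability_c = resolvability_c, degenerate = FALSE),
            class = "monomer_calibration")
}

#' Expected brightness parameters of an N-mer
#'
#' N co-localized independent fluorophores have summed brightness with mean
#' `N * mu1` and s.d. `sqrt(N) * sigma1`.
#'
#' @param calib A `monomer_calibration`.
#' @param N Oligomer size (>= 1), possibly a vector.
#' @return Matrix with columns `mu_N`, `sigma_N`, one row per N.
#' @export
nmer_params <- function(calib, N) {
  if (any(N < 1)) stop("N must be >= 1")
  cbind(mu_N = N * calib$mu1, sigma_N = sqrt(N) * calib$sigma1)
}

#' Maximum resolvable stoichiometry
#'
#' Adjacent mixture components are separated by `mu1` while the N-th
#' component has width `sqrt(N) * sigma1`; components are considered
#' resolvable while the separation exceeds `c` times that width, i.e. up to
#' `N = floor((mu1 / (c * sigma1))^2)`, capped at `n_cap` (brighter species
#' cannot be assigned a stoichiometry and are excluded from fits).
#'
#' @param mu1,sigma1 Monomer calibration values, or a `monomer_calibration`
#'   as the first argument.
#' @param resolvability_c Separation factor (default 2).
#' @param n_cap Hard cap (default 6).
#' @return Integer n_max in 1..n_cap.
#' @export
max_resolvable <- function(mu1, sigma1 = NULL, resolvability_c = 2, n_cap = 6) {
  if (inherits(mu1, "monomer_calibration")) {
    sigma1 <- mu1$sigma1
    mu1 <- mu1$mu1
  }
  stopifnot(resolvability_c > 0, mu1 > 0, sigma1 >= 0)
  if (sigma1 == 0) return(as.integer(n_cap))
  n <- floor((mu1 / (resolvability_c * sigma1))^2)
  as.integer(min(n_cap, max(1, n)))
}

#' @export
print.monomer_calibration <- function(x, ...) {
  cat("Monomer brightness calibration\n")
  cat(sprintf("  mu1 = %.4g counts, sigma1 = %.4g counts (n = %s)\n",
              x$mu1, x$sigma1, format(x$n_used)))
  cat(sprintf("  max resolvable stoichiometry n_max = %d (c = %.2g)\n",
              x$n_max, x$resolvability_c))
  if (x$degenerate) cat("  note: histogram fit degenerate; sample moments used\n")
  invisible(x)
}

#' Monomer brightness reference from photobleaching traces
#'
#' Selects, for every particle, the brightness immediately before complete
#' bleaching — the level of the last non-zero plateau of the filtered trace —
#' which with overwhelming probability reflects a single remaining
#' fluorophore. Used as the empirical monomer reference of the p.d.f. method.
#'
#' @param traces A `trace_set` (or list of numeric traces).
#' @param params [ck_params()] used for filtering and plateau segmentation.
#' @param min_plateau_frames Minimum length of the final plateau for a trace
#'   to contribute (short plateaus give noisy level estimates).
#' @param monomer_step_counts Optional rough monomer step (counts) used as
#'   the segmentation threshold; a noise-derived threshold is used otherwise.
#' @param trim Discard values above `trim` times the median (one pass);
#'   removes last plateaus that still carried two fluorophores because their
#'   bleaching events merged. Default 1.75 (about mean + 3 s.d. for typical
#'   brightness spreads); set to `Inf` to disable.
#' @return Numeric vector of last-plateau brightness values (counts).
#' @export
monomer_reference_from_traces <- function(traces, params = ck_params(),
                                          min_plateau_frames = 4,
                                          monomer_step_counts = NULL,
                                          trim = 1.75) {
  vals <- vapply(traces, function(tr) {
    lv <- last_level(as.numeric(tr), params, min_plateau_frames,
                     monomer_step_counts)
    if (is.null(lv)) NA_real_ else lv
  }, numeric(1))
  vals <- vals[is.finite(vals) & vals > 0]
  if (is.finite(trim) && length(vals)) {
    vals <- vals[vals <= trim * stats::median(vals)]
    vals <- vals[vals <= trim * stats::median(vals)]
  }
  vals
}
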