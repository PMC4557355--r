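#' Estimate the labelled-subunit distribution from single-particle data
#'
#' Front door to the three estimators of the observed labelled-count
#' distribution L_m:
#' \describe{
#'   \item{`"gaussian"`}{constrained Gaussian-mixture fit of the brightness
#'     histogram — component n pinned at mean `n * mu1`, s.d.
#'     `sqrt(n) * sigma1` from the calibration, only the nonnegative areas
#'     free ([fit_gaussian_mixture()]);}
#'   \item{`"pdf"`}{fit of the empirical brightness p.d.f. by a nonnegative
#'     combination of N-mer p.d.f.s obtained by self-convolution of an
#'     empirical monomer reference ([fit_pdf_mixture()]);}
#'   \item{`"steps"`}{direct census of photobleaching step counts
#'     ([census_from_steps()]).}
#' }
#' All three return a `stoich_fit` object whose `coef()` are the fractions
#' L_m (m = 1..n_max); apply [correct_labelling()] to convert these to true
#' oligomer fractions S_N.
#'
#' @param x Brightness values (methods `"gaussian"`, `"pdf"`) or a list of
#'   `step_result` objects (method `"steps"`).
#' @param calib A `monomer_calibration` (required for `"gaussian"`, used for
#'   grid scales in `"pdf"` when given).
#' @param method One of `"gaussian"`, `"pdf"`, `"steps"`.
#' @param ... Passed on to the specific estimator.
#' @return Object of class `stoich_fit`.
#' @export
stoich_fit <- function(x, calib = NULL,
                       method = c("gaussian", "pdf", "steps"), ...) {
  method <- match.arg(method)
  switch(method,
         gaussian = fit_gaussian_mixture(x, calib, ...),
         pdf = fit_pdf_mixture(x, calib = calib, ...),
         steps = census_from_steps(x, ...))
}

new_stoich_fit <- function(fractions, method, n, n_max, excluded = 0L,
                           ...) {
  stopifnot(all(fractions >= -1e-12), abs(sum(fractions) - 1) < 1e-9)
  structure(c(list(fractions = stats::setNames(pmax(fractions, 0),
                                               paste0("L", seq_len(n_max))),
                   method = method, n = n, n_max = n_max,
                   excluded = excluded),
              list(...)),
            class = "stoich_fit")
}

#' Constrained Gaussian-mixture fit of a brightness histogram
#'
#' Fits the histogram of per-particle brightness with
#' `sum_n A_n * Normal(n * mu1, sqrt(n) * sigma1)`, n = 1..n_max, where the
#' component means and widths are pinned to the monomer calibration and only
#' the areas `A_n >= 0` are free. With fixed component shapes this is a
#' linear nonnegative least-squares problem (no mixture degeneracy). The
#' normalized areas estimate the observed labelled-count fractions L_m.
#' Particles brighter than `(n_max + 0.5) * mu1` cannot be assigned a
#' stoichiometry; they are excluded from the fit and reported in `excluded`.
#'
#' @param values Positive per-particle brightness values (counts).
#' @param calib A `monomer_calibration`.
#' @param n_max Number of components (default 6, the resolvability cap).
#' @param bin_width Histogram bin width; default `sigma1 / 3`.
#' @param min_n Minimum sample size (default 100).
#' @return A `stoich_fit` with extra fields `areas`, `residual`, `bin_width`,
#'   `breaks`, `density`, `mids` and the calibration snapshot `calib`.
#' @export
fit_gaussian_mixture <- function(values, calib, n_max = 6,
                                 bin_width = calib$sigma1 / 3, min_n = 100) {
  if (is.null(calib) || !inherits(calib, "monomer_calibration"))
    stop("a monomer_calibration is required")
  v <- as.numeric(values)
  v <- v[is.finite(v) & v > 0]
  if (length(v) < min_n)
    stop(sprintf("need at least %d brightness values, got %d", min_n,
                 length(v)))
  cutoff <- (n_max + 0.5) * calib$mu1
  excluded <- sum(v > cutoff)
  v <- v[v <= cutoff]
  if (length(v) < min_n) stop("too few values below the brightness cutoff")

  breaks <- seq(0, cutoff + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  dens <- h$counts / (length(v) * bin_width)

  np <- nmer_params(calib, seq_len(n_max))
  # expected density of component n in each bin (bin-integrated, not
  # midpoint-evaluated, so narrow components are handled exactly)
  M <- vapply(seq_len(n_max), function(n) {
    (stats::pnorm(breaks[-1], np[n, 1], np[n, 2]) -
       stats::pnorm(breaks[-length(breaks)], np[n, 1], np[n, 2])) / bin_width
  }, numeric(length(dens)))

  fit <- pracma::lsqnonneg(M, dens)
  A <- fit$x
  if (sum(A) <= 0) stop("degenerate histogram: all component areas zero")
  new_stoich_fit(A / sum(A), method = "gaussian", n = length(v),
                 n_max = n_max, excluded = excluded,
                 areas = A, residual = sum((dens - M %*% A)^2),
                 bin_width = bin_width, breaks = breaks, density = dens,
                 mids = h$mids, calib = calib)
}

#' Empirical probability density on a uniform grid
#'
#' Gaussian-kernel density estimate, renormalized so its trapezoidal
#' integral is exactly 1.
#'
#' @param values Sample values.
#' @param kernel_sd Kernel s.d. (the smoothing bandwidth).
#' @param grid_max Upper end of the support (lower end is 0).
#' @param spacing Grid spacing.
#' @return Object of class `empirical_pdf`: list with `grid` and `density`.
#' @export
empirical_pdf <- function(values, kernel_sd, grid_max, spacing) {
  stopifnot(kernel_sd > 0, spacing > 0, grid_max > spacing)
  n_grid <- floor(grid_max / spacing) + 1
  d <- stats::density(values, bw = kernel_sd, kernel = "gaussian",
                      from = 0, to = (n_grid - 1) * spacing, n = n_grid)
  dens <- pmax(d$y, 0)
  dens <- dens / .trapz(d$x, dens)
  structure(list(grid = d$x, density = dens), class = "empirical_pdf")
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Brightness p.d.f. of an N-mer by self-convolution
#'
#' The brightness of N independent co-localized fluorophores is the N-fold
#' sum of single-fluorophore brightnesses, so its p.d.f. is the (N-1)-fold
#' self-convolution of the monomer p.d.f. Computed by discrete linear
#' convolution on the (uniform) grid, truncated to the original support and
#' renormalized to integrate to 1.
#'
#' @param monomer_pdf An `empirical_pdf` on a uniform grid starting at 0.
#' @param N Oligomer size (>= 1).
#' @return An `empirical_pdf` on the same grid.
#' @export
build_nmer_pdf <- function(monomer_pdf, N) {
  stopifnot(inherits(monomer_pdf, "empirical_pdf"), N >= 1)
  g <- monomer_pdf$grid
  dg <- diff(g)
  if (max(abs(dg - dg[1])) > 1e-9 * dg[1]) stop("grid must be uniform")
  if (abs(g[1]) > 1e-9) stop("grid must start at 0")
  h <- dg[1]
  p <- monomer_pdf$density
  out <- p
  if (N > 1) {
    for (k in seq_len(N - 1)) {
      full <- .conv_open(out, p) * h
      out <- full[seq_along(g)]  # support starts at 0 for both factors
    }
  }
  s <- .trapz(g, out)
  if (s <= 0) stop("convolution lost all mass on the grid; extend grid_max")
  structure(list(grid = g, density = out / s), class = "empirical_pdf")
}

# open (full) linear convolution via FFT
.conv_open <- function(a, b) {
  n <- length(a) + length(b) - 1
  nf <- stats::nextn(n, 2)
  re <- Re(stats::fft(stats::fft(c(a, numeric(nf - length(a)))) *
                        stats::fft(c(b, numeric(nf - length(b)))),
                      inverse = TRUE)) / nf
  pmax(re[seq_len(n)], 0)
}

#' Fit a brightness p.d.f. by a combination of N-mer p.d.f.s
#'
#' Model-free counterpart of [fit_gaussian_mixture()]: the monomer reference
#' sample (brightness immediately before complete bleaching, see
#' [monomer_reference_from_traces()]) is smoothed into an empirical p.d.f.;
#' higher N-mer p.d.f.s follow by self-convolution; the sample's empirical
#' p.d.f. is then fitted by nonnegative least squares on these components and
#' the weights normalized into fractions L_m.
#'
#' Grid scales follow the monomer reference: kernel width `sigma1 / 5`, grid
#' spacing `sigma1 / 20`, support `[0, (n_max + 2) * mu1]`, with `mu1`,
#' `sigma1` taken from `calib` when supplied and otherwise from the reference
#' sample's moments.
#'
#' @param values Per-particle brightness values of the full sample.
#' @param monomer_reference Brightness values of the monomer reference.
#' @param calib Optional `monomer_calibration` for the grid scales.
#' @param n_max Number of components (default 6).
#' @param min_n Minimum size of both samples (default 100).
#' @return A `stoich_fit` with extra fields `weights`, `components`
#'   (list of `empirical_pdf`), `sample_pdf`, `residual`.
#' @export
fit_pdf_mixture <- function(values, monomer_reference, calib = NULL,
                            n_max = 6, min_n = 100) {
  v <- as.numeric(values); v <- v[is.finite(v) & v > 0]
  r <- as.numeric(monomer_reference); r <- r[is.finite(r) & r > 0]
  if (length(v) < min_n || length(r) < min_n)
    stop(sprintf("need at least %d values in sample and reference", min_n))
  mu1 <- if (!is.null(calib)) calib$mu1 else mean(r)
  sigma1 <- if (!is.null(calib)) calib$sigma1 else stats::sd(r)
  if (sigma1 <= 0) stop("degenerate monomer reference")

  grid_max <- (n_max + 2) * mu1
  spacing <- sigma1 / 20
  excluded <- sum(v > (n_max + 0.5) * mu1)
  v <- v[v <= grid_max]

  mono <- empirical_pdf(r, kernel_sd = sigma1 / 5, grid_max = grid_max,
                        spacing = spacing)
  comps <- lapply(seq_len(n_max), function(N) build_nmer_pdf(mono, N))
  samp <- empirical_pdf(v, kernel_sd = sigma1 / 5, grid_max = grid_max,
                        spacing = spacing)

  M <- vapply(comps, function(cp) cp$density, numeric(length(samp$grid)))
  if (n_max == 1) {
    w <- 1
    resid <- sum((samp$density - M[, 1])^2)
  } else {
    fit <- pracma::lsqnonneg(M, samp$density)
    w <- fit$x
    resid <- fit$resid.norm
  }
  if (sum(w) <= 0) stop("degenerate p.d.f. fit: all weights zero")
  new_stoich_fit(w / sum(w), method = "pdf", n = length(v), n_max = n_max,
                 excluded = excluded, weights = w, components = comps,
                 sample_pdf = samp, monomer_pdf = mono, residual = resid)
}

#' Labelled-count fractions from a photobleaching step census
#'
#' `L_m` is the fraction of particles showing exactly m bleaching steps,
#' among particles with 1 to `n_max` steps. Zero-step particles (no event
#' detected) are excluded; particles with more than `n_max` steps are
#' reported in `excluded`.
#'
#' @param results List of `step_result` objects (or an integer vector of
#'   per-particle step counts).
#' @param n_max Largest countable stoichiometry (default 6).
#' @param complete_only Use only traces flagged as fully bleached (final
#'   level below half a monomer unit). An unbleached fluorophore hides one
#'   step, so incomplete traces systematically undercount; default TRUE.
#' @return A `stoich_fit` (method `"steps"`) with extra field `counts`.
#' @export
census_from_steps <- function(results, n_max = 6, complete_only = TRUE) {
  counts <- if (is.numeric(results)) as.integer(results)
            else vapply(results, function(r) as.integer(r$n_steps),
                        integer(1))
  if (!is.numeric(results) && complete_only) {
    ok <- vapply(results, function(r) !isFALSE(r$complete), logical(1))
    counts <- counts[ok]
  }
  if (!length(counts)) stop("no step results")
  usable <- counts[counts >= 1 & counts <= n_max]
  if (!length(usable)) stop("all traces have zero (or only >n_max) steps")
  tab <- tabulate(usable, nbins = n_max)
  new_stoich_fit(tab / sum(tab), method = "steps", n = length(usable),
                 n_max = n_max, excluded = sum(counts > n_max),
                 counts = tab)
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.stoich_fit <- function(object, ...) object$fractions

#' @export
print.stoich_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Labelled-subunit distribution (%s method, n = %d)\n",
              x$method, x$n))
  print(round(x$fractions, digits))
  if (x$excluded > 0)
    cat(sprintf("  %d particle(s) brighter than the n_max cutoff excluded\n",
                x$excluded))
  invisible(x)
}

#' @export
summary.stoich_fit <- function(object, p = NULL, ...) {
  cat(sprintf("Stoichiometry fit: method = %s, particles used = %d, ",
              object$method, object$n))
  cat(sprintf("excluded = %d\n", object$excluded))
  print(round(object$fractions, 3))
  if (!is.null(object$residual))
    cat(sprintf("residual sum of squares: %.4g\n", object$residual))
  if (!is.null(p)) {
    S <- correct_labelling(object$fractions, p)
    cat(sprintf("corrected for labelling p = %g:\n", p))
    print(round(unclass(S), 3))
  }
  invisible(object)
}

#' Plot a stoichiometry fit
#'
#' For the Gaussian method: brightness histogram (density scale) with the
#' fitted component curves and their sum. For the p.d.f. method: empirical
#' sample p.d.f. with the weighted N-mer components. For the step census: a
#' bar plot of the step-count fractions.
#'
#' @param x A `stoich_fit`.
#' @param ... Further arguments passed to the underlying plot call.
#' @export
plot.stoich_fit <- function(x, ...) {
  if (x$method == "gaussian") {
    graphics::plot(x$mids, x$density, type = "h", lwd = 3, col = "grey70",
                   xlab = "brightness (counts)", ylab = "density",
                   main = "Brightness mixture fit", ...)
    np <- nmer_params(x$calib, seq_len(x$n_max))
    xx <- seq(0, max(x$breaks), length.out = 400)
    tot <- numeric(length(xx))
    for (n in seq_len(x$n_max)) {
      yy <- x$areas[n] * stats::dnorm(xx, np[n, 1], np[n, 2])
      tot <- tot + yy
      graphics::lines(xx, yy, col = n + 1)
    }
    graphics::lines(xx, tot, lwd = 2)
  } else if (x$method == "pdf") {
    graphics::plot(x$sample_pdf$grid, x$sample_pdf$density, type = "l",
                   lwd = 2, xlab = "brightness (counts)", ylab = "density",
                   main = "p.d.f. mixture fit", ...)
    for (n in seq_len(x$n_max))
      graphics::lines(x$components[[n]]$grid,
                      x$weights[n] * x$components[[n]]$density, col = n + 1)
  } else {
    graphics::barplot(x$fractions, names.arg = seq_len(x$n_max),
                      xlab = "photobleaching steps", ylab = "fraction",
                      main = "Step-count census", ...)
  }
  invisible(x)
}
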