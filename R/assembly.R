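#' Configuration of the particle-based assembly simulation
#'
#' Defaults reproduce the published simulation geometry: a 7 x 7 x 7 um box
#' with 1,163 Bax molecules, twice as many cBid molecules and 1.25 x as many
#' LUVs (1,453), evolved for 10 minutes in 50 us steps. Soluble particles
#' diffuse freely; a LUV is a sphere of radius `luv_radius_um` (200 nm
#' extrusion pore size) that carries bound cBid and at most one resident Bax
#' complex. Soluble Bax binds a vesicle only when recruited by bound cBid or
#' by already-bound Bax (autoactivation); a bound monomer detaches at
#' `k_mono_off` unless dimerization stabilizes it; complexes shrink at
#' `k_shrink`, slowed by `even_stabilization` for even sizes, and grow on
#' each Bax arrival, with growth into an even size favoured by the same
#' factor. Second-order rates are converted to binding radii
#' ([binding_radius()]) and floored at the vesicle radius (geometric
#' contact).
#'
#' The kinetic rate defaults are demonstration values chosen to land in the
#' qualitative regime of the published model (its exact parameter table is
#' not public); all are explicit arguments.
#'
#' @param box_side_um Box side (um).
#' @param n_bax,n_cbid,n_luv Particle counts.
#' @param dt_s Time step (s).
#' @param duration_s Simulated time (s).
#' @param sample_dt_s Sampling interval (s).
#' @param D_bax,D_cbid,D_luv Diffusion coefficients (um^2/s).
#' @param luv_radius_um Vesicle radius (um).
#' @param k_cbid_on,k_bax_on_cbid,k_bax_on_bax Volumetric association rates
#'   (um^3/s); defaults are diffusion-limited at vesicle contact. Set to 0 to
#'   disable the corresponding recruitment path.
#' @param k_cbid_off,k_mono_off,k_shrink First-order rates (1/s).
#' @param even_stabilization Multiplier (>= 1) favouring even complex sizes.
#' @param oligomer_cap Hard cap on complex size.
#' @param seed Integer seed.
#' @return Object of class `assembly_config`.
#' @export
assembly_config <- function(box_side_um = 7, n_bax = 1163,
                            n_cbid = 2 * n_bax, n_luv = round(1.25 * n_bax),
                            dt_s = 5e-5, duration_s = 600, sample_dt_s = 1,
                            D_bax = 60, D_cbid = 100, D_luv = 2.5,
                            luv_radius_um = 0.1,
                            k_cbid_on = 4 * pi * (D_cbid + D_luv) * luv_radius_um,
                            k_bax_on_cbid = 4 * pi * (D_bax + D_luv) * luv_radius_um,
                            k_bax_on_bax = 4 * pi * (D_bax + D_luv) * luv_radius_um,
                            k_cbid_off = 1, k_mono_off = 1, k_shrink = 0.1,
                            even_stabilization = 10, oligomer_cap = 12,
                            seed = 1L) {
  stopifnot(box_side_um > 0, n_bax >= 0, n_cbid >= 0, n_luv >= 1,
            dt_s > 0, duration_s > 0, sample_dt_s >= dt_s,
            D_bax >= 0, D_cbid >= 0, D_luv >= 0, luv_radius_um > 0,
            k_cbid_on >= 0, k_bax_on_cbid >= 0, k_bax_on_bax >= 0,
            k_cbid_off >= 0, k_mono_off >= 0, k_shrink >= 0,
            even_stabilization >= 1, oligomer_cap >= 2)
  structure(as.list(environment()), class = "assembly_config")
}

#' Binding radius of a second-order reaction
#'
#' Inverts the Smoluchowski diffusion-limited rate: a volumetric association
#' rate `k_on` (um^3/s) between partners with relative diffusion `D_sum`
#' becomes an encounter radius `k_on / (4 * pi * D_sum)` below which the
#' reaction fires. For protein-vesicle encounters the radius is additionally
#' floored at the vesicle radius, since geometric contact dominates at these
#' scales.
#'
#' @param k_on Volumetric rate (um^3/s).
#' @param D_sum Sum of the partners' diffusion coefficients (um^2/s).
#' @param floor_radius Optional lower bound on the radius (um).
#' @return Radius in um (0 when `k_on` is 0, disabling the reaction).
#' @export
binding_radius <- function(k_on, D_sum, floor_radius = NULL) {
  stopifnot(k_on >= 0, D_sum > 0)
  if (k_on == 0) return(0)
  r <- k_on / (4 * pi * D_sum)
  if (!is.null(floor_radius)) r <- max(r, floor_radius)
  r
}

#' Effective well-mixed association rate of the fixed-step engine
#'
#' In the fast-diffusion (well-mixed) limit successive positions are
#' independent, so per step a pair reacts with probability equal to the
#' volume fraction of the binding sphere; the corresponding volumetric rate
#' is `(4/3) * pi * radius^3 / dt`. This is the rate at which a Gillespie
#' model of the same scheme matches the spatial engine in that limit.
#'
#' @param radius Binding radius (um).
#' @param dt_s Engine time step (s).
#' @return Volumetric rate (um^3/s).
#' @export
wellmixed_on_rate <- function(radius, dt_s) (4 / 3) * pi * radius^3 / dt_s

#' Run the particle-based assembly simulation
#'
#' @param config An [assembly_config()].
#' @return Object of class `assembly_timecourse`: data frame columns `time`,
#'   `soluble_bax`, `soluble_cbid`, `occupied_luvs`, plus attributes
#'   `size_hist` (samples x sizes matrix of complex counts), `config` and
#'   `capped_events`.
#' @export
run_assembly <- function(config) {
  stopifnot(inherits(config, "assembly_config"))
  sd_max <- sqrt(2 * max(config$D_bax, config$D_cbid, config$D_luv) *
                   config$dt_s)
  if (sd_max > config$luv_radius_um / 2)
    warning(sprintf(paste0("rms step (%.3g um) exceeds half the vesicle ",
                           "radius; encounters may be under-sampled at this ",
                           "dt"), sd_max))
  r_cbid <- binding_radius(config$k_cbid_on, config$D_cbid + config$D_luv,
                           config$luv_radius_um)
  r_bc <- binding_radius(config$k_bax_on_cbid, config$D_bax + config$D_luv,
                         config$luv_radius_um)
  r_bb <- binding_radius(config$k_bax_on_bax, config$D_bax + config$D_luv,
                         config$luv_radius_um)
  set.seed(config$seed)
  out <- .assembly_engine(config$box_side_um, config$n_bax, config$n_cbid,
                          config$n_luv, config$dt_s, config$duration_s,
                          config$sample_dt_s, config$D_bax, config$D_cbid,
                          config$D_luv, r_cbid, r_bc, r_bb,
                          config$k_cbid_off, config$k_mono_off,
                          config$k_shrink, config$even_stabilization,
                          config$oligomer_cap)
  tc <- data.frame(time = out$time, soluble_bax = out$soluble_bax,
                   soluble_cbid = out$soluble_cbid,
                   occupied_luvs = out$occupied_luvs)
  structure(tc, class = c("assembly_timecourse", "data.frame"),
            size_hist = out$size_hist, config = config,
            capped_events = out$capped_events,
            binding_radii = c(cbid = r_cbid, bax_cbid = r_bc, bax_bax = r_bb))
}

.nearest_sample <- function(tc, t) {
  if (t < min(tc$time) - 1e-9 || t > max(tc$time) + 1e-9)
    stop("time outside the simulated range")
  which.min(abs(tc$time - t))
}

#' Fraction of vesicles carrying a Bax complex
#'
#' @param tc An `assembly_timecourse`.
#' @param t Time (s); the nearest sample is used. Default: final sample.
#' @return Fraction in [0, 1].
#' @export
luv_occupancy_fraction <- function(tc, t = max(tc$time)) {
  i <- .nearest_sample(tc, t)
  tc$occupied_luvs[i] / attr(tc, "config")$n_luv
}

#' Even-to-odd complex mass ratio
#'
#' Ratio of the number of Bax molecules residing in even-sized complexes to
#' those in odd-sized complexes at a given time, over sizes up to `max_size`.
#'
#' @param tc An `assembly_timecourse`.
#' @param t Time (s); nearest sample. Default: final sample.
#' @param max_size Largest complex size included (default: the cap).
#' @return Ratio (Inf when no odd mass, NaN when no mass at all).
#' @export
even_odd_mass_ratio <- function(tc, t = max(tc$time), max_size = Inf) {
  i <- .nearest_sample(tc, t)
  hist <- attr(tc, "size_hist")[i, ]
  sizes <- seq_along(hist)
  keep <- sizes <= max_size
  mass <- sizes * hist
  sum(mass[keep & sizes %% 2 == 0]) / sum(mass[keep & sizes %% 2 == 1])
}

#' Complex size distribution at a time point
#'
#' @inheritParams even_odd_mass_ratio
#' @return Named vector of complex counts by size.
#' @export
size_distribution <- function(tc, t = max(tc$time)) {
  i <- .nearest_sample(tc, t)
  h <- attr(tc, "size_hist")[i, ]
  stats::setNames(h, seq_along(h))
}

#' @export
print.assembly_timecourse <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Assembly simulation: %g um box, %d Bax / %d cBid / %d LUVs, %g s\n",
              cfg$box_side_um, cfg$n_bax, cfg$n_cbid, cfg$n_luv,
              cfg$duration_s))
  cat(sprintf("  final LUV occupancy: %.1f%%; soluble Bax %d -> %d\n",
              100 * luv_occupancy_fraction(x), x$soluble_bax[1],
              x$soluble_bax[nrow(x)]))
  h <- size_distribution(x)
  if (sum(h) > 0) {
    cat("  final complex sizes:\n")
    print(h[h > 0])
  }
  invisible(x)
}

#' @export
plot.assembly_timecourse <- function(x, ...) {
  cfg <- attr(x, "config")
  graphics::matplot(x$time, cbind(x$soluble_bax, x$soluble_cbid,
                                  x$occupied_luvs),
                    type = "l", lty = 1, col = c("orange", "blue", "magenta"),
                    xlab = "time (s)", ylab = "particles", ...)
  graphics::abline(h = cfg$n_luv, lty = 2)
  graphics::legend("right", c("soluble Bax", "soluble cBid",
                              "LUVs with Bax"), lty = 1,
                   col = c("orange", "blue", "magenta"), bty = "n")
  invisible(x)
}

#' Gillespie reference for the reduced binding scheme
#'
#' Exact stochastic simulation of the well-mixed scheme `A + L <-> AL` with
#' volumetric rate `k_on` (um^3/s) and dissociation `k_off` (1/s) in volume
#' `volume` (um^3), used as the independent oracle for the spatial engine in
#' its fast-diffusion limit. Vesicles can bind any number of A (matching the
#' engine's activator binding).
#'
#' @param k_on,k_off Rates.
#' @param n_a,n_l Initial counts of A and L.
#' @param volume Volume (um^3).
#' @param t_end End time (s).
#' @param stationary_from Start of the averaging window (s).
#' @param seed Optional seed.
#' @param record Keep the full event trajectory (may be large); default
#'   FALSE, only the time-averaged bound fraction is accumulated.
#' @return List: `bound_fraction` (time-averaged fraction of A bound over
#'   the stationary window), and when `record = TRUE` the event `times` and
#'   `bound` trajectory.
#' @export
well_mixed_reference <- function(k_on, k_off, n_a, n_l, volume,
                                 t_end, stationary_from = t_end / 2,
                                 seed = NULL, record = FALSE) {
  stopifnot(n_a >= 1, n_l >= 1, volume > 0, t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  c_on <- k_on / volume  # per-pair propensity (1/s)
  t <- 0
  bound <- 0L
  nrec <- 0L
  times <- numeric(if (record) 1024 else 0)
  states <- integer(if (record) 1024 else 0)
  acc_time <- 0
  acc_int <- 0
  while (t < t_end) {
    a_free <- n_a - bound
    rate_on <- c_on * a_free * n_l
    rate_off <- k_off * bound
    tot <- rate_on + rate_off
    if (tot <= 0) {
      dt <- t_end - t
      if (t >= stationary_from) {
        acc_time <- acc_time + dt
        acc_int <- acc_int + dt * bound
      }
      break
    }
    dt <- stats::rexp(1, tot)
    t_next <- min(t + dt, t_end)
    w0 <- max(t, stationary_from)
    if (t_next > w0) {
      acc_time <- acc_time + (t_next - w0)
      acc_int <- acc_int + (t_next - w0) * bound
    }
    t <- t + dt
    if (t > t_end) break
    bound <- if (stats::runif(1) * tot < rate_on) bound + 1L else bound - 1L
    if (record) {
      nrec <- nrec + 1L
      if (nrec > length(times)) {  # grow geometrically
        length(times) <- 2L * length(times)
        length(states) <- 2L * length(states)
      }
      times[nrec] <- t
      states[nrec] <- bound
    }
  }
  out <- list(bound_fraction = if (acc_time > 0) acc_int / (acc_time * n_a)
              else bound / n_a)
  if (record) {
    out$times <- times[seq_len(nrec)]
    out$bound <- states[seq_len(nrec)]
  }
  out
}

#' Exact equilibrium bound fraction of the reduced scheme
#'
#' Stationary mean of the birth-death chain on the number of bound A
#' molecules (0..n_a) with birth rate `c_on * (n_a - b) * n_l` and death rate
#' `k_off * b`, computed from the detailed-balance stationary distribution.
#'
#' @inheritParams well_mixed_reference
#' @return Expected bound fraction at equilibrium.
#' @export
equilibrium_bound_fraction <- function(k_on, k_off, n_a, n_l, volume) {
  c_on <- k_on / volume
  if (k_off <= 0) return(1)
  b <- 0:n_a
  logpi <- cumsum(c(0, log(c_on * (n_a - b[-length(b)]) * n_l) -
                      log(k_off * (b[-1]))))
  logpi <- logpi - max(logpi)
  pi <- exp(logpi) / sum(exp(logpi))
  sum(b * pi) / n_a
}

#' Write an assembly timecourse as CSV
#'
#' Columns: time, soluble counts, occupancy and one column per complex size.
#' @param tc An `assembly_timecourse`.
#' @param path Output path.
#' @export
write_timecourse_csv <- function(tc, path) {
  h <- attr(tc, "size_hist")
  colnames(h) <- paste0("size_", seq_len(ncol(h)))
  utils::write.csv(cbind(as.data.frame(tc), h), path, row.names = FALSE)
  invisible(path)
}
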