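#' Photophysical model of a labelled particle
#'
#' Bundles the per-fluorophore emission and bleaching parameters used by the
#' synthetic-data generator. Brightness of a single fluorophore is drawn once
#' per fluorophore from Normal(`mu1`, `sigma1`) (truncated to positive values),
#' so `sigma1` describes particle-to-particle brightness variation, the
#' quantity recovered by monomer calibration. Each fluorophore bleaches in a
#' single irreversible step after an exponentially distributed number of
#' frames; blinking is not modelled.
#'
#' The default frame timing follows a stroboscopic acquisition of 1 ms
#' illumination with a 90 ms inter-frame delay, i.e. 91 ms per frame.
#'
#' @param mu1 Mean integrated brightness of one fluorophore per frame (counts).
#' @param sigma1 Between-particle s.d. of single-fluorophore brightness (counts).
#' @param bleach_mean_frames Mean of the exponential photobleaching lifetime,
#'   in frames.
#' @param background_rate Background photons per pixel per frame.
#' @param read_noise_sd Gaussian camera read noise s.d. (counts).
#' @param t_ill_s Illumination time per frame (seconds).
#' @param frame_delay_s Delay between frames (seconds).
#' @return An object of class `photophysics_model`.
#' @examples
#' photophysics_model(mu1 = 1000, sigma1 = 250)
#' @export
photophysics_model <- function(mu1 = 1000, sigma1 = 250,
                               bleach_mean_frames = 150,
                               background_rate = 5, read_noise_sd = 2,
                               t_ill_s = 0.001, frame_delay_s = 0.090) {
  stopifnot(is.numeric(mu1), mu1 > 0, is.numeric(sigma1), sigma1 >= 0,
            bleach_mean_frames > 0, background_rate >= 0, read_noise_sd >= 0,
            t_ill_s > 0, frame_delay_s >= 0)
  structure(list(mu1 = mu1, sigma1 = sigma1,
                 bleach_mean_frames = bleach_mean_frames,
                 background_rate = background_rate,
                 read_noise_sd = read_noise_sd,
                 t_ill_s = t_ill_s, frame_delay_s = frame_delay_s,
                 frame_interval_s = t_ill_s + frame_delay_s),
            class = "photophysics_model")
}

#' Imaging geometry for the synthetic movie renderer
#'
#' @param psf_sigma_px Gaussian point-spread-function s.d. in pixels.
#' @param fov_px Width/height of the (square) field of view in pixels.
#' @param pixel_size_nm Physical pixel size in nanometres.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(psf_sigma_px = 1.2, fov_px = 64, pixel_size_nm = 160) {
  stopifnot(psf_sigma_px > 0, fov_px >= 16, pixel_size_nm > 0)
  structure(list(psf_sigma_px = psf_sigma_px, fov_px = as.integer(fov_px),
                 pixel_size_nm = pixel_size_nm),
            class = "optics_model")
}

#' @export
print.photophysics_model <- function(x, ...) {
  cat("Photophysics model\n")
  cat(sprintf("  mu1 = %.4g counts, sigma1 = %.4g counts\n", x$mu1, x$sigma1))
  cat(sprintf("  bleach lifetime (mean) = %.4g frames\n", x$bleach_mean_frames))
  cat(sprintf("  background = %.4g counts/px/frame, read noise sd = %.4g\n",
              x$background_rate, x$read_noise_sd))
  cat(sprintf("  frame interval = %.4g s\n", x$frame_interval_s))
  invisible(x)
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf("Optics model: PSF sigma %.3g px, FOV %d x %d px, pixel %.4g nm\n",
              x$psf_sigma_px, x$fov_px, x$fov_px, x$pixel_size_nm))
  invisible(x)
}
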