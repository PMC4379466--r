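#' Camera model for an EMCCD acquisition
#'
#' Describes the camera geometry and noise model used both by the forward
#' simulator and by the localization routines to convert raw counts back to
#' photons. The defaults describe a typical back-illuminated EMCCD behind a
#' 100x objective: 80 nm effective pixel size, 50 ms integration at 17
#' frames per second.
#'
#' @param pixel_size_nm Effective object-plane pixel size in nm.
#' @param integration_ms Exposure (integration) time per frame in ms.
#' @param fps Frame rate in frames per second. `fps * integration_ms` must
#'   not exceed 1000, i.e. the exposure fits inside the frame period.
#' @param em_gain Electron-multiplying gain (counts per photoelectron).
#' @param read_noise Read noise in counts rms (after gain).
#' @param offset Camera baseline offset in counts.
#' @param qe Quantum efficiency in `[0, 1]`.
#' @return A `camera_model` list.
#' @export
#' @examples
#' camera_model()
camera_model <- function(pixel_size_nm = 80, integration_ms = 50, fps = 17,
                         em_gain = 50, read_noise = 10, offset = 100, qe = 0.9) {
  stopifnot(pixel_size_nm > 0, integration_ms > 0, fps > 0,
            em_gain > 0, read_noise >= 0, qe >= 0, qe <= 1)
  if (fps * integration_ms > 1000 + 1e-9) {
    abort("camera_model: integration time exceeds the frame period (fps * integration_ms > 1000)",
          class = "smlmpipe_error")
  }
  structure(
    list(pixel_size_nm = pixel_size_nm, integration_ms = integration_ms,
         fps = fps, em_gain = em_gain, read_noise = read_noise,
         offset = offset, qe = qe),
    class = "camera_model"
  )
}

#' Gaussian approximation of the microscope point spread function
#'
#' The Airy profile of a high-NA objective is approximated by a 2D Gaussian
#' with `sigma_psf = 0.25 * wavelength / NA`, a standard rule of thumb for
#' the standard deviation best matching the Airy core. The defaults
#' (510 nm emission, NA 1.4 oil immersion) give `sigma_psf` of ~91 nm.
#'
#' @param wavelength_nm Emission wavelength in nm.
#' @param na Numerical aperture of the objective.
#' @param sigma_nm Override for the Gaussian sigma in nm; if `NULL` it is
#'   derived as `0.25 * wavelength_nm / na`.
#' @return A `psf_model` list with fields `wavelength_nm`, `na`, `sigma_nm`.
#' @export
#' @examples
#' psf_model()$sigma_nm
psf_model <- function(wavelength_nm = 510, na = 1.4, sigma_nm = NULL) {
  stopifnot(wavelength_nm > 0, na > 0)
  if (is.null(sigma_nm)) sigma_nm <- 0.25 * wavelength_nm / na
  stopifnot(sigma_nm > 0)
  structure(list(wavelength_nm = wavelength_nm, na = na, sigma_nm = sigma_nm),
            class = "psf_model")
}

#' Photo-switching kinetics of the simulated fluorophores
#'
#' Parameters of the stochastic switching model: fluorophores sit in a
#' long-lived dark state and recover to the emissive state at rate
#' `recovery_rate`; an emissive burst lasts an exponential on-time with mean
#' `mean_on_time_ms` (~60 ms for standard fluorescent proteins under strong
#' excitation), after which the molecule either bleaches irreversibly (with
#' probability `bleach_prob`) or returns to the dark state. A fraction of
#' the population does not switch at all: it fluoresces continuously until
#' an exponential bleaching time with rate `nonswitching_bleach_rate`,
#' emulating the non-switching background population that photo-bleaches
#' over the acquisition and degrades early-movie localization accuracy.
#'
#' @param recovery_rate Dark-to-on recovery rate per emitter, 1/s. The
#'   default 0.02/s corresponds to a mean dark-state lifetime of 50 s
#'   (seconds to minutes).
#' @param mean_on_time_ms Mean emissive on-time per burst, ms.
#' @param dark_lifetime_s Mean dark-state lifetime, s (`1 / recovery_rate`
#'   unless given explicitly; kept as metadata).
#' @param bleach_prob Probability of irreversible bleaching after a burst.
#' @param photon_range Length-2 numeric: (min, max) detected photons per
#'   burst, drawn uniformly. Default `c(100, 1000)`.
#' @param nonswitching_fraction Fraction of emitters that fluoresce
#'   continuously (no switching) until they bleach.
#' @param nonswitching_bleach_rate Bleaching rate of the non-switching
#'   population, 1/s.
#' @return A `switching_params` list.
#' @export
switching_params <- function(recovery_rate = 0.02, mean_on_time_ms = 60,
                             dark_lifetime_s = 1 / max(recovery_rate, 1e-12),
                             bleach_prob = 0.5, photon_range = c(100, 1000),
                             nonswitching_fraction = 0,
                             nonswitching_bleach_rate = 0.05) {
  stopifnot(recovery_rate >= 0, mean_on_time_ms > 0, dark_lifetime_s >= 0,
            bleach_prob >= 0, bleach_prob <= 1,
            length(photon_range) == 2, photon_range[1] <= photon_range[2],
            photon_range[1] >= 0,
            nonswitching_fraction >= 0, nonswitching_fraction <= 1,
            nonswitching_bleach_rate >= 0)
  structure(
    list(recovery_rate = recovery_rate, mean_on_time_ms = mean_on_time_ms,
         dark_lifetime_s = dark_lifetime_s, bleach_prob = bleach_prob,
         photon_range = photon_range,
         nonswitching_fraction = nonswitching_fraction,
         nonswitching_bleach_rate = nonswitching_bleach_rate),
    class = "switching_params"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %g nm/px, %g ms @ %g fps, gain %g, read noise %g, offset %g, QE %g\n",
              x$pixel_size_nm, x$integration_ms, x$fps, x$em_gain,
              x$read_noise, x$offset, x$qe))
  invisible(x)
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> lambda %g nm, NA %g, sigma %.1f nm\n",
              x$wavelength_nm, x$na, x$sigma_nm))
  invisible(x)
}

#' @export
print.switching_params <- function(x, ...) {
  cat(sprintf(paste0("<switching_params> recovery %g/s, on-time %g ms, bleach p %g, ",
                     "photons [%g, %g], nonswitching %g (bleach %g/s)\n"),
              x$recovery_rate, x$mean_on_time_ms, x$bleach_prob,
              x$photon_range[1], x$photon_range[2],
              x$nonswitching_fraction, x$nonswitching_bleach_rate))
  invisible(x)
}
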