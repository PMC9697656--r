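#' Evenly sampled 1-D surface height profile
#'
#' @param x_mm sample positions in mm, evenly spaced (constant spacing to
#'   1e-9 relative).
#' @param z_um heights in micrometres (`NA` marks dropouts).
#' @return object of class `surface_profile` with fields `x_mm`, `z_um`,
#'   `spacing_um` and evaluation length `length_mm`.
#' @export
surface_profile <- function(x_mm, z_um) {
  check(length(x_mm) >= 2 && length(x_mm) == length(z_um),
        "profile needs >= 2 (x, z) samples of equal length")
  dx <- diff(x_mm)
  check(all(dx > 0), "x_mm must be strictly increasing")
  check(max(dx) - min(dx) <= 1e-9 * max(dx),
        "x_mm must be evenly spaced (to 1e-9 relative)")
  structure(list(x_mm = as.numeric(x_mm), z_um = as.numeric(z_um),
                 spacing_um = dx[1] * 1000,
                 length_mm = x_mm[length(x_mm)] - x_mm[1]),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("surface profile: %d points, %.4g mm long, %.4g um spacing\n",
              length(x$x_mm), x$length_mm, x$spacing_um))
  invisible(x)
}

#' Generate an analytic surface profile with closed-form roughness
#'
#' Produces flat, sine, square or sawtooth profiles of known arithmetic
#' roughness (0, 2A/pi, A and A/2 respectively), optionally with a linear
#' drift that the detrending stage must remove, plus optional Gaussian
#' height noise.  For the periodic kinds the wavelength must divide the
#' evaluated length into whole periods so the closed forms hold.
#'
#' @param kind one of `"flat"`, `"sine"`, `"square"`, `"sawtooth"`.
#' @param amplitude_um peak amplitude A in micrometres.
#' @param wavelength_um spatial period in micrometres (periodic kinds).
#' @param length_mm evaluation length in mm.
#' @param spacing_um sample spacing in micrometres.
#' @param drift_slope_um_per_mm linear baseline slope added to the signal.
#' @param noise_sd_um optional Gaussian height noise (default 0).
#' @param seed integer seed (used only when `noise_sd_um > 0`).
#' @return a [surface_profile()].
#' @examples
#' p <- generate_profile("sine", amplitude_um = 10)
#' roughness_ra(detrend_profile(p)) # ~ 2 * 10 / pi
#' @export
generate_profile <- function(kind = c("flat", "sine", "square", "sawtooth"),
                             amplitude_um = 10, wavelength_um = 1000,
                             length_mm = 10, spacing_um = 1,
                             drift_slope_um_per_mm = 0, noise_sd_um = 0,
                             seed = 1L) {
  kind <- match.arg(kind)
  check(is_number(spacing_um) && spacing_um > 0, "spacing must be positive")
  check(is_number(length_mm) && length_mm > 0, "length must be positive")
  length_um <- length_mm * 1000
  if (kind != "flat") {
    check(is_number(wavelength_um) && wavelength_um > 0,
          "wavelength must be positive")
    n_per <- length_um / wavelength_um
    check(abs(n_per - round(n_per)) < 1e-9,
          "wavelength must divide the evaluated length into whole periods")
  }
  x_um <- seq(0, length_um, by = spacing_um)
  phase <- 2 * pi * x_um / wavelength_um
  z <- switch(kind,
    flat = rep(0, length(x_um)),
    sine = amplitude_um * sin(phase),
    # sign convention keeps |z| = A at the zero crossings of sin
    square = amplitude_um * ifelse(sin(phase) >= 0, 1, -1),
    sawtooth = amplitude_um * (2 * ((x_um / wavelength_um) %% 1) - 1))
  z <- z + drift_slope_um_per_mm * x_um / 1000
  if (noise_sd_um > 0)
    z <- z + with_seed(seed, rnorm(length(z), 0, noise_sd_um))
  surface_profile(x_um / 1000, z)
}
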