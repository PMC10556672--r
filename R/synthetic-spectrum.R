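# Synthetic absorbance spectra (90% acetone extract) constructed so that the
# trichromatic pigment equations invert them exactly, plus a simple
# exponential growth-curve generator.

gauss_band <- function(wl, center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))

# Unit spectra: linear combinations of red absorption bands whose values at
# 630/647/664 nm satisfy quantify(S_a) = (1, 0) and quantify(S_c) = (0, 1)
# ug/mL under the stored coefficient set, so generated spectra round-trip.
unit_pigment_spectra <- function(wl, coefficients = pigment_coefficients()) {
  b664 <- gauss_band(wl, 664, 9)
  b630 <- gauss_band(wl, 630, 10)
  at <- function(band, l) band[which.min(abs(wl - l))]
  # rows: the two trichromatic equations applied to (A630, A647, A664)
  eqn <- rbind(
    c(coefficients$chl_a[["A630"]], coefficients$chl_a[["A647"]],
      coefficients$chl_a[["A664"]]),
    c(coefficients$chl_c[["A630"]], coefficients$chl_c[["A647"]],
      coefficients$chl_c[["A664"]]))
  v664 <- c(at(b664, 630), at(b664, 647), at(b664, 664))
  v630 <- c(at(b630, 630), at(b630, 647), at(b630, 664))
  M <- eqn %*% cbind(v664, v630) # 2x2: (amp664, amp630) -> (chl_a, chl_c)
  amps_a <- solve(M, c(1, 0))
  amps_c <- solve(M, c(0, 1))
  list(chl_a = amps_a[1] * b664 + amps_a[2] * b630 +
         0.08 * amps_a[1] * gauss_band(wl, 430, 12),
       chl_c = amps_c[1] * b664 + amps_c[2] * b630 +
         0.1 * abs(amps_c[1]) * gauss_band(wl, 450, 14))
}

#' Generate a synthetic absorbance spectrum for given pigment concentrations
#'
#' Builds a 400-800 nm spectrum as a sum of Gaussian absorption bands whose
#' heights at 630, 647 and 664 nm are consistent, by inversion of the
#' trichromatic equations, with the requested chlorophyll a and c
#' concentrations, so [quantify_pigments()] recovers them.
#'
#' @param chl_a_ug_ml,chl_c_ug_ml pigment concentrations, ug/mL (>= 0)
#' @param noise Gaussian absorbance noise standard deviation (0 = none)
#' @param turbidity constant scattering offset added across the spectrum
#'   (removed by the 750 nm correction)
#' @param seed integer seed; NULL leaves the RNG state alone
#' @param wavelength_nm wavelength grid
#' @return data.frame with `wavelength_nm`, `absorbance`
#' @export
generate_absorbance_spectrum <- function(chl_a_ug_ml, chl_c_ug_ml, noise = 0,
                                         turbidity = 0, seed = NULL,
                                         wavelength_nm = 400:800) {
  if (chl_a_ug_ml < 0 || chl_c_ug_ml < 0) {
    stop("pigment concentrations must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- unit_pigment_spectra(wavelength_nm)
  ab <- chl_a_ug_ml * u$chl_a + chl_c_ug_ml * u$chl_c + turbidity
  if (noise > 0) ab <- ab + rnorm(length(ab), 0, noise)
  data.frame(wavelength_nm = wavelength_nm, absorbance = ab)
}

#' Simulate an exponential growth curve of cell density
#'
#' @param n0 initial density, cells/mL
#' @param rate_div_per_day division rate, doublings per day
#' @param days numeric vector of sampling days
#' @param noise lognormal noise sd on density (0 = none)
#' @param seed integer seed
#' @return data.frame with `day`, `density_cells_ml`
#' @export
simulate_growth_curve <- function(n0 = 1e5, rate_div_per_day = 0.73,
                                  days = 0:7, noise = 0, seed = NULL) {
  stopifnot(n0 > 0, all(days >= 0))
  if (!is.null(seed)) set.seed(seed)
  dens <- n0 * 2^(rate_div_per_day * days)
  if (noise > 0) dens <- dens * exp(rnorm(length(days), 0, noise))
  data.frame(day = days, density_cells_ml = dens)
}
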