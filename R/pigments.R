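# Chlorophyll a and c quantification from 90% acetone extract absorbance
# spectra (trichromatic equations) and conversion to per-cell content.

#' Trichromatic pigment equation coefficients
#'
#' Reads the coefficient set (90% acetone, 1 cm path) from a YAML config so
#' alternate coefficient sets can be swapped in:
#' chl a = 11.85 A664 - 1.54 A647 - 0.08 A630,
#' chl c1+c2 = 24.52 A630 - 7.60 A647 - 1.67 A664 (ug/mL).
#'
#' @param file path to a YAML coefficient file; default = the set shipped
#'   with the package
#' @return list with `chl_a`, `chl_c` named coefficient vectors
#' @export
pigment_coefficients <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "pigment_coefficients.yaml",
                        package = "ldscope")
  }
  cfg <- yaml::read_yaml(file)
  list(chl_a = unlist(cfg$chl_a), chl_c = unlist(cfg$chl_c))
}

spectrum_at <- function(spectrum, wavelengths) {
  wl <- spectrum$wavelength_nm
  ab <- spectrum$absorbance
  stopifnot(all(diff(wl) > 0), all(is.finite(ab)))
  vapply(wavelengths, function(l) {
    i <- which(wl == l)
    if (length(i)) return(ab[i[1]])
    if (l < min(wl) || l > max(wl)) {
      stop("spectrum does not cover ", l, " nm")
    }
    k <- findInterval(l, wl)
    if (wl[k + 1] - wl[k] > 2) {
      stop("grid spacing around ", l, " nm exceeds 2 nm; cannot interpolate")
    }
    approx(wl, ab, xout = l)$y
  }, 0)
}

#' Quantify chlorophyll a and c from an extract absorbance spectrum
#'
#' Reads absorbances at 630, 647 and 664 nm (turbidity-corrected by
#' subtracting A750 by default) and applies the trichromatic 90%-acetone
#' equations. Wavelengths absent from the grid are linearly interpolated if
#' the grid spacing is at most 2 nm. Negative concentrations are clipped to
#' zero with a warning; raw values are kept in the `raw` field.
#'
#' @param spectrum data.frame with `wavelength_nm`, `absorbance`
#' @param correct_turbidity subtract A750 before applying the equations
#' @param coefficients list from [pigment_coefficients()]
#' @return list of class `pigment_result`: `chl_a_ug_ml`, `chl_c_ug_ml`,
#'   `raw` (unclipped values), `absorbances`
#' @export
quantify_pigments <- function(spectrum, correct_turbidity = TRUE,
                              coefficients = pigment_coefficients()) {
  a <- spectrum_at(spectrum, c(630, 647, 664))
  names(a) <- c("A630", "A647", "A664")
  if (correct_turbidity) {
    a <- a - spectrum_at(spectrum, 750)
  }
  chl_a <- sum(coefficients$chl_a[names(a)] * a)
  chl_c <- sum(coefficients$chl_c[names(a)] * a)
  raw <- c(chl_a = chl_a, chl_c = chl_c)
  if (any(raw < 0)) {
    warning("negative pigment concentration clipped to zero (raw: ",
            paste(signif(raw, 3), collapse = ", "), ")")
  }
  structure(list(chl_a_ug_ml = max(chl_a, 0), chl_c_ug_ml = max(chl_c, 0),
                 raw = raw, absorbances = a),
            class = "pigment_result")
}

#' Convert extract concentrations to per-cell pigment content
#'
#' `pg/cell = conc (ug/mL) * extract volume (mL) / (culture volume (mL) *
#' density (cells/mL)) * 1e6`.
#'
#' @param result a `pigment_result` (or a named list with `chl_a_ug_ml`,
#'   `chl_c_ug_ml`)
#' @param extract_volume_ml total extract volume, mL (sample-specific: it
#'   depends on the number of lysis cycles, so it is a required input)
#' @param culture_volume_ml harvested culture volume, mL
#' @param cell_density_per_ml culture cell density, cells/mL (> 0)
#' @return list: `chl_a_pg_cell`, `chl_c_pg_cell`, `total_pg_cell`
#' @export
per_cell_content <- function(result, extract_volume_ml, culture_volume_ml,
                             cell_density_per_ml) {
  stopifnot(extract_volume_ml > 0, culture_volume_ml > 0)
  if (cell_density_per_ml <= 0) stop("cell density must be positive")
  f <- extract_volume_ml / (culture_volume_ml * cell_density_per_ml) * 1e6
  a <- result$chl_a_ug_ml * f
  c_ <- result$chl_c_ug_ml * f
  list(chl_a_pg_cell = a, chl_c_pg_cell = c_, total_pg_cell = a + c_)
}
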