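# Per-pixel feature stack for the brightfield pixel classifier: raw
# intensity, Sobel edge magnitude, moving-maximum texture, and a Gabor
# filter bank.

gabor_kernel <- function(sigma_px, wavelength_px, theta, phase = 0) {
  r <- ceiling(2.5 * sigma_px)
  g <- expand.grid(x = -r:r, y = -r:r)
  rot <- g$x * cos(theta) + g$y * sin(theta)
  env <- exp(-(g$x^2 + g$y^2) / (2 * sigma_px^2))
  k <- env * cos(2 * pi * rot / wavelength_px + phase)
  matrix(k - mean(k), 2 * r + 1, 2 * r + 1)
}

#' Compute the per-pixel feature stack of a brightfield image
#'
#' Features: raw intensity, Sobel gradient magnitude (edges), moving-maximum
#' response (texture), and Gabor energy at `n_orientations` orientations
#' (edge + texture). Filter geometry is exposed because the reference
#' workflow names the filters but not their parameters.
#'
#' @param image numeric matrix
#' @param max_radius moving-maximum window radius, px
#' @param gabor_sigma_px,gabor_wavelength_px Gabor envelope and carrier
#' @param n_orientations number of Gabor orientations
#' @return 3D array (rows x cols x features) with named feature planes
#' @export
compute_pixel_features <- function(image, max_radius = 2,
                                   gabor_sigma_px = 3,
                                   gabor_wavelength_px = 8,
                                   n_orientations = 4) {
  stopifnot(is.matrix(image), all(is.finite(image)), length(image) > 0)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(image, sx, boundary = "replicate")
  gy <- EBImage::filter2(image, t(sx), boundary = "replicate")
  feats <- list(
    intensity = image,
    edge_sobel = sqrt(gx^2 + gy^2),
    texture_max = moving_max(image, max_radius)
  )
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  energies <- lapply(thetas, function(th) {
    kr <- gabor_kernel(gabor_sigma_px, gabor_wavelength_px, th, 0)
    ki <- gabor_kernel(gabor_sigma_px, gabor_wavelength_px, th, pi / 2)
    fr <- EBImage::filter2(image, kr, boundary = "replicate")
    fi <- EBImage::filter2(image, ki, boundary = "replicate")
    sqrt(fr^2 + fi^2)
  })
  # aggregate the orientation bank to rotation-invariant responses so the
  # classifier generalises to cell orientations absent from the training set
  feats$gabor_max <- Reduce(pmax, energies)
  feats$gabor_mean <- Reduce(`+`, energies) / length(energies)
  out <- array(unlist(feats, use.names = FALSE),
               dim = c(dim(image), length(feats)))
  dimnames(out) <- list(NULL, NULL, names(feats))
  out
}
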