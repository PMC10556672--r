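# Array helpers shared by the synthetic generators and the segmentation
# stages: shifted views, separable Gaussian blur (direct or FFT), moving
# maximum, Otsu thresholding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift an array along one dimension, zero-filling
#' @param x numeric array (2D or 3D)
#' @param k integer shift (positive shifts towards higher indices)
#' @param along dimension index
#' @return array of the same shape
#' @keywords internal
shift_arr <- function(x, k, along) {
  if (k == 0) return(x)
  d <- dim(x)
  n <- d[along]
  out <- array(0, d)
  if (abs(k) >= n) return(out)
  src <- if (k > 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k > 0) seq.int(1 + k, n) else seq_len(n + k)
  idx_out <- lapply(d, seq_len)
  idx_in <- lapply(d, seq_len)
  idx_out[[along]] <- dst
  idx_in[[along]] <- src
  piece <- do.call(`[`, c(list(x), idx_in, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_out, list(piece)))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

conv1 <- function(x, kern, along) {
  r <- (length(kern) - 1) / 2
  out <- array(0, dim(x))
  for (i in seq_along(kern)) {
    if (kern[i] < 1e-12) next
    out <- out + kern[i] * shift_arr(x, i - r - 1, along)
  }
  out
}

# Broad blurs (baseline estimation) on a decimated grid: stride sampling,
# Gaussian blur at the reduced scale, then block upsampling. The result is
# smooth at the pooling scale by construction, so decimation is harmless.
blur_gaussian_coarse <- function(x, sigma_vox, factor = NULL) {
  d <- dim(x)
  f <- factor %||% pmax(1L, pmin(floor(sigma_vox / 4), floor(d / 8)))
  f <- pmax(1L, as.integer(f))
  idx <- lapply(seq_along(d), function(a) seq(1L, d[a], by = f[a]))
  coarse <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  coarse <- blur_gaussian_direct(coarse, sigma_vox / f)
  up <- lapply(seq_along(d), function(a) {
    rep(seq_along(idx[[a]]), each = f[a])[seq_len(d[a])]
  })
  do.call(`[`, c(list(coarse), up, list(drop = FALSE)))
}

#' Separable Gaussian blur with per-axis sigma (in voxels)
#'
#' Uses direct shifted-sum convolution with edge renormalisation for small
#' kernels; large kernels (baseline estimation) run on a decimated grid and
#' are block-upsampled, which is exact up to terms smooth at the pooling
#' scale.
#' @param x 2D or 3D numeric array
#' @param sigma_vox sigma per dimension, voxels; recycled
#' @return blurred array
#' @keywords internal
blur_gaussian <- function(x, sigma_vox) {
  d <- dim(x)
  nd <- length(d)
  sigma_vox <- rep(sigma_vox, length.out = nd)
  if (all(sigma_vox <= 0)) return(x)
  if (any(6 * sigma_vox + 1 > 41)) return(blur_gaussian_coarse(x, sigma_vox))
  blur_gaussian_direct(x, sigma_vox)
}

blur_gaussian_direct <- function(x, sigma_vox) {
  d <- dim(x)
  nd <- length(d)
  sigma_vox <- rep(sigma_vox, length.out = nd)
  out <- x
  profs <- vector("list", nd)
  for (a in seq_len(nd)) {
    if (sigma_vox[a] <= 0) {
      profs[[a]] <- rep(1, d[a])
      next
    }
    kern <- gaussian_kernel_1d(sigma_vox[a])
    out <- conv1(out, kern, a)
    r <- (length(kern) - 1) / 2
    prof <- as.numeric(convolve(rep(1, d[a]), kern, type = "open"))
    profs[[a]] <- prof[(r + 1):(r + d[a])]
  }
  norm <- Reduce(function(A, b) outer(A, b), profs)
  out / norm
}

#' Moving maximum over a (2r+1)^ndim window (grey-scale dilation)
#' @keywords internal
moving_max <- function(x, r) {
  out <- x
  for (a in seq_along(dim(x))) {
    acc <- out
    for (k in seq_len(r)) {
      acc <- pmax(acc, shift_arr(out, k, a), shift_arr(out, -k, a))
    }
    out <- acc
  }
  out
}

#' Otsu threshold of a numeric array
#'
#' Histogram-based between-class variance maximisation; operates on any
#' numeric array (the 2D implementations in image packages are not defined
#' for 3D stacks).
#' @param x numeric array
#' @param nbins number of histogram bins
#' @return threshold value
#' @keywords internal
otsu_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  rg <- range(v)
  if (diff(rg) == 0) return(rg[1])
  br <- seq(rg[1], rg[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(findInterval(v, br, all.inside = TRUE), nbins))
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  wtot <- w[nbins]
  mtot <- m[nbins]
  w1 <- w[-nbins]
  m1 <- m[-nbins]
  w2 <- wtot - w1
  ok <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, nbins - 1)
  bc[ok] <- (mtot * w1[ok] - wtot * m1[ok])^2 / (w1[ok] * w2[ok])
  br[-c(1, nbins + 1)][which.max(bc)]
}

#' Label connected components of a binary 2D or 3D array
#' @param mask logical array
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D)
#' @return integer array of dense labels (0 = background)
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  stopifnot(length(d) %in% c(2L, 3L))
  connectivity <- connectivity %||% if (length(d) == 2) 8L else 26L
  cpp_label_components(as.logical(mask), as.integer(d),
                       as.integer(connectivity))
}

#' Anisotropic Euclidean distance transform (distance to background)
#' @param mask logical array; distances are computed for TRUE voxels
#' @param spacing physical voxel size per dimension
#' @return numeric array of distances in physical units
#' @export
distance_transform <- function(mask, spacing = rep(1, length(dim(mask)))) {
  d <- dim(mask)
  stopifnot(length(d) %in% c(2L, 3L), length(spacing) == length(d))
  sqrt(cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing)))
}
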