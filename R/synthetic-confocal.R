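# Synthetic two-channel confocal stacks: a single fusiform cell with a
# central bilobed plastid (chlorophyll channel) and spherical LDs (BODIPY
# channel), rendered with a Gaussian point-spread approximation and Poisson
# counting noise, plus a ground-truth table of every object.

draw_ld_volumes <- function(strategy, total) {
  draw_basal <- function(n) {
    v <- exp(rnorm(n, log(0.15), 0.8))
    pmin(pmax(v, 0.005), 0.7)
  }
  switch(strategy,
    basal_only = {
      n <- rpois(1, 3) + 2L
      v <- draw_basal(n)
      v * total / sum(v)
    },
    two_large_dominant = {
      f <- runif(1, 0.87, 0.93)          # fraction held by the two largest
      split <- runif(1, 0.5, 0.62)
      big <- total * f * c(split, 1 - split)
      n_b <- rpois(1, 3) + 1L
      v <- draw_basal(n_b)
      v <- v * total * (1 - f) / sum(v)
      v <- pmin(v, 0.7)
      c(big, v)
    },
    many_medium = {
      # Pt1-like repartition: the two largest hold ~60-72% of the total
      for (i in 1:200) {
        n <- sample(4:8, 1)
        v <- rgamma(n, shape = 2)
        v <- v * total / sum(v)
        fr <- sum(sort(v, decreasing = TRUE)[1:2]) / sum(v)
        if (fr >= 0.58 && fr <= 0.72) return(v)
      }
      total * c(0.33, 0.32, 0.14, 0.11, 0.06, 0.04) # deterministic fallback
    },
    fragmented_distant = {
      n <- sample(10:14, 1)
      v <- draw_basal(n)
      v * total / sum(v)
    })
}

render_sphere <- function(arr, center_vox, r_um, voxel, value = 1) {
  d <- dim(arr)
  r_vox <- r_um / voxel
  lo <- pmax(1, floor(center_vox - r_vox - 2))
  hi <- pmin(d, ceiling(center_vox + r_vox + 2))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx <- ((ix - 0.5) - center_vox[1]) * voxel[1]
  dy <- ((iy - 0.5) - center_vox[2]) * voxel[2]
  dz <- ((iz - 0.5) - center_vox[3]) * voxel[3]
  rr <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  aa <- pmin(1, pmax(0, (r_um - rr) / mean(voxel) + 0.5))
  arr[ix, iy, iz] <- pmax(arr[ix, iy, iz], value * aa)
  arr
}

#' Generate a synthetic two-channel confocal z-stack with ground truth
#'
#' Renders one fusiform cell (axis along x, centred in the stack): the
#' chlorophyll channel contains a central elongated bilobed plastid region,
#' the BODIPY channel contains spherical LDs whose volumes and positions
#' follow `config$ld_strategy`. Channels are blurred with a Gaussian
#' point-spread approximation and corrupted with Poisson counting noise
#' (hybrid-detector counting mode); `noise_level = 0` and
#' `psf_sigma_um = 0` give a deterministic noise-free stack.
#'
#' @param config a [scene_config()]; `n_cells` is ignored (one cell per
#'   stack, mirroring per-cell selection in the analysis)
#' @return list with `channels` (list of 3D arrays `thylakoid`, `ld`),
#'   `mask` (logical 3D cell envelope), `truth` (data.frame: object_id,
#'   type in cell/ld/plastid, volume_um3, cx_um, cy_um, cz_um, radius_um,
#'   width_um, length_um), `voxel_size_um`, `config`
#' @export
generate_confocal_stack <- function(config) {
  validate_scene_config(config)
  set.seed(config$seed)
  v <- config$voxel_size_um
  W <- runif(1, config$width_range_um[1], config$width_range_um[2])
  L <- runif(1, config$length_range_um[1], config$length_range_um[2])

  margin <- c(1.2, 1.2, 1.2)
  dims <- ceiling((c(L, W, W) + 2 * margin) / v)
  ctr_um <- dims * v / 2 # cell centre in physical coordinates
  xs <- (seq_len(dims[1]) - 0.5) * v[1] - ctr_um[1]
  ys <- (seq_len(dims[2]) - 0.5) * v[2] - ctr_um[2]
  zs <- (seq_len(dims[3]) - 0.5) * v[3] - ctr_um[3]

  # cell envelope: spindle of revolution about the x axis
  rho <- spindle_halfwidth(xs, L / 2, W / 2)
  R2 <- outer(ys^2, zs^2, `+`)
  mask <- array(FALSE, dims)
  for (i in seq_len(dims[1])) {
    if (rho[i] > 0) mask[i, , ] <- R2 <= rho[i]^2
  }
  envelope_vol <- sum(mask) * prod(v)

  # plastid: two overlapping prolate lobes, side by side across y
  a_l <- 0.18 * L
  b_l <- 0.55
  off <- 0.45
  plastid <- array(FALSE, dims)
  ixp <- which(abs(xs) <= a_l + 0.1)
  for (s in c(-1, 1)) {
    Q <- outer(outer((xs[ixp] / a_l)^2, ((ys - s * off) / b_l)^2, `+`),
               (zs / b_l)^2, `+`)
    plastid[ixp, , ] <- plastid[ixp, , ] | (Q <= 1)
  }
  plastid <- plastid & mask
  pl_idx <- which(plastid, arr.ind = TRUE)
  pl_bary <- (colMeans(pl_idx) - 0.5) * v
  pl_vol <- nrow(pl_idx) * prod(v)

  # LD volumes and placement
  vols <- draw_ld_volumes(config$ld_strategy, config$total_ld_volume_um3)
  if (sum(vols) > 0.25 * envelope_vol) {
    stop("total LD volume ", round(sum(vols), 2),
         " um^3 exceeds the cell envelope capacity (",
         round(0.25 * envelope_vol, 2), " um^3)")
  }
  radii <- (3 * vols / (4 * pi))^(1 / 3)
  ord <- order(radii, decreasing = TRUE)
  centers <- matrix(NA_real_, length(vols), 3) # cell-frame coordinates, um
  for (j in ord) {
    r <- radii[j]
    placed <- FALSE
    for (try in 1:400) {
      if (config$ld_strategy == "fragmented_distant" &&
          runif(1) < 0.8) {
        # distant placement: along the tapered arms, > 5 um from the plastid
        u <- sample(c(-1, 1), 1) * runif(1, 5.2, 0.92 * L / 2)
      } else {
        u <- runif(1, -0.88, 0.88) * L / 2
      }
      avail <- 0.92 * spindle_halfwidth(u, L / 2, W / 2) - r
      if (!is.finite(avail) || avail < 0) next
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * avail
      cand <- c(u, rad * cos(ang), rad * sin(ang))
      ok <- TRUE
      for (jj in seq_len(nrow(centers))) {
        if (jj == j || is.na(centers[jj, 1])) next
        if (sqrt(sum((cand - centers[jj, ])^2)) <
            1.06 * (r + radii[jj])) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        centers[j, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place an LD of radius ", round(r, 2),
           " um inside the cell envelope; total LD volume exceeds capacity")
    }
  }

  # render channels
  chl <- array(0, dims)
  chl[plastid] <- 1
  ld <- array(0, dims)
  for (j in seq_along(vols)) {
    cvox <- (centers[j, ] + ctr_um) / v
    ld <- render_sphere(ld, cvox, radii[j], v)
  }

  psf <- config$psf_sigma_um / v
  if (any(psf > 0)) {
    chl <- blur_gaussian(chl, psf)
    ld <- blur_gaussian(ld, psf)
  }
  if (config$noise_level > 0) {
    peak <- 80
    bg <- 0.8 * config$noise_level
    chl <- array(rpois(length(chl), chl * peak + bg) / peak, dims)
    ld <- array(rpois(length(ld), ld * peak + bg) / peak, dims)
  }

  truth <- data.frame(
    object_id = c(0L, seq_along(vols), length(vols) + 1L),
    type = c("cell", rep("ld", length(vols)), "plastid"),
    volume_um3 = c(estimate_cell_volume(W, L), vols, pl_vol),
    cx_um = c(ctr_um[1], centers[, 1] + ctr_um[1], pl_bary[1]),
    cy_um = c(ctr_um[2], centers[, 2] + ctr_um[2], pl_bary[2]),
    cz_um = c(ctr_um[3], centers[, 3] + ctr_um[3], pl_bary[3]),
    radius_um = c(NA, radii, NA),
    width_um = c(W, rep(NA, length(vols) + 1)),
    length_um = c(L, rep(NA, length(vols) + 1))
  )
  list(channels = list(thylakoid = chl, ld = ld),
       mask = mask,
       truth = truth,
       voxel_size_um = v,
       config = config)
}
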