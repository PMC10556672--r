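# 2D particle analysis on the probability map: connected components,
# shape descriptors (circularity, fitted ellipse, Feret diameter, aspect
# ratio, roundness, solidity), ecotype-specific filtering, and the
# prolate-spheroid volume estimate.

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Shape measurements of one particle from its pixel coordinates (1-based
# rows/cols) and the object's binary crop.
measure_particle <- function(coords, crop) {
  n <- nrow(coords)
  # ordered outer contour (0-based in the crop frame)
  oc <- EBImage::ocontour(crop)[[1]]
  cx <- oc[, 1] + 1
  cy <- oc[, 2] + 1
  m <- nrow(oc)
  if (m >= 2) {
    dx <- cx[c(2:m, 1)] - cx
    dy <- cy[c(2:m, 1)] - cy
    perim_px <- sum(sqrt(dx^2 + dy^2))
  } else {
    perim_px <- 4 # single-pixel object: unit-square boundary
  }
  # second-central-moment fitted ellipse, scaled to match the pixel area
  # (the source tool's "Fit ellipse" semantics); 1/12 is the variance of a
  # unit pixel, preventing degenerate single-row objects
  covm <- stats::cov(coords) * (n - 1) / n + diag(1 / 12, 2)
  ev <- eigen(covm, symmetric = TRUE)$values
  a0 <- 2 * sqrt(ev[1])
  b0 <- 2 * sqrt(ev[2])
  s <- sqrt(n / (pi * a0 * b0))
  major_px <- 2 * a0 * s
  minor_px <- 2 * b0 * s
  # Feret diameter: max pairwise distance over convex-hull contour points
  hull <- grDevices::chull(cx, cy)
  hx <- cx[hull]
  hy <- cy[hull]
  feret_px <- if (length(hull) >= 2) {
    sqrt(max(outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2))
  } else {
    1
  }
  # solidity: pixel area over convex hull of the pixel corners
  corn_x <- c(cx - 0.5, cx - 0.5, cx + 0.5, cx + 0.5)
  corn_y <- c(cy - 0.5, cy + 0.5, cy - 0.5, cy + 0.5)
  ch <- grDevices::chull(corn_x, corn_y)
  hull_area <- polygon_area(corn_x[ch], corn_y[ch])
  c(area_px = n, perim_px = perim_px, major_px = major_px,
    minor_px = minor_px, feret_px = feret_px,
    hull_area_px = max(hull_area, n))
}

#' Segment and measure particles from a cell-probability map
#'
#' Thresholds the probability map, labels connected components and measures
#' each particle: area, perimeter, circularity `4*pi*area/perimeter^2`,
#' second-moment fitted ellipse (area-matched), Feret diameter (maximum
#' caliper), aspect ratio (major/minor), roundness `4*area/(pi*major^2)`
#' and solidity (area / convex hull area). Width is the ellipse minor axis,
#' length the Feret diameter, and the estimated volume applies the
#' prolate-spheroid model to them.
#'
#' @param prob_map numeric matrix of per-pixel cell probabilities (or any
#'   2D map; a binary mask works too)
#' @param threshold probability threshold in (0, 1)
#' @param pixel_size_um pixel size, um
#' @param min_px discard components smaller than this many pixels (specks)
#' @return data.frame with one row per particle: label, area_um2,
#'   perimeter_um, circularity, ellipse_major_um, ellipse_minor_um,
#'   feret_um, AR, roundness, solidity, width_um, length_um, volume_um3,
#'   cx_um, cy_um
#' @export
segment_particles <- function(prob_map, threshold = 0.5, pixel_size_um,
                              min_px = 5) {
  stopifnot(threshold > 0, threshold < 1, pixel_size_um > 0)
  mask <- prob_map >= threshold
  labels <- label_components(mask, 8L)
  nlab <- max(labels)
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      ellipse_major_um = numeric(),
                      ellipse_minor_um = numeric(), feret_um = numeric(),
                      AR = numeric(), roundness = numeric(),
                      solidity = numeric(), width_um = numeric(),
                      length_um = numeric(), volume_um3 = numeric(),
                      cx_um = numeric(), cy_um = numeric())
  if (nlab == 0) return(empty)
  idx <- which(labels > 0)
  ord <- order(labels[idx])
  idx <- idx[ord]
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  starts <- c(1, which(diff(lab) != 0) + 1, length(lab) + 1)
  out <- vector("list", nlab)
  p <- pixel_size_um
  for (k in seq_len(nlab)) {
    sel <- starts[k]:(starts[k + 1] - 1)
    if (length(sel) < min_px) next
    co <- cbind(rows[sel], cols[sel])
    rr <- range(co[, 1])
    cr <- range(co[, 2])
    crop <- matrix(0L, diff(rr) + 1, diff(cr) + 1)
    crop[cbind(co[, 1] - rr[1] + 1, co[, 2] - cr[1] + 1)] <- 1L
    m <- measure_particle(cbind(co[, 1] - rr[1] + 1, co[, 2] - cr[1] + 1),
                          crop)
    area_um2 <- m[["area_px"]] * p^2
    width_um <- m[["minor_px"]] * p
    length_um <- m[["feret_px"]] * p
    out[[k]] <- data.frame(
      label = k,
      area_um2 = area_um2,
      perimeter_um = m[["perim_px"]] * p,
      circularity = 4 * pi * m[["area_px"]] / m[["perim_px"]]^2,
      ellipse_major_um = m[["major_px"]] * p,
      ellipse_minor_um = width_um,
      feret_um = length_um,
      AR = m[["major_px"]] / m[["minor_px"]],
      roundness = 4 * m[["area_px"]] / (pi * m[["major_px"]]^2),
      solidity = m[["area_px"]] / m[["hull_area_px"]],
      width_um = width_um,
      length_um = length_um,
      volume_um3 = estimate_cell_volume(width_um, length_um),
      cx_um = (mean(co[, 1]) - 0.5) * p,
      cy_um = (mean(co[, 2]) - 0.5) * p
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ecotype-specific particle filter configuration
#'
#' Defaults reproduce the reference screening: area 25-200 um^2,
#' circularity 0-0.4, then AR >= 3 / roundness <= 0.3 / solidity >= 0.55
#' for Pt1 and AR >= 3.5 / roundness <= 0.3 / solidity >= 0.5 for Pt4.
#'
#' @param ecotype "Pt1" or "Pt4"
#' @return list with `area_range`, `circularity_range`, `min_AR`,
#'   `max_roundness`, `min_solidity`
#' @export
ecotype_filter_config <- function(ecotype = c("Pt1", "Pt4")) {
  ecotype <- match.arg(ecotype)
  list(area_range = c(25, 200),
       circularity_range = c(0, 0.4),
       min_AR = if (ecotype == "Pt1") 3 else 3.5,
       max_roundness = 0.3,
       min_solidity = if (ecotype == "Pt1") 0.55 else 0.5)
}

#' Filter particles with the ecotype-specific shape screen
#'
#' Retains particles satisfying all five predicates: area and circularity
#' in range, AR at least `min_AR`, roundness at most `max_roundness`,
#' solidity at least `min_solidity`. Row order is preserved.
#'
#' @param particles data.frame from [segment_particles()]
#' @param config list from [ecotype_filter_config()]
#' @return filtered data.frame
#' @export
filter_cells <- function(particles, config) {
  stopifnot(all(c("area_um2", "circularity", "AR", "roundness",
                  "solidity") %in% names(particles)))
  keep <- particles$area_um2 >= config$area_range[1] &
    particles$area_um2 <= config$area_range[2] &
    particles$circularity >= config$circularity_range[1] &
    particles$circularity <= config$circularity_range[2] &
    particles$AR >= config$min_AR &
    particles$roundness <= config$max_roundness &
    particles$solidity >= config$min_solidity
  particles[keep, , drop = FALSE]
}
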