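# Synthetic brightfield scenes: dark fusiform cells on a light background,
# with debris blobs and bubble rings as distractors, and a ground-truth
# table of planted dimensions and prolate-spheroid volumes.

#' Generate a synthetic brightfield mosaic with ground truth
#'
#' Places `n_cells` spindle-shaped (tapered-end) dark cells at random
#' positions and orientations on a light background, together with soft
#' debris blobs and high-contrast bubble rings that the downstream shape
#' filters are expected to reject. The drawn outline is calibrated so that
#' its second-moment fitted-ellipse minor axis equals the recorded truth
#' width and its Feret diameter equals the truth length.
#'
#' @param config a [scene_config()]
#' @param image_size_px side length of the square image; computed from
#'   `n_cells` if NULL
#' @return list with `image` (matrix, intensities in 0..1), `truth`
#'   (data.frame: object_id, type, cx_um, cy_um, theta, width_um, length_um,
#'   volume_um3, radius_um), `cell_labels` and `distractor_labels` (integer
#'   matrices keyed by object_id), `pixel_size_um`, and `n_placed`, the
#'   number of cells successfully placed after bounded retries.
#' @export
generate_brightfield_mosaic <- function(config, image_size_px = NULL) {
  validate_scene_config(config)
  set.seed(config$seed)
  p <- config$pixel_size_um
  lmax <- config$length_range_um[2]
  if (is.null(image_size_px)) {
    side_um <- sqrt(max(config$n_cells, 4) * 620) + lmax
    image_size_px <- ceiling(side_um / p)
  }
  n <- image_size_px
  side_um <- n * p

  # --- placement -----------------------------------------------------------
  cells <- list()
  margin <- lmax / 2 + 1.5
  for (i in seq_len(config$n_cells)) {
    w <- runif(1, config$width_range_um[1], config$width_range_um[2])
    l <- runif(1, config$length_range_um[1], config$length_range_um[2])
    placed <- FALSE
    for (try in 1:60) {
      cx <- runif(1, margin, side_um - margin)
      cy <- runif(1, margin, side_um - margin)
      th <- runif(1, 0, pi)
      dirv <- c(cos(th), sin(th))
      p1 <- c(cx, cy) - l / 2 * dirv
      p2 <- c(cx, cy) + l / 2 * dirv
      ok <- TRUE
      for (c2 in cells) {
        d <- segment_distance(p1, p2, c2$p1, c2$p2)
        if (d < (w + c2$w) / 2 + 1.2) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        cells[[length(cells) + 1]] <-
          list(id = i, cx = cx, cy = cy, th = th, w = w, l = l,
               p1 = p1, p2 = p2)
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  n_placed <- length(cells)
  if (n_placed < config$n_cells) {
    message("placed ", n_placed, " of ", config$n_cells,
            " cells after bounded retries")
  }

  # --- distractors ---------------------------------------------------------
  distractors <- list()
  k <- 0
  add_distractor <- function(type, r_um) {
    cx <- runif(1, r_um + 1, side_um - r_um - 1)
    cy <- runif(1, r_um + 1, side_um - r_um - 1)
    k <<- k + 1
    distractors[[k]] <<- list(id = k, type = type, cx = cx, cy = cy, r = r_um)
  }
  for (i in seq_len(config$n_debris)) add_distractor("debris", runif(1, 1, 2.5))
  for (i in seq_len(config$n_bubbles)) add_distractor("bubble", runif(1, 2, 4))

  # --- render --------------------------------------------------------------
  xs <- (seq_len(n) - 0.5) * p
  img <- matrix(0.82, n, n) +
    outer(0.025 * xs / side_um, 0.02 * xs / side_um, `+`)
  cell_labels <- matrix(0L, n, n)
  distractor_labels <- matrix(0L, n, n)
  minor_factor <- spindle_minor_factor()
  edge <- p # soft-edge width, um

  for (ce in cells) {
    w_draw <- ce$w / minor_factor # max half-width so fitted minor == width
    # extend the drawn tips so the half-coverage point of the profile sits
    # at +/- L/2: the digitised Feret then matches the truth length
    half <- (ce$l / 2) / sqrt(1 - min(0.5, 0.5 * edge / w_draw))
    r_b <- half + 2
    ix <- which(abs(xs - ce$cx) <= r_b)
    iy <- which(abs(xs - ce$cy) <= r_b)
    if (!length(ix) || !length(iy)) next
    X <- outer(xs[ix] - ce$cx, rep(1, length(iy)))
    Y <- outer(rep(1, length(ix)), xs[iy] - ce$cy)
    u <- cos(ce$th) * X + sin(ce$th) * Y
    v <- -sin(ce$th) * X + cos(ce$th) * Y
    h <- spindle_halfwidth(u, half, w_draw)
    alpha <- pmin(1, pmax(0, (h - abs(v)) / edge + 0.5))
    # radial internal shading (darker midline, lighter flanks) so each
    # cell spans a range of intensities, as real brightfield cells do
    shade <- 0.31 + runif(1, -0.03, 0.03) +
      0.1 * pmin(1, (abs(v) / pmax(h, 0.1))^2)
    img[ix, iy] <- img[ix, iy] * (1 - alpha) + shade * alpha
    lab <- cell_labels[ix, iy]
    lab[alpha > 0.5] <- ce$id
    cell_labels[ix, iy] <- lab
  }

  for (dd in distractors) {
    r_b <- dd$r + 1.5
    ix <- which(abs(xs - dd$cx) <= r_b)
    iy <- which(abs(xs - dd$cy) <= r_b)
    if (!length(ix) || !length(iy)) next
    X <- outer(xs[ix] - dd$cx, rep(1, length(iy)))
    Y <- outer(rep(1, length(ix)), xs[iy] - dd$cy)
    rr <- sqrt(X^2 + Y^2)
    if (dd$type == "debris") {
      alpha <- exp(-rr^2 / (2 * (dd$r / 1.6)^2))
      img[ix, iy] <- img[ix, iy] - 0.35 * alpha
      lab <- distractor_labels[ix, iy]
      lab[alpha > 0.5] <- dd$id
      distractor_labels[ix, iy] <- lab
    } else {
      ring <- pmin(1, pmax(0, (0.35 - abs(rr - dd$r)) / edge + 0.5))
      inner <- pmin(1, pmax(0, (dd$r - 0.35 - rr) / edge + 0.5))
      img[ix, iy] <- img[ix, iy] * (1 - ring) + 0.15 * ring
      img[ix, iy] <- img[ix, iy] * (1 - 0.5 * inner) + 0.95 * 0.5 * inner
      lab <- distractor_labels[ix, iy]
      lab[ring > 0.5 | inner > 0.5] <- dd$id
      distractor_labels[ix, iy] <- lab
    }
  }

  img <- blur_gaussian(img, 0.6)
  if (config$noise_level > 0) {
    img <- img + matrix(rnorm(n * n, 0, 0.02 * config$noise_level), n, n)
  }
  img <- pmin(pmax(img, 0), 1) # img first so dim attributes survive

  # --- truth ---------------------------------------------------------------
  truth_cells <- if (n_placed) {
    data.frame(
      object_id = vapply(cells, `[[`, 0, "id"),
      type = "cell",
      cx_um = vapply(cells, `[[`, 0, "cx"),
      cy_um = vapply(cells, `[[`, 0, "cy"),
      theta = vapply(cells, `[[`, 0, "th"),
      width_um = vapply(cells, `[[`, 0, "w"),
      length_um = vapply(cells, `[[`, 0, "l"),
      radius_um = NA_real_
    )
  } else {
    data.frame(object_id = integer(), type = character(), cx_um = numeric(),
               cy_um = numeric(), theta = numeric(), width_um = numeric(),
               length_um = numeric(), radius_um = numeric())
  }
  if (nrow(truth_cells)) {
    truth_cells$volume_um3 <-
      estimate_cell_volume(truth_cells$width_um, truth_cells$length_um)
  } else {
    truth_cells$volume_um3 <- numeric()
  }
  truth_dist <- if (k) {
    data.frame(
      object_id = vapply(distractors, `[[`, 0, "id"),
      type = vapply(distractors, `[[`, "", "type"),
      cx_um = vapply(distractors, `[[`, 0, "cx"),
      cy_um = vapply(distractors, `[[`, 0, "cy"),
      theta = NA_real_, width_um = NA_real_, length_um = NA_real_,
      radius_um = vapply(distractors, `[[`, 0, "r"),
      volume_um3 = NA_real_
    )
  } else {
    truth_cells[0, ]
  }
  list(image = img,
       truth = rbind(truth_cells, truth_dist),
       cell_labels = cell_labels,
       distractor_labels = distractor_labels,
       pixel_size_um = p,
       n_placed = n_placed)
}
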