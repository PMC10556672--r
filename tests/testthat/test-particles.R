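prob_from_mask <- function(mask) mask * 0.9 + 0.05

test_that("an ideal disk is nearly circular and isotropic", {
  m <- disc_mask(c(64, 64), c(32, 32), 10)
  p <- segment_particles(prob_from_mask(m), 0.5, 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$circularity, 1, tolerance = 0.1)
  expect_equal(p$AR, 1, tolerance = 0.05)
})

test_that("an ideal ellipse recovers its axes, AR and Feret diameter", {
  xy <- expand.grid(x = 1:110, y = 1:50)
  m <- matrix(FALSE, 110, 50)
  inside <- ((xy$x - 50.5) / 30)^2 + ((xy$y - 20.5) / 5)^2 <= 1
  m[as.matrix(xy[inside, 1:2])] <- TRUE
  p <- segment_particles(prob_from_mask(m), 0.5, 1)
  expect_equal(p$AR, 6, tolerance = 0.05)
  expect_equal(p$feret_um, 60, tolerance = 0.03)
  expect_equal(p$ellipse_major_um, 60, tolerance = 0.05)
  expect_equal(p$ellipse_minor_um, 10, tolerance = 0.05)
})

test_that("a clean synthetic spindle recovers width and length", {
  cfg <- scene_config("Pt1", n_cells = 1, noise_level = 0,
                      width_range_um = c(4, 4), length_range_um = c(23, 23),
                      n_debris = 0, n_bubbles = 0, seed = 3)
  sim <- generate_brightfield_mosaic(cfg, image_size_px = 260)
  pr <- 1 - sim$image
  pr <- (pr - min(pr)) / diff(range(pr))
  p <- segment_particles(pr, 0.5, cfg$pixel_size_um, min_px = 50)
  p <- p[which.max(p$area_um2), ]
  expect_equal(p$width_um, 4, tolerance = 0.1)
  expect_equal(p$length_um, 23, tolerance = 0.05)
})

test_that("empty foreground yields an empty particle table, not an error", {
  p <- segment_particles(matrix(0.1, 30, 30), 0.5, 1)
  expect_equal(nrow(p), 0)
})

test_that("Feret diameter equals the brute-force boundary-pair maximum", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(FALSE, 48, 48)
    # random blob: union of a few discs
    for (k in 1:3) {
      m <- m | disc_mask(c(48, 48), c(runif(1, 15, 33), runif(1, 15, 33)),
                         runif(1, 4, 9))
    }
    lab <- label_components(m, 8L)
    m[lab != 1] <- FALSE # keep one component
    p <- segment_particles(prob_from_mask(m), 0.5, 1, min_px = 5)
    co <- which(m, arr.ind = TRUE)
    # boundary pixels: any pixel with a 4-neighbour outside
    pad <- matrix(FALSE, 50, 50)
    pad[2:49, 2:49] <- m
    inner <- pad[2:49, 2:49] & pad[1:48, 2:49] & pad[3:50, 2:49] &
      pad[2:49, 1:48] & pad[2:49, 3:50]
    bd <- which(m & !inner, arr.ind = TRUE)
    oracle <- sqrt(max(outer(bd[, 1], bd[, 1], `-`)^2 +
                         outer(bd[, 2], bd[, 2], `-`)^2))
    expect_equal(p$feret_um[which.max(p$area_um2)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("the ecotype screen applies all five predicates", {
  base <- data.frame(label = 1, area_um2 = 80, perimeter_um = 50,
                     circularity = 0.2, ellipse_major_um = 21,
                     ellipse_minor_um = 3.7, feret_um = 23, AR = 5.8,
                     roundness = 0.17, solidity = 0.8, width_um = 3.7,
                     length_um = 23, volume_um3 = 100, cx_um = 0, cy_um = 0)
  for (eco in c("Pt1", "Pt4")) {
    cfgf <- ecotype_filter_config(eco)
    expect_equal(nrow(filter_cells(base, cfgf)), 1) # spindle retained
    big <- base
    big$area_um2 <- 210 # above the 25-200 um^2 area window
    expect_equal(nrow(filter_cells(big, cfgf)), 0)
    round_debris <- base
    round_debris$circularity <- 0.9
    expect_equal(nrow(filter_cells(round_debris, cfgf)), 0)
    low_ar <- base
    low_ar$AR <- 2.0
    expect_equal(nrow(filter_cells(low_ar, cfgf)), 0)
    high_round <- base
    high_round$roundness <- 0.5
    expect_equal(nrow(filter_cells(high_round, cfgf)), 0)
    low_sol <- base
    low_sol$solidity <- 0.3
    expect_equal(nrow(filter_cells(low_sol, cfgf)), 0)
  }
  # Pt1 is stricter on solidity, Pt4 on AR
  mid <- base
  mid$solidity <- 0.52
  expect_equal(nrow(filter_cells(mid, ecotype_filter_config("Pt1"))), 0)
  expect_equal(nrow(filter_cells(mid, ecotype_filter_config("Pt4"))), 1)
  mid2 <- base
  mid2$AR <- 3.2
  expect_equal(nrow(filter_cells(mid2, ecotype_filter_config("Pt1"))), 1)
  expect_equal(nrow(filter_cells(mid2, ecotype_filter_config("Pt4"))), 0)
})

test_that("filtering is idempotent and preserves row order", {
  sim <- generate_brightfield_mosaic(scene_config("Pt1", n_cells = 10,
                                                  seed = 17))
  pr <- 1 - sim$image
  pr <- (pr - min(pr)) / diff(range(pr))
  parts <- segment_particles(pr, 0.55, sim$pixel_size_um)
  cfgf <- ecotype_filter_config("Pt1")
  once <- filter_cells(parts, cfgf)
  twice <- filter_cells(once, cfgf)
  expect_identical(once, twice)
  expect_true(!is.unsorted(once$label))
})

test_that("particle shape invariants hold on a segmented population", {
  sim <- generate_brightfield_mosaic(scene_config("Pt4", n_cells = 12,
                                                  seed = 23))
  pr <- 1 - sim$image
  pr <- (pr - min(pr)) / diff(range(pr))
  parts <- segment_particles(pr, 0.55, sim$pixel_size_um)
  expect_true(all(parts$area_um2 > 0))
  expect_true(all(parts$circularity > 0 & parts$circularity <= 1.1))
  expect_true(all(parts$AR >= 1))
  expect_true(all(parts$roundness > 0 & parts$roundness <= 1 + 1e-9))
  expect_true(all(parts$solidity > 0 & parts$solidity <= 1 + 1e-9))
  tol <- 2 * sim$pixel_size_um
  expect_true(all(parts$ellipse_minor_um <= parts$ellipse_major_um + tol))
  expect_true(all(parts$ellipse_major_um <= parts$feret_um + tol))
  expect_equal(parts$volume_um3,
               pi / 6 * parts$width_um^2 * parts$length_um)
})
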