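vox <- c(0.1, 0.1, 0.1)

test_that("preprocessing removes a constant baseline entirely", {
  const <- array(0.7, c(40, 40, 24))
  out <- preprocess_channel(const, channel_params("LD", "Pt1"), vox)
  expect_lt(max(out), 1e-10)
  expect_true(all(out >= 0))
})

test_that("a bright sphere on black survives preprocessing", {
  arr <- array(0, c(80, 80, 50))
  arr[sphere_mask(c(80, 80, 50), c(4, 4, 2.5), 0.9, vox)] <- 1
  out <- preprocess_channel(arr, channel_params("LD", "Pt1"), vox)
  expect_gt(sum(out), 0.9 * sum(arr)) # integrated intensity within 10%
})

test_that("smoothing spreads a point source with the requested sigma", {
  arr <- array(0, c(41, 41, 41))
  arr[21, 21, 21] <- 1
  p <- list(smooth_um = 0.3, background_um = 5, channel = "LD")
  out <- preprocess_channel(arr, p, vox, background_scale_factor = 10)
  w <- out[, 21, 21]
  mu <- sum(w * seq_len(41)) / sum(w)
  sdev <- sqrt(sum(w * (seq_len(41) - mu)^2) / sum(w)) * vox[1]
  expect_equal(sdev, 0.3, tolerance = 0.1)
})

test_that("sub-voxel smoothing scales warn and still run", {
  arr <- array(runif(8000), c(20, 20, 20))
  p <- list(smooth_um = 0.01, background_um = 0.5, channel = "LD")
  expect_warning(preprocess_channel(arr, p, vox), "minimal smoothing")
})

test_that("disjoint spheres give one label each", {
  d <- c(60, 30, 30)
  arr <- array(0, d)
  arr[sphere_mask(d, c(1.5, 1.5, 1.5), 0.6, vox)] <- 1
  arr[sphere_mask(d, c(4.5, 1.5, 1.5), 0.6, vox)] <- 1
  lab <- segment_objects(arr, 0.5, split_touching = FALSE,
                         voxel_size_um = vox)
  expect_equal(max(lab), 2)
})

test_that("touching spheres split with the watershed and merge without", {
  d <- c(60, 30, 30)
  r <- 0.6
  # centre distance for ~10% volume overlap
  frac <- vapply(seq(1.0, 1.9, 0.01) * r,
                 function(dd) sphere_overlap_fraction(r, dd), 0)
  dsep <- seq(1.0, 1.9, 0.01)[which.min(abs(frac - 0.10))] * r
  arr <- array(0, d)
  arr[sphere_mask(d, c(2.2, 1.5, 1.5), r, vox)] <- 1
  arr[sphere_mask(d, c(2.2 + dsep, 1.5, 1.5), r, vox)] <- 1
  split_lab <- segment_objects(arr, 0.5, split_touching = TRUE,
                               voxel_size_um = vox)
  merged_lab <- segment_objects(arr, 0.5, split_touching = FALSE,
                                voxel_size_um = vox)
  expect_equal(max(split_lab), 2)
  expect_equal(max(merged_lab), 1)
})

test_that("k planted spheres with <25% overlap return exactly k objects", {
  d <- c(100, 40, 40)
  r <- 0.5
  dsep <- 1.35 * r # overlap fraction ~11%, below 25%
  for (k in 2:5) {
    arr <- array(0, d)
    for (i in seq_len(k)) {
      arr[sphere_mask(d, c(1.2 + (i - 1) * dsep, 2, 2), r, vox)] <- 1
    }
    lab <- segment_objects(arr, 0.5, split_touching = TRUE,
                           voxel_size_um = vox)
    expect_equal(max(lab), k)
  }
})

test_that("a planted 1 um^3 sphere is recovered within 15%", {
  cfg <- scene_config("Pt1", ld_strategy = "many_medium", seed = 14)
  st <- generate_confocal_stack(cfg)
  trl <- st$truth[st$truth$type == "ld", ]
  pre <- preprocess_channel(st$channels$ld, channel_params("LD", "Pt1"),
                            st$voxel_size_um)
  lab <- segment_objects(pre, NULL, TRUE, st$voxel_size_um,
                         refine = "volume_matched")
  obj <- measure_objects(lab, st$voxel_size_um)
  m <- match_objects(obj$bx_um, obj$by_um, obj$bz_um,
                     trl$cx_um, trl$cy_um, trl$cz_um, max_dist = 0.5)
  big <- which(m$ok & trl$volume_um3[m$nearest] > 0.5)
  expect_gte(length(big), 1)
  rel <- abs(obj$volume_um3[big] - trl$volume_um3[m$nearest[big]]) /
    trl$volume_um3[m$nearest[big]]
  expect_true(all(rel <= 0.15))
})

test_that("objects outside the cell mask are removed by barycenter", {
  d <- c(60, 30, 30)
  arr <- array(0, d)
  arr[sphere_mask(d, c(1.5, 1.5, 1.5), 0.5, vox)] <- 1 # inside
  arr[sphere_mask(d, c(5, 1.5, 1.5), 0.4, vox)] <- 1   # outside
  cell <- sphere_mask(d, c(1.6, 1.5, 1.5), 1.3, vox)
  lab <- segment_objects(arr, 0.5, FALSE, vox)
  expect_equal(max(lab), 2)
  kept <- exclude_outside_cell(lab, cell)
  expect_equal(max(kept), 1)
  # all-inside case is the identity
  kept2 <- exclude_outside_cell(lab, array(TRUE, d))
  expect_identical(kept2, lab)
  # straddling object with barycenter inside is kept
  cell3 <- array(FALSE, d)
  cell3[1:16, , ] <- TRUE # boundary cuts the first sphere's edge
  expect_equal(max(exclude_outside_cell(lab, cell3)), 1)
})

test_that("volumes and barycenters follow the voxel-centre convention", {
  lab <- array(0L, c(10, 10, 10))
  lab[1, 1, 1] <- 1L
  m <- measure_objects(lab, c(0.1, 0.1, 0.1))
  expect_equal(m$volume_um3, 0.001)
  expect_equal(c(m$bx_um, m$by_um, m$bz_um), c(0.05, 0.05, 0.05))
  # two-voxel object along x: barycenter midway
  lab[2, 1, 1] <- 1L
  m2 <- measure_objects(lab, c(0.1, 0.1, 0.1))
  expect_equal(m2$bx_um, 0.1)
  # symmetric sphere: barycenter at the centre within half a voxel
  d <- c(40, 40, 40)
  sp <- sphere_mask(d, c(2, 2, 2), 0.8, vox)
  m3 <- measure_objects(array(as.integer(sp), d), vox)
  expect_true(all(abs(c(m3$bx_um, m3$by_um, m3$bz_um) - 2) < 0.05))
})

test_that("total object volume never exceeds the stack volume", {
  set.seed(30)
  arr <- array(runif(40 * 40 * 20), c(40, 40, 20))
  lab <- segment_objects(arr, 0.5, TRUE, vox, min_voxels = 1)
  m <- measure_objects(lab, vox)
  expect_lte(sum(m$volume_um3), prod(dim(arr)) * prod(vox))
})

test_that("the full stack analysis yields one thylakoid and located LDs", {
  cfg <- scene_config("Pt4", ld_strategy = "two_large_dominant", seed = 5)
  st <- generate_confocal_stack(cfg)
  rec <- analyze_cell_stack(st, "Pt4", cell_id = 7L)
  expect_s3_class(rec$lds, "data.frame")
  expect_equal(nrow(rec$thylakoid), 1)
  expect_equal(rec$cell_id, 7L)
  expect_true(all(rec$lds$distance_um >= 0))
  trl <- st$truth[st$truth$type == "ld", ]
  expect_equal(nrow(rec$lds), nrow(trl))
  expect_equal(sum(rec$lds$volume_um3), sum(trl$volume_um3),
               tolerance = 0.1)
})
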