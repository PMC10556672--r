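# The synthetic generators are first-class code: their ground truth must
# honour the configured study conditions (dimensions, LD strategies,
# geometry) and be bit-reproducible from the seed.

test_that("scene configuration enforces its invariants", {
  expect_error(scene_config("Pt1", width_range_um = c(5, 30),
                            length_range_um = c(10, 20)),
               "elongated")
  expect_error(scene_config("Pt1", voxel_size_um = c(0.1, 0.1, 0)))
  cfg <- scene_config("Pt4")
  expect_equal(cfg$width_range_um, c(4, 4.4))
  expect_equal(cfg$length_range_um, c(27.7, 28.6))
  expect_equal(cfg$voxel_size_um[3], 0.1)
})

test_that("an empty scene gives a background-only image and empty truth", {
  cfg <- scene_config("Pt1", n_cells = 0, n_debris = 0, n_bubbles = 0,
                      seed = 1)
  sim <- generate_brightfield_mosaic(cfg, image_size_px = 64)
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$cell_labels == 0))
  expect_true(all(sim$image > 0.5)) # light background only
})

test_that("brightfield generation is bit-identical under a fixed seed", {
  cfg <- scene_config("Pt1", n_cells = 8, seed = 7)
  a <- generate_brightfield_mosaic(cfg, image_size_px = 320)
  b <- generate_brightfield_mosaic(cfg, image_size_px = 320)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("truth volumes lie in the interval implied by the dimensions", {
  # evaluate the volume model at the interval endpoints:
  # pi/6 * 3.5^2 * 22.6 = 144.97 and pi/6 * 4^2 * 23.5 = 196.87
  cfg <- scene_config("Pt1", n_cells = 30, width_range_um = c(3.5, 4),
                      length_range_um = c(22.6, 23.5), seed = 12)
  sim <- generate_brightfield_mosaic(cfg)
  v <- sim$truth$volume_um3[sim$truth$type == "cell"]
  lo <- pi / 6 * 3.5^2 * 22.6
  hi <- pi / 6 * 4^2 * 23.5
  expect_equal(round(lo, 1), 145.0)
  expect_equal(round(hi, 1), 196.9)
  expect_true(all(v >= lo & v <= hi))
})

test_that("basal-only stacks contain only small LDs", {
  st <- generate_confocal_stack(scene_config("Pt1",
                                             ld_strategy = "basal_only",
                                             seed = 2))
  v <- st$truth$volume_um3[st$truth$type == "ld"]
  expect_true(all(v >= 0.005 & v <= 0.7))
})

test_that("LD strategy contracts hold on truth volumes", {
  for (seed in 1:5) {
    st <- generate_confocal_stack(
      scene_config("Pt4", ld_strategy = "two_large_dominant", seed = seed))
    v <- st$truth$volume_um3[st$truth$type == "ld"]
    expect_gte(fraction_two_largest(v), 85)
    expect_gte(sum(sort(v, decreasing = TRUE)[1:2]), 0.85 * sum(v))
    st2 <- generate_confocal_stack(
      scene_config("Pt1", ld_strategy = "many_medium", seed = seed))
    v2 <- st2$truth$volume_um3[st2$truth$type == "ld"]
    expect_lte(fraction_two_largest(v2), 75)
  }
})

test_that("LD centres lie inside the envelope; plastid sits on the axis", {
  for (seed in c(3, 8)) {
    st <- generate_confocal_stack(
      scene_config("Pt1", ld_strategy = "many_medium", seed = seed))
    trl <- st$truth[st$truth$type == "ld", ]
    vox <- cbind(ceiling(trl$cx_um / st$voxel_size_um[1]),
                 ceiling(trl$cy_um / st$voxel_size_um[2]),
                 ceiling(trl$cz_um / st$voxel_size_um[3]))
    expect_true(all(st$mask[vox]))
    # plastid barycenter sits on the cell's long axis (y = z = centre)
    pl <- st$truth[st$truth$type == "plastid", ]
    ctr <- dim(st$mask) * st$voxel_size_um / 2
    expect_lt(abs(pl$cy_um - ctr[2]), 0.15)
    expect_lt(abs(pl$cz_um - ctr[3]), 0.15)
  }
})

test_that("every rendered LD appears in the truth table and vice versa", {
  cfg <- scene_config("Pt1", ld_strategy = "many_medium", noise_level = 0,
                      psf_sigma_um = 0, seed = 6)
  st <- generate_confocal_stack(cfg)
  lab <- label_components(st$channels$ld >= 0.5)
  expect_equal(max(lab), sum(st$truth$type == "ld"))
})

test_that("noise-free voxelised spheres match the analytic volume", {
  # r >= 5 voxels, no blur, no noise
  cfg <- scene_config("Pt4", ld_strategy = "two_large_dominant",
                      noise_level = 0, psf_sigma_um = 0, seed = 9)
  st <- generate_confocal_stack(cfg)
  trl <- st$truth[st$truth$type == "ld", ]
  big <- trl[trl$radius_um >= 5 * max(st$voxel_size_um), ]
  lab <- label_components(st$channels$ld >= 0.5)
  obj <- measure_objects(lab, st$voxel_size_um)
  m <- match_objects(obj$bx_um, obj$by_um, obj$bz_um,
                     big$cx_um, big$cy_um, big$cz_um, max_dist = 0.3)
  hit <- which(m$ok)
  expect_gte(length(hit), 1)
  rel <- abs(obj$volume_um3[hit] - big$volume_um3[m$nearest[hit]]) /
    big$volume_um3[m$nearest[hit]]
  expect_true(all(rel <= 0.05))
})

test_that("confocal generation is reproducible and rejects impossible loads", {
  cfg <- scene_config("Pt1", ld_strategy = "basal_only", seed = 21)
  a <- generate_confocal_stack(cfg)
  b <- generate_confocal_stack(cfg)
  expect_identical(a$channels$ld, b$channels$ld)
  expect_identical(a$truth, b$truth)
  expect_error(generate_confocal_stack(
    scene_config("Pt1", ld_strategy = "two_large_dominant",
                 total_ld_volume_um3 = 500, seed = 1)),
    "capacity")
})

test_that("synthetic spectra invert to the requested concentrations", {
  flat <- generate_absorbance_spectrum(0, 0, 0)
  expect_true(all(flat$absorbance == 0))
  sp <- generate_absorbance_spectrum(2.0, 0.5)
  q <- quantify_pigments(sp)
  expect_equal(q$chl_a_ug_ml, 2.0, tolerance = 0.01)
  expect_equal(q$chl_c_ug_ml, 0.5, tolerance = 0.01)
  s1 <- generate_absorbance_spectrum(1, 1, noise = 0.01, seed = 5)
  s2 <- generate_absorbance_spectrum(1, 1, noise = 0.01, seed = 5)
  expect_identical(s1, s2)
  expect_error(generate_absorbance_spectrum(-1, 0), "non-negative")
})

test_that("growth curves follow the configured division rate", {
  g <- simulate_growth_curve(1e5, 0.73, days = 0:7)
  expect_equal(division_rate(g$density_cells_ml[1], g$density_cells_ml[8],
                             7), 0.73)
})
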