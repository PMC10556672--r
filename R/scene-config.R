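#' Configuration of a synthetic microscopy scene
#'
#' Bundles the parameters shared by the brightfield and confocal generators:
#' ecotype-specific cell dimensions, the LD placement strategy, sampling
#' geometry and noise. Defaults emulate the measured population ranges of the
#' two ecotypes (Pt1 width 3.5-4 um, length 22.6-23.5 um; Pt4 width 4-4.4 um,
#' length 27.7-28.6 um) and the acquisition geometry (z step 0.1 um).
#'
#' @param ecotype "Pt1" or "Pt4"
#' @param n_cells number of cells to place (>= 0; 0 gives a background-only
#'   scene)
#' @param width_range_um cell width interval, um; ecotype default if NULL
#' @param length_range_um cell length interval, um; ecotype default if NULL
#' @param ld_strategy LD population strategy: "basal_only" (small LDs only,
#'   N-replete-like), "two_large_dominant" (two LDs holding >= 85% of LD
#'   volume plus a basal set; Pt4-like), "many_medium" (more equal
#'   repartition; Pt1-like), "fragmented_distant" (many small LDs far from
#'   the plastid; post-resupply-like)
#' @param total_ld_volume_um3 target per-cell total LD volume; strategy
#'   default if NULL
#' @param pixel_size_um brightfield pixel size (default 0.23, typical for a
#'   x50 objective with 0.5 tube-lens magnification)
#' @param voxel_size_um confocal voxel size (x, y, z); default
#'   c(0.072, 0.072, 0.1)
#' @param psf_sigma_um Gaussian point-spread sigma per axis applied to
#'   confocal channels; 0 disables blurring
#' @param noise_level dimensionless noise scale; 0 disables noise
#' @param n_debris,n_bubbles distractor counts in brightfield scenes;
#'   defaults scale with `n_cells`
#' @param seed integer seed controlling all randomness of the generators
#' @return a `scene_config` list
#' @export
scene_config <- function(ecotype = c("Pt1", "Pt4"),
                         n_cells = 25,
                         width_range_um = NULL,
                         length_range_um = NULL,
                         ld_strategy = c("basal_only", "two_large_dominant",
                                         "many_medium", "fragmented_distant"),
                         total_ld_volume_um3 = NULL,
                         pixel_size_um = 0.23,
                         voxel_size_um = c(0.072, 0.072, 0.1),
                         psf_sigma_um = c(0.1, 0.1, 0.15),
                         noise_level = 1,
                         n_debris = NULL,
                         n_bubbles = NULL,
                         seed = 1L) {
  ecotype <- match.arg(ecotype)
  ld_strategy <- match.arg(ld_strategy)
  if (is.null(width_range_um)) {
    width_range_um <- if (ecotype == "Pt1") c(3.5, 4) else c(4, 4.4)
  }
  if (is.null(length_range_um)) {
    length_range_um <- if (ecotype == "Pt1") c(22.6, 23.5) else c(27.7, 28.6)
  }
  if (is.null(total_ld_volume_um3)) {
    total_ld_volume_um3 <- switch(ld_strategy,
      basal_only = 0.45,
      two_large_dominant = 8.7,
      many_medium = 6.2,
      fragmented_distant = 3.0)
  }
  if (is.null(n_debris)) n_debris <- max(0L, round(0.15 * n_cells))
  if (is.null(n_bubbles)) n_bubbles <- max(0L, round(0.1 * n_cells))

  cfg <- list(ecotype = ecotype, n_cells = as.integer(n_cells),
              width_range_um = as.numeric(width_range_um),
              length_range_um = as.numeric(length_range_um),
              ld_strategy = ld_strategy,
              total_ld_volume_um3 = total_ld_volume_um3,
              pixel_size_um = pixel_size_um,
              voxel_size_um = as.numeric(voxel_size_um),
              psf_sigma_um = rep(as.numeric(psf_sigma_um), length.out = 3),
              noise_level = noise_level,
              n_debris = as.integer(n_debris),
              n_bubbles = as.integer(n_bubbles),
              seed = as.integer(seed))
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$n_cells >= 0,
    length(cfg$width_range_um) == 2, length(cfg$length_range_um) == 2,
    all(cfg$width_range_um > 0), all(cfg$length_range_um > 0),
    diff(cfg$width_range_um) >= 0, diff(cfg$length_range_um) >= 0,
    cfg$pixel_size_um > 0,
    length(cfg$voxel_size_um) == 3, all(cfg$voxel_size_um > 0),
    cfg$noise_level >= 0, cfg$seed < 2^31
  )
  if (cfg$width_range_um[2] >= cfg$length_range_um[1]) {
    stop("fusiform cells are elongated: width range must lie below the ",
         "length range")
  }
  invisible(cfg)
}
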