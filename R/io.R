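# Readers and writers (TIFF stacks with JSON sidecars, spectra, tidy CSVs)
# and the pipeline driver chaining simulate -> segment -> metrics -> stats.
# Channel order and voxel sizes travel in a JSON sidecar rather than TIFF
# tags (dialect-proof); intensities are stored normalised with the scale in
# the sidecar.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a two-channel confocal stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-major (all z of channel 1, then channel 2). The
#' sidecar records channel names, dimensions, voxel sizes and the intensity
#' scale used for normalisation.
#'
#' @param stack list with `channels` (named list of 3D arrays),
#'   `voxel_size_um`, optionally `mask`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_confocal_stack <- function(stack, path) {
  ch <- stack$channels
  d <- dim(ch[[1]])
  scale <- max(1e-12, max(vapply(ch, max, 0)))
  pages <- list()
  for (nm in names(ch)) {
    a <- ch[[nm]] / scale
    for (z in seq_len(d[3])) pages[[length(pages) + 1]] <- a[, , z]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!is.null(stack$mask)) {
    mask_pages <- lapply(seq_len(d[3]), function(z) {
      matrix(as.numeric(stack$mask[, , z]), d[1], d[2])
    })
    tiff::writeTIFF(mask_pages, paste0(path, ".mask.tif"),
                    bits.per.sample = 8L)
  }
  meta <- list(channels = names(ch), dims = d,
               voxel_size_um = stack$voxel_size_um,
               intensity_scale = scale,
               has_mask = !is.null(stack$mask))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a confocal stack written by [write_confocal_stack()]
#'
#' @param path TIFF path (the `.json` sidecar must sit next to it)
#' @return list with `channels`, `mask` (or NULL), `voxel_size_um`
#' @export
read_confocal_stack <- function(path) {
  meta <- tryCatch(jsonlite::read_json(sidecar_path(path),
                                       simplifyVector = TRUE),
                   error = function(e) {
                     stop("cannot read sidecar for '", path, "': ",
                          conditionMessage(e))
                   })
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("corrupted or unreadable TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  d <- as.integer(meta$dims)
  nz <- d[3]
  channels <- list()
  for (i in seq_along(meta$channels)) {
    a <- array(0, d)
    for (z in seq_len(nz)) a[, , z] <- pages[[(i - 1) * nz + z]]
    channels[[meta$channels[i]]] <- a * meta$intensity_scale
  }
  mask <- NULL
  if (isTRUE(meta$has_mask)) {
    mp <- tiff::readTIFF(paste0(path, ".mask.tif"), all = TRUE)
    mask <- array(FALSE, d)
    for (z in seq_len(nz)) mask[, , z] <- mp[[z]] > 0.5
  }
  list(channels = channels, mask = mask,
       voxel_size_um = as.numeric(meta$voxel_size_um))
}

#' Write a brightfield image as TIFF plus JSON sidecar
#' @param image numeric matrix in 0..1
#' @param path output path
#' @param pixel_size_um pixel size recorded in the sidecar
#' @return `path`, invisibly
#' @export
write_brightfield_tiff <- function(image, path, pixel_size_um) {
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a brightfield image written by [write_brightfield_tiff()]
#' @param path TIFF path
#' @return list with `image`, `pixel_size_um`
#' @export
read_brightfield_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) {
                    stop("corrupted or unreadable TIFF '", path, "': ",
                         conditionMessage(e))
                  })
  list(image = img, pixel_size_um = as.numeric(meta$pixel_size_um))
}

#' Read / write a two-column absorbance spectrum CSV
#' @param path CSV path (columns `wavelength_nm`, `absorbance`)
#' @return data.frame
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("wavelength_nm", "absorbance") %in% names(df)))
  df
}

#' @rdname read_spectrum_csv
#' @param spectrum data.frame to write
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(spectrum, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if missing)
#' @param seed master seed; per-stage seeds are derived from it
#' @param ecotypes ecotypes to simulate and analyse
#' @param n_cells_2d cells per brightfield scene
#' @param n_stacks confocal stacks (cells) per ecotype
#' @param strategies named LD strategy per ecotype
#' @param noise_level generator noise level
#' @return a `run_config` list
#' @export
run_config <- function(out_dir = tempfile("ldscope_run_"), seed = 1L,
                       ecotypes = c("Pt1", "Pt4"), n_cells_2d = 30,
                       n_stacks = 3,
                       strategies = c(Pt1 = "many_medium",
                                      Pt4 = "two_large_dominant"),
                       noise_level = 1) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 ecotypes = ecotypes, n_cells_2d = n_cells_2d,
                 n_stacks = n_stacks, strategies = strategies,
                 noise_level = noise_level,
                 provenance = c(
                   area_filter = "published protocol default: 25-200 um2",
                   circularity_filter = "published protocol default: 0-0.4",
                   shape_screen = paste("published protocol default: AR,",
                                        "roundness, solidity per ecotype"),
                   channel_params = paste("published modelling defaults:",
                                          "smooth/background per channel"),
                   z_step = "published acquisition default: 0.1 um")),
            class = "run_config")
}

run_stage <- function(name, manifest, fun) {
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$stages <- c(manifest$stages, name)
  manifest$results[[name]] <- res
  manifest
}

#' Run the full synthetic pipeline
#'
#' Chains the six stages - brightfield simulation, 2D morphometry,
#' confocal simulation, 3D object modelling, LD metrics, and group
#' statistics - writing each stage's tidy CSV outputs under
#' `config$out_dir` together with a JSON run manifest (stage list, seeds,
#' configuration, package version). Re-running with the same configuration
#' reproduces all CSV outputs bit-identically.
#'
#' @param config a [run_config()]
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(package_version = as.character(utils::packageVersion("ldscope")),
              seed = config$seed, config = unclass(config)[
                c("seed", "ecotypes", "n_cells_2d", "n_stacks",
                  "strategies", "noise_level", "provenance")],
              stages = character(), results = list())

  man <- run_stage("simulate_brightfield", man, function() {
    out <- list()
    for (i in seq_along(config$ecotypes)) {
      eco <- config$ecotypes[i]
      cfg <- scene_config(eco, n_cells = config$n_cells_2d,
                          noise_level = config$noise_level,
                          seed = config$seed + 100L * i)
      sim <- generate_brightfield_mosaic(cfg)
      tif <- file.path(config$out_dir, paste0("brightfield_", eco, ".tif"))
      write_brightfield_tiff(sim$image, tif, sim$pixel_size_um)
      write.csv(sim$truth, file.path(config$out_dir,
                                     paste0("truth_2d_", eco, ".csv")),
                row.names = FALSE)
      out[[eco]] <- sim
    }
    out
  })

  man <- run_stage("morphometry_2d", man, function() {
    sims <- man$results$simulate_brightfield
    cells <- list()
    for (eco in config$ecotypes) {
      sim <- sims[[eco]]
      feats <- compute_pixel_features(sim$image)
      labels <- annotate_training_pixels(sim, seed = config$seed)
      clf <- train_pixel_classifier(feats, labels, seed = config$seed)
      prob <- predict_cell_probability(clf, feats)
      parts <- segment_particles(prob, 0.5, sim$pixel_size_um)
      kept <- filter_cells(parts, ecotype_filter_config(eco))
      kept$ecotype <- if (nrow(kept)) eco else character(0)
      write.csv(kept, file.path(config$out_dir,
                                paste0("cells_2d_", eco, ".csv")),
                row.names = FALSE)
      cells[[eco]] <- kept
    }
    cells
  })

  man <- run_stage("simulate_stacks", man, function() {
    paths <- list()
    for (eco in config$ecotypes) {
      for (j in seq_len(config$n_stacks)) {
        cfg <- scene_config(eco, ld_strategy = config$strategies[[eco]],
                            noise_level = config$noise_level,
                            seed = config$seed + 1000L * j +
                              10L * match(eco, config$ecotypes))
        st <- generate_confocal_stack(cfg)
        tif <- file.path(config$out_dir,
                         sprintf("stack_%s_%02d.tif", eco, j))
        write_confocal_stack(st, tif)
        write.csv(st$truth,
                  file.path(config$out_dir,
                            sprintf("truth_3d_%s_%02d.csv", eco, j)),
                  row.names = FALSE)
        paths[[length(paths) + 1]] <- list(ecotype = eco, path = tif,
                                           cell_id = j)
      }
    }
    paths
  })

  man <- run_stage("objects_3d", man, function() {
    records <- list()
    rows <- list()
    for (entry in man$results$simulate_stacks) {
      st <- read_confocal_stack(entry$path)
      rec <- analyze_cell_stack(st, entry$ecotype, cell_id = entry$cell_id)
      records[[length(records) + 1]] <- rec
      lds <- rec$lds
      if (nrow(lds)) {
        lds$cell_id <- rec$cell_id
        lds$ecotype <- rec$ecotype
        rows[[length(rows) + 1]] <- lds
      }
    }
    objects <- if (length(rows)) do.call(rbind, rows) else data.frame()
    write.csv(objects, file.path(config$out_dir, "objects_3d.csv"),
              row.names = FALSE)
    records
  })

  man <- run_stage("ld_metrics", man, function() {
    records <- man$results$objects_3d
    rows <- do.call(rbind, lapply(records, cell_ld_metrics,
                                  timepoint = "synthetic"))
    write.csv(rows, file.path(config$out_dir, "ld_metrics.csv"),
              row.names = FALSE)
    groups <- do.call(rbind, lapply(split(rows, rows$ecotype),
                                    summarize_group))
    write.csv(groups, file.path(config$out_dir, "ld_group_summary.csv"),
              row.names = FALSE)
    list(rows = rows, groups = groups)
  })

  man <- run_stage("stats", man, function() {
    rows <- man$results$ld_metrics$rows
    out <- data.frame()
    sp <- split(rows$total_ld_volume_um3, rows$ecotype)
    if (length(sp) == 2 && all(lengths(sp) >= 2)) {
      pt <- pair_test(sp[[1]], sp[[2]])
      out <- data.frame(test = "t_test_total_ld_volume",
                        groups = paste(names(sp), collapse = " vs "),
                        t = pt$t, p = pt$p, code = pt$code)
    }
    write.csv(out, file.path(config$out_dir, "stats.csv"),
              row.names = FALSE)
    out
  })

  manifest <- man[c("package_version", "seed", "config", "stages")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}
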