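# Shared synthetic batches at study scale, computed once per test session
# (they back several acceptance checks).

# 200 Pt1 cells across 8 brightfield scenes with distractors; classifier
# trained on ~20% of the cells of the first scene only.
acceptance_2d_batch <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n_scenes <- 8L
    scenes <- lapply(seq_len(n_scenes), function(i) {
      generate_brightfield_mosaic(scene_config("Pt1", n_cells = 25,
                                               seed = 200L + i))
    })
    feats1 <- compute_pixel_features(scenes[[1]]$image)
    labels1 <- annotate_training_pixels(scenes[[1]], fraction_cells = 0.2,
                                        seed = 99L)
    clf <- train_pixel_classifier(feats1, labels1, seed = 99L)

    res <- list()
    for (i in seq_len(n_scenes)) {
      sim <- scenes[[i]]
      feats <- if (i == 1) feats1 else compute_pixel_features(sim$image)
      prob <- predict_cell_probability(clf, feats)
      parts <- segment_particles(prob, 0.5, sim$pixel_size_um)
      kept <- filter_cells(parts, ecotype_filter_config("Pt1"))
      tr_c <- sim$truth[sim$truth$type == "cell", ]
      tr_d <- sim$truth[sim$truth$type != "cell", ]
      m <- match_objects(kept$cx_um, kept$cy_um, 0,
                         tr_c$cx_um, tr_c$cy_um, 0, max_dist = 3)
      matched <- m$ok
      dd <- sqrt(outer(kept$cx_um, tr_d$cx_um, `-`)^2 +
                   outer(kept$cy_um, tr_d$cy_um, `-`)^2)
      dist_hit <- if (nrow(tr_d) && nrow(kept)) {
        apply(dd, 2, min) < tr_d$radius_um + 1
      } else {
        rep(FALSE, nrow(tr_d))
      }
      res[[i]] <- list(
        n_planted = nrow(tr_c),
        n_recovered = length(unique(m$nearest[matched])),
        n_distractors = nrow(tr_d),
        n_distractors_kept = sum(dist_hit),
        rel_err = abs(kept$volume_um3[matched] -
                        tr_c$volume_um3[m$nearest[matched]]) /
          tr_c$volume_um3[m$nearest[matched]],
        width = kept$width_um[matched],
        length = kept$length_um[matched],
        held_out_acc = if (i > 1) {
          mean(prob[sim$cell_labels > 0] >= 0.5)
        } else {
          NA_real_
        }
      )
    }
    cache <<- list(
      n_planted = sum(vapply(res, `[[`, 0, "n_planted")),
      n_recovered = sum(vapply(res, `[[`, 0, "n_recovered")),
      n_distractors = sum(vapply(res, `[[`, 0, "n_distractors")),
      n_distractors_kept = sum(vapply(res, `[[`, 0, "n_distractors_kept")),
      rel_err = unlist(lapply(res, `[[`, "rel_err")),
      width = unlist(lapply(res, `[[`, "width")),
      length = unlist(lapply(res, `[[`, "length")),
      held_out_acc = mean(vapply(res, `[[`, 0, "held_out_acc"),
                          na.rm = TRUE))
    cache
  }
})

# 30 confocal stacks: 10 per LD strategy (Pt4 two_large_dominant, Pt1
# many_medium, Pt1 fragmented_distant), analysed end to end.
acceptance_3d_batch <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    plan <- data.frame(
      strategy = rep(c("two_large_dominant", "many_medium",
                       "fragmented_distant"), each = 10),
      seed = 300L + 1:30)
    plan$ecotype <- ifelse(plan$strategy == "two_large_dominant",
                           "Pt4", "Pt1")
    rows <- vector("list", nrow(plan))
    perld_err <- c()
    bary_err_vox <- c()
    dist_oracle_dev <- c()
    distant_flags <- list()
    for (i in seq_len(nrow(plan))) {
      cfg <- scene_config(plan$ecotype[i], ld_strategy = plan$strategy[i],
                          seed = plan$seed[i])
      st <- generate_confocal_stack(cfg)
      rec <- analyze_cell_stack(st, plan$ecotype[i], cell_id = i)
      trl <- st$truth[st$truth$type == "ld", ]
      m <- match_objects(rec$lds$bx_um, rec$lds$by_um, rec$lds$bz_um,
                         trl$cx_um, trl$cy_um, trl$cz_um, max_dist = 0.6)
      ok <- m$ok
      perld_err <- c(perld_err,
                     abs(rec$lds$volume_um3[ok] -
                           trl$volume_um3[m$nearest[ok]]) /
                       trl$volume_um3[m$nearest[ok]])
      bary_err_vox <- c(bary_err_vox,
                        m$dist[ok] / max(st$voxel_size_um))
      # Euclidean-distance oracle: direct formula evaluation
      oracle <- sqrt((rec$lds$bx_um - rec$thylakoid$bx_um)^2 +
                       (rec$lds$by_um - rec$thylakoid$by_um)^2 +
                       (rec$lds$bz_um - rec$thylakoid$bz_um)^2)
      dist_oracle_dev <- c(dist_oracle_dev,
                           abs(rec$lds$distance_um - oracle))
      distant_flags[[i]] <- rec$lds$distance_um > 5
      rows[[i]] <- data.frame(
        strategy = plan$strategy[i],
        n_true = nrow(trl),
        n_meas = nrow(rec$lds),
        total_rel_err = abs(sum(rec$lds$volume_um3) -
                              sum(trl$volume_um3)) / sum(trl$volume_um3),
        frac2_meas = if (nrow(rec$lds) >= 2) {
          fraction_two_largest(rec$lds$volume_um3)
        } else {
          NA_real_
        },
        n_thylakoid = nrow(rec$thylakoid),
        thy_rel_err = abs(rec$thylakoid$volume_um3 -
                            st$truth$volume_um3[st$truth$type == "plastid"]) /
          st$truth$volume_um3[st$truth$type == "plastid"]
      )
    }
    cache <<- list(per_stack = do.call(rbind, rows),
                   perld_err = perld_err,
                   bary_err_vox = bary_err_vox,
                   dist_oracle_dev = dist_oracle_dev,
                   distant_fragmented = unlist(
                     distant_flags[plan$strategy == "fragmented_distant"]))
    cache
  }
})
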