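# Per-cell and per-group LD statistics: counts, total volume, the fraction
# of LD volume in the two largest droplets (inequality-of-distribution
# indicator), size and distance classes, group summaries and the derived
# report quantities.

#' Fraction of total LD volume held by the two largest LDs
#'
#' Returns `100 * (sum of the two largest volumes) / (sum of all volumes)`,
#' tending to 100 when lipids concentrate in only two droplets and lower for
#' a more equal repartition. Scale-invariant, and exactly 100 when there are
#' only two droplets.
#'
#' @param volumes numeric vector of per-LD volumes, um^3 (>= 2 values, all
#'   positive)
#' @return percentage in (0, 100]
#' @export
fraction_two_largest <- function(volumes) {
  if (length(volumes) < 2) {
    stop("fraction_two_largest is undefined for fewer than 2 LDs")
  }
  if (any(volumes <= 0)) stop("all LD volumes must be positive")
  100 * sum(sort(volumes, decreasing = TRUE)[1:2]) / sum(volumes)
}

#' Classify LD volumes into the basal-small and large populations
#'
#' The basal population spans 0.005-0.7 um^3; the 0.7 um^3 boundary is
#' inclusive. Volumes below 0.005 um^3 are flagged as sub-detection via the
#' `sub_detection` attribute.
#'
#' @param volume numeric vector of volumes, um^3 (> 0)
#' @return character vector in {"basal_small", "large"} with a logical
#'   `sub_detection` attribute
#' @export
classify_ld_size <- function(volume) {
  stopifnot(all(volume > 0))
  out <- ifelse(volume <= 0.7, "basal_small", "large")
  attr(out, "sub_detection") <- volume < 0.005
  out
}

#' Classify LD-plastid distances as close or distant
#'
#' Close means at most 5 um from the plastid barycenter (inclusive);
#' distant means strictly greater.
#'
#' @param d numeric distances, um (>= 0)
#' @return character vector in {"close", "distant"}
#' @export
classify_distance <- function(d) {
  stopifnot(all(d >= 0))
  ifelse(d <= 5, "close", "distant")
}

#' Per-cell LD metrics row from a 3D cell record
#'
#' @param record a `cell_record_3d` from [analyze_cell_stack()]
#' @param timepoint label stored in the row
#' @param min_lds_for_fraction minimum LD count for the two-largest fraction
#'   (cells below it get NA there, mirroring the at-least-3-LDs restriction)
#' @return one-row data.frame: cell_id, ecotype, timepoint, ld_count,
#'   total_ld_volume_um3, mean_ld_volume_um3, fraction_two_largest_pct,
#'   thylakoid_volume_um3, n_close, n_distant
#' @export
cell_ld_metrics <- function(record, timepoint = NA_character_,
                            min_lds_for_fraction = 3) {
  stopifnot(inherits(record, "cell_record_3d"))
  vols <- record$lds$volume_um3
  n <- length(vols)
  frac <- if (n >= max(2, min_lds_for_fraction)) {
    fraction_two_largest(vols)
  } else {
    NA_real_
  }
  dcl <- if (n) classify_distance(record$lds$distance_um) else character()
  data.frame(
    cell_id = record$cell_id,
    ecotype = record$ecotype,
    timepoint = timepoint,
    ld_count = n,
    total_ld_volume_um3 = sum(vols),
    mean_ld_volume_um3 = if (n) mean(vols) else 0,
    fraction_two_largest_pct = frac,
    thylakoid_volume_um3 = if (nrow(record$thylakoid)) {
      record$thylakoid$volume_um3
    } else {
      NA_real_
    },
    n_close = sum(dcl == "close"),
    n_distant = sum(dcl == "distant")
  )
}

#' Summarise per-cell LD metrics for one group (ecotype x timepoint)
#'
#' Means and sample standard deviations of LD count, total LD volume,
#' thylakoid volume and cell volume (where present), plus the individual
#' mean LD volume `V_Lipid/LD` defined as the ratio of group means,
#' `mean(total LD volume) / mean(LD count)` - the definition that
#' reproduces the published per-group values. No dispersion is reported for
#' this ratio because none follows from the per-cell data.
#'
#' @param rows data.frame of per-cell rows ([cell_ld_metrics()] output,
#'   optionally with a `cell_volume_um3` column)
#' @return one-row data.frame of group summaries
#' @export
summarize_group <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  grab <- function(col) {
    if (col %in% names(rows)) rows[[col]] else NA_real_
  }
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sd_or_na <- function(x) if (all(is.na(x))) NA_real_ else sd(x, na.rm = TRUE)
  lc <- grab("ld_count")
  vl <- grab("total_ld_volume_um3")
  data.frame(
    ecotype = if ("ecotype" %in% names(rows)) rows$ecotype[1] else NA,
    timepoint = if ("timepoint" %in% names(rows)) rows$timepoint[1] else NA,
    n_cells = nrow(rows),
    ld_count_mean = mean_or_na(lc), ld_count_sd = sd_or_na(lc),
    total_ld_volume_mean = mean_or_na(vl), total_ld_volume_sd = sd_or_na(vl),
    thylakoid_volume_mean = mean_or_na(grab("thylakoid_volume_um3")),
    thylakoid_volume_sd = sd_or_na(grab("thylakoid_volume_um3")),
    cell_volume_mean = mean_or_na(grab("cell_volume_um3")),
    cell_volume_sd = sd_or_na(grab("cell_volume_um3")),
    v_lipid_per_ld = mean_or_na(vl) / mean_or_na(lc)
  )
}

#' Individual mean LD volume from group means
#'
#' `V_Lipid/LD = mean total LD volume / mean LD count`, displayed to two
#' decimals in the reference tables.
#'
#' @param vlipid_mean group mean total LD volume, um^3/cell
#' @param ld_count_mean group mean LD count per cell
#' @return um^3/LD (unrounded); vectorised
#' @export
v_lipid_per_ld <- function(vlipid_mean, ld_count_mean) {
  stopifnot(all(ld_count_mean > 0))
  vlipid_mean / ld_count_mean
}

#' Derived report: LD share of cell volume, volume changes, ecotype ratio
#'
#' From per-group summaries computes (a) the LD percentage of cell volume,
#' `100 * mean total LD volume / mean cell volume`; (b) the change in mean
#' total LD volume and in mean cell volume between two timepoints; (c) the
#' between-ecotype cell volume ratio `100 * mean(Pt4) / mean(Pt1)` at a
#' reference timepoint. Missing group keys yield NA entries rather than
#' being skipped.
#'
#' @param groups data.frame with columns `ecotype`, `timepoint`,
#'   `total_ld_volume_mean`, `cell_volume_mean` (e.g. rbind of
#'   [summarize_group()] rows or [reference_group_means()])
#' @param from,to timepoints for the change computations
#' @param ratio_at timepoint for the ecotype volume ratio
#' @return list with `ld_pct_of_cell_volume` (data.frame), `ld_volume_change`
#'   (data.frame, um^3), `cell_volume_change` (data.frame, um^3), and
#'   `ecotype_volume_ratio_pct` (scalar)
#' @export
derived_report <- function(groups, from = "D0", to = "D11",
                           ratio_at = "D0") {
  pick <- function(eco, tp, col) {
    i <- which(groups$ecotype == eco & groups$timepoint == tp)
    if (!length(i)) NA_real_ else groups[[col]][i[1]]
  }
  ecos <- unique(groups$ecotype)
  pct <- data.frame(
    ecotype = rep(ecos, each = 2),
    timepoint = rep(c(from, to), length(ecos)))
  pct$ld_pct_of_cell_volume <- mapply(function(e, tp) {
    100 * pick(e, tp, "total_ld_volume_mean") / pick(e, tp, "cell_volume_mean")
  }, pct$ecotype, pct$timepoint)
  ldch <- data.frame(ecotype = ecos)
  ldch$ld_volume_change_um3 <- vapply(ecos, function(e) {
    pick(e, to, "total_ld_volume_mean") - pick(e, from, "total_ld_volume_mean")
  }, 0)
  cvch <- data.frame(ecotype = ecos)
  cvch$cell_volume_change_um3 <- vapply(ecos, function(e) {
    pick(e, to, "cell_volume_mean") - pick(e, from, "cell_volume_mean")
  }, 0)
  ratio <- 100 * pick("Pt4", ratio_at, "cell_volume_mean") /
    pick("Pt1", ratio_at, "cell_volume_mean")
  list(ld_pct_of_cell_volume = pct,
       ld_volume_change = ldch,
       cell_volume_change = cvch,
       ecotype_volume_ratio_pct = ratio)
}

#' Published reference group summaries for the two ecotypes
#'
#' Per-group means and standard deviations of LD count and total LD volume
#' (V_Lipid), the displayed individual mean LD volume (V_Lipid/LD), and the
#' mean cell volumes, for Pt1 and Pt4 across the nitrogen-starvation (D0,
#' D3, D7, D11) and resupply (h24, h72) time course, as printed in the
#' reference study of these ecotypes. Cell-volume means are only printed for
#' D0, D11 and h24. Used for desk-check consistency tests and the derived
#' report.
#'
#' @return data.frame with one row per ecotype x timepoint
#' @export
reference_group_means <- function() {
  tp <- c("D0", "D3", "D7", "D11", "h24", "h72")
  data.frame(
    ecotype = rep(c("Pt1", "Pt4"), each = 6),
    timepoint = rep(tp, 2),
    ld_count_mean = c(3.57, 6.80, 6.20, 6.96, 12.10, 2.70,
                      2.65, 4.08, 4.59, 5.31, 10.39, 4.76),
    ld_count_sd = c(2.08, 2.78, 2.65, 3.06, 7.62, 2.71,
                    2.43, 1.25, 2.15, 2.62, 6.15, 1.57),
    total_ld_volume_mean = c(0.32, 2.36, 3.12, 6.15, 4.15, 0.39,
                             0.56, 5.41, 5.39, 8.72, 2.03, 0.61),
    total_ld_volume_sd = c(0.35, 1.95, 1.95, 3.52, 3.80, 0.83,
                           0.33, 3.28, 3.20, 5.42, 1.43, 0.32),
    v_lipid_per_ld_printed = c(0.09, 0.35, 0.50, 0.88, 0.34, 0.14,
                               0.21, 1.32, 1.17, 1.64, 0.20, 0.13),
    cell_volume_mean = c(199, NA, NA, 158, 171, NA,
                         278, NA, NA, 258, 300, NA)
  )
}
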