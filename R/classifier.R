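# Supervised pixel classification: sparse two-class annotations train a
# bagged-tree model that maps the feature stack to a per-pixel "cell"
# probability map.

#' Train a two-class pixel classifier
#'
#' Trains a bootstrap-aggregated decision-tree classifier (random forest) on
#' sparsely annotated pixels: class 1 = "cell", class 2 = "background"
#' (which includes debris and bubbles).
#'
#' @param features array from [compute_pixel_features()]
#' @param labels integer matrix of the image's shape: 0 = unlabeled,
#'   1 = cell, 2 = background
#' @param ntree number of trees
#' @param seed integer seed for reproducible training
#' @return a `pixel_classifier` object
#' @export
train_pixel_classifier <- function(features, labels, ntree = 40,
                                   seed = NULL) {
  stopifnot(length(dim(features)) == 3,
            all(dim(labels) == dim(features)[1:2]))
  idx <- which(labels == 1L | labels == 2L)
  if (!length(idx)) stop("no annotated pixels")
  y <- factor(ifelse(labels[idx] == 1L, "cell", "background"),
              levels = c("cell", "background"))
  if (nlevels(droplevels(y)) < 2) {
    stop("both classes must be represented in the annotations")
  }
  tab <- table(y)
  if (max(tab) > 5 * min(tab)) {
    warning("annotation classes are strongly imbalanced (",
            tab[1], " cell vs ", tab[2], " background pixels)")
  }
  nf <- dim(features)[3]
  X <- matrix(features, ncol = nf)[idx, , drop = FALSE]
  colnames(X) <- dimnames(features)[[3]]
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree)
  structure(list(model = rf, feature_names = colnames(X), ntree = ntree),
            class = "pixel_classifier")
}

#' Predict the per-pixel cell probability map
#'
#' @param classifier a `pixel_classifier`
#' @param features array from [compute_pixel_features()]
#' @return numeric matrix of P(cell) in 0..1
#' @export
predict_cell_probability <- function(classifier, features) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  nf <- dim(features)[3]
  X <- matrix(features, ncol = nf)
  colnames(X) <- dimnames(features)[[3]]
  pr <- predict(classifier$model, X, type = "prob")[, "cell"]
  matrix(pr, dim(features)[1], dim(features)[2])
}

#' Build training annotations from a synthetic scene's ground truth
#'
#' Emulates the manual annotation protocol: a fraction of the planted cells
#' (default 20%) is marked as "cell", and an equal number of pixels outside
#' the cells as "background" - partly in a band right next to the annotated
#' cells (so the decision boundary at the cell halo is well determined),
#' partly on distractor objects, the rest uniformly over the background.
#'
#' @param sim output of [generate_brightfield_mosaic()]
#' @param fraction_cells fraction of planted cells to annotate
#' @param per_object_px maximum annotated pixels per cell
#' @param seed integer seed
#' @return integer label matrix (0/1/2) for [train_pixel_classifier()]
#' @export
annotate_training_pixels <- function(sim, fraction_cells = 0.2,
                                     per_object_px = 400, seed = 1L) {
  set.seed(seed)
  labels <- matrix(0L, nrow(sim$image), ncol(sim$image))
  ids <- setdiff(unique(as.integer(sim$cell_labels)), 0L)
  if (!length(ids)) stop("scene contains no cells to annotate")
  chosen <- sample(ids, max(1, ceiling(fraction_cells * length(ids))))
  n_cell_px <- 0L
  band_pool <- integer()
  any_cell <- sim$cell_labels != 0L
  for (id in chosen) {
    px <- which(sim$cell_labels == id)
    px <- sample(px, min(per_object_px, length(px)))
    labels[px] <- 1L
    n_cell_px <- n_cell_px + length(px)
    # background band 3-6 px outside this cell
    ai <- which(sim$cell_labels == id, arr.ind = TRUE)
    rr <- pmax(1, min(ai[, 1]) - 8):pmin(nrow(labels), max(ai[, 1]) + 8)
    cc <- pmax(1, min(ai[, 2]) - 8):pmin(ncol(labels), max(ai[, 2]) + 8)
    m <- matrix(as.numeric(sim$cell_labels[rr, cc] == id),
                length(rr), length(cc))
    band <- moving_max(m, 6) > 0.5 & moving_max(m, 2) < 0.5 &
      !any_cell[rr, cc]
    bidx <- which(band, arr.ind = TRUE)
    if (nrow(bidx)) {
      band_pool <- c(band_pool,
                     (cc[bidx[, 2]] - 1L) * nrow(labels) + rr[bidx[, 1]])
    }
  }
  bg_pool <- which(sim$cell_labels == 0L)
  dist_pool <- intersect(bg_pool, which(sim$distractor_labels != 0L))
  n_band <- min(length(band_pool), round(0.4 * n_cell_px))
  n_dist <- min(length(dist_pool), round(0.2 * n_cell_px))
  bg_px <- unique(c(
    if (n_band) sample(band_pool, n_band),
    if (n_dist) sample(dist_pool, n_dist)))
  rest <- setdiff(bg_pool, c(bg_px, band_pool))
  bg_px <- c(bg_px, sample(rest, max(0, n_cell_px - length(bg_px))))
  labels[bg_px] <- 2L
  labels
}
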