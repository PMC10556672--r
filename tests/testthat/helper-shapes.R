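# Geometric fixtures built in code: binary spheres/discs on voxel grids
# (independent of the package's own renderer) and truth-matching utilities.

# Binary 3D sphere mask from voxel-centre coordinates (physical spacing).
sphere_mask <- function(dims, center_um, r_um, spacing = c(1, 1, 1)) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dims[3]) - 0.5) * spacing[3]
  rr <- outer(outer((xs - center_um[1])^2, (ys - center_um[2])^2, `+`),
              (zs - center_um[3])^2, `+`)
  array(rr <= r_um^2, dims)
}

disc_mask <- function(dims, center_px, r_px) {
  xy <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  m <- matrix(FALSE, dims[1], dims[2])
  m[as.matrix(xy[(xy$x - center_px[1])^2 + (xy$y - center_px[2])^2 <=
                   r_px^2, 1:2])] <- TRUE
  m
}

# Greedy nearest-centre matching of measured objects to truth rows.
match_objects <- function(mx, my, mz, tx, ty, tz, max_dist = Inf) {
  mz <- rep(mz, length.out = length(mx))
  tz <- rep(tz, length.out = length(tx))
  dm <- sqrt(outer(mx, tx, `-`)^2 + outer(my, ty, `-`)^2 +
               outer(mz, tz, `-`)^2)
  nearest <- apply(dm, 1, which.min)
  mind <- apply(dm, 1, min)
  list(nearest = nearest, dist = mind, ok = mind <= max_dist)
}

# Volume fraction of the smaller of two equal spheres contained in their
# overlap lens, for centre distance d (closed form).
sphere_overlap_fraction <- function(r, d) {
  if (d >= 2 * r) return(0)
  v_lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  v_lens / (4 / 3 * pi * r^3)
}
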