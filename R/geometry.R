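# Cell-scale geometry: the prolate-spheroid volume model, the LD-plastid
# Euclidean distance, and the spindle (fusiform) outline used by the
# synthetic generators.

#' Prolate-spheroid cell volume
#'
#' Volume of a fusiform cell approximated as a prolate spheroid,
#' `V = pi/6 * width^2 * length`, with width and length in micrometres.
#' Width enters squared: it is the short (minor) axis of the spheroid.
#'
#' @param width cell width, um (> 0); vectorised
#' @param length cell length, um (> 0); vectorised
#' @return estimated volume, um^3
#' @examples
#' estimate_cell_volume(4, 24) # 64 * pi
#' @export
estimate_cell_volume <- function(width, length) {
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0)) {
    stop("width and length must be positive and finite")
  }
  pi / 6 * width^2 * length
}

#' Euclidean distance between an LD barycenter and the plastid barycenter
#'
#' @param ld numeric xyz (um) or a data.frame row with `bx_um`, `by_um`,
#'   `bz_um` columns
#' @param plastid same format as `ld`
#' @return distance in um
#' @export
ld_plastid_distance <- function(ld, plastid) {
  as_xyz <- function(p) {
    if (is.data.frame(p) || is.list(p)) {
      c(p$bx_um, p$by_um, p$bz_um)
    } else {
      as.numeric(p)
    }
  }
  a <- as_xyz(ld)
  b <- as_xyz(plastid)
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(sum((a - b)^2))
}

# Half-width profile of the spindle outline: h(x) = w * (1 - (2x/L)^2) for
# |x| <= L/2. Tapered (pointed) tips, maximum half-width w at the centre.
spindle_halfwidth <- function(x, half_length, w_max) {
  u <- x / half_length
  h <- w_max * (1 - u^2)
  h[abs(u) > 1] <- -Inf
  h
}

# Ratio between the area-matched second-moment fitted-ellipse minor axis and
# the drawn maximum half-width of the spindle profile above. Closed form from
# the profile's moments: minor = 2 * (2*w*sqrt(8/35)) * sqrt(A / (pi*a0*b0))
# with A = (4/3)*w*L, a0 = L/sqrt(5), b0 = 2*w*sqrt(8/35).
spindle_minor_factor <- function() {
  b0 <- 2 * sqrt(8 / 35)           # per unit w
  a0 <- 1 / sqrt(5)                # per unit L
  s <- sqrt((4 / 3) / (pi * a0 * b0))
  2 * b0 * s
}

# Minimum distance between two segments (for non-overlapping cell placement)
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  seg_intersect <- function(a, b, c, d) {
    ccw <- function(A, B, C) (C[2] - A[2]) * (B[1] - A[1]) >
      (B[2] - A[2]) * (C[1] - A[1])
    ccw(a, c, d) != ccw(b, c, d) && ccw(a, b, c) != ccw(a, b, d)
  }
  if (seg_intersect(p1, p2, q1, q2)) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2),
      pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}
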