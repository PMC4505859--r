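# Minimum-image geometry in orthorhombic periodic boxes. All distances in nm.

#' Minimum-image displacement
#'
#' Wraps a displacement (or matrix of displacements) into the minimum-image
#' convention for an orthorhombic box.
#'
#' @param d numeric vector of length 3 or an n x 3 matrix of displacements.
#' @param box box edge lengths (length 3).
#' @return displacement(s) of the same shape, each component in
#'   `[-box/2, box/2)`.
#' @export
min_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

# All cross-pair minimum-image distances between coordinate sets a (na x 3)
# and b (nb x 3); returns an na x nb matrix. Vectorised via outer(); memory is
# O(na * nb), fine at the bead counts this package works with.
pair_distances <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(a[, 3], b[, 3], "-")
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Lateral (x-y) minimum-image distances, for quasi-planar lipid analyses.
pair_distances_xy <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy)
}

# Wrap absolute coordinates into [0, box).
wrap_coords <- function(coords, box) {
  for (k in 1:3) coords[, k] <- coords[, k] %% box[k]
  coords
}

# Row index helper: bead ids are 0-based, rows are 1-based.
bead_rows <- function(bead_ids) as.integer(bead_ids) + 1L
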