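#' Rasterize per-slice planar contours into a structure mask
#'
#' Contours are closed polygons drawn on axial slices (planes of constant
#' axis-3 coordinate).  Each voxel center on the matching grid slice is
#' tested with the even-odd rule; a point exactly on a polygon edge counts
#' as inside, so a 20x20 mm axis-aligned square whose vertices sit on
#' voxel-center coordinates of a 1 mm grid fills 21x21 voxels.  Several
#' polygons on one slice combine by the even-odd (XOR) rule, so disjoint
#' polygons union and nested ones carve holes.
#'
#' @param polygons list of contours; each a list with `z` (slice position,
#'   mm) and `xy` (n x 2 matrix of vertices in mm on axes 1 and 2).  A
#'   closing repeat of the first vertex is optional.
#' @param grid `image_grid` supplying the target geometry.
#' @param name structure name for the resulting mask.
#' @return a `structure_mask`.  Warns if every polygon falls outside the
#'   grid (all-false mask).
#' @export
rasterize_contours <- function(polygons, grid, name = "structure") {
  stopifnot(inherits(grid, "image_grid"))
  sh <- dim(grid$values)
  mask <- array(FALSE, sh)
  zs <- grid_coords(grid, 3)
  xs <- grid_coords(grid, 1)
  ys <- grid_coords(grid, 2)
  tol <- grid$spacing[3] / 2
  any_hit <- FALSE
  for (poly in polygons) {
    xy <- as.matrix(poly$xy)
    if (nrow(xy) >= 2 &&
        all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12))
      xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3)
      stop("polygon must have at least 3 distinct vertices")
    dk <- abs(zs - poly$z)
    k <- which.min(dk)
    if (dk[k] > tol + 1e-9) next      # slice off-grid -> contributes nothing
    inside <- points_in_polygon(xs, ys, xy)
    if (any(inside)) any_hit <- TRUE
    mask[, , k] <- xor(mask[, , k], inside)
  }
  if (!any_hit)
    warning("no polygon intersected the grid; mask is empty")
  structure_mask(name, mask, grid)
}

# Even-odd test of the lattice xs x ys against polygon `xy` (m x 2).
# Points on an edge (within 1e-9 mm) are inside.
points_in_polygon <- function(xs, ys, xy) {
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  m <- nrow(xy)
  crossings <- integer(nx * ny)
  on_edge <- logical(nx * ny)
  for (e in seq_len(m)) {
    a <- xy[e, ]; b <- xy[if (e == m) 1 else e + 1, ]
    # on-segment test
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - a[1]) * dx + (py - a[2]) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (a[1] + t * dx - px)^2 + (a[2] + t * dy - py)^2
      on_edge <- on_edge | d2 < 1e-18
    }
    # half-open ray crossing (ray towards +x)
    cond <- (a[2] > py) != (b[2] > py)
    if (any(cond)) {
      xint <- a[1] + (py[cond] - a[2]) / (b[2] - a[2]) * dx
      hit <- logical(sum(cond)); hit[px[cond] < xint] <- TRUE
      crossings[cond] <- crossings[cond] + as.integer(hit)
    }
  }
  matrix((crossings %% 2L == 1L) | on_edge, nx, ny)
}
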