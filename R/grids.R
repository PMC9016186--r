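#' Geometry-aware 3D scalar volume
#'
#' An `image_grid` holds one scalar quantity (HU, mass density, relative
#' stopping power, or dose) on a regular 3D lattice.  Geometry follows the
#' voxel-center convention: the world coordinate (mm) of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#' Axis 2 is the anterior-posterior beam axis by convention.
#'
#' @param values numeric 3D array of voxel values.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param spacing numeric length-3, mm voxel spacing, strictly positive.
#' @param quantity one of `"HU"`, `"density"`, `"RSP"`, `"dose"`.
#' @param frame label of the coordinate frame (free text).
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(values, origin, spacing,
                       quantity = c("HU", "density", "RSP", "dose"),
                       frame = "patient") {
  quantity <- match.arg(quantity)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive on all axes")
  if (any(dim(values) < 1L))
    stop("grid shape must be >= 1 per axis")
  if (quantity %in% c("density", "dose") &&
      any(values < 0, na.rm = TRUE))
    stop(sprintf("%s values must be non-negative", quantity))
  structure(
    list(values = values, origin = origin, spacing = spacing,
         quantity = quantity, frame = frame),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s  shape %s  spacing %s mm  origin %s mm\n",
              x$quantity, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%.4g, %.4g]  frame '%s'\n",
              min(x$values), max(x$values), x$frame))
  invisible(x)
}

grid_shape <- function(grid) dim(grid$values)

#' Voxel-center coordinates along one axis
#' @param grid an `image_grid`.
#' @param axis axis index (1, 2 or 3).
#' @return numeric vector of mm positions of voxel centers.
#' @export
grid_coords <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' @rdname grid_coords
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Rigid transform (4x4 homogeneous matrix)
#'
#' Maps points from a moving frame into a target frame; the 3x3 rotation
#' block must be orthonormal with determinant +1, translation in mm.
#'
#' @param matrix 4x4 numeric homogeneous matrix.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 4, 4)
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("rotation block is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation block must have determinant +1 (no reflection)")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of a homogeneous rigid transform must be (0,0,0,1)")
  structure(list(matrix = m), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param translation mm length-3 vector; convenience constructor.
#' @export
translation_transform <- function(translation) {
  m <- diag(4)
  m[1:3, 4] <- as.numeric(translation)
  rigid_transform(m)
}

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @export
invert_transform <- function(x) {
  R <- x$matrix[1:3, 1:3]; t <- x$matrix[1:3, 4]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t
  rigid_transform(m)
}

#' Read / write a rigid transform as plain text
#'
#' Format: 4 lines of 4 numbers, row-major, translations in mm.
#' `#` comment lines are ignored on read.
#' @param path file path.
#' @param x a `rigid_transform`.
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop("transform file must contain exactly 4 numeric rows")
  rows <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
  if (any(lengths(rows) != 4))
    stop("each transform row must contain 4 numbers")
  rigid_transform(do.call(rbind, rows))
}

#' @rdname read_transform
#' @export
write_transform <- function(x, path) {
  stopifnot(inherits(x, "rigid_transform"))
  writeLines(apply(x$matrix, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  invisible(path)
}

# Trilinear interpolation of a 3D array at world points (n x 3 matrix, mm).
# Points outside the voxel-center bounding box get `fill`.  Returns a list
# with `values` and logical `outside`.
trilinear_sample <- function(grid, pts, fill = 0) {
  v <- grid$values
  d <- dim(v)
  u <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")  # 0-based
  outside <- (u[, 1] < 0 | u[, 1] > d[1] - 1 |
              u[, 2] < 0 | u[, 2] > d[2] - 1 |
              u[, 3] < 0 | u[, 3] > d[3] - 1)
  # clamp so index arithmetic stays valid; outside points overwritten below
  u[, 1] <- pmin(pmax(u[, 1], 0), d[1] - 1)
  u[, 2] <- pmin(pmax(u[, 2], 0), d[2] - 1)
  u[, 3] <- pmin(pmax(u[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(u[, 1]), d[1] - 2); i0[d[1] == 1] <- 0
  j0 <- pmin(floor(u[, 2]), d[2] - 2); j0[d[2] == 1] <- 0
  k0 <- pmin(floor(u[, 3]), d[3] - 2); k0[d[3] == 1] <- 0
  fx <- u[, 1] - i0; fy <- u[, 2] - j0; fz <- u[, 3] - k0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- 1 + i0 + n1 * j0 + n12 * k0
  ix <- if (d[1] > 1) 1L else 0L
  iy <- if (d[2] > 1) n1 else 0L
  iz <- if (d[3] > 1) n12 else 0L
  val <-
    v[base]                * (1 - fx) * (1 - fy) * (1 - fz) +
    v[base + ix]           * fx       * (1 - fy) * (1 - fz) +
    v[base + iy]           * (1 - fx) * fy       * (1 - fz) +
    v[base + ix + iy]      * fx       * fy       * (1 - fz) +
    v[base + iz]           * (1 - fx) * (1 - fy) * fz +
    v[base + ix + iz]      * fx       * (1 - fy) * fz +
    v[base + iy + iz]      * (1 - fx) * fy       * fz +
    v[base + ix + iy + iz] * fx       * fy       * fz
  val[outside] <- fill
  list(values = val, outside = outside)
}

default_fill <- function(quantity) {
  switch(quantity, HU = -1000, density = 0.00121, RSP = 0, dose = 0)
}

#' Resample a volume through a rigid transform
#'
#' Produces a volume on `target_geometry` by pulling values from `moving`
#' with trilinear interpolation: for each target voxel center `p`, the
#' sampled point is `T^-1 p` in the moving frame (the transform maps
#' moving -> target).  Points outside the moving volume are filled with a
#' quantity-dependent value (air HU, air density, 0 dose/RSP).
#'
#' @param moving an `image_grid`.
#' @param transform a `rigid_transform` mapping moving frame to target frame.
#' @param target_geometry an `image_grid` (geometry template) or a list with
#'   `origin`, `spacing`, `shape`.
#' @param fill override for the out-of-volume fill value.
#' @return an `image_grid` on the target geometry; the attribute
#'   `outside` holds the logical array of voxels that fell outside the
#'   moving volume.
#' @export
resample_rigid <- function(moving, transform, target_geometry, fill = NULL) {
  stopifnot(inherits(moving, "image_grid"))
  if (inherits(target_geometry, "image_grid"))
    target_geometry <- list(origin = target_geometry$origin,
                            spacing = target_geometry$spacing,
                            shape = dim(target_geometry$values))
  if (inherits(transform, "rigid_transform")) {
    inv <- invert_transform(transform)$matrix
  } else stop("`transform` must be a rigid_transform")
  if (is.null(fill)) fill <- default_fill(moving$quantity)
  sh <- as.integer(target_geometry$shape)
  org <- target_geometry$origin; sp <- target_geometry$spacing
  xs <- org[1] + (seq_len(sh[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(sh[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(sh[3]) - 1) * sp[3]
  pts <- cbind(rep(xs, times = sh[2] * sh[3]),
               rep(rep(ys, each = sh[1]), times = sh[3]),
               rep(zs, each = sh[1] * sh[2]))
  mpts <- pts %*% t(inv[1:3, 1:3])
  mpts <- sweep(mpts, 2, inv[1:3, 4], "+")
  s <- trilinear_sample(moving, mpts, fill = fill)
  out <- image_grid(array(s$values, dim = sh), org, sp,
                    quantity = moving$quantity, frame = moving$frame)
  attr(out, "outside") <- array(s$outside, dim = sh)
  out
}

#' 2D planar dose on a regular in-plane lattice
#'
#' Represents a measured or extracted dose plane perpendicular to one grid
#' axis.  The in-plane axes are the remaining two volume axes in increasing
#' order; `values` is indexed `[i1, i2]` along them.
#'
#' @param values numeric matrix of dose (cGy), non-negative.
#' @param plane_axis the beam-depth axis the plane is perpendicular to.
#' @param depth mm position of the plane along `plane_axis`.
#' @param origin mm length-2 position of the first lattice point.
#' @param spacing mm length-2 lattice pitch, strictly positive.
#' @return object of class `planar_dose`.
#' @export
planar_dose <- function(values, plane_axis, depth, origin, spacing) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (any(values < 0, na.rm = TRUE)) stop("dose values must be non-negative")
  if (!is.finite(depth)) stop("`depth` must be finite")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 2L || length(spacing) != 2L)
    stop("in-plane origin/spacing must have length 2")
  if (any(spacing <= 0)) stop("in-plane spacing must be positive")
  plane_axis <- as.integer(plane_axis)
  if (!plane_axis %in% 1:3) stop("`plane_axis` must be 1, 2 or 3")
  structure(list(values = values, plane_axis = plane_axis, depth = depth,
                 origin = origin, spacing = spacing),
            class = "planar_dose")
}

#' @export
print.planar_dose <- function(x, ...) {
  cat(sprintf(
    "<planar_dose> %dx%d @ depth %.2f mm (axis %d), pitch %s mm, max %.3g cGy\n",
    nrow(x$values), ncol(x$values), x$depth, x$plane_axis,
    paste(signif(x$spacing, 4), collapse = "x"), max(x$values)))
  invisible(x)
}

plane_coords <- function(plane, which) {
  n <- dim(plane$values)[which]
  plane$origin[which] + (seq_len(n) - 1) * plane$spacing[which]
}

#' Boolean structure mask on a grid geometry
#'
#' @param name structure name.
#' @param mask logical 3D array matching the grid shape.
#' @param grid `image_grid` whose geometry the mask lives on.
#' @return object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (!is.logical(mask) || !all(dim(mask) == dim(grid$values)))
    stop("mask must be a logical array with the grid's shape")
  structure(list(name = name, mask = mask, origin = grid$origin,
                 spacing = grid$spacing, frame = grid$frame),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels (%.2f cm^3)\n", x$name,
              sum(x$mask), sum(x$mask) * prod(x$spacing) / 1000))
  invisible(x)
}
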