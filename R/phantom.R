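# Digital phantoms, CBCT distortion, detector simulation.
#
# The phantom generator is a stated world standing in for the physical
# anthropomorphic phantoms: a soft-tissue body ellipsoid with a bone
# shell (plus two low-density lungs for the thorax site), resting on a
# solid-water base slab, with a wedge-shaped target whose distal surface
# slopes linearly across the field so that its gradient crosses the
# detector plane inside the slab.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Digital phantom specification
#'
#' Defaults describe a head-sized phantom on a 1 mm isotropic grid and a
#' thorax on a 2 mm grid (half resolution purely for runtime; geometry in
#' mm is unchanged).  The beam axis is axis 2 (anterior-posterior), entry
#' from the low-y side.  The wedge target's distal surface runs linearly
#' from `wedge_distal[1]` mm at the low-x edge to `wedge_distal[2]` mm at
#' the high-x edge and must bracket `detector_depth`.
#'
#' @param site `"head"` or `"thorax"`.
#' @param spacing,shape,origin grid geometry (mm / voxel counts).
#' @param body_center,body_semi mm center and semi-axes of the body
#'   ellipsoid.
#' @param shell_mm bone-shell thickness, mm.
#' @param lung_centers,lung_semi lung ellipsoid geometry (thorax only).
#' @param slab_y mm interval `[from, to)` of the solid-water base along y.
#' @param detector_depth mm physical depth of the detector plane (axis 2).
#' @param wedge_x,wedge_z mm lateral extent of the wedge target.
#' @param wedge_proximal mm proximal target surface depth.
#' @param wedge_distal length-2 mm: distal depth at the low- and high-x
#'   edge of the target.
#' @param hu_noise_sd CT HU noise standard deviation (0 = noise free).
#' @param seed RNG seed used by the generator.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(site = c("head", "thorax"),
                         spacing = NULL, shape = NULL, origin = c(0, 0, 0),
                         body_center = NULL, body_semi = NULL,
                         shell_mm = 4,
                         lung_centers = NULL, lung_semi = NULL,
                         slab_y = NULL, detector_depth = NULL,
                         wedge_x = NULL, wedge_z = NULL,
                         wedge_proximal = NULL, wedge_distal = NULL,
                         hu_noise_sd = 0, seed = 1L) {
  site <- match.arg(site)
  if (site == "head") {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(shape)) shape <- c(120L, 140L, 120L)
    if (is.null(body_center)) body_center <- c(59.5, 58, 59.5)
    if (is.null(body_semi)) body_semi <- c(46, 44, 46)
    if (is.null(slab_y)) slab_y <- c(102, 132)
    if (is.null(detector_depth)) detector_depth <- 118
    if (is.null(wedge_x)) wedge_x <- c(20, 99)
    if (is.null(wedge_z)) wedge_z <- c(20, 99)
    if (is.null(wedge_proximal)) wedge_proximal <- 85
    if (is.null(wedge_distal)) wedge_distal <- c(104, 127.7)
  } else {
    if (is.null(spacing)) spacing <- c(2, 2, 2)
    if (is.null(shape)) shape <- c(150L, 110L, 100L)
    if (is.null(body_center)) body_center <- c(149, 96, 99)
    if (is.null(body_semi)) body_semi <- c(135, 88, 130)
    if (is.null(lung_centers))
      lung_centers <- list(c(85, 96, 96), c(213, 96, 96))
    if (is.null(lung_semi)) lung_semi <- c(45, 55, 75)
    if (is.null(slab_y)) slab_y <- c(184, 212)
    if (is.null(detector_depth)) detector_depth <- 196
    if (is.null(wedge_x)) wedge_x <- c(55, 115)
    if (is.null(wedge_z)) wedge_z <- c(120, 160)
    if (is.null(wedge_proximal)) wedge_proximal <- 155
    if (is.null(wedge_distal)) wedge_distal <- c(188, 206)
  }
  extent <- origin + (shape - 1) * spacing
  if (wedge_x[1] < origin[1] || wedge_x[2] > extent[1] ||
      wedge_z[1] < origin[3] || wedge_z[2] > extent[3] ||
      wedge_proximal < origin[2] || max(wedge_distal) > extent[2])
    stop("wedge target does not fit inside the grid")
  if (detector_depth < wedge_distal[1] || detector_depth > wedge_distal[2])
    stop(sprintf(
      "wedge gradient [%g, %g] mm does not intersect the detector plane at %g mm",
      wedge_distal[1], wedge_distal[2], detector_depth))
  structure(list(site = site, spacing = spacing, shape = as.integer(shape),
                 origin = origin, body_center = body_center,
                 body_semi = body_semi, shell_mm = shell_mm,
                 lung_centers = lung_centers, lung_semi = lung_semi,
                 slab_y = slab_y, detector_depth = detector_depth,
                 wedge_x = wedge_x, wedge_z = wedge_z,
                 wedge_proximal = wedge_proximal,
                 wedge_distal = wedge_distal,
                 hu_noise_sd = hu_noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

PHANTOM_CLASSES <- c(air = 1L, lung = 2L, soft = 3L, bone = 4L, water = 5L)
PHANTOM_DENSITY <- c(air = 0.00121, lung = 0.26, soft = 1.04,
                     bone = 1.55, water = 1.00)

# vectorized piecewise-linear inverse of an HU-density table (requires
# strictly increasing densities, true of the default calibration)
invert_hu_vec <- function(table, density) {
  d <- table$density; h <- table$hu
  keep <- c(TRUE, diff(d) > 0)
  d <- d[keep]; h <- h[keep]
  if (length(d) < 2)
    stop("table is not invertible (constant density)")
  stats::approx(d, h, xout = as.numeric(density), rule = 2,
                ties = "ordered")$y
}

# HU a material class maps to under `table`, i.e. the table's inverse at
# the class density (exact at anchors).
invert_hu <- function(table, density) {
  vapply(density, function(d) {
    hit <- which(abs(table$density - d) < 1e-12)
    if (length(hit)) return(table$hu[hit[1]])
    if (d <= table$density[1]) return(table$hu[1])
    if (d >= table$density[length(table$density)])
      return(table$hu[length(table$hu)])
    i <- findInterval(d, table$density)
    lo <- table$density[i]; hi <- table$density[i + 1]
    if (hi == lo) return(table$hu[i])
    table$hu[i] + (d - lo) / (hi - lo) * (table$hu[i + 1] - table$hu[i])
  }, 0)
}

in_ellipsoid <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

#' Build a digital phantom
#'
#' Generates the true density volume, a CT HU volume obtained by
#' inverting the CT HU-density table at each voxel's density (plus
#' optional seeded Gaussian HU noise), the wedge target mask and the
#' solid-water base mask.  Material interfaces are anti-aliased by
#' 2x2x2 subvoxel supersampling, mimicking the partial-volume averaging
#' of real CT: without it, the voxelized bone shell aliases into a
#' column-parity WEPL ripple of almost one voxel that imprints on every
#' distal dose surface.  Deterministic for a given spec and seed.
#'
#' @param spec a [phantom_spec].
#' @param table the CT [hu_density_table] used to synthesize HU.
#' @return list with elements `ct` (HU `image_grid`), `density` (truth),
#'   `wedge` and `base` (`structure_mask`), `classes` (majority-class
#'   integer array, see `PHANTOM_CLASSES`), and `spec`.
#' @export
make_phantom <- function(spec, table = default_ct_table()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing; org <- spec$origin
  xs <- org[1] + (seq_len(sh[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(sh[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(sh[3]) - 1) * sp[3]
  X <- array(rep(xs, times = sh[2] * sh[3]), sh)
  Y <- array(rep(rep(ys, each = sh[1]), times = sh[3]), sh)
  Z <- array(rep(zs, each = sh[1] * sh[2]), sh)

  # occupancy fractions by 2x2x2 supersampling (offsets +/- spacing/4)
  f_outer <- array(0, sh); f_inner <- array(0, sh); f_lung <- array(0, sh)
  inner_semi <- pmax(spec$body_semi - spec$shell_mm, 1)
  for (ox in c(-0.25, 0.25) * sp[1])
    for (oy in c(-0.25, 0.25) * sp[2])
      for (oz in c(-0.25, 0.25) * sp[3]) {
        Xs <- X + ox; Ys <- Y + oy; Zs <- Z + oz
        f_outer <- f_outer +
          in_ellipsoid(Xs, Ys, Zs, spec$body_center, spec$body_semi)
        f_inner <- f_inner +
          in_ellipsoid(Xs, Ys, Zs, spec$body_center, inner_semi)
        if (spec$site == "thorax")
          for (ctr in spec$lung_centers)
            f_lung <- f_lung +
              in_ellipsoid(Xs, Ys, Zs, ctr, spec$lung_semi)
      }
  f_outer <- f_outer / 8; f_inner <- f_inner / 8
  f_lung <- pmin(f_lung / 8, f_inner)

  dens <- PHANTOM_DENSITY[["air"]] +
    f_outer * (PHANTOM_DENSITY[["bone"]] - PHANTOM_DENSITY[["air"]]) +
    f_inner * (PHANTOM_DENSITY[["soft"]] - PHANTOM_DENSITY[["bone"]]) +
    f_lung * (PHANTOM_DENSITY[["lung"]] - PHANTOM_DENSITY[["soft"]])
  slab <- Y >= spec$slab_y[1] & Y < spec$slab_y[2]
  dens[slab] <- PHANTOM_DENSITY[["water"]]

  # majority material class per voxel (for CBCT distortion bookkeeping)
  f_bone <- f_outer - f_inner
  f_soft <- f_inner - f_lung
  f_air <- 1 - f_outer
  fr <- cbind(as.numeric(f_air), as.numeric(f_lung),
              as.numeric(f_soft), as.numeric(f_bone))
  cls <- array(max.col(fr, ties.method = "last"), sh)
  cls[slab] <- PHANTOM_CLASSES[["water"]]

  density <- image_grid(array(dens, sh), org, sp, quantity = "density")

  hu <- array(invert_hu_vec(table, dens), sh)
  if (spec$hu_noise_sd > 0)
    hu <- hu + with_seed(spec$seed,
                         array(stats::rnorm(length(hu), 0, spec$hu_noise_sd),
                               sh))
  ct <- image_grid(hu, org, sp, quantity = "HU")

  slope <- (spec$wedge_distal[2] - spec$wedge_distal[1]) /
    (spec$wedge_x[2] - spec$wedge_x[1])
  distal_at <- spec$wedge_distal[1] + (X - spec$wedge_x[1]) * slope
  wedge <- X >= spec$wedge_x[1] & X <= spec$wedge_x[2] &
    Z >= spec$wedge_z[1] & Z <= spec$wedge_z[2] &
    Y >= spec$wedge_proximal & Y <= distal_at
  if (!any(wedge)) stop("wedge target mask is empty")

  list(ct = ct, density = density,
       wedge = structure_mask("wedge_ctv", wedge, density),
       base = structure_mask("base", slab, density),
       classes = cls, spec = spec)
}

#' Per-class CBCT distortion model
#'
#' Image-domain emulation of CBCT HU infidelity: an affine map
#' `a_c * HU + b_c` per material class, a radial cupping term
#' `cupping * (r / r0)^2` in the axial (x-y) plane, and seeded Gaussian
#' HU noise.
#'
#' @param a,b named numeric vectors (one entry per class label) of
#'   per-class slope and offset.
#' @param cupping cupping amplitude, HU at radius `r0`.
#' @param r0 cupping reference radius, mm.
#' @param noise_sd HU noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return object of class `cbct_distortion`.
#' @export
cbct_distortion <- function(a = c(air = 1, lung = 1, soft = 1, bone = 1,
                                  water = 1),
                            b = c(air = 0, lung = 0, soft = 0, bone = 0,
                                  water = 0),
                            cupping = 0, r0 = 100, noise_sd = 0,
                            seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(a)) || is.null(names(b)))
    stop("a and b must be named by material class")
  structure(list(a = a, b = b, cupping = cupping, r0 = r0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cbct_distortion")
}

#' Distort a CT HU volume into a synthetic CBCT
#'
#' Every voxel must belong to a class named in the distortion; the output
#' is `a_c * HU + b_c + cupping * (r/r0)^2 + N(0, noise_sd^2)`,
#' deterministic under the distortion's seed.
#'
#' @param ct `image_grid` of HU.
#' @param classes integer array of class codes (`PHANTOM_CLASSES`) as
#'   returned by [make_phantom].
#' @param d a [cbct_distortion].
#' @return `image_grid` of CBCT HU.
#' @export
distort_to_cbct <- function(ct, classes, d) {
  stopifnot(inherits(ct, "image_grid"), inherits(d, "cbct_distortion"))
  if (!all(dim(classes) == dim(ct$values)))
    stop("class array shape does not match the CT grid")
  labels <- names(PHANTOM_CLASSES)[match(classes, PHANTOM_CLASSES)]
  if (anyNA(labels) || !all(unique(labels) %in% names(d$a)) ||
      !all(unique(labels) %in% names(d$b)))
    stop("every voxel must be assigned a class covered by the distortion")
  hu <- d$a[labels] * as.numeric(ct$values) + d$b[labels]
  hu <- array(hu, dim(ct$values))
  if (d$cupping != 0) {
    sh <- dim(ct$values)
    xs <- grid_coords(ct, 1); ys <- grid_coords(ct, 2)
    cx <- mean(range(xs)); cy <- mean(range(ys))
    r2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    hu <- hu + array(rep(d$cupping * r2 / d$r0^2, times = sh[3]), sh)
  }
  if (d$noise_sd > 0)
    hu <- hu + with_seed(d$seed,
                         array(stats::rnorm(length(hu), 0, d$noise_sd),
                               dim(hu)))
  image_grid(hu, ct$origin, ct$spacing, quantity = "HU", frame = ct$frame)
}

#' Expected CBCT mean HU of each phantom class under a distortion
#'
#' Convenience for building noise-free VOI samples: applies only the
#' affine part of the distortion to the class HU implied by the CT table.
#' @param d a [cbct_distortion].
#' @param table CT [hu_density_table].
#' @param classes class labels to report.
#' @return named numeric vector of CBCT HU.
#' @export
expected_cbct_hu <- function(d, table = default_ct_table(),
                             classes = names(PHANTOM_CLASSES)) {
  ct_hu <- invert_hu(table, PHANTOM_DENSITY[classes])
  stats::setNames(d$a[classes] * ct_hu + d$b[classes], classes)
}

#' Simulate a 2D ion-chamber-array measurement
#'
#' Samples the 3D dose with trilinear interpolation on a regular detector
#' lattice at the given physical depth, then applies multiplicative
#' Gaussian noise (seeded).  The lattice defaults to a 27x27 array at
#' 10 mm pitch centered on the lateral center of the dose grid.
#'
#' @param dose `image_grid` with `quantity = "dose"`.
#' @param depth mm position of the detector plane along `axis`.
#' @param axis beam-depth axis (default 2).
#' @param pitch detector pitch, mm.
#' @param n number of chambers per in-plane axis (length 1 or 2).
#' @param noise relative noise standard deviation (e.g. 0.01 for 1%).
#' @param seed RNG seed for the noise.
#' @param center optional mm length-2 lateral center of the lattice.
#' @return a [planar_dose].
#' @export
simulate_measurement <- function(dose, depth, axis = 2, pitch = 10,
                                 n = c(27, 27), noise = 0, seed = 1L,
                                 center = NULL) {
  stopifnot(inherits(dose, "image_grid"))
  if (dose$quantity != "dose") stop("expected a dose grid")
  rng <- range(grid_coords(dose, axis))
  if (depth < rng[1] || depth > rng[2])
    stop(sprintf("detector depth %.2f mm outside grid extent [%.2f, %.2f]",
                 depth, rng[1], rng[2]))
  if (length(n) == 1) n <- rep(n, 2)
  if (length(pitch) == 1) pitch <- rep(pitch, 2)
  lat <- setdiff(1:3, axis)
  if (is.null(center))
    center <- c(mean(range(grid_coords(dose, lat[1]))),
                mean(range(grid_coords(dose, lat[2]))))
  o <- center - (n - 1) / 2 * pitch
  us <- o[1] + (seq_len(n[1]) - 1) * pitch[1]
  vs <- o[2] + (seq_len(n[2]) - 1) * pitch[2]
  pts <- matrix(0, n[1] * n[2], 3)
  pts[, lat[1]] <- rep(us, times = n[2])
  pts[, lat[2]] <- rep(vs, each = n[1])
  pts[, axis] <- depth
  vals <- matrix(trilinear_sample(dose, pts, fill = 0)$values, n[1], n[2])
  if (noise > 0) {
    fac <- with_seed(seed,
                     matrix(stats::rnorm(length(vals), 1, noise),
                            n[1], n[2]))
    vals <- pmax(vals * fac, 0)
  }
  planar_dose(vals, plane_axis = axis, depth = depth,
              origin = o, spacing = pitch)
}
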