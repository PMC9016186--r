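#' Piecewise-linear HU to mass-density table
#'
#' Anchors must have strictly increasing HU and non-decreasing density.
#' Conversion clamps outside the anchor range (flat extrapolation), which
#' is how the table covers the full diagnostic range [-1000, 3000] HU even
#' when the outermost anchors sit inside it.
#'
#' @param hu numeric vector of HU anchor positions (strictly increasing).
#' @param density numeric vector of mass densities, g/cm^3 (non-decreasing).
#' @param modality `"CT"` or `"CBCT"`.
#' @return object of class `hu_density_table`.
#' @export
hu_density_table <- function(hu, density, modality = c("CT", "CBCT")) {
  modality <- match.arg(modality)
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) == 0) stop("empty HU-density table")
  if (length(hu) != length(density)) stop("hu and density lengths differ")
  if (any(diff(hu) <= 0)) stop("HU anchors must be strictly increasing")
  if (any(diff(density) < 0)) stop("densities must be non-decreasing")
  if (any(density < 0)) stop("densities must be non-negative")
  if (density[1] > 0.0013)
    warning("first anchor density exceeds air (0.0013 g/cm^3); ",
            "low-HU voxels will clamp to ", density[1])
  structure(list(hu = hu, density = density, modality = modality),
            class = "hu_density_table")
}

#' @export
print.hu_density_table <- function(x, ...) {
  cat(sprintf("<hu_density_table> %s, %d anchors, HU [%g, %g]\n",
              x$modality, length(x$hu), min(x$hu), max(x$hu)))
  print(data.frame(hu = x$hu, density = x$density), row.names = FALSE)
  invisible(x)
}

#' Default CT HU to mass-density calibration
#'
#' A compact stoichiometric-style curve anchored at air, inflated lung,
#' adipose, water, soft tissue and bone.  These anchors also define the
#' HU each digital-phantom material class is assigned, so converting a
#' noise-free phantom recovers the true densities exactly.
#' @return an `hu_density_table` for CT.
#' @export
default_ct_table <- function() {
  hu_density_table(
    hu = c(-1000, -700, -98, 0, 40, 1000, 3000),
    density = c(0.00121, 0.26, 0.95, 1.000, 1.04, 1.55, 2.70),
    modality = "CT")
}

#' Convert an HU volume to mass density
#'
#' Piecewise-linear interpolation between table anchors with clamping at
#' the ends (no extrapolation beyond the anchor densities).
#'
#' @param grid `image_grid` with `quantity = "HU"`.
#' @param table an `hu_density_table`.
#' @return `image_grid` with `quantity = "density"` (g/cm^3).
#' @export
density_from_hu <- function(grid, table) {
  stopifnot(inherits(grid, "image_grid"), inherits(table, "hu_density_table"))
  if (grid$quantity != "HU") stop("input grid must hold HU")
  vals <- pw_linear(table$hu, table$density, grid$values)
  image_grid(array(vals, dim(grid$values)), grid$origin, grid$spacing,
             quantity = "density", frame = grid$frame)
}

pw_linear <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  stats::approx(x, y, xout = as.numeric(xout), rule = 2, ties = "ordered")$y
}

#' Volume-of-interest sample for group-based CBCT calibration
#'
#' @param material_class label, unique within one calibration set
#'   (e.g. `"air"`, `"lung"`, `"soft"`, `"bone"`, `"insert-3"`).
#' @param mean_hu_cbct mean HU of the VOI on the CBCT image.
#' @param mean_hu_ct mean HU of the same VOI on CT (may be `NA` when
#'   `known_density` is given).
#' @param known_density physical density of the material when known
#'   (density-phantom inserts), else `NA`.
#' @return object of class `voi_sample`.
#' @export
voi_sample <- function(material_class, mean_hu_cbct, mean_hu_ct = NA,
                       known_density = NA) {
  if (is.na(mean_hu_ct) && is.na(known_density))
    stop("a VOI sample needs mean_hu_ct or known_density")
  structure(list(material_class = material_class,
                 mean_hu_cbct = as.numeric(mean_hu_cbct),
                 mean_hu_ct = as.numeric(mean_hu_ct),
                 known_density = as.numeric(known_density)),
            class = "voi_sample")
}

# weighted pool-adjacent-violators: smallest change making y non-decreasing
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  ym <- y; wm <- w; idx <- as.list(seq_len(n))
  i <- 1
  while (i < length(ym)) {
    if (ym[i] > ym[i + 1] + 1e-15) {
      wsum <- wm[i] + wm[i + 1]
      ym[i] <- (ym[i] * wm[i] + ym[i + 1] * wm[i + 1]) / wsum
      wm[i] <- wsum
      idx[[i]] <- c(idx[[i]], idx[[i + 1]])
      ym <- ym[-(i + 1)]; wm <- wm[-(i + 1)]; idx <- idx[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  out <- numeric(n)
  for (b in seq_along(ym)) out[idx[[b]]] <- ym[b]
  out
}

#' Fit a group-based CBCT HU-density table from VOI samples
#'
#' Implements patient-group calibration: each sample's density comes from
#' its known physical density when available, otherwise from the CT
#' reference table applied to its CT mean HU.  Anchors are the pairs
#' `(mean_hu_cbct, density)` sorted by CBCT HU.  If noise produces a
#' density inversion, a weighted pool-adjacent-violators pass restores
#' monotonicity (with a warning).  Coverage of [-1000, 3000] HU is by
#' clamping, as for every table.
#'
#' @param samples list of [voi_sample] objects (at least 3 distinct
#'   classes spanning air to bone).
#' @param reference the CT `hu_density_table`.
#' @return an `hu_density_table` with `modality = "CBCT"`.
#' @export
fit_group_table <- function(samples, reference) {
  stopifnot(inherits(reference, "hu_density_table"))
  if (length(samples) < 3)
    stop("group calibration needs at least 3 material classes")
  classes <- vapply(samples, function(s) s$material_class, "")
  if (anyDuplicated(classes))
    stop("material_class labels must be unique within a calibration set")
  hu_cbct <- vapply(samples, function(s) s$mean_hu_cbct, 0)
  dens <- vapply(samples, function(s) {
    if (!is.na(s$known_density)) s$known_density
    else pw_linear(reference$hu, reference$density, s$mean_hu_ct)
  }, 0)
  ord <- order(hu_cbct)
  hu_cbct <- hu_cbct[ord]; dens <- dens[ord]
  if (any(diff(hu_cbct) < 1))
    stop("duplicate CBCT HU anchors (within 1 HU) between classes '",
         classes[ord][which(diff(hu_cbct) < 1)[1]], "' and '",
         classes[ord][which(diff(hu_cbct) < 1)[1] + 1], "'")
  if (diff(range(dens)) < 1.0)
    warning("VOI samples do not span air to bone; ",
            "calibration outside the sampled range is clamped")
  if (any(diff(dens) < 0)) {
    warning("density inversion across CBCT HU anchors; ",
            "applying pool-adjacent-violators monotonicity repair")
    dens <- pava(dens)
  }
  hu_density_table(hu_cbct, dens, modality = "CBCT")
}

#' Density to relative-stopping-power table
#'
#' Collapses the composition / mean-ionization lookup of a clinical dose
#' engine into a single piecewise-linear map from mass density to proton
#' stopping power relative to water.  RSP(1 g/cm^3) must be 1.
#'
#' @param density strictly increasing densities, g/cm^3.
#' @param rsp non-decreasing relative stopping powers.
#' @return object of class `rsp_table`.
#' @export
rsp_table <- function(density, rsp) {
  density <- as.numeric(density); rsp <- as.numeric(rsp)
  if (length(density) == 0) stop("empty RSP table")
  if (length(density) != length(rsp)) stop("length mismatch")
  if (any(diff(density) <= 0)) stop("densities must be strictly increasing")
  if (any(diff(rsp) < 0)) stop("RSP must be non-decreasing")
  at_water <- pw_linear(density, rsp, 1.0)
  if (abs(at_water - 1.0) > 1e-6)
    stop(sprintf("RSP at 1.0 g/cm^3 must be 1 (got %.8f)", at_water))
  structure(list(density = density, rsp = rsp), class = "rsp_table")
}

#' Default density to RSP anchors
#'
#' Anchors at vacuum/air, inflated lung, adipose, water and cortical-ish
#' bone; soft tissues track density closely, bone falls below it because
#' of its higher effective ionization energy.
#' @return an `rsp_table`.
#' @export
default_rsp_table <- function() {
  rsp_table(density = c(0.000, 0.260, 0.920, 1.000, 1.600),
            rsp = c(0.000, 0.275, 0.950, 1.000, 1.480))
}

#' Convert a density volume to relative stopping power
#'
#' @param grid `image_grid` with `quantity = "density"`.
#' @param table an [rsp_table].
#' @return `image_grid` with `quantity = "RSP"`.
#' @export
rsp_from_density <- function(grid, table = default_rsp_table()) {
  stopifnot(inherits(grid, "image_grid"), inherits(table, "rsp_table"))
  if (grid$quantity != "density") stop("input grid must hold density")
  vals <- pw_linear(table$density, table$rsp, grid$values)
  image_grid(array(vals, dim(grid$values)), grid$origin, grid$spacing,
             quantity = "RSP", frame = grid$frame)
}

#' Force a density override inside a structure
#'
#' Used for the solid-water base: every voxel of `mask` is set to
#' `value` g/cm^3 regardless of its imaged HU.
#' @param grid `image_grid` with `quantity = "density"`.
#' @param mask a `structure_mask` on the same geometry.
#' @param value override density, g/cm^3 (default solid water, 1.00).
#' @return the modified density grid.
#' @export
apply_density_override <- function(grid, mask, value = 1.00) {
  stopifnot(inherits(grid, "image_grid"), inherits(mask, "structure_mask"))
  if (grid$quantity != "density") stop("override applies to density grids")
  if (!all(dim(mask$mask) == dim(grid$values)))
    stop("mask geometry does not match grid")
  grid$values[mask$mask] <- value
  grid
}

# -- YAML serialization -------------------------------------------------

#' Read / write calibration tables as YAML
#'
#' HU-density tables serialize as `modality` plus a list of `[hu,
#' density]` pairs; RSP tables as `[density, rsp]` pairs.
#' @param x the table object.
#' @param path file path.
#' @export
write_hu_table <- function(x, path) {
  stopifnot(inherits(x, "hu_density_table"))
  yaml::write_yaml(list(modality = x$modality,
                        anchors = mapply(c, x$hu, x$density,
                                         SIMPLIFY = FALSE)), path)
  invisible(path)
}

#' @rdname write_hu_table
#' @export
read_hu_table <- function(path) {
  y <- yaml::read_yaml(path)
  a <- do.call(rbind, lapply(y$anchors, as.numeric))
  hu_density_table(a[, 1], a[, 2], modality = y$modality)
}

#' @rdname write_hu_table
#' @export
write_rsp_table <- function(x, path) {
  stopifnot(inherits(x, "rsp_table"))
  yaml::write_yaml(list(anchors = mapply(c, x$density, x$rsp,
                                         SIMPLIFY = FALSE)), path)
  invisible(path)
}

#' @rdname write_hu_table
#' @export
read_rsp_table <- function(path) {
  y <- yaml::read_yaml(path)
  a <- do.call(rbind, lapply(y$anchors, as.numeric))
  rsp_table(a[, 1], a[, 2])
}
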