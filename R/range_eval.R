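#' Extract a 2D dose plane from a 3D dose grid
#'
#' Trilinear interpolation of the volume at the lattice points of a
#' detector-style plane at the requested depth.  The lattice defaults to
#' the geometry of a supplied template plane (normally the measurement).
#'
#' @param dose `image_grid` with `quantity = "dose"`.
#' @param depth mm position along `axis`; must lie inside the grid.
#' @param axis beam-depth axis.
#' @param lattice a [planar_dose] template, or a list with `origin`
#'   (mm 2-vector), `spacing` (mm 2-vector) and `n` (2 counts).
#' @return a [planar_dose] at `depth`.
#' @export
extract_plane <- function(dose, depth, axis = 2, lattice) {
  stopifnot(inherits(dose, "image_grid"))
  rng <- range(grid_coords(dose, axis))
  if (depth < rng[1] || depth > rng[2])
    stop(sprintf("plane depth %.2f mm outside grid extent [%.2f, %.2f]",
                 depth, rng[1], rng[2]))
  if (inherits(lattice, "planar_dose"))
    lattice <- list(origin = lattice$origin, spacing = lattice$spacing,
                    n = dim(lattice$values))
  lat <- setdiff(1:3, axis)
  n <- lattice$n
  us <- lattice$origin[1] + (seq_len(n[1]) - 1) * lattice$spacing[1]
  vs <- lattice$origin[2] + (seq_len(n[2]) - 1) * lattice$spacing[2]
  pts <- matrix(0, n[1] * n[2], 3)
  pts[, lat[1]] <- rep(us, times = n[2])
  pts[, lat[2]] <- rep(vs, each = n[1])
  pts[, axis] <- depth
  vals <- matrix(trilinear_sample(dose, pts, fill = 0)$values, n[1], n[2])
  planar_dose(pmax(vals, 0), plane_axis = axis, depth = depth,
              origin = lattice$origin, spacing = lattice$spacing)
}

#' Sweep candidate depths and gamma-match against a measurement
#'
#' Extracts calculated planes at `step`-spaced candidate depths within
#' `window` mm of the measurement's physical depth and records the gamma
#' passing rate of each against the measurement (measurement = gamma
#' reference).  The lateral registration is never adjusted: under the
#' working assumption, a calculation error can only shift the dose
#' pattern along the range direction.
#'
#' @param measurement the measured [planar_dose] (gamma reference).
#' @param dose calculated 3D dose `image_grid`.
#' @param window half-width of the depth window, mm (default 10).
#' @param step candidate spacing, mm (default 1).
#' @param params a [gamma_params].
#' @return object of class `range_sweep_result` with `depths`,
#'   `pass_rates`, the physical depth, and a `degenerate` flag set when
#'   every candidate matches equally (gradient-free comparison).
#' @export
sweep_depths <- function(measurement, dose, window = 10, step = 1,
                         params = gamma_params()) {
  stopifnot(inherits(measurement, "planar_dose"),
            inherits(dose, "image_grid"))
  physical <- measurement$depth
  axis <- measurement$plane_axis
  rng <- range(grid_coords(dose, axis))
  if (physical - window < rng[1] || physical + window > rng[2])
    stop("depth window extends outside the dose grid")
  depths <- physical + seq(-window, window, by = step)
  rates <- vapply(depths, function(d) {
    pl <- extract_plane(dose, d, axis = axis, lattice = measurement)
    gamma_map(measurement, pl, params)$pass_rate
  }, 0)
  degenerate <- diff(range(rates)) < 1e-12
  if (degenerate)
    warning("passing rate identical at all candidate depths; ",
            "the comparison carries no range information")
  structure(list(depths = depths, pass_rates = rates,
                 physical_depth = physical, step = step,
                 params = params, degenerate = degenerate),
            class = "range_sweep_result")
}

#' @export
print.range_sweep_result <- function(x, ...) {
  cat(sprintf(
    "<range_sweep_result> %d depths in [%.1f, %.1f] mm; peak %.2f%% at %.1f mm\n",
    length(x$depths), min(x$depths), max(x$depths), max(x$pass_rates),
    x$depths[which.max(x$pass_rates)]))
  if (!is.null(x$best_depth))
    cat(sprintf("  refined best depth %.3f mm; range error %+.3f%% of %.1f mm WEPL\n",
                x$best_depth, x$range_error_pct, x$wepl_to_detector))
  invisible(x)
}

#' Refined best-match depth from a sweep
#'
#' The candidate with the highest passing rate, refined to sub-step
#' resolution by a parabolic fit through the peak and its two neighbors
#' when the peak is interior.  A plateau of equal maxima returns the
#' plateau midpoint with a low-confidence flag.
#'
#' @param sweep a `range_sweep_result` with at least 3 candidates.
#' @return best depth in mm, with attribute `low_confidence`.
#' @export
best_match <- function(sweep) {
  stopifnot(inherits(sweep, "range_sweep_result"))
  d <- sweep$depths; r <- sweep$pass_rates
  if (length(d) < 3) stop("best_match needs at least 3 candidate depths")
  if (diff(range(r)) < 1e-12)
    stop("all passing rates equal: gradient-free comparison, no best match")
  peak <- max(r)
  at_peak <- which(abs(r - peak) < 1e-9)
  low_conf <- FALSE
  if (length(at_peak) > 1) {
    best <- mean(range(d[at_peak]))
    low_conf <- TRUE
  } else {
    k <- at_peak
    if (k == 1 || k == length(d)) {
      best <- d[k]
      low_conf <- TRUE
    } else {
      denom <- r[k - 1] - 2 * r[k] + r[k + 1]
      best <- if (abs(denom) < 1e-12) d[k] else
        d[k] + 0.5 * sweep$step * (r[k - 1] - r[k + 1]) / denom
    }
  }
  structure(best, low_confidence = low_conf)
}

#' Percentage range error from a depth mismatch
#'
#' `epsilon = 100 * (physical - best) / wepl_to_detector`.  Sign
#' convention: positive when the measurement pattern is found at a
#' *shallower* calculated plane than the physical detector depth, i.e.
#' when the calculation's stopping-power/WEPL mapping is too high and
#' the calculated ranges fall short of the measured ones; a uniform
#' stopping-power overestimate of `f`% yields a range error of about
#' `+f`%.
#'
#' @param best_depth refined best-match depth, mm.
#' @param physical_depth actual detector depth, mm.
#' @param wepl_to_detector water-equivalent path length from the entry
#'   surface to the physical detector plane, mm (> 0); the denominator
#'   of the percentage.
#' @return range error in percent.
#' @export
percent_range_error <- function(best_depth, physical_depth,
                                wepl_to_detector) {
  if (!is.finite(wepl_to_detector) || wepl_to_detector <= 0)
    stop("wepl_to_detector must be positive")
  100 * (physical_depth - as.numeric(best_depth)) / wepl_to_detector
}

#' WEPL to the detector plane
#'
#' The denominator of the percentage range error.  Two definitions are
#' provided.  `"sensitivity"` (the default used by
#' [evaluate_range_uncertainty]) is the depth-sensitivity-weighted mean
#' WEPL over the detector lattice: each point is weighted by the squared
#' depth derivative of the calculated dose at the physical detector
#' depth (restricted to points at or above `threshold`% of the maximum).
#' This is the WEPL scale consistent with a weighted-least-squares
#' depth-shift estimator, so a uniform stopping-power error of `f`%
#' maps to a range error of about `f`%, even when the WEPL varies
#' laterally across the field (as it does under a curved phantom
#' surface).  `"central_axis"` is the WEPL along the column nearest the
#' beam's weight-averaged lateral center, simpler but biased high for
#' curved entry surfaces.
#'
#' @param rsp `image_grid` of relative stopping power.
#' @param beam the [beam_spec].
#' @param depth physical detector depth, mm.
#' @param dose calculated dose `image_grid` (needed for
#'   `"sensitivity"`).
#' @param lattice a [planar_dose] (or list with `origin`, `spacing`,
#'   `n`) giving the detector lattice (needed for `"sensitivity"`).
#' @param method `"sensitivity"` or `"central_axis"`.
#' @param threshold low-dose cutoff, % of the plane maximum.
#' @return WEPL in mm.
#' @export
wepl_to_detector <- function(rsp, beam, depth, dose = NULL,
                             lattice = NULL,
                             method = c("sensitivity", "central_axis"),
                             threshold = 10) {
  method <- match.arg(method)
  if (method == "central_axis")
    return(central_axis_wepl(rsp, beam, depth))
  if (is.null(dose) || is.null(lattice))
    stop("sensitivity-weighted WEPL needs the calculated dose and lattice")
  if (inherits(lattice, "planar_dose"))
    lattice <- list(origin = lattice$origin, spacing = lattice$spacing,
                    n = dim(lattice$values))
  axis <- beam$axis
  lat <- setdiff(1:3, axis)
  n <- lattice$n
  us <- lattice$origin[1] + (seq_len(n[1]) - 1) * lattice$spacing[1]
  vs <- lattice$origin[2] + (seq_len(n[2]) - 1) * lattice$spacing[2]
  mkpts <- function(y) {
    pts <- matrix(0, n[1] * n[2], 3)
    pts[, lat[1]] <- rep(us, times = n[2])
    pts[, lat[2]] <- rep(vs, each = n[1])
    pts[, axis] <- y
    pts
  }
  W <- wepl_profile(rsp, axis, beam$entry)
  wvals <- trilinear_sample(W, mkpts(depth))$values
  h <- dose$spacing[axis]
  d0 <- trilinear_sample(dose, mkpts(depth))$values
  dp <- trilinear_sample(dose, mkpts(depth + h))$values
  dm <- trilinear_sample(dose, mkpts(depth - h))$values
  sens2 <- ((dp - dm) / (2 * h))^2
  sel <- d0 >= threshold / 100 * max(d0) & sens2 > 0
  if (!any(sel))
    stop("calculated dose carries no depth sensitivity at the detector; ",
         "cannot define an effective WEPL")
  sum(wvals[sel] * sens2[sel]) / sum(sens2[sel])
}

# central-axis WEPL from the entry surface to `depth` along the beam
# axis, evaluated on the column nearest the beam's lateral center.
central_axis_wepl <- function(rsp, beam, depth, model = NULL) {
  W <- wepl_profile(rsp, beam$axis, beam$entry)
  lat <- setdiff(1:3, beam$axis)
  wmean <- stats::weighted.mean
  cu <- wmean(beam$spots$u, beam$spots$weight)
  cv <- wmean(beam$spots$v, beam$spots$weight)
  iu <- which.min(abs(grid_coords(rsp, lat[1]) - cu))
  iv <- which.min(abs(grid_coords(rsp, lat[2]) - cv))
  dcoords <- grid_coords(rsp, beam$axis)
  idx <- matrix(0L, length(dcoords), 3)
  idx[, lat[1]] <- iu; idx[, lat[2]] <- iv
  idx[, beam$axis] <- seq_along(dcoords)
  stats::approx(dcoords, W$values[idx], xout = depth, rule = 2)$y
}

#' End-to-end range-uncertainty evaluation on an image
#'
#' Chains the full verification pipeline: HU to density (with optional
#' structure overrides), density to RSP, beam dose recalculation, depth
#' sweep against the measurement, best-match refinement, and conversion
#' to a percentage range error normalized by the central-axis WEPL to
#' the physical detector plane.
#'
#' @param image `image_grid` of HU (CT or CBCT).
#' @param table the matching [hu_density_table].
#' @param rsp_tab an [rsp_table].
#' @param beam the planned [beam_spec] (weights included).
#' @param measurement measured [planar_dose].
#' @param overrides optional list of `list(mask =, value =)` density
#'   overrides (e.g. the solid-water base).
#' @param model a [bragg_model].
#' @param window,step depth-sweep window half-width and step, mm.
#' @param params a [gamma_params].
#' @return a `range_sweep_result` augmented with `best_depth`,
#'   `range_error_pct`, `wepl_to_detector`, `low_confidence`, and a
#'   `provenance` list (table modality, parameters).
#' @export
evaluate_range_uncertainty <- function(image, table, rsp_tab, beam,
                                       measurement, overrides = list(),
                                       model = bragg_model(),
                                       window = 10, step = 1,
                                       params = gamma_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  density <- stage("density_from_hu", density_from_hu(image, table))
  for (ov in overrides)
    density <- stage("override",
                     apply_density_override(density, ov$mask,
                                            ov$value %||% 1.00))
  rsp <- stage("rsp_from_density", rsp_from_density(density, rsp_tab))
  dose <- stage("compute_beam_dose", compute_beam_dose(beam, rsp, model))
  sweep <- stage("sweep_depths",
                 sweep_depths(measurement, dose, window = window,
                              step = step, params = params))
  best <- stage("best_match", best_match(sweep))
  # the denominator is evaluated at the matched plane: its dose pattern
  # reproduces the measurement, so the sensitivity weights (and the
  # WEPL) characterize the plane the measurement corresponds to
  wepl_det <- stage("wepl",
                    wepl_to_detector(rsp, beam, as.numeric(best),
                                     dose = dose, lattice = measurement,
                                     method = "sensitivity",
                                     threshold = params$threshold))
  eps <- stage("percent_range_error",
               percent_range_error(best, measurement$depth, wepl_det))
  sweep$best_depth <- as.numeric(best)
  sweep$low_confidence <- isTRUE(attr(best, "low_confidence"))
  sweep$range_error_pct <- eps
  sweep$wepl_to_detector <- wepl_det
  sweep$provenance <- list(
    modality = table$modality,
    window_mm = window, step_mm = step,
    gamma = unclass(params),
    bragg = unclass(model),
    denominator = "depth-sensitivity-weighted mean WEPL to detector plane")
  sweep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
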