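#' Gamma-index comparison parameters
#'
#' @param dd dose-difference criterion, % of the normalization dose.
#' @param dta distance-to-agreement criterion, mm.
#' @param norm `"max_ref"` (global normalization to the maximum reference
#'   dose, the plane-array QA convention) or an explicit dose in cGy.
#' @param threshold low-dose threshold, % of the normalization dose;
#'   reference points below it are excluded from the statistics.
#' @param search_radius search disk radius in multiples of `dta`.
#' @param step evaluated-plane interpolation step, mm (default `dta/10`
#'   at the standard 3 mm criterion, bounding the discretization error of
#'   gamma at roughly 0.1).
#' @return object of class `gamma_params`.
#' @export
gamma_params <- function(dd = 3, dta = 3, norm = "max_ref",
                         threshold = 10, search_radius = 3, step = 0.3) {
  if (dd <= 0 || dta <= 0) stop("dd and dta must be positive")
  if (threshold < 0 || threshold >= 100)
    stop("threshold must be in [0, 100)")
  if (search_radius < 1) stop("search_radius must be >= 1")
  if (step <= 0) stop("step must be positive")
  structure(list(dd = dd, dta = dta, norm = norm, threshold = threshold,
                 search_radius = search_radius, step = step),
            class = "gamma_params")
}

# shared definition of the candidate-offset lattice: step-spaced lattice
# positions within the search disk (inclusive boundary)
gamma_offsets <- function(params) {
  r <- params$search_radius * params$dta
  m <- ceiling(r / params$step)
  o <- params$step * (-m:m)
  g <- expand.grid(dx = o, dy = o)
  g <- g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, ]
  list(dx = g$dx, dy = g$dy, dist2 = g$dx^2 + g$dy^2)
}

plane_extent <- function(plane) {
  d <- dim(plane$values)
  list(x = c(plane$origin[1], plane$origin[1] + (d[1] - 1) * plane$spacing[1]),
       y = c(plane$origin[2], plane$origin[2] + (d[2] - 1) * plane$spacing[2]))
}

# vectorized bilinear interpolation on a planar_dose; points must lie
# inside the lattice extent (indices are clamped defensively)
plane_bilinear <- function(plane, x, y) {
  d <- dim(plane$values)
  ux <- (x - plane$origin[1]) / plane$spacing[1]
  uy <- (y - plane$origin[2]) / plane$spacing[2]
  ux <- pmin(pmax(ux, 0), d[1] - 1)
  uy <- pmin(pmax(uy, 0), d[2] - 1)
  i0 <- pmin(floor(ux), max(d[1] - 2, 0))
  j0 <- pmin(floor(uy), max(d[2] - 2, 0))
  fx <- ux - i0; fy <- uy - j0
  v <- plane$values
  base <- 1 + i0 + d[1] * j0
  ix <- if (d[1] > 1) 1L else 0L
  iy <- if (d[2] > 1) d[1] else 0L
  v[base] * (1 - fx) * (1 - fy) + v[base + ix] * fx * (1 - fy) +
    v[base + iy] * (1 - fx) * fy + v[base + ix + iy] * fx * fy
}

gamma_normalization <- function(reference, params) {
  dn <- if (is.numeric(params$norm)) params$norm else max(reference$values)
  if (!is.finite(dn) || dn <= 0)
    stop("normalization dose must be positive")
  dn
}

#' 2D gamma-index map of an evaluated plane against a reference
#'
#' For every reference point above the low-dose threshold, the gamma
#' index is the minimum over evaluated-plane positions `e` within the
#' search disk of
#' `sqrt(|e - r|^2 / dta^2 + (D_eval(e) - D_ref(r))^2 / (dd% * D_norm)^2)`,
#' with `D_eval` bilinearly interpolated on a `step`-spaced lattice of
#' offsets.  Candidates falling outside the evaluated plane are dropped
#' (truncated disk, flagged per point).  Gamma is not symmetric in its
#' arguments: the measurement is conventionally the reference.
#'
#' @param reference the reference [planar_dose] (e.g. the measurement).
#' @param evaluated the evaluated [planar_dose] (e.g. a calculated plane).
#' @param params a [gamma_params].
#' @return object of class `gamma_result`: gamma matrix (NA where
#'   excluded), logical `excluded` and `truncated` matrices, `pass_rate`
#'   (% of included points with gamma <= 1), `n_included`, `d_norm`, and
#'   the parameter echo.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params()) {
  stopifnot(inherits(reference, "planar_dose"),
            inherits(evaluated, "planar_dose"))
  if (reference$plane_axis != evaluated$plane_axis)
    stop("planes are perpendicular to different axes")
  re <- plane_extent(reference); ee <- plane_extent(evaluated)
  rad <- params$search_radius * params$dta
  if (re$x[1] > ee$x[2] + rad || re$x[2] < ee$x[1] - rad ||
      re$y[1] > ee$y[2] + rad || re$y[2] < ee$y[1] - rad)
    stop("reference and evaluated planes do not overlap spatially ",
         "(even within the search radius)")
  dn <- gamma_normalization(reference, params)
  dt <- params$dd / 100 * dn
  thr <- params$threshold / 100 * dn
  off <- gamma_offsets(params)
  d <- dim(reference$values)
  rx <- plane_coords(reference, 1)
  ry <- plane_coords(reference, 2)
  gam <- matrix(NA_real_, d[1], d[2])
  excl <- matrix(FALSE, d[1], d[2])
  trunc <- matrix(FALSE, d[1], d[2])
  eps <- 1e-9
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dr <- reference$values[i, j]
    if (dr < thr) { excl[i, j] <- TRUE; next }
    px <- rx[i] + off$dx
    py <- ry[j] + off$dy
    ok <- px >= ee$x[1] - eps & px <= ee$x[2] + eps &
      py >= ee$y[1] - eps & py <= ee$y[2] + eps
    if (!all(ok)) trunc[i, j] <- TRUE
    if (!any(ok)) { gam[i, j] <- Inf; next }
    de <- plane_bilinear(evaluated, px[ok], py[ok])
    g2 <- off$dist2[ok] / params$dta^2 + (de - dr)^2 / dt^2
    gam[i, j] <- sqrt(min(g2))
  }
  if (all(excl))
    stop("all reference points fall below the low-dose threshold")
  new_gamma_result(gam, excl, trunc, params, dn)
}

new_gamma_result <- function(gam, excl, trunc, params, dn) {
  inc <- !excl
  passing <- gam[inc] <= 1 + 1e-9
  structure(list(gamma = gam, excluded = excl, truncated = trunc,
                 pass_rate = 100 * mean(passing),
                 n_included = sum(inc), d_norm = dn, params = params),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.2f%% passing (%d/%d included points, %d excluded < %g%%)\n",
    x$pass_rate, sum(x$gamma[!x$excluded] <= 1 + 1e-9), x$n_included,
    sum(x$excluded), x$params$threshold))
  cat(sprintf("  criteria %g%%/%g mm, norm %.4g cGy\n",
              x$params$dd, x$params$dta, x$d_norm))
  invisible(x)
}

#' Exhaustive brute-force gamma oracle
#'
#' Same definition as [gamma_map], evaluated by plain exhaustive search
#' over the full interpolated disk with an independent bilinear
#' interpolation, intended as a test oracle.  Guarded to small planes.
#'
#' @inheritParams gamma_map
#' @return a `gamma_result`.
#' @export
brute_force_gamma <- function(reference, evaluated,
                              params = gamma_params()) {
  d <- dim(reference$values)
  if (d[1] > 50 || d[2] > 50)
    stop("brute_force_gamma is guarded to reference planes <= 50x50")
  re <- plane_extent(reference); ee <- plane_extent(evaluated)
  r <- params$search_radius * params$dta
  if (re$x[1] > ee$x[2] + r || re$x[2] < ee$x[1] - r ||
      re$y[1] > ee$y[2] + r || re$y[2] < ee$y[1] - r)
    stop("reference and evaluated planes do not overlap spatially ",
         "(even within the search radius)")
  dn <- gamma_normalization(reference, params)
  dt <- params$dd / 100 * dn
  thr <- params$threshold / 100 * dn
  m <- ceiling(r / params$step)
  ev <- evaluated$values
  ed <- dim(ev)
  exs <- plane_coords(evaluated, 1)
  eys <- plane_coords(evaluated, 2)
  # cell lookup + area weights, written independently of plane_bilinear;
  # degenerate (single row/column) dimensions collapse their weight
  axis_cell <- function(coords, x) {
    if (length(coords) == 1) return(list(i = 1L, i2 = 1L, t = 0))
    i <- findInterval(x, coords, all.inside = TRUE)
    t <- (x - coords[i]) / (coords[i + 1] - coords[i])
    list(i = i, i2 = i + 1L, t = min(max(t, 0), 1))
  }
  interp_eval <- function(x, y) {
    cx <- axis_cell(exs, x); cy <- axis_cell(eys, y)
    ev[cx$i, cy$i] * (1 - cx$t) * (1 - cy$t) +
      ev[cx$i2, cy$i] * cx$t * (1 - cy$t) +
      ev[cx$i, cy$i2] * (1 - cx$t) * cy$t +
      ev[cx$i2, cy$i2] * cx$t * cy$t
  }
  gam <- matrix(NA_real_, d[1], d[2])
  excl <- matrix(FALSE, d[1], d[2])
  trunc <- matrix(FALSE, d[1], d[2])
  rx <- plane_coords(reference, 1)
  ry <- plane_coords(reference, 2)
  eps <- 1e-9
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dr <- reference$values[i, j]
    if (dr < thr) { excl[i, j] <- TRUE; next }
    best <- Inf
    any_dropped <- FALSE; any_kept <- FALSE
    for (a in -m:m) for (b in -m:m) {
      dx <- a * params$step; dy <- b * params$step
      if (dx * dx + dy * dy > r * r + 1e-9) next
      x <- rx[i] + dx; y <- ry[j] + dy
      if (x < ee$x[1] - eps || x > ee$x[2] + eps ||
          y < ee$y[1] - eps || y > ee$y[2] + eps) {
        any_dropped <- TRUE; next
      }
      any_kept <- TRUE
      de <- interp_eval(x, y)
      g2 <- (dx * dx + dy * dy) / params$dta^2 + (de - dr)^2 / (dt * dt)
      if (g2 < best) best <- g2
    }
    trunc[i, j] <- any_dropped
    gam[i, j] <- if (any_kept) sqrt(best) else Inf
  }
  if (all(excl))
    stop("all reference points fall below the low-dose threshold")
  new_gamma_result(gam, excl, trunc, params, dn)
}

#' Gamma passing rate
#'
#' `100 * #(gamma <= 1) / #included`; excluded (below-threshold) points
#' do not count.
#' @param result a `gamma_result`.
#' @return percentage in [0, 100].
#' @export
passing_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$gamma[!result$excluded]
  if (length(g) == 0) stop("no included points in gamma result")
  100 * mean(g <= 1 + 1e-9)
}
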