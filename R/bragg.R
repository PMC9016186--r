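#' Analytic Bragg-peak depth-dose model
#'
#' A two-piece analytic pristine peak standing in for a Monte Carlo depth
#' dose: an entrance plateau `p` plus a proximal Gaussian shoulder of
#' width `sigma_p` for water-equivalent depths `w <= R`, and a pure
#' Gaussian distal falloff of width `sigma_d` beyond the range, continuous
#' with `D(R) = 1`:
#' \deqn{D(w) = p + (1-p) e^{-(w-R)^2 / 2\sigma_p^2}, \quad w \le R}
#' \deqn{D(w) = e^{-(w-R)^2 / 2\sigma_d^2}, \quad w > R}
#' The distal 50% depth therefore sits at `R + sigma_d * sqrt(2 log 2)`.
#'
#' @param plateau entrance plateau level relative to the peak, in [0, 1).
#' @param sigma_p proximal shoulder width, mm.
#' @param sigma_d distal falloff width, mm (the range-sensitive gradient).
#' @return object of class `bragg_model`.
#' @export
bragg_model <- function(plateau = 0.35, sigma_p = 6.0, sigma_d = 3.0) {
  if (plateau < 0 || plateau >= 1) stop("plateau must be in [0, 1)")
  if (sigma_p <= 0 || sigma_d <= 0) stop("sigma_p and sigma_d must be > 0")
  structure(list(plateau = plateau, sigma_p = sigma_p, sigma_d = sigma_d),
            class = "bragg_model")
}

#' Pristine Bragg depth dose
#' @param w water-equivalent depth(s), mm.
#' @param R nominal range (depth of the peak), mm, > 0.
#' @param model a [bragg_model].
#' @return relative dose, peak-normalized to 1 at `w = R`.
#' @export
pristine_bragg <- function(w, R, model = bragg_model()) {
  if (R <= 0) stop("range R must be positive")
  dw <- w - R
  prox <- model$plateau +
    (1 - model$plateau) * exp(-dw^2 / (2 * model$sigma_p^2))
  dist <- exp(-dw^2 / (2 * model$sigma_d^2))
  ifelse(dw <= 0, prox, dist)
}

axis_perm <- function(axis) c(axis, setdiff(1:3, axis))

#' Cumulative water-equivalent depth along grid-aligned rays
#'
#' Midpoint-rule WEPL: at voxel `k` (counted from the entry side) along a
#' column, `W_k = sum_{j<=k} RSP_j * delta - RSP_k * delta / 2`, so the
#' value is the water-equivalent depth of the voxel *center*.  Monotone
#' non-decreasing along each ray for non-negative RSP.
#'
#' @param rsp `image_grid` with `quantity = "RSP"` (non-negative).
#' @param axis beam-depth axis (1-3).
#' @param entry `"+"` if the beam enters from the low-coordinate side of
#'   `axis` (the default, anterior for axis 2), `"-"` for the opposite.
#' @return `image_grid` holding the water-equivalent depth in mm of every
#'   voxel center (tagged with quantity `"RSP"`, the dimensionless family
#'   it derives from).
#' @export
wepl_profile <- function(rsp, axis = 2, entry = c("+", "-")) {
  entry <- match.arg(entry)
  stopifnot(inherits(rsp, "image_grid"))
  if (any(rsp$values < 0)) stop("RSP values must be non-negative")
  delta <- rsp$spacing[axis]
  perm <- axis_perm(axis)
  a <- aperm(rsp$values, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  if (entry == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = d[1])
  w <- (cs - m / 2) * delta
  if (entry == "-") w <- w[rev(seq_len(nrow(w))), , drop = FALSE]
  out <- aperm(array(w, d), order(perm))
  g <- rsp
  g$values <- out
  g$quantity <- "RSP"   # mm water-equivalent depth; reuses the RSP slot
  g
}

#' Pencil-beam spot list
#'
#' @param spots data frame with one row per spot: columns `u`, `v`
#'   (lateral position, mm, on the two non-beam axes in increasing axis
#'   order), `range` (nominal water-equivalent range, mm), `sigma`
#'   (lateral Gaussian width, mm) and `weight` (>= 0).
#' @param axis beam-depth axis (default 2, anterior-posterior).
#' @param entry entry side, `"+"` (low coordinate) or `"-"`.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(spots, axis = 2, entry = "+") {
  spots <- as.data.frame(spots)
  need <- c("u", "v", "range", "sigma", "weight")
  if (!all(need %in% names(spots)))
    stop("spots need columns ", paste(need, collapse = ", "))
  if (any(spots$range <= 0)) stop("all spot ranges must be positive")
  if (any(spots$sigma <= 0)) stop("all lateral sigmas must be positive")
  if (any(spots$weight < 0) || !any(spots$weight > 0))
    stop("weights must be non-negative with at least one positive")
  structure(list(spots = spots, axis = as.integer(axis), entry = entry),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> %d spots on axis %d (entry %s); range [%.1f, %.1f] mm\n",
    nrow(x$spots), x$axis, x$entry, min(x$spots$range), max(x$spots$range)))
  invisible(x)
}

#' Compute 3D dose from a spot list on an RSP grid
#'
#' Superposition of analytic pencil beams: each spot deposits
#' `weight * D_bragg(W(voxel), R) * G(lateral offset; sigma)` where `W` is
#' the midpoint-rule WEPL along the (grid-aligned) beam axis and `G` is a
#' normalized 2D Gaussian in the plane perpendicular to the beam.  Linear
#' in the weights; lateral width constant with depth.
#'
#' @param beam a [beam_spec]; its axis must be a grid axis.
#' @param rsp `image_grid` of relative stopping power.
#' @param model a [bragg_model].
#' @param cutoff_sigma lateral truncation of the Gaussian kernel, in
#'   multiples of `sigma` (default 4; dose beyond is dropped).
#' @param wepl optional precomputed [wepl_profile] result for `rsp`.
#' @return `image_grid` with `quantity = "dose"` (cGy when weights carry
#'   cGy normalization).
#' @export
compute_beam_dose <- function(beam, rsp, model = bragg_model(),
                              cutoff_sigma = 4, wepl = NULL) {
  stopifnot(inherits(beam, "beam_spec"), inherits(rsp, "image_grid"))
  axis <- beam$axis
  if (!axis %in% 1:3)
    stop("beam axis must be aligned with a grid axis (1-3)")
  if (is.null(wepl)) wepl <- wepl_profile(rsp, axis, beam$entry)
  lat <- setdiff(1:3, axis)
  perm <- c(axis, lat)
  wp <- aperm(wepl$values, perm)
  d <- dim(wp)
  u <- rsp$origin[lat[1]] + (seq_len(d[2]) - 1) * rsp$spacing[lat[1]]
  v <- rsp$origin[lat[2]] + (seq_len(d[3]) - 1) * rsp$spacing[lat[2]]
  sp <- beam$spots
  dose <- cpp_accumulate_spots(
    as.numeric(wp), as.integer(d), u, v,
    as.matrix(sp[, c("u", "v", "range", "sigma", "weight")]),
    model$plateau, model$sigma_p, model$sigma_d, cutoff_sigma)
  out <- aperm(array(dose, d), order(perm))
  image_grid(out, rsp$origin, rsp$spacing, quantity = "dose",
             frame = rsp$frame)
}

# Influence matrix: dose per unit weight of each spot at sample points.
# pts_idx: n x 3 matrix of voxel indices (1-based); W: wepl grid.
spot_influence <- function(beam, rsp, model, wepl, pts_idx) {
  lat <- setdiff(1:3, beam$axis)
  coords <- cbind(
    rsp$origin[1] + (pts_idx[, 1] - 1) * rsp$spacing[1],
    rsp$origin[2] + (pts_idx[, 2] - 1) * rsp$spacing[2],
    rsp$origin[3] + (pts_idx[, 3] - 1) * rsp$spacing[3])
  sp <- beam$spots
  cpp_spot_influence(wepl$values[pts_idx],
                     coords[, lat[1]], coords[, lat[2]],
                     as.matrix(sp[, c("u", "v", "range", "sigma",
                                      "weight")]),
                     model$plateau, model$sigma_p, model$sigma_d)
}
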