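#' Cumulative dose-volume histogram for one structure
#'
#' `V(d)` is the percentage of the structure volume receiving at least
#' dose `d`, tabulated on uniform bin edges from 0; `V(0) = 100` exactly
#' and the curve is monotone non-increasing, reaching 0 beyond the
#' maximum dose.
#'
#' @param dose `image_grid` with `quantity = "dose"`.
#' @param mask `structure_mask` on the same geometry (nonempty).
#' @param bin_width histogram bin width, cGy (default 1).
#' @return object of class `dvh_curve`: `structure`, `edges` (cGy),
#'   `volume_pct`, `volume_cm3`, `dmax`, `dmean`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 1) {
  stopifnot(inherits(dose, "image_grid"), inherits(mask, "structure_mask"))
  if (dose$quantity != "dose") stop("expected a dose grid")
  if (!all(dim(mask$mask) == dim(dose$values)) ||
      max(abs(mask$origin - dose$origin)) > 1e-6 ||
      max(abs(mask$spacing - dose$spacing)) > 1e-6)
    stop("mask and dose grid geometry differ")
  dvals <- dose$values[mask$mask]
  if (length(dvals) == 0) stop("empty structure mask")
  edges <- seq(0, max(dvals) + 2 * bin_width, by = bin_width)
  # V(edge) = % of voxels with dose >= edge
  v <- 100 * (1 - stats::ecdf(dvals)(edges - 1e-12))
  v[1] <- 100
  structure(list(structure = mask$name, edges = edges, volume_pct = v,
                 volume_cm3 = length(dvals) * prod(dose$spacing) / 1000,
                 dmax = max(dvals), dmean = mean(dvals),
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> '%s': %.2f cm^3, Dmean %.1f cGy, Dmax %.1f cGy\n",
    x$structure, x$volume_cm3, x$dmean, x$dmax))
  invisible(x)
}

#' Evaluate a DVH metric
#'
#' Supported metric tokens: `"V100%"` (or any `"Vx%"`: volume percentage
#' receiving at least `x`% of the prescription, linearly interpolated
#' between bin edges), `"Dmean"`, `"Dmax"`.
#'
#' @param curve a [compute_dvh] result.
#' @param metric metric token.
#' @param prescription prescription dose, cGy (needed for `Vx%`).
#' @return metric value (% for Vx, cGy for Dmean/Dmax).
#' @export
dvh_metric <- function(curve, metric, prescription = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (metric == "Dmean") return(curve$dmean)
  if (metric == "Dmax") return(curve$dmax)
  m <- regmatches(metric, regexec("^V([0-9.]+)%$", metric))[[1]]
  if (length(m) == 2) {
    if (is.null(prescription)) stop("Vx% metrics need a prescription")
    level <- as.numeric(m[2]) / 100 * prescription
    if (level <= 0) return(100)
    if (level > max(curve$edges)) return(0)
    return(stats::approx(curve$edges, curve$volume_pct, xout = level,
                         rule = 2)$y)
  }
  stop("unknown DVH metric token: ", metric)
}

#' Daily dose verification on a CBCT (or repeat CT)
#'
#' Implements the daily verification workflow: rigidly align the daily
#' image into the planning frame, convert to density (with overrides)
#' and stopping power using the modality's calibration, recalculate the
#' planned beam (no re-optimization), compute the configured DVH
#' metrics, and compare them against flag thresholds.
#'
#' The beam corridor (lateral spot extent padded by 3 sigma, full depth)
#' must be covered by the daily image after alignment; a daily image
#' whose field of view truncates the beam path is a hard error, since
#' the entire beam path must be inside the FOV for the recalculated
#' dose to be trusted.
#'
#' @param daily_image `image_grid` of HU (CBCT or CT) in its own frame.
#' @param transform `rigid_transform` mapping daily frame to planning
#'   frame.
#' @param table `hu_density_table` for the daily image's modality.
#' @param rsp_tab an [rsp_table].
#' @param beam planned [beam_spec] with weights.
#' @param target target `structure_mask` (planning frame).
#' @param oars named list of OAR `structure_mask`s.
#' @param prescription prescription dose, cGy.
#' @param overrides density overrides as in
#'   [evaluate_range_uncertainty].
#' @param model a [bragg_model].
#' @param thresholds named list of flag rules; default flags target
#'   V100% below 95.
#' @param fraction_label free-text label for the fraction.
#' @param modality `"CT"` or `"CBCT"` (defaults to the table modality).
#' @param bin_width DVH bin width, cGy.
#' @return object of class `verification_report`.
#' @export
verify_daily <- function(daily_image, transform, table, rsp_tab, beam,
                         target, oars = list(), prescription,
                         overrides = list(), model = bragg_model(),
                         thresholds = list(target_v100_min = 95),
                         fraction_label = "fx", modality = NULL,
                         bin_width = 1) {
  stopifnot(inherits(daily_image, "image_grid"),
            inherits(target, "structure_mask"))
  planning_geom <- list(origin = target$origin, spacing = target$spacing,
                        shape = dim(target$mask))
  aligned <- resample_rigid(daily_image, transform, planning_geom)
  outside <- attr(aligned, "outside")
  # FOV check over the beam corridor
  lat <- setdiff(1:3, beam$axis)
  pad <- 3 * max(beam$spots$sigma)
  ucoords <- aligned$origin[lat[1]] +
    (seq_len(dim(aligned$values)[lat[1]]) - 1) * aligned$spacing[lat[1]]
  vcoords <- aligned$origin[lat[2]] +
    (seq_len(dim(aligned$values)[lat[2]]) - 1) * aligned$spacing[lat[2]]
  usel <- ucoords >= min(beam$spots$u) - pad &
    ucoords <= max(beam$spots$u) + pad
  vsel <- vcoords >= min(beam$spots$v) - pad &
    vcoords <= max(beam$spots$v) + pad
  corridor <- array(FALSE, dim(aligned$values))
  sel <- list(TRUE, TRUE, TRUE)
  sel[[lat[1]]] <- usel; sel[[lat[2]]] <- vsel
  corridor[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  if (any(outside & corridor))
    stop("daily image field of view does not cover the entire beam path; ",
         "the full path must be inside the FOV for dose recalculation")

  density <- density_from_hu(aligned, table)
  for (ov in overrides)
    density <- apply_density_override(density, ov$mask, ov$value %||% 1.00)
  rsp <- rsp_from_density(density, rsp_tab)
  dose <- compute_beam_dose(beam, rsp, model)

  metrics <- list()
  tgt_curve <- compute_dvh(dose, target, bin_width)
  metrics[[paste0(target$name, ".V100%")]] <-
    dvh_metric(tgt_curve, "V100%", prescription)
  for (nm in names(oars)) {
    cv <- compute_dvh(dose, oars[[nm]], bin_width)
    metrics[[paste0(nm, ".Dmean")]] <- dvh_metric(cv, "Dmean")
    metrics[[paste0(nm, ".Dmax")]] <- dvh_metric(cv, "Dmax")
  }
  flags <- list()
  if (!is.null(thresholds$target_v100_min)) {
    v100 <- metrics[[paste0(target$name, ".V100%")]]
    flags[[length(flags) + 1]] <- list(
      metric = paste0(target$name, ".V100%"),
      threshold = thresholds$target_v100_min,
      triggered = v100 < thresholds$target_v100_min)
  }
  structure(list(
    fraction = fraction_label,
    modality = modality %||% table$modality,
    prescription = prescription,
    metrics = metrics,
    flags = flags,
    provenance = list(table_modality = table$modality,
                      transform = as.numeric(transform$matrix),
                      bragg = unclass(model),
                      bin_width = bin_width)),
    class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %s (%s), prescription %g cGy\n",
              x$fraction, x$modality, x$prescription))
  for (nm in names(x$metrics))
    cat(sprintf("  %-24s %8.2f\n", nm, x$metrics[[nm]]))
  for (fl in x$flags)
    if (isTRUE(fl$triggered))
      cat(sprintf("  FLAG: %s below threshold %g\n", fl$metric,
                  fl$threshold))
  invisible(x)
}

#' Serialize / restore a verification report (JSON)
#' @param report a `verification_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "verification_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$metrics <- lapply(x$metrics, as.numeric)
  x$flags <- lapply(x$flags, function(fl)
    list(metric = fl$metric, threshold = as.numeric(fl$threshold),
         triggered = isTRUE(fl$triggered)))
  structure(x, class = "verification_report")
}

#' Trend table over serial verification reports
#'
#' One row per fraction with every metric, plus a modality-stratified
#' summary (min, max, worst fraction) per metric.
#'
#' @param reports list of `verification_report`s sharing one
#'   prescription.
#' @return list with `table` (data.frame, one row per report) and
#'   `summary` (data.frame per metric and modality).
#' @export
batch_report <- function(reports) {
  if (length(reports) < 1) stop("need at least one report")
  presc <- vapply(reports, function(r) r$prescription, 0)
  if (diff(range(presc)) > 1e-9)
    stop("reports mix different prescription doses")
  metric_names <- unique(unlist(lapply(reports, function(r)
    names(r$metrics))))
  tab <- data.frame(
    fraction = vapply(reports, function(r) r$fraction, ""),
    modality = vapply(reports, function(r) r$modality, ""),
    stringsAsFactors = FALSE)
  for (nm in metric_names)
    tab[[nm]] <- vapply(reports, function(r)
      r$metrics[[nm]] %||% NA_real_, 0)
  summ <- do.call(rbind, lapply(metric_names, function(nm) {
    do.call(rbind, lapply(unique(tab$modality), function(mod) {
      rows <- tab[tab$modality == mod, ]
      vals <- rows[[nm]]
      worst_i <- if (grepl("V100", nm)) which.min(vals) else which.max(vals)
      data.frame(metric = nm, modality = mod, n = nrow(rows),
                 min = min(vals), max = max(vals),
                 worst_fraction = rows$fraction[worst_i],
                 stringsAsFactors = FALSE)
    }))
  }))
  list(table = tab, summary = summ)
}
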