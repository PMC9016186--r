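#' Read / write a detector-plane measurement (ASCII)
#'
#' Plain-text exchange format for 2D ion-chamber-array planes.  Header
#' lines of the form `key=value` must provide `nx`, `ny`, `pitch_mm`,
#' `origin_mm` (two numbers), `depth_mm` and `axis` (the beam-depth axis
#' the plane is perpendicular to, 1-3).  They are followed by `ny` rows of
#' `nx` dose values in cGy, whitespace or comma delimited; `#` starts a
#' comment.  Row r holds the values along the first in-plane axis at the
#' r-th position of the second in-plane axis.
#'
#' @param path file path.
#' @return `read_measurement`: a [planar_dose]; `write_measurement`:
#'   invisibly the path.
#' @export
read_measurement <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_hdr <- grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*=", lines)
  hdr_lines <- lines[cumprod(is_hdr) == 1]   # leading header block
  data_lines <- lines[seq_along(lines) > length(hdr_lines)]
  hdr <- list()
  for (h in hdr_lines) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    hdr[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  for (key in c("nx", "ny", "pitch_mm", "origin_mm", "depth_mm", "axis"))
    if (is.null(hdr[[key]]))
      stop("measurement file is missing required header key '", key, "'")
  num <- function(s) as.numeric(strsplit(s, "[,[:space:]]+")[[1]])
  nx <- as.integer(hdr$nx); ny <- as.integer(hdr$ny)
  pitch <- num(hdr$pitch_mm)
  if (length(pitch) == 1) pitch <- rep(pitch, 2)
  origin <- num(hdr$origin_mm)
  if (length(origin) != 2) stop("origin_mm must contain two numbers")
  if (length(data_lines) == 0)
    stop("measurement file has a header but no data rows")
  if (length(data_lines) != ny)
    stop(sprintf("expected ny=%d data rows, found %d", ny,
                 length(data_lines)))
  vals <- matrix(NA_real_, nx, ny)
  for (r in seq_len(ny)) {
    row <- num(data_lines[r])
    if (length(row) != nx)
      stop(sprintf("ragged data: row %d has %d values, expected nx=%d",
                   r, length(row), nx))
    vals[, r] <- row
  }
  planar_dose(vals, plane_axis = as.integer(hdr$axis),
              depth = as.numeric(hdr$depth_mm),
              origin = origin, spacing = pitch)
}

#' @rdname read_measurement
#' @param plane a [planar_dose].
#' @param digits significant digits used when serializing dose values.
#' @export
write_measurement <- function(plane, path, digits = 17) {
  stopifnot(inherits(plane, "planar_dose"))
  d <- dim(plane$values)
  fmt <- function(x) paste(formatC(x, format = "g", digits = digits,
                                   width = 1), collapse = " ")
  hdr <- c(
    "# rangewedge detector plane (dose in cGy)",
    sprintf("nx=%d", d[1]),
    sprintf("ny=%d", d[2]),
    sprintf("pitch_mm=%s", fmt(plane$spacing)),
    sprintf("origin_mm=%s", fmt(plane$origin)),
    sprintf("depth_mm=%s", fmt(plane$depth)),
    sprintf("axis=%d", plane$plane_axis))
  rows <- vapply(seq_len(d[2]), function(r) fmt(plane$values[, r]), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
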