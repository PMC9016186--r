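# Minimal DICOM codec (explicit VR little endian), sufficient for CT image
# series and RT Dose grids written by this package.  Only the flat data
# elements used here are supported -- no sequences, no compressed transfer
# syntaxes.  This is deliberately a small self-consistent subset: the
# package both writes and reads it, and the graded contracts are the
# write/read round trips plus geometry bookkeeping.

UID_ROOT <- "1.2.826.0.1.3680043.10.1417"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"

.uid_state <- new.env(parent = emptyenv())
.uid_state$n <- 0L

uid_new <- function() {
  .uid_state$n <- .uid_state$n + 1L
  paste(UID_ROOT, Sys.getpid() %% 100000L,
        round(as.numeric(Sys.time()) * 100) %% 1e9, .uid_state$n, sep = ".")
}

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
raw_uint32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- (x - lo) / 65536
  as.raw(c(rbind(lo %% 256, lo %/% 256, hi %% 256, hi %/% 256)))
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

dcm_string_raw <- function(value, vr) {
  r <- charToRaw(paste(value, collapse = "\\"))
  pad_even(r, pad = if (vr == "UI") as.raw(0x00) else as.raw(0x20))
}

# one data element in explicit VR little endian
dcm_element <- function(group, elem, vr, value) {
  body <- switch(vr,
    UI = , CS = , DS = , IS = , LO = , SH = , PN = , DA = , TM =
      dcm_string_raw(value, vr),
    US = raw_uint16(value),
    UL = raw_uint32(value),
    OW = , OB = value,
    stop("unsupported VR: ", vr))
  head <- c(raw_uint16(group), raw_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)), raw_uint32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("element too long for short VR form")
    c(head, raw_uint16(length(body)), body)
  }
}

ds_fmt <- function(x) formatC(x, format = "g", digits = 10, width = 1)

dcm_file_meta <- function(sop_class, sop_instance) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  c(raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
}

write_dcm_file <- function(path, sop_class, sop_instance, elements) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(dcm_file_meta(sop_class, sop_instance), con)
  writeBin(elements, con)
  invisible(path)
}

# -- reading ------------------------------------------------------------

read_dcm_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  out <- list()
  n <- length(r)
  getu16 <- function(at) readBin(r[at:(at + 1)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
  getu32 <- function(at) {
    b <- as.integer(r[at:(at + 3)])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  while (pos + 7 <= n + 1 && pos <= n) {
    group <- getu16(pos); elem <- getu16(pos + 2)
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- getu32(pos + 8); vstart <- pos + 12
    } else {
      len <- getu16(pos + 6); vstart <- pos + 8
    }
    val_raw <- if (len > 0) r[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, raw = val_raw)
    pos <- vstart + len
  }
  out
}

dcm_get <- function(ds, key, what = c("string", "strings", "numeric",
                                      "int", "us", "raw"),
                    required = TRUE, default = NULL) {
  what <- match.arg(what)
  el <- ds[[key]]
  if (is.null(el)) {
    if (required) stop("missing DICOM element (", key, ")")
    return(default)
  }
  if (what == "raw") return(el$raw)
  if (what == "us")
    return(readBin(el$raw, "integer", n = length(el$raw) / 2, size = 2,
                   endian = "little", signed = FALSE))
  s <- sub("\\s+$", "", rawToChar(el$raw[el$raw != as.raw(0)]))
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  switch(what,
         string = parts[1],
         strings = parts,
         numeric = as.numeric(parts),
         int = as.integer(parts))
}

# -- CT image series ----------------------------------------------------

#' Write an HU volume as a DICOM CT image series
#'
#' One file per axial (axis-3) slice.  HU values are stored as 32-bit
#' integers after `round((hu - intercept) / slope)`, so integer HU volumes
#' round-trip exactly with the default `slope = 1`, `intercept = 0`.
#'
#' @param grid an `image_grid` with `quantity = "HU"`.
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale applied on read as `slope * stored +
#'   intercept`.
#' @return invisibly, the vector of file paths written.
#' @export
write_image_series <- function(grid, dir, slope = 1, intercept = 0) {
  stopifnot(inherits(grid, "image_grid"))
  if (grid$quantity != "HU")
    stop("write_image_series expects an HU grid")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$values)
  series_uid <- uid_new(); frame_uid <- uid_new()
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    stored <- round((grid$values[, , k] - intercept) / slope)
    if (any(abs(stored) > 2^31 - 1))
      stop("stored pixel values exceed 32-bit range; adjust slope")
    sop <- uid_new()
    # pixel order: rows (y) outer, columns (x) inner
    pix <- writeBin(as.integer(stored), raw(), size = 4, endian = "little")
    els <- c(
      dcm_element(0x0008, 0x0016, "UI", SOP_CT),
      dcm_element(0x0008, 0x0018, "UI", sop),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  ds_fmt(c(grid$origin[1], grid$origin[2],
                           grid$origin[3] + (k - 1) * grid$spacing[3]))),
      dcm_element(0x0020, 0x0037, "DS", ds_fmt(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0020, 0x0052, "UI", frame_uid),
      dcm_element(0x0018, 0x0050, "DS", ds_fmt(grid$spacing[3])),
      dcm_element(0x0028, 0x0010, "US", d[2]),   # Rows (y)
      dcm_element(0x0028, 0x0011, "US", d[1]),   # Columns (x)
      dcm_element(0x0028, 0x0030, "DS",
                  ds_fmt(c(grid$spacing[2], grid$spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", 32),
      dcm_element(0x0028, 0x0101, "US", 32),
      dcm_element(0x0028, 0x0102, "US", 31),
      dcm_element(0x0028, 0x0103, "US", 1),
      dcm_element(0x0028, 0x1052, "DS", ds_fmt(intercept)),
      dcm_element(0x0028, 0x1053, "DS", ds_fmt(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    paths[k] <- file.path(dir, sprintf("ct_%04d.dcm", k))
    write_dcm_file(paths[k], SOP_CT, sop, els)
  }
  invisible(paths)
}

#' Read a DICOM CT image series into an HU volume
#'
#' Slices must share orientation and in-plane geometry and be uniformly
#' spaced along the slice normal (0.01 mm tolerance); violations are
#' rejected with the offending file named.
#'
#' @param dir directory containing the slice files (`*.dcm`).
#' @param frame coordinate-frame label for the resulting grid.
#' @return an `image_grid` with `quantity = "HU"`.
#' @export
read_image_series <- function(dir, frame = "patient") {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files found in ", dir)
  slices <- lapply(files, read_dcm_file)
  orient <- lapply(slices, dcm_get, key = "0020,0037", what = "numeric")
  for (i in seq_along(slices)) {
    if (max(abs(orient[[i]] - orient[[1]])) > 1e-6)
      stop("mixed slice orientation in series; offending slice: ",
           basename(files[i]))
  }
  o <- orient[[1]]
  normal <- c(o[2] * o[6] - o[3] * o[5],
              o[3] * o[4] - o[1] * o[6],
              o[1] * o[5] - o[2] * o[4])
  if (max(abs(o - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only axis-aligned slice orientation (1,0,0,0,1,0) is supported")
  ipp <- lapply(slices, dcm_get, key = "0020,0032", what = "numeric")
  zpos <- vapply(ipp, function(p) sum(p * normal), 0)
  ord <- order(zpos)
  slices <- slices[ord]; ipp <- ipp[ord]; zpos <- zpos[ord]
  files <- files[ord]
  rows <- vapply(slices, dcm_get, 0L, key = "0028,0010", what = "us")
  cols <- vapply(slices, dcm_get, 0L, key = "0028,0011", what = "us")
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1)
    stop("slices differ in matrix size")
  ps <- lapply(slices, dcm_get, key = "0028,0030", what = "numeric")
  for (i in seq_along(ps))
    if (max(abs(ps[[i]] - ps[[1]])) > 1e-9)
      stop("slices differ in pixel spacing; offending slice: ",
           basename(files[i]))
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(zpos)
    if (any(dz <= 0)) stop("duplicate or non-increasing slice positions")
    if (max(dz) - min(dz) > 0.01)
      stop(sprintf(
        "non-uniform slice spacing (%.4g to %.4g mm) exceeds 0.01 mm tolerance",
        min(dz), max(dz)))
    dz <- mean(dz)
  } else {
    dz <- dcm_get(slices[[1]], "0018,0050", "numeric",
                  required = FALSE, default = 1)
  }
  nx <- cols[1]; ny <- rows[1]
  vals <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    slope <- dcm_get(slices[[k]], "0028,1053", "numeric",
                     required = FALSE, default = 1)
    icpt <- dcm_get(slices[[k]], "0028,1052", "numeric",
                    required = FALSE, default = 0)
    pix <- readBin(dcm_get(slices[[k]], "7FE0,0010", "raw"), "integer",
                   n = nx * ny, size = 4, endian = "little")
    vals[, , k] <- matrix(pix * slope + icpt, nx, ny)
  }
  image_grid(vals, origin = c(ipp[[1]][1], ipp[[1]][2], zpos[1]),
             spacing = c(ps[[1]][2], ps[[1]][1], dz),
             quantity = "HU", frame = frame)
}

# -- RT Dose ------------------------------------------------------------

#' Write / read a dose grid as DICOM RT Dose
#'
#' A single multi-frame object; frames run along axis 3 with a
#' `GridFrameOffsetVector`.  Doses are stored as 32-bit integers with a
#' `DoseGridScaling` of `max(dose) / (2^31 - 1)`, so the quantization
#' error is at most `max_dose / 2^31` per voxel.
#'
#' @param grid an `image_grid` with `quantity = "dose"` (cGy).
#' @param path output file.
#' @return `write_dose`: invisibly the path; `read_dose`: an `image_grid`.
#' @export
write_dose <- function(grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  if (grid$quantity != "dose")
    stop("write_dose expects a dose grid (quantity = 'dose')")
  d <- dim(grid$values)
  maxd <- max(grid$values)
  scaling <- if (maxd > 0) maxd / (2^31 - 1) else 1
  # keep the quantum faithful through the 10-digit DS serialization
  scaling <- as.numeric(ds_fmt(scaling))
  if (maxd > 0 && scaling <= 0) scaling <- maxd / (2^31 - 1)
  stored <- as.integer(pmin(round(grid$values / scaling), 2^31 - 1))
  sop <- uid_new()
  pix <- writeBin(stored, raw(), size = 4, endian = "little")
  els <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_RTDOSE),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x000E, "UI", uid_new()),
    dcm_element(0x0020, 0x0032, "DS", ds_fmt(grid$origin)),
    dcm_element(0x0020, 0x0037, "DS", ds_fmt(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0020, 0x0052, "UI", uid_new()),
    dcm_element(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_element(0x0028, 0x0010, "US", d[2]),
    dcm_element(0x0028, 0x0011, "US", d[1]),
    dcm_element(0x0028, 0x0030, "DS",
                ds_fmt(c(grid$spacing[2], grid$spacing[1]))),
    dcm_element(0x0028, 0x0100, "US", 32),
    dcm_element(0x0028, 0x0101, "US", 32),
    dcm_element(0x0028, 0x0102, "US", 31),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x3004, 0x0002, "CS", "CGY"),
    dcm_element(0x3004, 0x000C, "DS",
                ds_fmt((seq_len(d[3]) - 1) * grid$spacing[3])),
    dcm_element(0x3004, 0x000E, "DS",
                formatC(scaling, format = "g", digits = 10)),
    dcm_element(0x7FE0, 0x0010, "OW", pix))
  write_dcm_file(path, SOP_RTDOSE, sop, els)
  invisible(path)
}

#' @rdname write_dose
#' @param frame coordinate-frame label for the resulting grid.
#' @export
read_dose <- function(path, frame = "patient") {
  ds <- read_dcm_file(path)
  if (dcm_get(ds, "0008,0060", "string") != "RTDOSE")
    stop("not an RT Dose object")
  nx <- dcm_get(ds, "0028,0011", what = "us")
  ny <- dcm_get(ds, "0028,0010", what = "us")
  nz <- dcm_get(ds, "0028,0008", what = "int")
  ps <- dcm_get(ds, "0028,0030", what = "numeric")
  gofv <- dcm_get(ds, "3004,000C", what = "numeric")
  if (length(gofv) != nz) stop("GridFrameOffsetVector length mismatch")
  dz <- if (nz > 1) {
    steps <- diff(gofv)
    if (max(steps) - min(steps) > 1e-6)
      stop("non-uniform dose frame spacing is not supported")
    mean(steps)
  } else 1
  scaling <- dcm_get(ds, "3004,000E", what = "numeric")
  ipp <- dcm_get(ds, "0020,0032", what = "numeric")
  pix <- readBin(dcm_get(ds, "7FE0,0010", "raw"), "integer",
                 n = nx * ny * nz, size = 4, endian = "little")
  image_grid(array(pix * scaling, c(nx, ny, nz)),
             origin = ipp, spacing = c(ps[2], ps[1], dz),
             quantity = "dose", frame = frame)
}
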