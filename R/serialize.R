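#' Read / write a beam specification as YAML
#'
#' Serializes the beam axis, entry side and the full spot list (lateral
#' positions, ranges, sigmas, weights).
#' @param beam a [beam_spec].
#' @param path file path.
#' @export
write_beam <- function(beam, path) {
  stopifnot(inherits(beam, "beam_spec"))
  yaml::write_yaml(list(axis = beam$axis, entry = beam$entry,
                        spots = lapply(beam$spots, as.numeric)), path)
  invisible(path)
}

#' @rdname write_beam
#' @export
read_beam <- function(path) {
  y <- yaml::read_yaml(path)
  beam_spec(as.data.frame(lapply(y$spots, as.numeric)),
            axis = y$axis, entry = y$entry)
}

#' Read / write a structure mask as run-length-encoded text
#'
#' Plain-text mask exchange: a header with the name, shape, origin and
#' spacing, then the run-length encoding of the flattened (column-major)
#' logical mask starting from `FALSE`.
#' @param mask a [structure_mask].
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  r <- rle(as.logical(mask$mask))
  num <- function(x) paste(formatC(x, format = "g", digits = 17,
                                   width = 1), collapse = " ")
  first <- if (length(r$values)) r$values[1] else FALSE
  writeLines(c(
    sprintf("name=%s", mask$name),
    sprintf("shape=%s", paste(dim(mask$mask), collapse = " ")),
    sprintf("origin_mm=%s", num(mask$origin)),
    sprintf("spacing_mm=%s", num(mask$spacing)),
    sprintf("first=%d", as.integer(first)),
    paste(r$lengths, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  kv <- function(key) sub(paste0("^", key, "="), "",
                          grep(paste0("^", key, "="), lines, value = TRUE))
  shape <- as.integer(strsplit(kv("shape"), " ")[[1]])
  origin <- as.numeric(strsplit(kv("origin_mm"), " ")[[1]])
  spacing <- as.numeric(strsplit(kv("spacing_mm"), " ")[[1]])
  first <- as.integer(kv("first")) == 1
  lens <- as.numeric(strsplit(trimws(lines[length(lines)]), " +")[[1]])
  vals <- rep(rep(c(first, !first), length.out = length(lens)), lens)
  grid <- image_grid(array(0, shape), origin, spacing, quantity = "HU")
  structure_mask(kv("name"), array(vals, shape), grid)
}
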