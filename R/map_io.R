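#' Flat-map on-disk format: matrix text plus JSON sidecar
#'
#' Maps are written as whitespace-separated numeric text (one matrix row per
#' line, `NA` for off-mask pixels) with a JSON sidecar (`<name>.json`)
#' carrying grid shape, pixel size and any additional metadata. Arrays with
#' a depth dimension are flattened to `nx*ny` rows by `n_depth` columns and
#' the sidecar records the original dimensions.
#'
#' @param x Numeric matrix, logical matrix or 3D array.
#' @param path Output path without extension; writes `<path>.txt` and
#'   `<path>.json`.
#' @param meta Named list of extra metadata for the sidecar.
#' @return The `.txt` path, invisibly.
#' @export
write_map <- function(x, path, meta = list()) {
  dims <- dim(x)
  m <- if (length(dims) > 2) matrix(x, dims[1] * dims[2], prod(dims[-(1:2)]))
       else x
  lg <- is.logical(m)
  if (lg) m <- m * 1L
  utils::write.table(m, paste0(path, ".txt"), row.names = FALSE,
                     col.names = FALSE)
  side <- c(list(dim = dims, logical = lg), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".txt"))
}

#' Read a map written by [write_map()]
#'
#' @param path Path without extension.
#' @return The matrix or array, with the sidecar attached as attribute
#'   `meta`.
#' @export
read_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(m) <- NULL
  dims <- side$dim
  x <- if (length(dims) > 2) array(m, dims) else matrix(m, dims[1], dims[2])
  if (isTRUE(side$logical)) x <- array(x == 1, dim(x))
  attr(x, "meta") <- side[setdiff(names(side), c("dim", "logical"))]
  x
}
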