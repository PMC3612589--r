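#' Read and write Middlebury .flo optical-flow files
#'
#' The `.flo` format stores a `width x height` grid of two-channel 32-bit
#' floats, little-endian, row-major, preceded by the sanity-check float
#' 202021.25 (the bytes "PIEH") and two int32 dimensions. The first stored
#' row is the top image row. Because this package's image frame has x
#' positive to the left and y positive upward, writers emit rows from
#' `y = +h/2` downward and columns from `x = +w/2` leftward, so that a
#' rendered field displays in conventional raster orientation without
#' mirroring; readers invert the mapping.
#'
#' Values pass through a 32-bit representation, so a write/read round trip
#' is exact at single precision.
#'
#' @param field A `flow_field` tibble from [render_flow_field()] (or any
#'   tibble with columns `x`, `y`, `u`, `v` on a complete regular grid).
#' @param path File path.
#' @return `read_flo()` returns a tibble `col`, `row`, `u`, `v` (1-based
#'   raster indices, row 1 at the top) with attributes `width` and `height`;
#'   `write_flo()` returns `path` invisibly.
#' @export
write_flo <- function(field, path) {
  xs <- sort(unique(field$x))
  ys <- sort(unique(field$y))
  nx <- length(xs)
  ny <- length(ys)
  if (nrow(field) != nx * ny) {
    abort("`field` must be a complete regular grid")
  }
  ord <- order(-field$y, -field$x) # top row first, leftward x decreasing
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4, endian = "little")
  writeBin(as.integer(c(nx, ny)), con, size = 4, endian = "little")
  inter <- as.vector(rbind(field$u[ord], field$v[ord]))
  writeBin(inter, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_flo
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  if (!isTRUE(all.equal(magic, 202021.25, tolerance = 1e-6))) {
    abort("not a .flo file (bad magic number)")
  }
  dims <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  nx <- dims[1]
  ny <- dims[2]
  dat <- readBin(con, "numeric", n = 2 * nx * ny, size = 4, endian = "little")
  u <- dat[seq(1, length(dat), by = 2)]
  v <- dat[seq(2, length(dat), by = 2)]
  out <- tidyr::expand_grid(row = seq_len(ny), col = seq_len(nx))
  out$u <- u
  out$v <- v
  structure(out, width = nx, height = ny)
}

#' @rdname write_flo
#' @export
write_flow_csv <- function(field, path) {
  utils::write.csv(field[, c("x", "y", "u", "v")], path, row.names = FALSE)
  invisible(path)
}
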