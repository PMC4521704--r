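#' A lightweight gridded raster
#'
#' A numeric matrix with a geotransform on an unprojected lat/long (WGS 84)
#' grid: `xll`/`yll` give the lower-left corner in decimal degrees and
#' `cellsize` the square pixel size. Missing pixels are stored as `NA` in
#' memory and written as the `nodata` sentinel on disk. Row 1 is the
#' northernmost row, matching on-disk order.
#'
#' @param values Numeric matrix (NA = nodata).
#' @param xll,yll Lower-left corner, decimal degrees.
#' @param cellsize Pixel size in decimal degrees (default 5 arc-minutes).
#' @param nodata Sentinel written on export (default -1).
#' @return An `lps_raster` object.
#' @export
lps_raster <- function(values, xll = 0, yll = 0, cellsize = 1 / 12,
                       nodata = -1) {
  stopifnot(is.matrix(values), is.numeric(values) || is.logical(values),
            is.finite(xll), is.finite(yll), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "lps_raster")
}

#' @export
print.lps_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("lps_raster: %d x %d, cellsize %g deg, origin (%g, %g), %d nodata\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll, sum(is.na(v))))
  invisible(x)
}

raster_values <- function(x) if (inherits(x, "lps_raster")) x$values else x

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (`.asc`): a six-line
#' header (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value)
#' followed by rows of space-separated values, north to south. Values are
#' written in full double precision.
#'
#' @param r An [lps_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asc_raster <- function(r, path) {
  stopifnot(inherits(r, "lps_raster"))
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.17g", r$xll),
    sprintf("YLLCORNER %.17g", r$yll),
    sprintf("CELLSIZE %.17g", r$cellsize),
    sprintf("NODATA_VALUE %.17g", r$nodata)), con)
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_asc_raster()] or any
#'   conforming tool.
#' @return An [lps_raster()]; nodata pixels are `NA`.
#' @export
read_asc_raster <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- toupper(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  m <- matrix(scan(path, skip = 6L, quiet = TRUE),
              nrow = vals[["NROWS"]], ncol = vals[["NCOLS"]], byrow = TRUE)
  m[m == vals[["NODATA_VALUE"]]] <- NA_real_
  lps_raster(m, xll = vals[["XLLCORNER"]], yll = vals[["YLLCORNER"]],
             cellsize = vals[["CELLSIZE"]], nodata = vals[["NODATA_VALUE"]])
}

check_same_shape <- function(...) {
  mats <- lapply(list(...), raster_values)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("grids are not co-registered (shapes: ",
         paste(unique(dims), collapse = ", "), ")")
  invisible(TRUE)
}

#' Compare two co-registered rasters
#'
#' Pearson correlation over jointly valid (non-NA) pixels plus a
#' cross-tabulation of density classes, the standard way two gridded density
#' maps of the same quantity are compared.
#'
#' @param a,b Matrices or [lps_raster()]s of identical shape.
#' @param density_breaks Cut points for the density classes (extended with
#'   -Inf/Inf as needed).
#' @return List with `r` (Pearson correlation), `n` (pixels compared) and
#'   `crosstab` (class table, rows = `a`).
#' @export
compare_rasters <- function(a, b, density_breaks = c(0, 1, 10, 100, 1000)) {
  a <- raster_values(a); b <- raster_values(b)
  check_same_shape(a, b)
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) stop("no jointly valid pixels to compare")
  brk <- unique(c(-Inf, density_breaks, Inf))
  list(r = stats::cor(a[ok], b[ok]),
       n = sum(ok),
       crosstab = table(a = cut(a[ok], brk), b = cut(b[ok], brk)))
}

#' Convert head-per-pixel counts to head per square kilometre
#'
#' Pixel area on an unprojected grid shrinks with latitude as cos(lat);
#' this divides each pixel by its true area so densities are comparable
#' across latitudes.
#'
#' @param r An [lps_raster()] of head per pixel.
#' @return An [lps_raster()] of head per km^2.
#' @export
density_per_km2 <- function(r) {
  stopifnot(inherits(r, "lps_raster"))
  v <- r$values
  km_per_deg <- 111.32
  lat <- r$yll + (nrow(v) - seq_len(nrow(v)) + 0.5) * r$cellsize
  area <- (r$cellsize * km_per_deg)^2 * cos(lat * pi / 180)
  out <- sweep(v, 1, area, "/")
  lps_raster(out, r$xll, r$yll, r$cellsize, r$nodata)
}
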