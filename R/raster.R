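#' In-memory georeferenced raster grid
#'
#' A minimal single-band raster: a numeric matrix (row 1 = northernmost row)
#' with an upper-left origin, square cell size and a nodata marker. Cells
#' marked nodata are excluded from every computation.
#'
#' @param values numeric matrix of cell values.
#' @param cellsize cell edge length (map units; decimal degrees by default).
#' @param xll,yll x and y of the lower-left corner of the grid.
#' @param nodata value marking missing cells (stored as `NA` internally).
#' @param crs free-text coordinate-reference label.
#' @return A `raster_grid`.
#' @export
raster_grid <- function(values, cellsize = 1, xll = 0, yll = 0,
                        nodata = -9999, crs = "WGS84") {
  values <- as.matrix(values)
  stopifnot(cellsize > 0, nrow(values) >= 1, ncol(values) >= 1)
  values[values == nodata] <- NA
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g, origin (%g, %g) [%s]\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, x$crs))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  values: %g .. %g (%d nodata cells)\n",
              min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a raster grid
#' @param r a `raster_grid`.
#' @return List with vectors `x` (per column) and `y` (per row, top first).
#' @export
raster_cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Row/column of the cell containing a point
#' @param r a `raster_grid`.
#' @param x,y point coordinates (map units).
#' @return Integer vector `c(row, col)`; error if outside the grid.
#' @export
raster_cell_at <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1
  row <- nr - floor((y - r$yll) / r$cellsize)
  if (col < 1 || col > nc || row < 1 || row > nr)
    stop(sprintf("point (%g, %g) falls outside the raster", x, y))
  c(as.integer(row), as.integer(col))
}

#' Read an ESRI ASCII grid
#' @param path path to a `.asc` file.
#' @param crs coordinate-reference label to attach.
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = "WGS84") {
  head <- readLines(path, n = 6)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  n_head <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                            "xllcenter", "yllcenter", "cellsize", "nodata_value"))
  body <- scan(path, skip = n_head, quiet = TRUE)
  nr <- vals["nrows"]; nc <- vals["ncols"]
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if ("xllcorner" %in% keys) vals["xllcorner"] else vals["xllcenter"] - vals["cellsize"] / 2
  yll <- if ("yllcorner" %in% keys) vals["yllcorner"] else vals["yllcenter"] - vals["cellsize"] / 2
  nodata <- if ("nodata_value" %in% keys) vals["nodata_value"] else -9999
  raster_grid(m, cellsize = unname(vals["cellsize"]), xll = unname(xll),
              yll = unname(yll), nodata = unname(nodata), crs = crs)
}

#' Write a raster grid as an ESRI ASCII file
#' @param r a `raster_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(r$values)),
               paste("nrows", nrow(r$values)),
               paste("xllcorner", r$xll),
               paste("yllcorner", r$yll),
               paste("cellsize", r$cellsize),
               paste("NODATA_value", r$nodata)), con)
  v <- r$values
  v[is.na(v)] <- r$nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of habitat cover within a buffer around a point
#'
#' Counts habitat-class cells whose centers fall within a great-circle radius
#' of the point; nodata cells are excluded from the denominator. Used to
#' summarise habitat amount within the foraging range of a sampling location
#' (default radius 2 km).
#'
#' @param landcover a `raster_grid` (geographic coordinates, degrees) whose
#'   values are compared with `habitat_values`.
#' @param lon,lat point coordinates in decimal degrees.
#' @param radius_km buffer radius in km.
#' @param habitat_values cell values counted as habitat.
#' @return Habitat fraction in \[0, 1\].
#' @export
habitat_fraction <- function(landcover, lon, lat, radius_km = 2,
                             habitat_values = 1) {
  stopifnot(radius_km > 0)
  cc <- raster_cell_centers(landcover)
  grid <- expand.grid(y = cc$y, x = cc$x)  # row-major to match values vector
  la1 <- lat * pi / 180
  la2 <- grid$y * pi / 180
  dlo <- (grid$x - lon) * pi / 180
  h <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin(dlo / 2)^2
  d <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  v <- as.vector(landcover$values)
  inside <- d <= radius_km & !is.na(v)
  if (!any(inside)) {
    # radius smaller than a cell: fall back to the containing cell
    rc <- raster_cell_at(landcover, lon, lat)
    val <- landcover$values[rc[1], rc[2]]
    if (is.na(val)) stop("buffer around the point contains only nodata cells")
    return(as.numeric(val %in% habitat_values))
  }
  mean(v[inside] %in% habitat_values)
}
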