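# Matrix-backed single-band raster with a simple cartesian grid geometry.
# Row 1 is the northernmost row (standard north-up raster orientation);
# coordinates are map units (km throughout this package), cell-centre
# registered.

#' Create a grid raster
#'
#' A lightweight single-band raster: a numeric matrix plus grid geometry.
#' Row 1 is the northernmost row; `xll`/`yll` give the lower-left corner of
#' the grid in map units and `cellsize` the (square) cell edge length.
#'
#' @param values Numeric matrix. `NA` encodes NoData.
#' @param xll,yll Coordinates of the lower-left corner (map units, km).
#' @param cellsize Cell edge length (km).
#' @param crs Coordinate reference system declaration (free-text string).
#'   Required before the raster can be written to disk.
#'
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = "LOCAL_CS[\"cartesian-km\"]") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("`cellsize` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize, crs = crs),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_raster> %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
    nrow(v), ncol(v), x$cellsize, x$xll, x$yll
  ))
  cat(sprintf("  crs: %s\n", if (is.null(x$crs)) "<none>" else x$crs))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d NoData cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
as.matrix.grid_raster <- function(x, ...) x$values

#' Test whether two rasters share one grid geometry
#'
#' @param a,b `grid_raster` objects.
#' @param tol Numeric tolerance on the geometry fields.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol &&
    abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_misaligned <- function(a, b, what_a = "raster A", what_b = "raster B") {
  if (!same_geometry(a, b)) {
    stop(sprintf(
      paste0("grid geometry mismatch between %s (%d x %d, cellsize %g, ",
             "origin %g,%g) and %s (%d x %d, cellsize %g, origin %g,%g); ",
             "align inputs explicitly before analysis"),
      what_a, nrow(a$values), ncol(a$values), a$cellsize, a$xll, a$yll,
      what_b, nrow(b$values), ncol(b$values), b$cellsize, b$xll, b$yll
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-centre coordinates of every cell
#'
#' @param r A `grid_raster`.
#' @return A data.frame with columns `row`, `col`, `x`, `y` in row-major
#'   order (row 1 = north).
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  data.frame(
    row = row, col = col,
    x = r$xll + (col - 0.5) * r$cellsize,
    y = r$yll + (nr - row + 0.5) * r$cellsize
  )
}

#' Locate the cell containing a point
#'
#' Points outside the raster extent get `NA` row/col (never an error):
#' downstream site assignment flags them as unassigned.
#'
#' @param r A `grid_raster`.
#' @param x,y Point coordinates (map units, vectorised).
#' @return data.frame with columns `row`, `col`.
#' @export
cell_at_xy <- function(r, x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (any(!is.finite(x) & !is.na(x)) || any(!is.finite(y) & !is.na(y))) {
    stop("malformed (non-finite) site coordinates", call. = FALSE)
  }
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1
  row <- nr - floor((y - r$yll) / r$cellsize)
  # points exactly on the top/right edge belong to the edge cell
  col[!is.na(x) & x == r$xll + nc * r$cellsize] <- nc
  row[!is.na(y) & y == r$yll + nr * r$cellsize] <- 1
  bad <- is.na(x) | is.na(y) | col < 1 | col > nc | row < 1 | row > nr
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# --- plain-text raster I/O (ESRI ASCII grid + .prj sidecar) ------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Writes the values as a plain-text `.asc` grid and the CRS declaration to a
#' `.prj` sidecar next to it. A raster without a CRS is refused: silently
#' assuming a coordinate system is forbidden in this package.
#'
#' @param r A `grid_raster`.
#' @param path Output path (`.asc`).
#' @param nodata Value used to encode `NA` cells on disk.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  if (is.null(r$crs) || is.na(r$crs) || !nzchar(r$crs)) {
    stop(sprintf("raster destined for '%s' has no CRS declaration", path),
         call. = FALSE)
  }
  v <- r$values
  v[is.na(v)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.15g", r$xll),
    sprintf("yllcorner %.15g", r$yll),
    sprintf("cellsize %.15g", r$cellsize),
    sprintf("NODATA_value %.15g", nodata)
  )
  body <- apply(v, 1L, function(row) paste(sprintf("%.15g", row), collapse = " "))
  writeLines(c(header, body), path)
  writeLines(r$crs, prj_path(path))
  invisible(path)
}

prj_path <- function(path) paste0(tools::file_path_sans_ext(path), ".prj")

#' Read an ESRI ASCII grid raster
#'
#' Requires the `.prj` CRS sidecar written by [write_ascii_grid()]; a raster
#' file without a CRS declaration is a hard error naming the file.
#'
#' @param path Path to the `.asc` file.
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file '%s' not found", path), call. = FALSE)
  pp <- prj_path(path)
  if (!file.exists(pp)) {
    stop(sprintf("raster '%s' has no CRS declaration ('%s' missing)", path, pp),
         call. = FALSE)
  }
  crs <- paste(readLines(pp, warn = FALSE), collapse = "\n")
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("raster '%s': expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}
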