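# Classify the climate-index rasters and the PAWHC raster into discrete
# classes and intersect them into TED codes. Interval convention everywhere:
# half-open, lower-inclusive (a value equal to a boundary goes to the upper
# class).

#' TED classification scheme
#'
#' Ascending class boundaries for the three climate factors plus the PAWHC
#' class interval. The default scheme has 10 growing-degree-day classes, 10
#' aridity-index classes and 3 seasonality classes; the boundaries are
#' configuration, editable per study region, not fixed constants of the
#' method.
#'
#' @param gdd_boundaries Strictly ascending GDD class boundaries (degC-day).
#' @param ai_boundaries Strictly ascending aridity-index boundaries.
#' @param seasonality_boundaries Strictly ascending seasonality boundaries (degC).
#' @param pawhc_interval PAWHC class interval (mm); 50 = moderate resolution,
#'   25 = high resolution.
#' @return An object of class `ted_scheme`.
#' @export
ted_scheme <- function(gdd_boundaries = seq(1000, 9000, by = 1000),
                       ai_boundaries = seq(0.2, 1.8, by = 0.2),
                       seasonality_boundaries = c(5, 10),
                       pawhc_interval = 50) {
  chk <- function(b, nm) {
    if (length(b) < 1 || is.unsorted(b, strictly = TRUE)) {
      stop(sprintf("%s must be strictly ascending", nm), call. = FALSE)
    }
  }
  chk(gdd_boundaries, "gdd_boundaries")
  chk(ai_boundaries, "ai_boundaries")
  chk(seasonality_boundaries, "seasonality_boundaries")
  if (pawhc_interval <= 0) stop("pawhc_interval must be > 0", call. = FALSE)
  structure(list(gdd_boundaries = gdd_boundaries,
                 ai_boundaries = ai_boundaries,
                 seasonality_boundaries = seasonality_boundaries,
                 pawhc_interval = pawhc_interval),
            class = "ted_scheme")
}

#' @export
print.ted_scheme <- function(x, ...) {
  cat(sprintf("<ted_scheme> %d GDD / %d aridity / %d seasonality classes, PAWHC interval %g mm\n",
              length(x$gdd_boundaries) + 1, length(x$ai_boundaries) + 1,
              length(x$seasonality_boundaries) + 1, x$pawhc_interval))
  invisible(x)
}

scheme_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Save / load a TED scheme as JSON
#'
#' @param scheme A [ted_scheme()].
#' @param path JSON file path.
#' @return `write_ted_scheme` returns `path` invisibly; `read_ted_scheme`
#'   returns the scheme.
#' @export
write_ted_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_ted_scheme
#' @export
read_ted_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ted_scheme(gdd_boundaries = as.numeric(x$gdd_boundaries),
             ai_boundaries = as.numeric(x$ai_boundaries),
             seasonality_boundaries = as.numeric(x$seasonality_boundaries),
             pawhc_interval = as.numeric(x$pawhc_interval))
}

#' Classify values against ascending boundaries
#'
#' Returns, for each value, the count of boundaries less than or equal to it:
#' class 0 below the first boundary, half-open lower-inclusive intervals
#' throughout. `NaN`/`NA` values propagate as `NA` (NoData), never an error.
#'
#' @param value Numeric vector.
#' @param boundaries Strictly ascending numeric boundaries.
#' @return Integer class indices.
#' @export
classify_value <- function(value, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly ascending", call. = FALSE)
  }
  out <- rep(NA_integer_, length(value))
  ok <- !is.na(value)
  out[ok] <- findInterval(value[ok], boundaries)
  out
}

#' PAWHC class index
#'
#' `floor(pawhc / interval)`; lower-inclusive, so 260 mm at a 50 mm interval
#' falls in class 5, the 250-300 mm band.
#'
#' @param pawhc PAWHC (mm), vectorised; `NA` propagates.
#' @param interval Class interval (mm).
#' @return Integer class indices.
#' @export
pawhc_class <- function(pawhc, interval) {
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  if (any(pawhc < 0, na.rm = TRUE)) stop("negative PAWHC", call. = FALSE)
  as.integer(floor(pawhc / interval))
}

# Bijective packing of the four class components into one integer
# (each component < 100).
ted_code_int <- function(g, a, s, p) {
  ((g * 100 + a) * 100 + s) * 100 + p
}

#' Render and parse TED codes
#'
#' A TED code is the composite of the three climate-class indices and the
#' PAWHC class, rendered as `"CZ<g>.<a>.<s>-W<p>"`. Rendering then parsing is
#' the identity.
#'
#' @param gdd_class,ai_class,seasonality_class,pawhc_class Integer class
#'   components (vectorised).
#' @return `render_ted_code`: character codes. `parse_ted_code`: data.frame
#'   of the four components.
#' @export
render_ted_code <- function(gdd_class, ai_class, seasonality_class, pawhc_class) {
  sprintf("CZ%d.%d.%d-W%d", gdd_class, ai_class, seasonality_class, pawhc_class)
}

#' @rdname render_ted_code
#' @param code Character vector of rendered TED codes.
#' @export
parse_ted_code <- function(code) {
  m <- regmatches(code, regexec("^CZ(\\d+)\\.(\\d+)\\.(\\d+)-W(\\d+)$", code))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad)) {
    stop("malformed TED code(s): ", paste(code[bad], collapse = ", "), call. = FALSE)
  }
  g <- vapply(m, function(x) as.integer(x[2]), 0L)
  a <- vapply(m, function(x) as.integer(x[3]), 0L)
  s <- vapply(m, function(x) as.integer(x[4]), 0L)
  p <- vapply(m, function(x) as.integer(x[5]), 0L)
  data.frame(gdd_class = g, ai_class = a, seasonality_class = s, pawhc_class = p)
}

#' Delineate technology extrapolation domains
#'
#' Classifies the three index rasters against the scheme boundaries and the
#' PAWHC raster into `pawhc_interval` bins, and intersects the four class
#' layers into a composite TED code per cell. All rasters must share one grid
#' geometry (no implicit resampling). NoData in any input propagates to the
#' output.
#'
#' @param indices A `climate_index_raster` (see [compute_index_rasters()]).
#' @param pawhc A `grid_raster` of PAWHC (mm).
#' @param scheme A [ted_scheme()].
#' @return An object of class `ted_raster`: `codes` (integer `grid_raster`
#'   of packed codes), `legend` (data.frame: `code_int`, `ted_code`, the four
#'   class components, cell count), and the `scheme`.
#' @export
delineate_teds <- function(indices, pawhc, scheme = ted_scheme()) {
  stopifnot(inherits(indices, "climate_index_raster"),
            inherits(scheme, "ted_scheme"))
  stop_if_misaligned(indices$gdd, indices$aridity_index, "gdd", "aridity_index")
  stop_if_misaligned(indices$gdd, indices$seasonality, "gdd", "seasonality")
  stop_if_misaligned(indices$gdd, pawhc, "climate indices", "pawhc")

  g <- classify_value(indices$gdd$values, scheme$gdd_boundaries)
  a <- classify_value(indices$aridity_index$values, scheme$ai_boundaries)
  s <- classify_value(indices$seasonality$values, scheme$seasonality_boundaries)
  p <- pawhc_class(pawhc$values, scheme$pawhc_interval)

  code <- ted_code_int(g, a, s, p)
  code[is.na(g) | is.na(a) | is.na(s) | is.na(p)] <- NA_real_
  codes <- grid_raster(matrix(code, nrow(indices$gdd$values), ncol(indices$gdd$values)),
                       xll = indices$gdd$xll, yll = indices$gdd$yll,
                       cellsize = indices$gdd$cellsize, crs = indices$gdd$crs)

  tab <- table(code)
  ints <- as.numeric(names(tab))
  comp <- data.frame(
    p = ints %% 100,
    s = (ints %/% 100) %% 100,
    a = (ints %/% 1e4) %% 100,
    g = ints %/% 1e6
  )
  legend <- data.frame(
    code_int = ints,
    ted_code = render_ted_code(comp$g, comp$a, comp$s, comp$p),
    gdd_class = as.integer(comp$g),
    ai_class = as.integer(comp$a),
    seasonality_class = as.integer(comp$s),
    pawhc_class = as.integer(comp$p),
    n_cells = as.integer(tab)
  )
  legend <- legend[order(legend$code_int), , drop = FALSE]
  rownames(legend) <- NULL
  structure(list(codes = codes, legend = legend, scheme = scheme),
            class = "ted_raster")
}

#' @export
print.ted_raster <- function(x, ...) {
  cat(sprintf("<ted_raster> %d distinct TEDs over %d classified cells (PAWHC interval %g mm)\n",
              nrow(x$legend), sum(x$legend$n_cells), x$scheme$pawhc_interval))
  invisible(x)
}

#' Number of distinct TEDs in a TED raster
#'
#' @param ted A `ted_raster`.
#' @return Integer count of distinct codes.
#' @export
n_teds <- function(ted) nrow(ted$legend)

#' Per-TED area table and mean TED size
#'
#' @param ted A `ted_raster`.
#' @param cell_area Area of one cell (km^2); defaults to `cellsize^2`.
#' @return A list: `areas` (data.frame `ted_code`, `area_km2`) and
#'   `mean_size_km2` (mean over distinct TEDs). Areas sum to the total
#'   non-NoData area.
#' @export
ted_area_stats <- function(ted, cell_area = NULL) {
  if (nrow(ted$legend) == 0) {
    stop("all-NoData TED raster: no area statistics", call. = FALSE)
  }
  if (is.null(cell_area)) cell_area <- ted$codes$cellsize^2
  areas <- data.frame(ted_code = ted$legend$ted_code,
                      area_km2 = ted$legend$n_cells * cell_area)
  list(areas = areas, mean_size_km2 = mean(areas$area_km2))
}
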