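# Administrative units as polygon rings, with GeoJSON round-trip.

#' Construct an admin-unit set
#'
#' @param unit_id Character vector of unit identifiers.
#' @param rings List of closed polygon rings (two-column x,y matrices; first
#'   vertex repeated last), one per unit, in map coordinates.
#' @param crs CRS declaration string shared by all rings.
#' @return An object of class `admin_units`.
#' @export
admin_units <- function(unit_id, rings, crs = "LOCAL_CS[\"cartesian-km\"]") {
  stopifnot(length(unit_id) == length(rings))
  if (anyDuplicated(unit_id)) stop("duplicate unit_id", call. = FALSE)
  for (ring in rings) {
    if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 4L) {
      stop("each ring must be a closed x,y matrix with >= 4 vertices", call. = FALSE)
    }
  }
  structure(list(unit_id = as.character(unit_id), rings = rings, crs = crs),
            class = "admin_units")
}

#' @export
print.admin_units <- function(x, ...) {
  cat(sprintf("<admin_units> %d polygons, crs: %s\n", length(x$unit_id), x$crs))
  invisible(x)
}

#' @export
length.admin_units <- function(x) length(x$unit_id)

rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

#' Write admin units to GeoJSON
#'
#' @param units An `admin_units` object.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(seq_along(units$unit_id), function(i) {
    ring <- units$rings[[i]]
    list(
      type = "Feature",
      properties = list(unit_id = units$unit_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(j) unname(ring[j, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", crs_declaration = units$crs,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read admin units from GeoJSON
#'
#' @param path A `.geojson` file written by [write_units_geojson()] (or any
#'   FeatureCollection of single-ring polygons with a `unit_id` property).
#' @return An `admin_units` object.
#' @export
read_units_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop(sprintf("'%s' is not a FeatureCollection", path),
                                 call. = FALSE)
  ids <- vapply(fc$features, function(f) as.character(f$properties$unit_id), "")
  rings <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  })
  crs <- if (!is.null(fc$crs_declaration)) as.character(fc$crs_declaration) else
    "LOCAL_CS[\"cartesian-km\"]"
  admin_units(ids, rings, crs = crs)
}

# Row-major cell indices whose centres fall inside each unit's ring.
# Returns a list (per unit) of integer vectors into the row-major cell order.
unit_cell_index <- function(units, raster) {
  cc <- cell_centres(raster)
  pts <- cbind(cc$x, cc$y)
  nc <- ncol(raster$values)
  lapply(units$rings, function(ring) {
    inside <- mgcv::in.out(ring, pts)
    which(inside)
  })
}
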