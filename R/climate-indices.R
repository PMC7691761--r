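# The three climate factors of the zonation: annual total growing
# degree-days, aridity index (precip / reference ET), and annual temperature
# seasonality. Each is computed per calendar year and averaged over years
# (mean of per-year index values, not indices of mean weather).

#' Annual total growing degree-days
#'
#' `GDD = sum over days of max(0, min(tmean, cap) - base)`. With a `years`
#' grouping vector, each year's total is computed and the per-year totals are
#' averaged; every year must be complete (365 or 366 days). Without `years`
#' the series is treated as a single period and summed as given.
#'
#' @param tmean Daily mean temperature series (degC).
#' @param base_temp Base temperature (degC); default 0, matching the reading
#'   of GDD as time not limited by cold temperature.
#' @param cap Optional upper cap on the daily mean (degC); `NULL` = no cap.
#' @param years Optional vector (same length as `tmean`) labelling each
#'   day's calendar year.
#' @return Mean annual GDD (degC-day).
#' @export
compute_gdd <- function(tmean, base_temp = 0, cap = NULL, years = NULL) {
  if (length(tmean) == 0) stop("empty temperature series", call. = FALSE)
  if (any(is.na(tmean))) stop("missing values in temperature series", call. = FALSE)
  x <- if (is.null(cap)) tmean else pmin(tmean, cap)
  inc <- pmax(0, x - base_temp)
  if (is.null(years)) return(sum(inc))
  if (length(years) != length(tmean)) {
    stop("`years` must match the series length", call. = FALSE)
  }
  n_per_year <- table(years)
  if (any(!n_per_year %in% c(365L, 366L))) {
    stop("series must cover whole calendar years (365 or 366 days each); ",
         "partial years are rejected", call. = FALSE)
  }
  mean(tapply(inc, years, sum))
}

#' Hargreaves-Samani reference evapotranspiration
#'
#' `PET = 0.0023 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin)` with
#' extraterrestrial radiation `Ra` (expressed in mm/day water equivalent)
#' from standard solar geometry. Chosen as the default PET because it needs
#' only temperature and latitude. Clamped at zero.
#'
#' @param tmin,tmax Daily minimum / maximum temperature (degC, vectorised).
#' @param latitude Latitude (decimal degrees, |lat| <= 66.5).
#' @param day_of_year Day of year (1-366).
#' @return Reference ET (mm/day).
#' @export
compute_pet_hargreaves <- function(tmin, tmax, latitude, day_of_year) {
  if (any(tmax < tmin)) stop("tmax < tmin", call. = FALSE)
  if (any(abs(latitude) > 66.5)) {
    stop("|latitude| must be <= 66.5 degrees (polar solar geometry unsupported)",
         call. = FALSE)
  }
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
  ra_mj <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  ra_mm <- 0.408 * ra_mj
  pet <- 0.0023 * ra_mm * ((tmin + tmax) / 2 + 17.8) * sqrt(tmax - tmin)
  pmax(pet, 0)
}

#' Aridity index
#'
#' Ratio of annual precipitation to annual reference ET; the multi-year value
#' is the mean of the per-year ratios.
#'
#' @param annual_precip Annual precipitation totals (mm), one per year.
#' @param annual_pet Annual reference ET totals (mm), one per year.
#' @return Mean annual aridity index (dimensionless).
#' @export
compute_aridity_index <- function(annual_precip, annual_pet) {
  if (length(annual_precip) != length(annual_pet)) {
    stop("precip and PET series must have equal length", call. = FALSE)
  }
  if (any(annual_pet <= 0)) {
    stop("aridity index undefined: annual PET must be > 0", call. = FALSE)
  }
  mean(annual_precip / annual_pet)
}

#' Annual temperature seasonality
#'
#' Population standard deviation of the 12 mean monthly temperatures,
#' averaged over years. Separates temperate (high) from tropical (low)
#' climates. Invariant under adding a constant to all months.
#'
#' @param monthly_tmean Either a length-12 vector (one year) or a matrix with
#'   12 columns (one row per year).
#' @return Mean annual seasonality (degC).
#' @export
compute_seasonality <- function(monthly_tmean) {
  if (is.null(dim(monthly_tmean))) monthly_tmean <- matrix(monthly_tmean, nrow = 1)
  if (ncol(monthly_tmean) != 12L) {
    stop("exactly 12 monthly means per year are required", call. = FALSE)
  }
  if (any(is.na(monthly_tmean))) stop("missing monthly means", call. = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mean(apply(monthly_tmean, 1L, pop_sd))
}

#' Compute the three climate index rasters
#'
#' Applies the scalar index operations cell-wise over a multi-year weather
#' grid and averages over years. PET comes from a supplied per-cell daily PET
#' matrix if given, otherwise from the Hargreaves-Samani computation on the
#' grid's tmin/tmax and per-row latitudes.
#'
#' @param weather A `weather_grid` (see [generate_weather_grid()], or any
#'   object with the same fields).
#' @param pet Optional matrix of daily PET (mm/day), cells x days, overriding
#'   the Hargreaves default.
#' @param base_temp,cap GDD parameters, see [compute_gdd()].
#' @return An object of class `climate_index_raster`: `gdd`,
#'   `aridity_index`, `seasonality` grid rasters sharing one geometry.
#' @export
compute_index_rasters <- function(weather, pet = NULL, base_temp = 0, cap = NULL) {
  w <- weather
  ncell <- w$nrow * w$ncol
  stopifnot(nrow(w$tmean) == ncell)
  if (!is.null(pet) && !all(dim(pet) == dim(w$tmean))) {
    stop("supplied PET band does not match the weather grid geometry", call. = FALSE)
  }
  years <- sort(unique(w$years))
  ny <- length(years)

  # per-year day indicator matrix (days x years)
  Y <- outer(w$years, years, `==`) * 1

  x <- if (is.null(cap)) w$tmean else pmin(w$tmean, cap)
  gdd_year <- pmax(x - base_temp, 0) %*% Y          # cells x years
  gdd <- rowMeans(gdd_year)

  if (is.null(pet)) {
    lat_cell <- rep(w$latitudes, each = w$ncol)     # row-major cell order
    pet <- compute_pet_hargreaves(
      w$tmin, w$tmax,
      latitude = matrix(lat_cell, ncell, ncol(w$tmin)),
      day_of_year = matrix(w$doy, ncell, ncol(w$tmin), byrow = TRUE)
    )
  }
  pet_year <- pet %*% Y
  if (any(pet_year <= 0)) {
    stop("aridity index undefined: a cell-year has non-positive annual PET",
         call. = FALSE)
  }
  precip_year <- w$precip %*% Y
  ai <- rowMeans(precip_year / pet_year)

  # monthly means per cell-year, then population SD of the 12 months
  seas_year <- matrix(NA_real_, ncell, ny)
  for (j in seq_len(ny)) {
    sel <- w$years == years[j]
    mo <- w$month[sel]
    M <- outer(mo, 1:12, `==`) * 1
    M <- sweep(M, 2L, colSums(M), `/`)
    mm <- w$tmean[, sel, drop = FALSE] %*% M        # cells x 12
    seas_year[, j] <- sqrt(rowMeans((mm - rowMeans(mm))^2))
  }
  seas <- rowMeans(seas_year)

  as_r <- function(v) grid_raster(matrix(v, w$nrow, w$ncol, byrow = TRUE),
                                  xll = w$xll, yll = w$yll,
                                  cellsize = w$cellsize, crs = w$crs)
  structure(list(gdd = as_r(gdd), aridity_index = as_r(ai),
                 seasonality = as_r(seas)),
            class = "climate_index_raster")
}

#' @export
print.climate_index_raster <- function(x, ...) {
  cat("<climate_index_raster>\n")
  for (nm in c("gdd", "aridity_index", "seasonality")) {
    rng <- range(x[[nm]]$values, na.rm = TRUE)
    cat(sprintf("  %-14s [%g, %g]\n", nm, rng[1], rng[2]))
  }
  invisible(x)
}
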