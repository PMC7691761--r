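# Synthetic inputs: gridded weather with climate gradients, blocky PAWHC,
# concentrated crop area, rectangular admin units, and yield panels whose
# mean rises and inter-annual CV falls with water supply.

# All randomness flows through an explicit seed; the caller's RNG state is
# saved and restored.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Yield-effect specification for the synthetic yield panel
#'
#' Encodes the generative yield model: a base level, additive effects of the
#' PAWHC and aridity classes, a year effect shared across all units, and
#' unit-year noise. The default PAWHC effect of 0.5 Mg/ha per 25 mm class
#' reflects the rule of thumb that 25 mm of extra crop water supply supports
#' roughly half a tonne of additional cereal yield in water-limited maize
#' systems. `cv_pawhc_slope` scales each unit's loading on the shared year
#' effect down with its PAWHC class, so better soils are more stable.
#'
#' @param base_yield Base yield level (Mg/ha).
#' @param pawhc_effect Yield increment per PAWHC class (Mg/ha).
#' @param aridity_effect Yield increment per aridity-index class (Mg/ha);
#'   higher class = wetter.
#' @param year_sd SD of the shared year effect (Mg/ha).
#' @param noise_sd SD of independent unit-year noise (Mg/ha).
#' @param cv_pawhc_slope Per-class change in the unit's loading on the year
#'   effect (negative = higher PAWHC classes are more stable).
#' @return An object of class `yield_effect_spec`.
#' @export
yield_effect_spec <- function(base_yield = 5, pawhc_effect = 0.5,
                              aridity_effect = 0.4, year_sd = 0.8,
                              noise_sd = 0.3, cv_pawhc_slope = -0.08) {
  if (year_sd < 0 || noise_sd < 0) {
    stop("sd parameters must be >= 0", call. = FALSE)
  }
  structure(list(base_yield = base_yield, pawhc_effect = pawhc_effect,
                 aridity_effect = aridity_effect, year_sd = year_sd,
                 noise_sd = noise_sd, cv_pawhc_slope = cv_pawhc_slope),
            class = "yield_effect_spec")
}

#' Configuration for the synthetic-fixture generators
#'
#' Defaults emulate a Corn-Belt-like study region: a north-south thermal
#' gradient spanning several growing-degree-day classes, a west-east moisture
#' gradient spanning several aridity-index classes, blocky soils drawn from
#' 100-350 mm PAWHC, and crop area concentrated in a subset of cells.
#'
#' @param grid_rows,grid_cols Grid dimensions (cells).
#' @param cell_size_km Cell edge length (km).
#' @param years Number of simulated calendar years (365-day years).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param gdd_gradient Increase in annual growing degree-days per row moving
#'   south (degC-day per row).
#' @param ai_gradient Increase in aridity index per column moving east
#'   (dimensionless per column).
#' @param pawhc_block_size Edge length (cells) of uniform PAWHC blocks.
#' @param pawhc_levels PAWHC values (mm) the blocks draw from.
#' @param crop_area_concentration Power-law exponent concentrating crop area
#'   (0 = uniform).
#' @param total_crop_area_ha Regional total harvested area spread over the grid.
#' @param unit_block_size Edge length (cells) of each rectangular admin unit.
#' @param yield_model A [yield_effect_spec()].
#' @param base_temp_north_c Mean annual temperature of the northernmost row (degC).
#' @param seasonal_amplitude_c Amplitude of the sinusoidal annual temperature
#'   cycle (degC).
#' @param diurnal_range_c Daily tmax - tmin (degC), constant.
#' @param monthly_anom_sd Region-wide monthly temperature anomaly SD (degC).
#' @param precip_anom_sd Log-scale SD of region-wide monthly precipitation
#'   anomalies.
#' @param ai_base Aridity index of the westernmost column (dimensionless).
#' @param pet_ref_mm Reference annual PET (mm) used to scale precipitation to
#'   the target aridity gradient.
#' @param origin_lat_deg Latitude of the northern grid edge (deg), used for
#'   solar geometry in PET.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(grid_rows = 20, grid_cols = 20, cell_size_km = 10,
                           years = 5, seed = 1L,
                           gdd_gradient = 150, ai_gradient = 0.03,
                           pawhc_block_size = 5,
                           pawhc_levels = seq(100, 350, by = 25),
                           crop_area_concentration = 1,
                           total_crop_area_ha = 1e6,
                           unit_block_size = 2,
                           yield_model = yield_effect_spec(),
                           base_temp_north_c = 9,
                           seasonal_amplitude_c = 12,
                           diurnal_range_c = 10,
                           monthly_anom_sd = 0.8,
                           precip_anom_sd = 0.2,
                           ai_base = 0.5,
                           pet_ref_mm = 1150,
                           origin_lat_deg = 44) {
  if (grid_rows < 1 || grid_cols < 1) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  if (length(pawhc_levels) < 1 || any(pawhc_levels < 0)) {
    stop("pawhc_levels must be non-empty and >= 0", call. = FALSE)
  }
  if (crop_area_concentration < 0) {
    stop("crop_area_concentration must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(yield_model, "yield_effect_spec"))
  structure(as.list(environment()), class = "fixture_config")
}

fixture_crs <- function(config) {
  sprintf("LOCAL_CS[\"cartesian-km\",ANCHOR_LAT[%g]]", config$origin_lat_deg)
}

# Reference latitude used for solar geometry: the grid's central latitude,
# applied to every row. The fixture's thermal gradient is carried entirely by
# temperature, so tying PET to per-row latitude would only entangle the two
# gradients; a single reference latitude keeps zero-gradient configs exactly
# homogeneous.
row_latitudes <- function(config) {
  rep(config$origin_lat_deg -
        (config$grid_rows / 2) * config$cell_size_km / 110.574,
      config$grid_rows)
}

#' Generate a multi-year daily weather grid
#'
#' Weather is generated monthly (sinusoidal annual temperature cycle plus
#' region-wide monthly anomalies shared by all cells) and resampled to daily
#' values: temperature by linear interpolation between month midpoints,
#' precipitation by spreading the monthly total evenly over its days. The
#' thermal gradient runs north to south (rows), the moisture gradient west to
#' east (columns). With both gradients zero every cell has an identical
#' climate.
#'
#' @param config A [fixture_config()].
#' @return An object of class `weather_grid`: daily `tmean`, `tmin`, `tmax`,
#'   `precip` matrices (cells in row-major order x days), calendar vectors,
#'   and the grid geometry.
#' @export
generate_weather_grid <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; ny <- config$years
  ncell <- nr * nc
  ndays_year <- 365L
  ndays <- ndays_year * ny
  mids <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
  month_of_doy <- rep(seq_len(12L), DAYS_IN_MONTH)

  # deterministic structure
  row_delta <- (seq_len(nr) - 1L) * config$gdd_gradient / 365  # degC offset per row
  seasonal <- config$seasonal_amplitude_c * cos(2 * pi * (1:12 - 7) / 12)
  ai_col <- config$ai_base + (seq_len(nc) - 1L) * config$ai_gradient
  precip_annual_col <- config$pet_ref_mm * ai_col
  # summer-weighted monthly precipitation profile, sums to 1
  pw <- 1 + 0.5 * cos(2 * pi * (1:12 - 7) / 12)
  pw <- pw / sum(pw)

  anoms <- with_seed(config$seed, list(
    t = matrix(stats::rnorm(12 * ny, sd = config$monthly_anom_sd), 12, ny),
    p = matrix(stats::rnorm(12 * ny), 12, ny)
  ))

  # shared daily temperature curve per year (before row offsets)
  shared_daily <- numeric(ndays)
  for (y in seq_len(ny)) {
    mo <- config$base_temp_north_c + seasonal + anoms$t[, y]
    # periodic interpolation within the year
    xs <- c(mids[12] - 365, mids, mids[1] + 365)
    ys <- c(mo[12], mo, mo[1])
    shared_daily[(y - 1L) * ndays_year + 1:365] <-
      stats::approx(xs, ys, xout = 1:365)$y
  }

  tmean <- matrix(rep(shared_daily, each = ncell), ncell, ndays)
  tmean <- tmean + rep(row_delta, each = nc)  # row-major cell order

  # monthly precipitation per column, lognormal region-wide anomaly with unit mean
  psd <- config$precip_anom_sd
  pmul <- exp(psd * anoms$p - psd^2 / 2)      # 12 x ny
  daily_p_shared <- numeric(ndays)            # column-1-equivalent profile, scale 1
  for (y in seq_len(ny)) {
    pm <- pw * pmul[, y]
    daily_p_shared[(y - 1L) * ndays_year + 1:365] <-
      rep(pm / DAYS_IN_MONTH, DAYS_IN_MONTH)
  }
  col_scale <- rep(precip_annual_col, times = nr)  # row-major order
  precip <- outer(col_scale, daily_p_shared)

  structure(list(
    nrow = nr, ncol = nc, xll = 0, yll = 0, cellsize = config$cell_size_km,
    crs = fixture_crs(config),
    latitudes = row_latitudes(config),
    years = rep(seq_len(ny), each = ndays_year),
    doy = rep(seq_len(ndays_year), times = ny),
    month = rep(month_of_doy, times = ny),
    tmean = tmean,
    tmin = tmean - config$diurnal_range_c / 2,
    tmax = tmean + config$diurnal_range_c / 2,
    precip = precip,
    pet = NULL
  ), class = "weather_grid")
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %d x %d cells, %d years of daily weather\n",
              x$nrow, x$ncol, max(x$years)))
  invisible(x)
}

# empty raster sharing a weather grid's geometry
weather_template <- function(w) {
  grid_raster(matrix(NA_real_, w$nrow, w$ncol), xll = w$xll, yll = w$yll,
              cellsize = w$cellsize, crs = w$crs)
}

#' Generate a blocky PAWHC raster
#'
#' Piecewise-constant square blocks of `pawhc_block_size` cells, each drawing
#' one value from `pawhc_levels` — mimicking the patchy spatial structure of
#' soil water holding capacity maps.
#'
#' @param config A [fixture_config()].
#' @return A `grid_raster` of PAWHC (mm).
#' @export
generate_pawhc_raster <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  bs <- config$pawhc_block_size
  nr <- config$grid_rows; nc <- config$grid_cols
  if (bs > nr || bs > nc) {
    stop("pawhc_block_size exceeds the grid dimensions", call. = FALSE)
  }
  nbr <- ceiling(nr / bs); nbc <- ceiling(nc / bs)
  vals <- with_seed(config$seed + 1L,
                    config$pawhc_levels[sample.int(length(config$pawhc_levels),
                                                   nbr * nbc, replace = TRUE)])
  block <- matrix(vals, nbr, nbc)
  m <- block[ceiling(seq_len(nr) / bs), ceiling(seq_len(nc) / bs), drop = FALSE]
  grid_raster(m, cellsize = config$cell_size_km, crs = fixture_crs(config))
}

#' Generate a crop-area raster and rectangular admin units
#'
#' Crop area is spread over the grid with a power-law weighting
#' (`crop_area_concentration` = 0 gives a uniform spread) and normalised to
#' `total_crop_area_ha`. Admin units tile the grid into square blocks of
#' `unit_block_size` cells (the last row/column of units may be smaller).
#'
#' @param config A [fixture_config()].
#' @return A list with `crop_area` (a `grid_raster`, ha per cell) and
#'   `units` (an [admin_units()] set).
#' @export
generate_crop_area_and_units <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  ncell <- nr * nc
  conc <- config$crop_area_concentration
  w <- if (conc == 0) rep(1, ncell) else
    with_seed(config$seed + 2L, stats::runif(ncell))^conc
  area <- config$total_crop_area_ha * w / sum(w)
  m <- matrix(area, nr, nc, byrow = TRUE)  # row-major cell order
  crop <- grid_raster(m, cellsize = config$cell_size_km, crs = fixture_crs(config))

  bs <- config$unit_block_size
  cs <- config$cell_size_km
  ids <- character(0); rings <- list()
  k <- 0L
  for (br in seq_len(ceiling(nr / bs))) {
    for (bc in seq_len(ceiling(nc / bs))) {
      r0 <- (br - 1L) * bs + 1L; r1 <- min(br * bs, nr)
      c0 <- (bc - 1L) * bs + 1L; c1 <- min(bc * bs, nc)
      k <- k + 1L
      ids[k] <- sprintf("U%04d", k)
      # map coords: x from columns, y from rows (row 1 = north)
      rings[[k]] <- rect_ring(
        xmin = (c0 - 1L) * cs, xmax = c1 * cs,
        ymin = (nr - r1) * cs, ymax = (nr - r0 + 1L) * cs
      )
    }
  }
  list(crop_area = crop, units = admin_units(ids, rings, crs = fixture_crs(config)))
}

#' Simulate a yield panel from planted unit classes
#'
#' The generative model is
#' `yield(u, t) = base + pawhc_effect * pawhc_class(u) + aridity_effect *
#' ai_class(u) + lambda(u) * year(t) + noise(u, t)`, with the year effect
#' drawn once and shared across units (regionally correlated weather years)
#' and `lambda(u) = max(0, 1 + cv_pawhc_slope * (pawhc_class(u) - min class))`
#' so higher-PAWHC units load less on the common year shock and have lower
#' inter-annual CV.
#'
#' @param unit_classes data.frame with columns `unit_id`, `ted_code`,
#'   `gdd_class`, `ai_class`, `seasonality_class`, `pawhc_class`.
#' @param spec A [yield_effect_spec()].
#' @param years Number of years (>= 3; fewer makes the downstream CV
#'   meaningless by design).
#' @param seed Integer seed.
#' @return A `yield_panel`: list with `records` (unit_id, year, yield_mg_ha)
#'   and `units` (the class table).
#' @export
simulate_yield_panel <- function(unit_classes, spec, years, seed) {
  stopifnot(inherits(spec, "yield_effect_spec"))
  if (years < 3) {
    stop("years must be >= 3: inter-annual CV is not meaningful on shorter panels",
         call. = FALSE)
  }
  need <- c("unit_id", "ted_code", "gdd_class", "ai_class",
            "seasonality_class", "pawhc_class")
  if (!all(need %in% names(unit_classes))) {
    stop("unit_classes lacks columns: ",
         paste(setdiff(need, names(unit_classes)), collapse = ", "), call. = FALSE)
  }
  nu <- nrow(unit_classes)
  draw <- with_seed(seed, list(
    year_effect = stats::rnorm(years, sd = spec$year_sd),
    noise = matrix(stats::rnorm(nu * years, sd = spec$noise_sd), nu, years)
  ))
  pmin_class <- min(unit_classes$pawhc_class)
  lambda <- pmax(0, 1 + spec$cv_pawhc_slope * (unit_classes$pawhc_class - pmin_class))
  mu <- spec$base_yield + spec$pawhc_effect * unit_classes$pawhc_class +
    spec$aridity_effect * unit_classes$ai_class
  y <- outer(mu, rep(1, years)) + outer(lambda, draw$year_effect) + draw$noise
  records <- data.frame(
    unit_id = rep(unit_classes$unit_id, times = years),
    year = rep(seq_len(years), each = nu),
    yield_mg_ha = as.vector(y)
  )
  yield_panel(records, unit_classes)
}

#' Generate a yield panel from a TED raster and admin units
#'
#' Assigns each unit the TED occurring in the majority of its cells (modal
#' code; lexicographic tie-break), then simulates yields with
#' [simulate_yield_panel()]. Units containing no raster cells are dropped
#' with a warning.
#'
#' @param ted A `ted_raster` (see [delineate_teds()]).
#' @param units An [admin_units()] set.
#' @param spec A [yield_effect_spec()].
#' @param years Number of years (>= 3).
#' @param seed Integer seed.
#' @return A `yield_panel`.
#' @export
generate_yield_panel <- function(ted, units, spec, years, seed) {
  idx <- unit_cell_index(units, ted$codes)
  codes <- as.vector(t(ted$codes$values))  # row-major
  pick <- vapply(idx, function(i) {
    v <- codes[i]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest code
  }, numeric(1))
  keep <- !is.na(pick)
  if (any(!keep)) {
    warning(sprintf("%d unit(s) contain no classified cells and were dropped",
                    sum(!keep)))
  }
  leg <- ted$legend
  m <- match(pick[keep], leg$code_int)
  unit_classes <- data.frame(
    unit_id = units$unit_id[keep],
    ted_code = leg$ted_code[m],
    gdd_class = leg$gdd_class[m],
    ai_class = leg$ai_class[m],
    seasonality_class = leg$seasonality_class[m],
    pawhc_class = leg$pawhc_class[m]
  )
  simulate_yield_panel(unit_classes, spec, years, seed)
}

#' Construct a yield panel
#'
#' @param records data.frame with columns `unit_id`, `year`, `yield_mg_ha`;
#'   (unit, year) pairs must be unique.
#' @param units data.frame mapping `unit_id` to its TED code and the four
#'   class components.
#' @return An object of class `yield_panel`.
#' @export
yield_panel <- function(records, units) {
  stopifnot(all(c("unit_id", "year", "yield_mg_ha") %in% names(records)))
  if (anyDuplicated(records[, c("unit_id", "year")])) {
    stop("duplicate (unit_id, year) records", call. = FALSE)
  }
  if (!all(records$unit_id %in% units$unit_id)) {
    stop("records reference unit_id values absent from the unit table", call. = FALSE)
  }
  structure(list(records = records, units = units), class = "yield_panel")
}

#' @export
print.yield_panel <- function(x, ...) {
  cat(sprintf("<yield_panel> %d units x %d years (%d records), %d TED(s)\n",
              nrow(x$units), length(unique(x$records$year)),
              nrow(x$records), length(unique(x$units$ted_code))))
  invisible(x)
}
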