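# Analog zones across disjoint regions, and income/risk accounting for
# cropping systems of different intensity within a shared zone. Crop yields
# (e.g. water-limited yields from a crop model) enter as data; the
# computation here is the zone matching and the income/risk comparison.

#' Find analog TEDs shared by two regions
#'
#' Set intersection of the TED codes present in two rasters produced under
#' the identical scheme, with per-region areas. An empty intersection is a
#' valid result, not an error.
#'
#' @param ted_a,ted_b `ted_raster` objects delineated under one [ted_scheme()].
#' @return data.frame: `ted_code`, `area_a_km2`, `area_b_km2`.
#' @export
find_analog_teds <- function(ted_a, ted_b) {
  if (!scheme_identical(ted_a$scheme, ted_b$scheme)) {
    stop("incomparable TED rasters: schemes differ (boundaries or PAWHC interval)",
         call. = FALSE)
  }
  shared <- intersect(ted_a$legend$ted_code, ted_b$legend$ted_code)
  shared <- sort(shared)
  ma <- match(shared, ted_a$legend$ted_code)
  mb <- match(shared, ted_b$legend$ted_code)
  data.frame(
    ted_code = shared,
    area_a_km2 = ted_a$legend$n_cells[ma] * ted_a$codes$cellsize^2,
    area_b_km2 = ted_b$legend$n_cells[mb] * ted_b$codes$cellsize^2
  )
}

#' Construct a cropping-system record
#'
#' Per-year, per-crop yields with prices and costs for one rotation.
#' Variable costs are apportioned per crop so an opportunistic crop that is
#' not sown in a year sheds its cost share; overheads are incurred
#' regardless.
#'
#' @param system_name System label (e.g. `"wheat-fallow"`).
#' @param yields data.frame with columns `year`, `crop`, `yield_mg_ha`
#'   (Mg/ha); one row per crop actually grown in that year.
#' @param prices Named numeric: price per crop (currency/Mg).
#' @param variable_cost Named numeric: variable cost per crop
#'   (currency/ha/yr), incurred only in years the crop is sown.
#' @param overhead_cost Overhead cost (currency/ha/yr), incurred every year.
#' @param soil_water_at_sowing Optional data.frame `year`, `crop`, `sw_mm`:
#'   plant-available soil water at sowing for opportunistic crops.
#' @return An object of class `cropping_system_record`.
#' @export
cropping_system_record <- function(system_name, yields, prices, variable_cost,
                                   overhead_cost, soil_water_at_sowing = NULL) {
  stopifnot(all(c("year", "crop", "yield_mg_ha") %in% names(yields)))
  if (any(yields$yield_mg_ha < 0) || any(prices < 0) ||
      any(variable_cost < 0) || overhead_cost < 0) {
    stop("yields, prices and costs must be >= 0", call. = FALSE)
  }
  years <- sort(unique(yields$year))
  if (length(years) < 3) {
    stop("a cropping-system record needs >= 3 years", call. = FALSE)
  }
  structure(list(system_name = system_name, yields = yields, prices = prices,
                 variable_cost = variable_cost, overhead_cost = overhead_cost,
                 soil_water_at_sowing = soil_water_at_sowing,
                 years = years),
            class = "cropping_system_record")
}

#' @export
print.cropping_system_record <- function(x, ...) {
  cat(sprintf("<cropping_system_record> %s: crops {%s}, %d years\n",
              x$system_name, paste(sort(unique(x$yields$crop)), collapse = ", "),
              length(x$years)))
  invisible(x)
}

#' Annual net income of a cropping system
#'
#' Gross income (sum over sown crops of yield x price) minus the variable
#' costs of the sown crops and the overhead cost. May be negative.
#'
#' @param record A [cropping_system_record()].
#' @param year Year within the record's series (vectorised).
#' @return Net income (currency/ha) per requested year.
#' @export
annual_net_income <- function(record, year) {
  vapply(year, function(yr) {
    if (!yr %in% record$years) {
      stop(sprintf("year %s outside the record's series", yr), call. = FALSE)
    }
    rows <- record$yields[record$yields$year == yr, , drop = FALSE]
    crops <- unique(rows$crop)
    missing_price <- setdiff(crops, names(record$prices))
    if (length(missing_price)) {
      stop("missing price for cropped year: ",
           paste(missing_price, collapse = ", "), call. = FALSE)
    }
    gross <- sum(rows$yield_mg_ha * record$prices[rows$crop])
    vc <- record$variable_cost[crops]
    vc <- sum(vc[!is.na(vc)])
    gross - vc - record$overhead_cost
  }, numeric(1))
}

#' Apply a soil-water sowing rule to opportunistic crops
#'
#' In years where plant-available soil water at sowing is below the
#' threshold, the opportunistic crop is not sown: its yield row and its
#' variable-cost share are removed for that year. The threshold is satisfied
#' at exactly `threshold` mm (a ">= threshold" rule). Crops with a
#' soil-water series in the record are the opportunistic ones.
#'
#' @param record A [cropping_system_record()] with `soil_water_at_sowing`.
#' @param threshold Minimum plant-available soil water at sowing (mm);
#'   default 60.
#' @return A modified `cropping_system_record`.
#' @export
apply_sowing_rule <- function(record, threshold = 60) {
  sw <- record$soil_water_at_sowing
  if (is.null(sw)) {
    stop("sowing rule requested but the record has no soil-water-at-sowing series",
         call. = FALSE)
  }
  skip <- sw[sw$sw_mm < threshold, c("year", "crop"), drop = FALSE]
  if (nrow(skip) == 0) return(record)
  y <- record$yields
  drop <- paste(y$year, y$crop) %in% paste(skip$year, skip$crop)
  record$yields <- y[!drop, , drop = FALSE]
  record
}

#' Compare cropping systems on yield, income and risk
#'
#' Per system: mean and inter-annual CV (sample SD / mean, percent) of the
#' annual total yield and of the annual net income, plus pairwise relative
#' income differences. All records must cover the same years.
#'
#' @param records List of [cropping_system_record()] objects (>= 1).
#' @return A `system_comparison`: list with `summary` (data.frame per
#'   system) and `relative_income_pct` (matrix of 100 * (row / col - 1)).
#' @export
compare_systems <- function(records) {
  if (!length(records)) stop("need at least one record", call. = FALSE)
  yrs <- records[[1]]$years
  for (r in records) {
    if (!identical(r$years, yrs)) {
      stop("records cover unequal year series", call. = FALSE)
    }
  }
  cv <- function(v) if (mean(v) == 0) NA_real_ else 100 * stats::sd(v) / abs(mean(v))
  rows <- lapply(records, function(r) {
    yield_by_year <- vapply(yrs, function(yr)
      sum(r$yields$yield_mg_ha[r$yields$year == yr]), numeric(1))
    income <- annual_net_income(r, yrs)
    data.frame(system_name = r$system_name,
               mean_annual_yield = mean(yield_by_year),
               yield_cv_percent = cv(yield_by_year),
               mean_net_income = mean(income),
               income_cv_percent = cv(income))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  inc <- summary$mean_net_income
  rel <- 100 * (outer(inc, inc, `/`) - 1)
  dimnames(rel) <- list(summary$system_name, summary$system_name)
  structure(list(summary = summary, relative_income_pct = rel),
            class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  cat("<system_comparison>\n")
  print(x$summary)
  invisible(x)
}
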