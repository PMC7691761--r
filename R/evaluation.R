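# Evaluate the zonation's ability to separate yield level and stability:
# crop-area-majority assignment of admin units to TEDs, zone-level mean/CV
# summaries and transects, variance partitioning (TED vs year), and the
# all-factors R^2 of the four class components.

#' Assign admin units to TEDs by the crop-area majority rule
#'
#' A unit is assigned to the TED holding strictly more than 50% of the
#' unit's crop area; at exactly 50% (or any non-majority split) it stays
#' unassigned. Cell membership is by cell centre in polygon. Units with zero
#' crop area are unassigned with a reason code.
#'
#' @param ted A `ted_raster`.
#' @param crop_area A `grid_raster` of harvested area (ha/cell), aligned
#'   with `ted`.
#' @param units An [admin_units()] set in the same coordinate system.
#' @return data.frame: `unit_id`, `ted_code` (`NA` = unassigned),
#'   `majority_share` (share of the unit's crop area in its leading TED), and
#'   `reason` (`"assigned"`, `"no_majority"`, `"no_crop_area"`, `"no_cells"`).
#' @export
assign_admin_units <- function(ted, crop_area, units) {
  stop_if_misaligned(ted$codes, crop_area, "ted raster", "crop area")
  idx <- unit_cell_index(units, ted$codes)
  code_rm <- as.vector(t(ted$codes$values))   # row-major cell order
  area_rm <- as.vector(t(crop_area$values))
  area_rm[is.na(area_rm)] <- 0

  n <- length(units$unit_id)
  out <- data.frame(unit_id = units$unit_id,
                    ted_code = rep(NA_character_, n),
                    majority_share = rep(NA_real_, n),
                    reason = rep("no_cells", n))
  for (i in seq_len(n)) {
    cells <- idx[[i]]
    if (!length(cells)) next
    codes <- code_rm[cells]
    areas <- area_rm[cells]
    keep <- !is.na(codes)
    total <- sum(areas[keep])
    if (total <= 0) { out$reason[i] <- "no_crop_area"; next }
    per_ted <- tapply(areas[keep], codes[keep], sum)
    share <- per_ted / total
    top <- which.max(share)
    out$majority_share[i] <- as.numeric(share[top])
    if (share[top] > 0.5) {
      ci <- as.numeric(names(share)[top])
      out$ted_code[i] <- ted$legend$ted_code[match(ci, ted$legend$code_int)]
      out$reason[i] <- "assigned"
    } else {
      out$reason[i] <- "no_majority"
    }
  }
  out
}

# per-unit mean yield and inter-annual CV (sample SD / mean * 100);
# units with fewer than `min_years` years are dropped with a warning.
unit_stats <- function(panel, min_years = 3L) {
  rec <- panel$records
  sp <- split(rec$yield_mg_ha, rec$unit_id)
  ny <- vapply(sp, length, 0L)
  if (any(ny < min_years)) {
    warning(sprintf("%d unit(s) with < %d years excluded from CV reporting",
                    sum(ny < min_years), min_years))
    sp <- sp[ny >= min_years]
  }
  us <- data.frame(
    unit_id = names(sp),
    mean_yield = vapply(sp, mean, 0),
    cv_percent = vapply(sp, function(v) 100 * stats::sd(v) / mean(v), 0)
  )
  merge(us, panel$units, by = "unit_id", sort = TRUE)
}

#' Zone-level yield and stability summaries
#'
#' Per group: number of units, mean yield over all unit-year records, and the
#' inter-annual CV. The CV is computed per unit over its years (sample SD /
#' mean, in percent) and then averaged over the group's units, so spatial
#' variation between units is not conflated with temporal variability.
#'
#' @param panel A `yield_panel`.
#' @param group_by Grouping factor: `"ted_code"` or one of the four class
#'   components (`"gdd_class"`, `"ai_class"`, `"seasonality_class"`,
#'   `"pawhc_class"`).
#' @return data.frame: `group`, `n_units`, `mean_yield`, `cv_percent`.
#' @export
zone_summaries <- function(panel, group_by = "ted_code") {
  choices <- c("ted_code", "gdd_class", "ai_class", "seasonality_class", "pawhc_class")
  group_by <- match.arg(group_by, choices)
  us <- unit_stats(panel)
  g <- us[[group_by]]
  rec <- merge(panel$records, panel$units[, c("unit_id", group_by)], by = "unit_id")
  mean_by_group <- tapply(rec$yield_mg_ha, rec[[group_by]], mean)
  out <- data.frame(group = sort(unique(as.character(g))))
  out$n_units <- as.integer(table(as.character(g))[out$group])
  out$mean_yield <- as.numeric(mean_by_group[out$group])
  out$cv_percent <- as.numeric(tapply(us$cv_percent, as.character(g), mean)[out$group])
  out
}

#' Ordered transect summary with trend flags
#'
#' Summaries in a stated group ordering (e.g. a NW-to-SE climate transect or
#' ascending PAWHC classes), plus flags for whether mean yield is monotone
#' non-decreasing and CV monotone non-increasing along the transect.
#'
#' @param panel A `yield_panel`.
#' @param ordered_groups Character vector of group labels in transect order.
#' @param group_by Grouping factor, as in [zone_summaries()].
#' @return List: `summary` (ordered data.frame), `mean_increasing`,
#'   `cv_decreasing` (logicals).
#' @export
transect_summary <- function(panel, ordered_groups, group_by = "ted_code") {
  zs <- zone_summaries(panel, group_by = group_by)
  unknown <- setdiff(as.character(ordered_groups), zs$group)
  if (length(unknown)) {
    stop("unknown group(s) in ordering: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ord <- zs[match(as.character(ordered_groups), zs$group), , drop = FALSE]
  rownames(ord) <- NULL
  list(summary = ord,
       mean_increasing = !is.unsorted(ord$mean_yield),
       cv_decreasing = !is.unsorted(rev(ord$cv_percent)))
}

#' Variance partition: TED vs year
#'
#' Two-factor sequential sum-of-squares decomposition of unit-year yields:
#' the TED factor entered first, then the year main effect plus the TED x
#' year interaction as one combined "year" term, and the residual. Also
#' reports the TED share excluding the error term — the convention used when
#' zonation quality is summarised as "share of explainable variance".
#'
#' @param panel A `yield_panel` with >= 2 TEDs and >= 2 years.
#' @return List: `fraction_ted`, `fraction_year`, `fraction_error` (shares of
#'   total SS, summing to 1), `ted_share_excl_error`, and the raw `ss`.
#' @export
variance_partition <- function(panel) {
  d <- merge(panel$records, panel$units[, c("unit_id", "ted_code")], by = "unit_id")
  if (length(unique(d$ted_code)) < 2) {
    stop("degenerate design: need >= 2 TEDs", call. = FALSE)
  }
  if (length(unique(d$year)) < 2) {
    stop("degenerate design: need >= 2 years", call. = FALSE)
  }
  d$ted <- factor(d$ted_code)
  d$yr <- factor(d$year)
  fit <- stats::lm(yield_mg_ha ~ ted + yr + ted:yr, data = d)
  a <- stats::anova(fit)
  ss <- stats::setNames(a[["Sum Sq"]], rownames(a))
  ss_ted <- ss[["ted"]]
  ss_year <- sum(ss[names(ss) %in% c("yr", "ted:yr")])
  ss_err <- ss[["Residuals"]]
  tot <- ss_ted + ss_year + ss_err
  list(fraction_ted = ss_ted / tot,
       fraction_year = ss_year / tot,
       fraction_error = ss_err / tot,
       ted_share_excl_error = ss_ted / (ss_ted + ss_year),
       ss = c(ted = ss_ted, year = ss_year, error = ss_err))
}

#' All-factors R-squared of the four TED components
#'
#' Least-squares fit of unit-level mean yield (and of unit-level CV) on the
#' four categorical class components, all entered; the coefficient of
#' determination summarises how much of the between-unit variation the
#' zonation factors capture. Factors with a single level are dropped; a
#' saturated or aliased design is reported with a flag, not an exception.
#'
#' @param panel A `yield_panel`.
#' @return List: `r2_mean_yield`, `r2_cv`, `factors_used`, `saturated`
#'   (logical flag).
#' @export
factor_r_squared <- function(panel) {
  us <- unit_stats(panel)
  facs <- c("gdd_class", "ai_class", "seasonality_class", "pawhc_class")
  use <- facs[vapply(facs, function(f) length(unique(us[[f]])) > 1, TRUE)]
  if (!length(use)) {
    stop("no factor has >= 2 levels", call. = FALSE)
  }
  for (f in use) us[[f]] <- factor(us[[f]])
  form <- function(resp) stats::as.formula(paste(resp, "~", paste(use, collapse = " + ")))
  r2 <- function(resp) {
    fit <- stats::lm(form(resp), data = us)
    list(r2 = summary(fit)$r.squared,
         saturated = fit$df.residual == 0 || anyNA(stats::coef(fit)))
  }
  m <- r2("mean_yield"); v <- r2("cv_percent")
  list(r2_mean_yield = m$r2, r2_cv = v$r2, factors_used = use,
       saturated = m$saturated || v$saturated)
}
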