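# Crop-area coverage curves over TEDs and trial-network placement: how many
# zones are needed for a target share of crop area, how well an existing
# network covers it, and the efficiency frontier of strategic placement.

#' Zonal crop area per TED
#'
#' Sums the harvested-area raster over each TED. Cells with zero crop area
#' contribute zero; NoData TED cells are excluded.
#'
#' @param ted A `ted_raster`.
#' @param crop_area A `grid_raster` of harvested area (ha per cell), aligned
#'   with the TED raster.
#' @return A `crop_area_table`: data.frame with columns `ted_code`,
#'   `crop_area_ha`, sorted by code, with the grand total as attribute
#'   `total_area`.
#' @export
crop_area_by_ted <- function(ted, crop_area) {
  stop_if_misaligned(ted$codes, crop_area, "ted raster", "crop area")
  code <- as.vector(ted$codes$values)
  area <- as.vector(crop_area$values)
  keep <- !is.na(code)
  sums <- tapply(ifelse(is.na(area[keep]), 0, area[keep]), code[keep], sum)
  ints <- as.numeric(names(sums))
  m <- match(ints, ted$legend$code_int)
  out <- data.frame(ted_code = ted$legend$ted_code[m],
                    crop_area_ha = as.numeric(sums))
  out <- out[order(out$ted_code), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total_area = sum(out$crop_area_ha),
            class = c("crop_area_table", "data.frame"))
}

#' Construct a crop-area table directly
#'
#' @param ted_code Character TED codes.
#' @param crop_area_ha Non-negative areas (ha).
#' @return A `crop_area_table`.
#' @export
crop_area_table <- function(ted_code, crop_area_ha) {
  if (any(crop_area_ha < 0)) stop("areas must be >= 0", call. = FALSE)
  if (anyDuplicated(ted_code)) stop("duplicate TED codes", call. = FALSE)
  out <- data.frame(ted_code = as.character(ted_code),
                    crop_area_ha = as.numeric(crop_area_ha))
  structure(out, total_area = sum(out$crop_area_ha),
            class = c("crop_area_table", "data.frame"))
}

#' Crop-area coverage curve
#'
#' Sorts TEDs from largest to smallest crop area (ties broken by
#' lexicographic TED code, so curves are deterministic) and accumulates the
#' fraction of total crop area covered by the first n TEDs. The increments
#' are non-increasing by construction: each additional TED contributes less
#' (diminishing returns).
#'
#' @param table A `crop_area_table`.
#' @return A `coverage_curve`: data.frame with `rank`, `ted_code`,
#'   `crop_area_ha`, `cumulative_fraction`.
#' @export
coverage_curve <- function(table) {
  total <- sum(table$crop_area_ha)
  if (total <= 0) stop("undefined coverage curve: total crop area is zero",
                       call. = FALSE)
  ord <- order(-table$crop_area_ha, table$ted_code)
  out <- data.frame(rank = seq_len(nrow(table)),
                    ted_code = table$ted_code[ord],
                    crop_area_ha = table$crop_area_ha[ord])
  out$cumulative_fraction <- cumsum(out$crop_area_ha) / total
  structure(out, class = c("coverage_curve", "data.frame"))
}

#' TEDs required for a coverage target
#'
#' Minimal number n of (largest) TEDs whose cumulative crop-area fraction
#' reaches the target.
#'
#' @param curve A [coverage_curve()].
#' @param target_fraction Target in `[0, 1]`.
#' @return Integer n.
#' @export
teds_for_coverage <- function(curve, target_fraction) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must be in [0, 1]", call. = FALSE)
  }
  if (target_fraction == 0) return(0L)
  # guard against cumulative rounding at the terminal 1.0
  cf <- pmin(1, curve$cumulative_fraction + 1e-12)
  as.integer(which(cf >= target_fraction)[1])
}

#' Assign trial sites to TEDs
#'
#' Point-in-cell lookup with cell-centre grid registration. Sites outside the
#' raster extent or on NoData cells are flagged unassigned — never dropped
#' silently.
#'
#' @param ted A `ted_raster`.
#' @param sites data.frame with columns `site_id`, `x`, `y` in the raster's
#'   coordinate system.
#' @return A `trial_network`: data.frame `site_id`, `x`, `y`, `ted_code`
#'   (`NA` = unassigned), with attribute `n_unassigned`.
#' @export
assign_sites <- function(ted, sites) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  rc <- cell_at_xy(ted$codes, sites$x, sites$y)
  code <- rep(NA_real_, nrow(sites))
  ok <- !is.na(rc$row)
  code[ok] <- ted$codes$values[cbind(rc$row[ok], rc$col[ok])]
  m <- match(code, ted$legend$code_int)
  out <- data.frame(site_id = sites$site_id, x = sites$x, y = sites$y,
                    ted_code = ted$legend$ted_code[m])
  n_un <- sum(is.na(out$ted_code))
  if (n_un > 0) {
    warning(sprintf("%d site(s) outside the extent or on NoData cells left unassigned",
                    n_un))
  }
  structure(out, n_unassigned = n_un,
            class = c("trial_network", "data.frame"))
}

#' Coverage achieved by a trial network
#'
#' @param network A `trial_network` (see [assign_sites()]), or any data.frame
#'   with a `ted_code` column.
#' @param table A `crop_area_table`.
#' @return List with `unique_ted_count` and `covered_area_fraction` (share of
#'   total crop area in the TEDs that contain at least one site).
#' @export
network_coverage <- function(network, table) {
  teds <- unique(network$ted_code[!is.na(network$ted_code)])
  total <- sum(table$crop_area_ha)
  frac <- if (length(teds) == 0) 0 else
    sum(table$crop_area_ha[table$ted_code %in% teds]) / total
  list(unique_ted_count = length(teds), covered_area_fraction = frac)
}

#' Minimal single-TED trial set for a coverage target
#'
#' Greedy pick of largest-area TEDs until the target crop-area fraction is
#' met. Because one site covers exactly one whole TED and areas are additive,
#' the greedy prefix of the coverage curve is provably a minimum-cardinality
#' solution.
#'
#' @param table A `crop_area_table`.
#' @param target_fraction Target in `[0, 1]`.
#' @return Character vector of selected TED codes (possibly empty).
#' @export
minimal_sites_for_coverage <- function(table, target_fraction) {
  if (target_fraction > 1) {
    stop("infeasible coverage target > 1", call. = FALSE)
  }
  curve <- coverage_curve(table)
  n <- teds_for_coverage(curve, target_fraction)
  if (n == 0) character(0) else curve$ted_code[seq_len(n)]
}

#' Maximum-coverage reallocation of a fixed number of trials
#'
#' The n largest-area TEDs: the best achievable coverage when each of n
#' trials is placed in a unique TED. Requesting more sites than there are
#' TEDs returns all of them.
#'
#' @param table A `crop_area_table`.
#' @param n_sites Number of trial sites (>= 0).
#' @return Character vector of selected TED codes.
#' @export
reallocate_max_coverage <- function(table, n_sites) {
  if (n_sites < 0) stop("n_sites must be >= 0", call. = FALSE)
  if (n_sites == 0) return(character(0))
  curve <- coverage_curve(table)
  curve$ted_code[seq_len(min(n_sites, nrow(curve)))]
}
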