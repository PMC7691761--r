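# Shared builders for small in-code fixtures.

with_seed_local <- tedzone:::with_seed

tiny_config <- function(seed = 42, ...) {
  fixture_config(grid_rows = 10, grid_cols = 10, years = 3, seed = seed, ...)
}

# Index rasters whose values sit at the midpoint of a requested class, so
# delineation must recover the planted classes exactly.
class_midpoint <- function(class, boundaries) {
  b <- boundaries
  n <- length(b)
  step_lo <- if (n > 1) b[2] - b[1] else 1
  step_hi <- if (n > 1) b[n] - b[n - 1] else 1
  ext <- c(b[1] - step_lo, b, b[n] + step_hi)
  (ext[class + 1] + ext[class + 2]) / 2
}

indices_from_classes <- function(g, a, s, scheme, cellsize = 1,
                                 crs = "LOCAL_CS[\"test-km\"]") {
  as_r <- function(m) grid_raster(m, cellsize = cellsize, crs = crs)
  structure(list(
    gdd = as_r(matrix(class_midpoint(g, scheme$gdd_boundaries), nrow(g), ncol(g))),
    aridity_index = as_r(matrix(class_midpoint(a, scheme$ai_boundaries), nrow(a), ncol(a))),
    seasonality = as_r(matrix(class_midpoint(s, scheme$seasonality_boundaries),
                              nrow(s), ncol(s)))
  ), class = "climate_index_raster")
}

# TED raster with planted class components (returns a delineated ted_raster).
ted_from_classes <- function(g, a, s, pawhc_mm, scheme = ted_scheme(),
                             cellsize = 1) {
  idx <- indices_from_classes(g, a, s, scheme, cellsize = cellsize)
  pw <- grid_raster(pawhc_mm, cellsize = cellsize, crs = "LOCAL_CS[\"test-km\"]")
  delineate_teds(idx, pw, scheme)
}

# A balanced unit-class table: n_per_group units in each of the given
# (pawhc_class, ai_class) combinations.
unit_classes_grid <- function(pawhc_classes, ai_classes, n_per_group) {
  combos <- expand.grid(pawhc_class = pawhc_classes, ai_class = ai_classes)
  n <- nrow(combos) * n_per_group
  df <- combos[rep(seq_len(nrow(combos)), each = n_per_group), , drop = FALSE]
  df$gdd_class <- 4L
  df$seasonality_class <- 1L
  df$unit_id <- sprintf("U%04d", seq_len(n))
  df$ted_code <- render_ted_code(df$gdd_class, df$ai_class,
                                 df$seasonality_class, df$pawhc_class)
  rownames(df) <- NULL
  df
}

# Exhaustive subset search over a crop-area table with <= 14 TEDs:
# minimum subset size reaching a target fraction, and best coverage for n.
exhaustive_min_size <- function(areas, target_fraction) {
  k <- length(areas)
  masks <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  sums <- as.vector(masks %*% areas)
  sizes <- rowSums(masks)
  ok <- sums >= target_fraction * sum(areas) - 1e-9
  min(sizes[ok])
}

exhaustive_best_coverage <- function(areas, n) {
  k <- length(areas)
  masks <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  sums <- as.vector(masks %*% areas)
  sizes <- rowSums(masks)
  if (n >= k) return(sum(areas))
  max(sums[sizes == n])
}

# A 1-row raster with two TEDs (left half / right half) and one unit spanning
# cells with configurable crop areas: the smallest setting where the county
# majority rule has all its edge cases.
majority_fixture <- function(areas) {
  n <- length(areas)
  g <- matrix(4L, 1, n); a <- matrix(2L, 1, n); s <- matrix(1L, 1, n)
  pw <- matrix(260, 1, n); pw[1, seq_len(floor(n / 2))] <- 120
  ted <- ted_from_classes(g, a, s, pw)
  crop <- grid_raster(matrix(areas, 1, n), cellsize = 1, crs = "x")
  units <- admin_units("U1", list(cbind(c(0, n, n, 0, 0), c(0, 0, 1, 1, 0))))
  list(ted = ted, crop = crop, units = units)
}

random_area_table <- function(k) {
  crop_area_table(sprintf("CZ%d.0.1-W%d", seq_len(k) %% 3, seq_len(k)),
                  round(stats::runif(k, 0, 100), 1))
}
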