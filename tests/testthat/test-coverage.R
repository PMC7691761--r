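toy_table <- function() {
  crop_area_table(c("CZ4.2.1-W5", "CZ4.3.1-W5", "CZ5.2.1-W4"), c(50, 30, 20))
}

test_that("zonal crop-area sums match a cell-by-cell oracle and conserve the total", {
  g <- matrix(4L, 4, 4); a <- matrix(2L, 4, 4); s <- matrix(1L, 4, 4)
  pw <- matrix(260, 4, 4)
  pw[1:2, ] <- 120; pw[3, ] <- 180   # three TEDs: 8, 4, 4 cells
  ted <- ted_from_classes(g, a, s, pw)
  area <- grid_raster(matrix(c(rep(50 / 8, 8), rep(30 / 4, 4), rep(20 / 4, 4)),
                             4, 4, byrow = TRUE),
                      cellsize = 1, crs = "LOCAL_CS[\"test-km\"]")
  tab <- crop_area_by_ted(ted, area)
  # cell-accounting oracle
  oracle <- tapply(as.vector(area$values), as.vector(ted$codes$values), sum)
  m <- match(ted$legend$code_int, as.numeric(names(oracle)))
  expect_equal(tab$crop_area_ha[match(ted$legend$ted_code, tab$ted_code)],
               as.numeric(oracle[m]))
  expect_equal(sum(tab$crop_area_ha), sum(area$values))
  # uniform area over two equal TEDs splits 50/50
  pw2 <- matrix(260, 4, 4); pw2[1:2, ] <- 120
  ted2 <- ted_from_classes(g, a, s, pw2)
  unif <- grid_raster(matrix(1, 4, 4), cellsize = 1, crs = "x")
  tab2 <- crop_area_by_ted(ted2, unif)
  expect_equal(tab2$crop_area_ha, c(8, 8))
})

test_that("coverage curves accumulate sorted fractions with deterministic ties", {
  cv <- coverage_curve(toy_table())
  expect_equal(cv$cumulative_fraction, c(0.5, 0.8, 1.0))
  expect_equal(cv$ted_code[1], "CZ4.2.1-W5")
  single <- coverage_curve(crop_area_table("CZ1.1.1-W1", 10))
  expect_equal(single$cumulative_fraction, 1.0)
  # increments non-increasing (sortedness => concavity)
  expect_true(all(diff(diff(c(0, cv$cumulative_fraction))) <= 1e-12))
  # equal areas break ties lexicographically
  tie <- coverage_curve(crop_area_table(c("CZ2.1.1-W3", "CZ1.1.1-W3"), c(5, 5)))
  expect_equal(tie$ted_code, c("CZ1.1.1-W3", "CZ2.1.1-W3"))
  expect_error(coverage_curve(crop_area_table(c("A1"), 0)), "zero")
})

test_that("teds_for_coverage is the minimal prefix length and monotone in the target", {
  cv <- coverage_curve(toy_table())
  expect_equal(teds_for_coverage(cv, 0), 0L)
  expect_equal(teds_for_coverage(cv, 0.5), 1L)
  expect_equal(teds_for_coverage(cv, 0.75), 2L)
  expect_equal(teds_for_coverage(cv, 1.0), 3L)
  expect_error(teds_for_coverage(cv, 1.2), "target")
  targets <- seq(0, 1, by = 0.05)
  ns <- vapply(targets, function(t) teds_for_coverage(cv, t), integer(1))
  expect_true(!is.unsorted(ns))
  # zero-area TEDs do not count towards full coverage
  with_zero <- crop_area_table(c("A1", "B1", "C1"), c(60, 40, 0))
  expect_equal(teds_for_coverage(coverage_curve(with_zero), 1.0), 2L)
})

test_that("sites are assigned by point-in-cell lookup, outside sites flagged", {
  g <- matrix(4L, 4, 4); a <- matrix(2L, 4, 4); s <- matrix(1L, 4, 4)
  pw <- matrix(260, 4, 4); pw[1:2, ] <- 120
  ted <- ted_from_classes(g, a, s, pw)  # cellsize 1, rows 1:2 = W2, rows 3:4 = W5
  sites <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                      x = c(0.5, 0.6, 2.5, 9.0),
                      y = c(0.5, 0.5, 3.5, 1.0))
  expect_warning(net <- assign_sites(ted, sites), "1 site")
  expect_equal(net$ted_code[1], "CZ4.2.1-W5")   # south row -> pawhc 260
  expect_equal(net$ted_code[1], net$ted_code[2])  # same cell, same TED
  expect_equal(net$ted_code[3], "CZ4.2.1-W2")   # north row -> pawhc 120
  expect_true(is.na(net$ted_code[4]))
  expect_equal(attr(net, "n_unassigned"), 1L)
})

test_that("network coverage counts unique TEDs and their area share", {
  tab <- toy_table()
  net <- data.frame(ted_code = c("CZ4.2.1-W5", "CZ4.2.1-W5", "CZ4.3.1-W5"))
  cov <- network_coverage(net, tab)
  expect_equal(cov$unique_ted_count, 2L)
  expect_equal(cov$covered_area_fraction, 0.8)
  expect_equal(network_coverage(data.frame(ted_code = character(0)), tab),
               list(unique_ted_count = 0L, covered_area_fraction = 0))
  all_cov <- network_coverage(data.frame(ted_code = tab$ted_code), tab)
  expect_equal(all_cov$covered_area_fraction, 1.0)
})

test_that("greedy site selection matches hand cases and the exhaustive oracle", {
  tab <- toy_table()
  expect_setequal(minimal_sites_for_coverage(tab, 0.6),
                  c("CZ4.2.1-W5", "CZ4.3.1-W5"))
  expect_length(minimal_sites_for_coverage(tab, 0.5), 1L)  # largest TED alone
  expect_equal(reallocate_max_coverage(tab, 0), character(0))
  expect_setequal(reallocate_max_coverage(tab, 2), c("CZ4.2.1-W5", "CZ4.3.1-W5"))
  expect_error(minimal_sites_for_coverage(tab, 1.5), "infeasible")

  withr::local_seed(17)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    t <- random_area_table(k)
    target <- runif(1, 0.05, 0.95)
    greedy <- minimal_sites_for_coverage(t, target)
    expect_equal(length(greedy), exhaustive_min_size(t$crop_area_ha, target))
    n <- sample.int(k, 1)
    picked <- reallocate_max_coverage(t, n)
    expect_equal(sum(t$crop_area_ha[t$ted_code %in% picked]),
                 exhaustive_best_coverage(t$crop_area_ha, n), tolerance = 1e-9)
  }
})

test_that("the reallocation frontier dominates random networks of equal size", {
  withr::local_seed(23)
  tab <- random_area_table(10)
  curve <- coverage_curve(tab)
  for (rep in 1:200) {
    n <- sample.int(10, 1)
    rand <- data.frame(ted_code = sample(tab$ted_code, n, replace = TRUE))
    best <- network_coverage(data.frame(ted_code = reallocate_max_coverage(tab, n)),
                             tab)$covered_area_fraction
    got <- network_coverage(rand, tab)$covered_area_fraction
    expect_lte(got, best + 1e-12)
  }
})
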