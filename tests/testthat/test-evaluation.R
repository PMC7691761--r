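test_that("admin units follow the strict >50% crop-area majority rule", {
  # 60/40 split: assigned to the left TED
  f <- majority_fixture(c(30, 30, 20, 20))
  out <- assign_admin_units(f$ted, f$crop, f$units)
  expect_equal(out$ted_code, "CZ4.2.1-W2")
  expect_equal(out$majority_share, 0.6)
  expect_equal(out$reason, "assigned")

  # exact 50/50: unassigned (strict inequality)
  f2 <- majority_fixture(c(25, 25, 25, 25))
  out2 <- assign_admin_units(f2$ted, f2$crop, f2$units)
  expect_true(is.na(out2$ted_code))
  expect_equal(out2$reason, "no_majority")

  # toy (3,1,1,0) over TEDs (X,X,Y,Y): X holds 4/5 = 80%
  f3 <- majority_fixture(c(3, 1, 1, 0))
  out3 <- assign_admin_units(f3$ted, f3$crop, f3$units)
  expect_equal(out3$majority_share, 0.8)
  expect_equal(out3$ted_code, "CZ4.2.1-W2")

  # zero crop area: unassigned with reason code
  f4 <- majority_fixture(c(0, 0, 0, 0))
  out4 <- assign_admin_units(f4$ted, f4$crop, f4$units)
  expect_equal(out4$reason, "no_crop_area")
})

test_that("unit assignment agrees with a brute-force cell-accounting oracle", {
  withr::local_seed(31)
  cfg <- tiny_config(unit_block_size = 3)
  idx <- compute_index_rasters(generate_weather_grid(cfg))
  ted <- delineate_teds(idx, generate_pawhc_raster(cfg), ted_scheme())
  cu <- generate_crop_area_and_units(cfg)
  out <- assign_admin_units(ted, cu$crop_area, cu$units)

  # oracle: loop rows/cols of each unit block directly on the matrices
  nr <- cfg$grid_rows; bs <- 3
  k <- 0
  for (br in seq_len(ceiling(nr / bs))) for (bc in seq_len(ceiling(nr / bs))) {
    k <- k + 1
    rows <- ((br - 1) * bs + 1):min(br * bs, nr)
    cols <- ((bc - 1) * bs + 1):min(bc * bs, nr)
    codes <- as.vector(ted$codes$values[rows, cols])
    areas <- as.vector(cu$crop_area$values[rows, cols])
    shares <- tapply(areas, codes, sum) / sum(areas)
    top <- which.max(shares)
    expected <- if (shares[top] > 0.5) {
      ted$legend$ted_code[match(as.numeric(names(shares)[top]), ted$legend$code_int)]
    } else NA_character_
    expect_equal(out$ted_code[k], expected)
  }
})

test_that("zone summaries compute per-unit CV then average within groups", {
  units <- unit_classes_grid(5, 2, 1)
  rec <- data.frame(unit_id = "U0001", year = 1:3, yield_mg_ha = c(8, 10, 12))
  panel <- yield_panel(rec, units)
  zs <- zone_summaries(panel, "ted_code")
  expect_equal(zs$mean_yield, 10)
  expect_equal(zs$cv_percent, 20)       # sd = 2, mean = 10
  expect_equal(zs$n_units, 1L)

  # constant yields: zero CV; CV invariant under doubling all yields
  rec2 <- rec; rec2$yield_mg_ha <- c(7, 7, 7)
  expect_equal(zone_summaries(yield_panel(rec2, units))$cv_percent, 0)
  rec3 <- rec; rec3$yield_mg_ha <- rec$yield_mg_ha * 2
  expect_equal(zone_summaries(yield_panel(rec3, units))$cv_percent, 20)
})

test_that("summaries are independent of record ordering", {
  uc <- unit_classes_grid(c(4, 6), c(1, 3), 5)
  panel <- simulate_yield_panel(uc, yield_effect_spec(), 6, seed = 8)
  shuffled <- panel
  withr::local_seed(9)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  expect_equal(zone_summaries(shuffled, "pawhc_class"),
               zone_summaries(panel, "pawhc_class"))
  expect_equal(variance_partition(shuffled)[1:4], variance_partition(panel)[1:4])
})

test_that("transects report ordered summaries and trend flags", {
  # planted: yield rises and year-loading falls with PAWHC class
  uc <- unit_classes_grid(c(2, 4, 6), 2, 10)
  spec <- yield_effect_spec(pawhc_effect = 0.5, year_sd = 0.6, noise_sd = 0.05,
                            cv_pawhc_slope = -0.12)
  panel <- simulate_yield_panel(uc, spec, 10, seed = 4)
  tr <- transect_summary(panel, c("2", "4", "6"), group_by = "pawhc_class")
  expect_equal(tr$summary$group, c("2", "4", "6"))
  expect_true(tr$mean_increasing)
  expect_true(tr$cv_decreasing)

  single <- transect_summary(panel, "4", group_by = "pawhc_class")
  expect_true(single$mean_increasing && single$cv_decreasing)
  expect_error(transect_summary(panel, c("2", "9"), group_by = "pawhc_class"),
               "unknown group")
})

test_that("variance partition matches the closed-form planted decomposition", {
  # only TED variance: share excluding error is exactly 1
  uc <- unit_classes_grid(c(4, 6), 2, 2)
  p0 <- simulate_yield_panel(uc, yield_effect_spec(year_sd = 0, noise_sd = 0),
                             4, seed = 1)
  vp0 <- suppressWarnings(variance_partition(p0))  # exact fit: F-test warning expected
  expect_equal(vp0$ted_share_excl_error, 1.0)

  # planted variances TED 4, year 1, noise 0 (balanced, constructed exactly):
  # share excluding error = 4 / (4 + 1) = 0.8
  mu <- c(0, 0, 4, 4)                       # unit means, pop variance 4
  yeff <- c(1, -1, 1, -1)                   # year effects, pop variance 1
  rec <- expand.grid(unit_id = sprintf("U%04d", 1:4), year = 1:4)
  rec$yield_mg_ha <- mu[as.integer(sub("U", "", rec$unit_id))] + yeff[rec$year] + 10
  units <- unit_classes_grid(c(4, 6), 2, 2)
  panel <- yield_panel(rec, units)
  vp <- suppressWarnings(variance_partition(panel))
  expect_equal(vp$ted_share_excl_error, 0.8, tolerance = 1e-9)
  expect_equal(vp$fraction_ted + vp$fraction_year + vp$fraction_error, 1,
               tolerance = 1e-9)
  expect_equal(vp$fraction_error, 0, tolerance = 1e-9)

  one_ted <- yield_panel(rec, within(units, ted_code <- "CZ1.1.1-W1"))
  expect_error(variance_partition(one_ted), "degenerate")
})

test_that("all-factor R^2 matches a two-pass arithmetic oracle", {
  # noiseless: yield an exact function of pawhc class
  uc <- unit_classes_grid(c(2, 4, 6), 2, 4)
  p0 <- simulate_yield_panel(uc, yield_effect_spec(year_sd = 0, noise_sd = 0),
                             4, seed = 1)
  expect_equal(suppressWarnings(factor_r_squared(p0))$r2_mean_yield, 1.0,
               tolerance = 1e-9)

  # noisy panel: R^2 equals 1 - SSresid/SStotal computed directly
  p1 <- simulate_yield_panel(uc, yield_effect_spec(), 6, seed = 2)
  fr <- factor_r_squared(p1)
  us <- tedzone:::unit_stats(p1)
  for (f in fr$factors_used) us[[f]] <- factor(us[[f]])
  fit <- lm(reformulate(fr$factors_used, "mean_yield"), data = us)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((us$mean_yield - mean(us$mean_yield))^2)
  expect_equal(fr$r2_mean_yield, 1 - ss_res / ss_tot, tolerance = 1e-9)

  # pure noise: R^2 small at 500 units
  uc_null <- unit_classes_grid(c(2, 4, 6, 8), c(1, 3), 63)  # 504 units
  p_null <- simulate_yield_panel(
    uc_null, yield_effect_spec(pawhc_effect = 0, aridity_effect = 0,
                               year_sd = 0, noise_sd = 1, cv_pawhc_slope = 0),
    6, seed = 3)
  expect_lt(factor_r_squared(p_null)$r2_mean_yield, 0.1)
})

test_that("shuffling unit-to-TED labels collapses the TED share to its null expectation", {
  uc <- unit_classes_grid(c(2, 4, 6, 8), c(1, 3), 25)  # 8 TEDs x 25 units
  spec <- yield_effect_spec(cv_pawhc_slope = 0)
  shuffled_frac <- expected_frac <- numeric(10)
  for (i in 1:10) {
    panel <- simulate_yield_panel(uc, spec, 10, seed = 100 + i)
    shuf <- panel
    shuf$units$ted_code <- with_seed_local(200 + i, sample(panel$units$ted_code))
    vp <- variance_partition(shuf)
    shuffled_frac[i] <- vp$fraction_ted
    # finite-population null: E[SS_between] = (G-1)/(U-1) * SS(unit means)
    m_u <- tapply(panel$records$yield_mg_ha, panel$records$unit_id, mean)
    ss_units <- 10 * sum((m_u - mean(m_u))^2)
    ss_tot <- sum((panel$records$yield_mg_ha - mean(panel$records$yield_mg_ha))^2)
    G <- length(unique(panel$units$ted_code)); U <- nrow(panel$units)
    expected_frac[i] <- (G - 1) / (U - 1) * ss_units / ss_tot
  }
  expect_lt(abs(mean(shuffled_frac) - mean(expected_frac)), 0.05)
  # and far below the planted share
  planted <- variance_partition(simulate_yield_panel(uc, spec, 10, seed = 55))
  expect_lt(mean(shuffled_frac), planted$fraction_ted / 2)
})
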