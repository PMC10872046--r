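test_that("grid_spec validates its extent and counts cells", {
  spec <- grid_spec(0, 0, 2e5, 1.1e6)
  expect_equal(spec$n_cells, 2200L)
  expect_error(grid_spec(0, 0, 1e5, 1e5, cell_size = 0), "cell_size")
  expect_error(grid_spec(0, 0, 0, 1e5), "extent")
  cents <- cell_centroids(grid_spec(0, 0, 2e4, 3e4))
  expect_equal(nrow(cents), 6L)
  # row-major from the lower-left origin
  expect_equal(cents$easting_m[1:2], c(5000, 15000))
  expect_equal(cents$northing_m[1:2], c(5000, 5000))
})

test_that("cell_index uses half-open cells and flags points off-grid", {
  spec <- grid_spec(0, 0, 3e4, 3e4)
  # a boundary point belongs to the cell whose half-open interval holds it
  expect_equal(cell_index(spec, 10000, 0), 2L)
  expect_equal(cell_index(spec, 0, 10000), 4L)
  expect_true(is.na(cell_index(spec, 30000, 0)))  # x_max itself is outside
  expect_true(is.na(cell_index(spec, -1, 5000)))
})

test_that("climate grid follows the stated gradients and is reproducible", {
  spec <- grid_spec(0, 0, 2e5, 1.1e6)
  g <- simulate_climate_grid(spec, gradient = list(mat_south = 10,
                                                   lapse = -1e-5),
                             noise_sd = list(MAT = 0, PREC = 0, SWC = 0),
                             seed = 3)
  expect_equal(nrow(g), 2200L)
  # noiseless MAT is exactly linear in northing: 10 C at y = 0,
  # -1 C per 100 km, so 5 C at y = 500 km
  expect_equal(g$MAT, 10 - 1e-5 * g$northing_m)
  y500 <- 10 - 1e-5 * 5e5
  expect_equal(y500, 5.0)
  # GDD5 is the stated monotone link, nonnegative
  expect_equal(g$GDD5, pmax(0, 200 * g$MAT + 300))
  expect_true(all(g$GDD5 >= 0) && all(g$PREC >= 0))
  expect_true(all(g$SWC >= 0 & g$SWC <= 1))
  # bit-identical under the same seed, different under another
  g2 <- simulate_climate_grid(spec, seed = 11)
  g3 <- simulate_climate_grid(spec, seed = 11)
  g4 <- simulate_climate_grid(spec, seed = 12)
  expect_identical(g2, g3)
  expect_false(identical(g2, g4))
})

test_that("species pool realizes the stated linear shift model", {
  # degenerate generator: all coefficients zero, no noise
  t0 <- simulate_species_pool(25, effect = list(intercept = 30),
                              shift_noise_sd = 0, seed = 5)
  expect_equal(nrow(t0), 25L)
  expect_equal(t0$true_shift_km, rep(30, 25))
  # a single breadth coefficient: species one scaled-SD apart differ by
  # exactly the coefficient
  t1 <- simulate_species_pool(50, effect = list(intercept = 0,
                                                Tbreadth = -30),
                              shift_noise_sd = 0, seed = 5)
  z <- (t1$sd_MAT - mean(t1$sd_MAT)) / sd(t1$sd_MAT)
  expect_equal(t1$true_shift_km, -30 * z)
  fit <- lm(true_shift_km ~ z, data = data.frame(true_shift_km =
                                                   t1$true_shift_km, z = z))
  expect_equal(unname(coef(fit)[2]), -30)
  # determinism
  expect_identical(simulate_species_pool(40, seed = 9),
                   simulate_species_pool(40, seed = 9))
})

test_that("trait levels follow the configured multinomial frequencies", {
  expect_error(simulate_species_pool(
    10, trait_freq = list(wintering = c(adult = 0.5, egg = 0.4))),
    "sum to 1")
  freq <- c(adult = 0.2, egg = 0.2, larva = 0.4, pupa = 0.2)
  counts <- c(adult = 0, egg = 0, larva = 0, pupa = 0)
  for (s in 1:50) {
    tt <- simulate_species_pool(200, seed = s)
    tab <- table(tt$wintering)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  gof <- chisq.test(counts, p = freq[names(counts)])
  expect_gt(gof$p.value, 0.01)
})

test_that("occurrence counts scale with recording effort", {
  spec <- grid_spec(0, 0, 1e5, 6e5)
  truth <- simulate_species_pool(10, effect = list(intercept = 0),
                                 shift_noise_sd = 0,
                                 edge_range = c(3e5, 5.5e5), seed = 1)
  ratios <- vapply(1:20, function(s) {
    occ <- simulate_occurrences(truth, spec,
                                effort = list(T1 = list(intensity = 0.3,
                                                        gradient = 0),
                                              T2 = list(intensity = 0.9,
                                                        gradient = 0)),
                                seed = s)
    yr <- occ$year
    sum(yr >= 2013) / sum(yr <= 1996)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.3)  # within 10% of the nominal 3
})

test_that("complete census with no shift gives identical quantiles", {
  spec <- grid_spec(0, 0, 1e5, 6e5)
  truth <- simulate_species_pool(5, effect = list(intercept = 0),
                                 shift_noise_sd = 0,
                                 edge_range = c(3e5, 5.5e5), seed = 2)
  occ <- simulate_occurrences(truth, spec,
                              effort = list(T1 = list(intensity = Inf,
                                                      gradient = 0),
                                            T2 = list(intensity = Inf,
                                                      gradient = 0)),
                              occupancy = list(p = 1), seed = 2)
  for (sp in truth$species_id) {
    y1 <- occ$northing_m[occ$species_id == sp & occ$year <= 1996]
    y2 <- occ$northing_m[occ$species_id == sp & occ$year >= 2013]
    expect_equal(quantile_edge(y1, 0.9), quantile_edge(y2, 0.9))
  }
})

test_that("a single occupied cell yields records at one coordinate", {
  spec <- grid_spec(0, 0, 1e4, 2e4)  # one column, two rows
  truth <- data.frame(species_id = "sp001", true_edge_T1_m = 1e4,
                      true_shift_km = 0)
  occ <- simulate_occurrences(truth, spec,
                              effort = list(T1 = list(intensity = 5,
                                                      gradient = 0),
                                            T2 = list(intensity = 5,
                                                      gradient = 0)),
                              occupancy = list(p = 1), seed = 3)
  expect_gt(nrow(occ), 0)
  expect_equal(unique(occ$easting_m), 5000)
  expect_equal(unique(occ$northing_m), 5000)
})

test_that("off-grid edges are flagged and skipped, and records stay on-grid", {
  spec <- grid_spec(0, 0, 1e5, 2e5)
  truth <- data.frame(species_id = c("ok", "off"),
                      true_edge_T1_m = c(1.5e5, 3e5),
                      true_shift_km = c(0, 0))
  expect_warning(occ <- simulate_occurrences(
    truth, spec, occupancy = list(p = 1), seed = 4), "outside grid")
  expect_identical(attr(occ, "skipped"), "off")
  expect_false("off" %in% occ$species_id)
  expect_true(all(occ$northing_m > 0 & occ$northing_m < 2e5))
  expect_true(all(occ$easting_m > 0 & occ$easting_m < 1e5))
})
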