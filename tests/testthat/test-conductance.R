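test_that("saturation vapor pressure matches steam-table anchors and is monotone", {
  expect_lt(abs(saturation_vapor_pressure(25) - 23.77), 0.05)
  expect_lt(abs(saturation_vapor_pressure(0) - 4.58) / 4.58, 0.01)
  t_grid <- seq(-10, 60, by = 5)
  expect_true(all(diff(saturation_vapor_pressure(t_grid)) > 0))
  expect_error(saturation_vapor_pressure(-20), "range")
  expect_error(saturation_vapor_pressure(70), "range")
})

test_that("mass-loss regression recovers exact and noisy slopes", {
  expect_error(mass_loss_rate(0:2, c(10, 9.9, 9.8)), ">= 4")
  reg <- mass_loss_rate(0:3, c(10.0, 9.9, 9.8, 9.7))
  expect_equal(reg$slope_mg_day, -100, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  const <- mass_loss_rate(0:4, rep(5, 5))
  expect_equal(const$slope_mg_day, 0)
  expect_equal(const$r_squared, 0)
  # normal-equations oracle on a noisy series
  set.seed(8)
  d <- 0:7
  m <- 5 - 0.05 * d + rnorm(8, 0, 0.005)
  reg <- mass_loss_rate(d, m)
  ref <- normal_equations_ols(d, m * 1000)
  expect_equal(reg$slope_mg_day, unname(ref[2]), tolerance = 1e-8)
  expect_equal(reg$intercept_mg, unname(ref[1]), tolerance = 1e-8)
  expect_error(mass_loss_rate(c(0, 1, 1, 2), c(5, 4, 4, 3)), "increasing")
})

test_that("conductance is the loss rate over the vapor-pressure difference", {
  expect_equal(water_vapor_conductance(-23.77, delta_p_torr = 23.77), 1)
  expect_equal(water_vapor_conductance(-11.885, delta_p_torr = 23.77), 0.5)
  expect_error(water_vapor_conductance(0.1, delta_p_torr = 23.77), "not losing")
  # adding a constant to all masses leaves G unchanged (slope-only dependence)
  set.seed(9)
  d <- 0:7; m <- 5 - 0.03 * d + rnorm(8, 0, 0.003)
  g1 <- water_vapor_conductance(mass_loss_rate(d, m)$slope_mg_day, temp_c = 25)
  g2 <- water_vapor_conductance(mass_loss_rate(d, m + 2)$slope_mg_day, temp_c = 25)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("egg QC separates clean, noisy, and fractured series", {
  set.seed(10)
  clean <- simulate_mass_series(1, delta_p = 23.77, m0 = 5, days = 8,
                                noise_sd = 0.003)
  qc <- qc_egg(clean$day, clean$mass_g)
  expect_true(qc$pass)
  # heavy noise kills R^2
  noisy <- simulate_mass_series(0.2, delta_p = 10, m0 = 5, days = 8,
                                noise_sd = 0.02, seed = 11)
  qc2 <- qc_egg(noisy$day, noisy$mass_g)
  expect_false(qc2$pass)
  expect_true("low_r2" %in% qc2$reasons)
  # mid-series fracture is flagged
  frac <- simulate_mass_series(1, delta_p = 23.77, m0 = 5, days = 8,
                               noise_sd = 0.003, fracture_day = 4, seed = 12)
  qc3 <- qc_egg(frac$day, frac$mass_g)
  expect_true("fracture_suspect" %in% qc3$reasons)
  # constant mass: nonnegative slope
  qc4 <- qc_egg(0:4, rep(5, 5))
  expect_true("nonnegative_slope" %in% qc4$reasons)
})

test_that("species means cap at the first three QC-passing eggs", {
  rec <- data.frame(egg_id = paste0("e", 1:4), species = "sp1", station = "mid",
                    elevation_m = 1500, temp_c = 20,
                    m_h2o_mg_day = c(0.6, 0.8, 1.0, 99) * 20,
                    delta_p_torr = 20, g_h2o = c(0.6, 0.8, 1.0, 99),
                    r_squared = 0.95, qc_pass = TRUE, qc_reasons = "",
                    stringsAsFactors = FALSE)
  expect_equal(species_conductance(rec)$g_h2o, 0.8)
  expect_equal(species_conductance(rec)$n_eggs, 3)
  # result independent of the 4th value
  rec$g_h2o[4] <- -123
  expect_equal(species_conductance(rec)$g_h2o, 0.8)
  # one egg -> that value; zero passing -> dropped with message
  one <- rec[1, ]
  expect_equal(species_conductance(one)$g_h2o, 0.6)
  none <- rec; none$qc_pass <- FALSE
  expect_message(out <- species_conductance(none), "dropped")
  expect_null(out)
})

test_that("Hoyt volume follows V = 0.51 L W^2 with its scaling law", {
  expect_equal(egg_volume(1, 1), 0.51)
  expect_equal(egg_volume(4, 3), 18.36)
  expect_equal(egg_volume(4, 2) * 4, egg_volume(4, 4))
  expect_error(egg_volume(1, 2), "L >= W")
  expect_error(egg_volume(2, 0), "L >= W")
})

test_that("allometric residualization handles exact, degenerate, and noisy fits", {
  x <- setNames(seq(0, 2, length.out = 10), paste0("s", 1:10))
  y <- 2 * x
  res <- suppressWarnings(allometric_residuals(y, x))
  expect_equal(unname(res$residuals), rep(0, 10), tolerance = 1e-10)
  expect_equal(res$r_squared, 1)
  expect_true(res$significant)
  expect_error(allometric_residuals(y, setNames(rep(1, 10), names(x))), "variance")
  # slope recovery within 3 SE at a realistic allometric exponent
  set.seed(13)
  xn <- setNames(rnorm(100), paste0("s", 1:100))
  yn <- 0.56 * xn + rnorm(100, 0, 0.2)
  resn <- allometric_residuals(yn, xn)
  se <- 0.2 / sqrt(sum((xn - mean(xn))^2))
  expect_lt(abs(resn$slope - 0.56), 3 * se)
})

test_that("elevation bands classify interior and gap values", {
  expect_equal(as.character(elevation_category(500)), "lowland")
  expect_equal(as.character(elevation_category(1500)), "mid")
  expect_equal(as.character(elevation_category(2700)), "highland")
  # 1000 m sits in the gap: 150 m from lowland's edge, 200 m from mid's
  expect_warning(lab <- elevation_category(1000), "nearest")
  expect_equal(as.character(lab), "lowland")
  expect_error(elevation_category(-5), ">= 0")
})

test_that("the per-egg table is deterministic and respects the dP mode", {
  b <- simulate_egg_study(n_species = 8, seed = 99)
  t1 <- conductance_table(b$mass_df)
  t2 <- conductance_table(b$mass_df)
  expect_identical(t1, t2)
  ts <- conductance_table(b$mass_df, delta_p_mode = "standard")
  expect_true(all(ts$delta_p_torr == 23.77))
  expect_false(all(t1$delta_p_torr == 23.77))
})
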