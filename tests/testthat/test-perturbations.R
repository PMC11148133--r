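test_that("cough source matches its analytic construction", {
  expect_identical(cough_source(0), 0)
  expect_equal(cough_source(c(0, 0)), c(0, 0))

  # independent arithmetic at t = mu_p with the default parameters
  expected <- 2356.30 / (0.1 * sqrt(2 * pi)) *
    (1 - exp(-0.5 * (0.25 / 0.1)^2) - exp(-0.5 * (1.88 / 0.1)^2) +
       exp(-0.5 * (2.13 / 0.1)^2))
  expect_equal(cough_source(1.88), expected, tolerance = 1e-12)
  expect_equal(expected, 8987.3, tolerance = 1e-5)

  expect_equal(cough_source(seq(0, 4, 0.1), cough_spec(A_kg_m3_s = 0)),
               rep(0, 41))
})

test_that("cough source extrema sit at the lobe means", {
  t <- seq(0, 4, by = 1e-4)
  s <- cough_source(t)
  expect_true(all(is.finite(s)))
  expect_lte(abs(t[which.max(s)] - 1.88), 0.02)
  expect_lte(abs(t[which.min(s)] - 2.13), 0.02)
})

test_that("cough spec validates", {
  expect_error(cough_spec(sigma_s = 0), "positive")
  expect_error(cough_spec(mu_p_s = 2.2, mu_n_s = 2.1), "smaller")
  expect_error(cough_spec(A_kg_m3_s = -1), "non-negative")
})

test_that("hydraulic resistance implements the Darcy law with unit conversion", {
  expect_equal(hydraulic_resistance(porous_zone_spec(0, area_m2 = 1e-4)), 0)

  # posterior zone with the published viscous resistance
  z <- porous_zone_spec(1e14, length_m = 0.01, area_m2 = 0.75 * 1.5e-4,
                        mu_kg_ms = 0.001003)
  r_si <- 1e14 * 0.001003 * 0.01 / (0.75 * 1.5e-4) # 8.916e12 Pa.s/m3
  expect_equal(r_si, 8.916e12, tolerance = 1e-4)
  expect_equal(hydraulic_resistance(z), r_si / 1.33322e8)
  expect_equal(hydraulic_resistance(z), 6.688e4, tolerance = 1e-3)

  # linear in R_v, mu, d; inverse in A
  base <- hydraulic_resistance(porous_zone_spec(1e8, 0.01, 1e-4, 0.001))
  expect_equal(hydraulic_resistance(porous_zone_spec(2e8, 0.01, 1e-4, 0.001)),
               2 * base)
  expect_equal(hydraulic_resistance(porous_zone_spec(1e8, 0.02, 1e-4, 0.001)),
               2 * base)
  expect_equal(hydraulic_resistance(porous_zone_spec(1e8, 0.01, 2e-4, 0.001)),
               base / 2)
  expect_equal(hydraulic_resistance(porous_zone_spec(1e8, 0.01, 1e-4, 0.002)),
               2 * base)
})

test_that("obstruction presets carry the published viscous resistances", {
  expect_equal(obstruction_case("control")[c("R_v_anterior_m2", "R_v_posterior_m2")],
               list(R_v_anterior_m2 = 0, R_v_posterior_m2 = 0))
  expect_equal(obstruction_case("OBS-1")$R_v_posterior_m2, 1e14)
  expect_equal(obstruction_case("OBS-2")$R_v_anterior_m2, 1e8)
  expect_equal(obstruction_case("OBS-3")$R_v_anterior_m2, 1e10)
  expect_equal(obstruction_case("OBS-3")$posterior_area_fraction, 0.75)
  expect_error(obstruction_case("custom"), "both")
  expect_error(obstruction_case("control", posterior_area_fraction = 1), "strictly")
})

test_that("foramen resistance recombines, saturates and orders correctly", {
  expect_equal(foramen_resistance(obstruction_case("control"), R_open = 0.05),
               0.05)

  # posterior fully blocked: only the widened anterior path remains
  blocked <- obstruction_case("custom", R_v_anterior_m2 = 0,
                              R_v_posterior_m2 = 1e20)
  expect_equal(foramen_resistance(blocked, R_open = 0.05), 0.05 / 0.25,
               tolerance = 1e-9)

  r <- vapply(c("control", "OBS-1", "OBS-2", "OBS-3"), function(nm) {
    foramen_resistance(obstruction_case(nm), R_open = 0.05)
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gte(r[["OBS-3"]] / r[["control"]], 100)
})

test_that("foramen resistance is monotone in each zone's viscous resistance", {
  set.seed(3)
  for (i in 1:15) {
    rv <- sort(10^runif(2, 6, 14))
    for (side in c("anterior", "posterior")) {
      cases <- lapply(rv, function(v) {
        obstruction_case("custom",
                         R_v_anterior_m2 = if (side == "anterior") v else 1e8,
                         R_v_posterior_m2 = if (side == "posterior") v else 1e8)
      })
      r <- vapply(cases, foramen_resistance, numeric(1))
      expect_gte(r[2], r[1])
    }
  }
})
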