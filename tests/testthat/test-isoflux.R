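make_meas <- function(jar_id, time_h, flux, delta) {
  tibble::tibble(jar_id = jar_id, time_h = time_h, flux = flux,
                 delta = delta)
}
make_jars <- function(jar_id, soil = "A", amendment = "soil") {
  tibble::tibble(jar_id = jar_id, soil = soil, amendment = amendment,
                 replicate = seq_along(jar_id), soil_mass_g = 5,
                 harvest_day = 26)
}

test_that("daily soil end-member is the control mean, with interpolation", {
  # three control jars measured on day 3 at 10, 12, 14 permil
  m <- make_meas(c("j1", "j2", "j3"), rep(3 * 24, 3), 1, c(10, 12, 14))
  em <- estimate_end_members(m, make_jars(c("j1", "j2", "j3")),
                             c(OM = 500))
  expect_equal(em$table$delta_soil[em$table$day == 3], 12)

  # days 2 and 4 observed, day 3 filled by linear midpoint
  m2 <- make_meas(c("j1", "j1"), c(2, 4) * 24, 1, c(10, 14))
  em2 <- estimate_end_members(m2, make_jars("j1"), c(OM = 500))
  expect_equal(em2$table$delta_soil[em2$table$day == 3], 12)
  expect_error(estimate_end_members(m2, make_jars("j1"), c(OM = 500),
                                    gap_fill = "none"), "without control")

  # single constant control jar -> constant series
  m3 <- make_meas(rep("j1", 5), (1:5) * 24, 1, rep(-27, 5))
  em3 <- estimate_end_members(m3, make_jars("j1"), c(OM = 500))
  expect_true(all(em3$table$delta_soil == -27))
})

test_that("end-member estimation fails without controls or separation", {
  m <- make_meas("j1", 24, 1, 100)
  expect_error(
    estimate_end_members(m, make_jars("j1", amendment = "OM"),
                         c(OM = 500)),
    "no unamended control")
  m2 <- make_meas("j1", 24, 1, 480)
  expect_error(estimate_end_members(m2, make_jars("j1"), c(OM = 500)),
               "separation below 50")
})

test_that("mixing model partition solves the two end-member system", {
  # measured delta equal to the soil end-member: all soil-derived
  p <- partition_flux(-27, 10, -27, 500)
  expect_equal(p$f_soil, 1)
  expect_equal(p$flux_amendment, 0)
  # midpoint symmetry
  expect_equal(partition_flux(473, 1, -27, 973)$f_soil, 0.5)
  # brute-force linear solve oracle: solve A f = b for the 2x2 system
  f_oracle <- solve(matrix(c(-27, 500, 1, 1), 2, 2, byrow = TRUE),
                    c(100, 1))[1]
  expect_equal(partition_flux(100, 1, -27, 500)$f_soil, f_oracle,
               tolerance = 1e-12)
  expect_equal(f_oracle, (100 - 500) / (-27 - 500), tolerance = 1e-12)
})

test_that("partition errors on degenerate end-members and clips with a count", {
  expect_error(partition_flux(0, 1, 10, 20), "ill-conditioned")
  expect_error(partition_flux(NaN, 1, -27, 500), "non-finite")
  p <- partition_flux(c(-50, 600, 100), 1, -27, 500)
  expect_equal(attr(p, "n_clipped"), 2L)
  expect_equal(p$f_soil[1], 1)  # delta below soil end-member -> clipped to 1
  expect_equal(p$f_soil[2], 0)
  unclipped <- partition_flux(c(-50, 600), 1, -27, 500, clip = FALSE)
  expect_gt(unclipped$f_soil[1], 1)
  expect_equal(attr(unclipped, "n_clipped"), 0L)
})

test_that("component fluxes add back to the total exactly", {
  d <- recovery_design(50, seed = 2)
  sim <- simulate_incubation(d)
  em <- estimate_end_members(sim$measurements, sim$jars, c(OM = 500))
  part <- partition_measurements(sim$measurements, sim$jars, em)
  resid <- abs(part$flux_soil + part$flux_amendment - part$flux)
  expect_lt(max(resid / pmax(part$flux, 1e-300)), 1e-12)
  expect_true(all(part$f_soil[part$amendment == "soil"] == 1))
  expect_true(attr(part, "n_clipped") >= 0)
})

test_that("noise-free partition recovers latent nSOC flux to 1e-9", {
  s <- two_pool_soil("A")
  d <- incubation_design(list(s),
                         list(om_amendment(priming = amplitude_for_percent(s, 80))),
                         n_reps = 2, harvest_days = 26, sd_delta = 0,
                         cv_flux = 0, seed = 1)
  sim <- simulate_incubation(d)
  em <- estimate_end_members(sim$measurements, sim$jars, c(OM = 500))
  part <- partition_measurements(sim$measurements, sim$jars, em)
  part <- part[order(part$jar_id, part$time_h), ]
  lat <- sim$truth$latent[order(sim$truth$latent$jar_id,
                                sim$truth$latent$time_h), ]
  rel <- abs(part$flux_soil - lat$flux_soil_latent) / lat$flux_soil_latent
  expect_lt(max(rel), 1e-9)
  expect_equal(attr(part, "n_clipped"), 0L)
})

test_that("trapezoidal accumulation handles rectangles, trapezoids, and t = 0", {
  jars <- make_jars("j1")
  # constant 1 ug/g/h measured at 24 h: back-extension gives 24 ug/g
  p1 <- partition_measurements(make_meas("j1", 24, 1, -27), jars,
                               estimate_end_members(
                                 make_meas("j1", 24, 1, -27), jars,
                                 c(OM = 500)))
  expect_equal(cumulate(p1)$cum_soil, 24)
  # fluxes (2, 0) at t = (0, 10 h): one trapezoid of area 10
  m2 <- make_meas(c("j1", "j1"), c(0, 10), c(2, 0), -27)
  p2 <- partition_measurements(m2, jars,
                               estimate_end_members(m2, jars, c(OM = 500)))
  expect_equal(max(cumulate(p2)$cum_soil), 10)
  # duplicate time points are rejected
  m3 <- make_meas(c("j1", "j1"), c(24, 24), 1, -27)
  p3 <- p2[c(1, 1), ]
  expect_error(cumulate(p3), "duplicate time")
})

test_that("trapezoid cumulative tracks the closed form at daily sampling", {
  # dominant error is the t = 0 back-extension of the first measured flux
  # (~ c0 k^2 / 2), so the achievable bound scales with k^2
  for (k in c(0.01, 0.05)) {
    sim <- simulate_incubation(single_pool_design(k = k))
    em <- estimate_end_members(sim$measurements, sim$jars, c(OM = 500))
    cum <- cumulate(partition_measurements(sim$measurements, sim$jars, em))
    ctrl <- cum[cum$amendment == "soil", ]
    closed <- 100 * (1 - exp(-k * 26))
    tol <- if (k <= 0.01) 0.001 else 0.005
    expect_lt(abs(max(ctrl$cum_soil) - closed) / closed, tol)
  }
})

test_that("treatment summary reproduces hand-computed SE and CI", {
  cum <- tibble::tibble(
    jar_id = paste0("j", 1:3), soil = "A", amendment = "OM",
    replicate = 1:3, time_h = 24, cum_soil = c(10, 12, 14))
  s <- summarize_treatment(cum)
  expect_equal(s$mean, 12)
  expect_equal(s$se, 2 / sqrt(3))  # sd = 2
  expect_equal(s$ci_low, 12 - 1.96 * 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(c(s$ci_low, s$ci_high), 3), c(9.737, 14.263))

  cum2 <- dplyr::mutate(cum[c(1, 1, 1, 1), ], cum_soil = 5,
                        jar_id = paste0("j", 1:4))
  s2 <- summarize_treatment(cum2)
  expect_equal(s2$se, 0)
  expect_equal(c(s2$ci_low, s2$ci_high), c(5, 5))

  s3 <- summarize_treatment(cum[1, ])
  expect_equal(s3$mean, 10)
  expect_true(is.na(s3$se))
})
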