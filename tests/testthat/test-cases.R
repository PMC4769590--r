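test_that("rat fixtures carry the published parameter sets", {
  cfgs <- rat_case_configs()
  expect_length(cfgs, 5)
  ctrl <- cfgs[[1]]
  expect_identical(ctrl$treatment$dose, 0)
  expect_true(is.na(ctrl$radio$alpha))
  expect_equal(ctrl$growth$theta, 0.72)
  c4000 <- cfgs[[5]]
  expect_equal(c4000$radio$alpha, 0.145)
  expect_equal(c4000$growth$theta, 0.838)
  expect_equal(c4000$treatment$dose, 40)
  for (cfg in cfgs) {
    expect_equal(cfg$growth$v0, 0.0157)
    expect_equal(cfg$growth$td0, 1.35)
    expect_equal(cfg$treatment$t_r, 11)
    expect_equal(cfg$treatment$tau_rad, 8)
    expect_equal(cfg$treatment$t_cl, 4)
    expect_equal(cfg$radio$alpha_beta, 10)
  }
  expect_equal(vapply(cfgs, function(x) x$meta$n_obs, integer(1)),
               c(11L, 11L, 19L, 18L, 14L))
})

test_that("clinical fixtures carry the published parameter sets", {
  cfgs <- clinical_case_configs()
  expect_length(cfgs, 5)
  c1 <- cfgs[[1]]
  expect_equal(c1$radio$alpha, 0.09)
  expect_equal(c1$growth$theta, 0.62)
  expect_equal(c1$treatment$t_cl, 13)
  expect_equal(c1$treatment$dose, 38.3)
  expect_identical(c1$meta$local_control, "CR")
  c5 <- cfgs[[5]]
  expect_equal(c5$growth$theta, 0.99)
  expect_identical(c5$meta$local_control, "PD")
  for (cfg in cfgs) expect_equal(cfg$treatment$tau_rad, 8)
  expect_equal(vapply(cfgs, function(x) x$td_at_treatment, numeric(1)),
               c(32.6, 28.0, 11.2, 16.1, 7.9))
  # irradiation-day table conflict is preserved as metadata
  expect_equal(cfgs[[3]]$treatment$t_r, 22)
  expect_equal(cfgs[[3]]$meta$t_r_alt_days, 137)
  expect_equal(cfgs[[4]]$treatment$t_r, 78)
  expect_equal(cfgs[[4]]$meta$t_r_alt_days, 8)
})

test_that("configurations round-trip through JSON losslessly", {
  for (cfg in all_fixture_configs()) {
    path <- withr::local_tempfile(fileext = ".json")
    write_case_config(cfg, path)
    back <- read_case_config(path)
    expect_equal(back, cfg, label = cfg$label)
  }
})

test_that("noise-free synthesis reproduces the model exactly", {
  cfg <- rat_3000()
  times <- seq(0, 40, length.out = 18)
  s <- synthesize_observations(cfg, times, noise_spec(cv = 0, seed = 1))
  expect_equal(residual_ss(rat_3000_truth, s, cfg), 0, tolerance = 1e-22)
  s2 <- synthesize_observations(cfg, times,
                                noise_spec(mode = "sphere_radius",
                                           dr_mm = 0, seed = 1))
  expect_identical(s$volumes, s2$volumes)
})

test_that("lognormal noise has the requested coefficient of variation", {
  cfg <- rat_case_configs()[[1]]
  times <- seq(0.1, 100, length.out = 1000)
  truth <- simulate_response(cfg, times)$v_total_cm3
  s <- synthesize_observations(cfg, times, noise_spec(cv = 0.1, seed = 99))
  ratio <- s$volumes / truth
  expect_lt(abs(sd(ratio) / mean(ratio) - 0.1), 0.01)
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})

test_that("sphere-radius noise stays inside the equivalent-sphere bounds", {
  cfg <- clinical_case_configs()[[4]]
  times <- seq(1, 130, length.out = 200)
  truth <- simulate_response(cfg, times)$v_total_cm3
  s <- synthesize_observations(cfg, times,
                               noise_spec(mode = "sphere_radius",
                                          dr_mm = 1, seed = 42))
  r <- (3 * truth / (4 * pi))^(1 / 3)
  lo <- 4 / 3 * pi * pmax(r - 0.1, 0)^3
  hi <- 4 / 3 * pi * (r + 0.1)^3
  expect_true(all(s$volumes >= lo - 1e-12 & s$volumes <= hi + 1e-12))
  expect_gt(sd(s$volumes / truth), 0)  # noise actually applied
})

test_that("synthesis is seed-deterministic and restores the global RNG", {
  cfg <- rat_3000()
  times <- seq(0, 40, length.out = 18)
  set.seed(123)
  before <- .Random.seed
  a <- synthesize_observations(cfg, times, noise_spec(cv = 0.05, seed = 7))
  expect_identical(.Random.seed, before)
  b <- synthesize_observations(cfg, times, noise_spec(cv = 0.05, seed = 7))
  expect_identical(a$volumes, b$volumes)
  c_ <- synthesize_observations(cfg, times, noise_spec(cv = 0.05, seed = 8))
  expect_false(identical(a$volumes, c_$volumes))
})

test_that("noise-free synthesize-and-fit closes the recovery loop", {
  cfg <- rat_3000()
  times <- seq(0, 40, length.out = 18)
  s <- synthesize_observations(cfg, times, noise_spec(cv = 0, seed = 1))
  f <- fit_simulated_annealing(s, fit_spec(steps = 20000, seed = 17), cfg)
  # light version of the full recovery criterion (which runs 100k steps)
  err <- abs(f$best_params - rat_3000_truth) / rat_3000_truth
  expect_lt(err[["theta"]], 0.05)
  expect_lt(err[["td0"]], 0.15)
  expect_lt(f$rss, 1e-3)
})
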