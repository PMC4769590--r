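test_that("zero dose reduces to the pure growth law", {
  cfg <- rat_case_configs()[[1]]  # control
  times <- seq(0, 60, by = 0.5)
  traj <- simulate_response(cfg, times)
  expect_equal(traj$v_total_cm3, gompertz_volume(times, cfg$growth))
  expect_identical(traj$v_nd_cm3, rep(0, length(times)))
  expect_equal(traj$lambda_per_day, growth_rate_at(times, cfg$growth))
})

test_that("phase-2 closed form matches scalar arithmetic and the RK oracle", {
  # continuity at the window start
  st0 <- phase2_closed_form(2.5, 0.02, 0.5, 0.4, 0.1, 0)
  expect_equal(st0$v_t, 2.5)
  expect_equal(st0$v_nd, 0)
  # case-1 coefficients: a = lam_r p - g, ratio e^(a * 8)
  lam_r <- 0.02126; p <- 0.445; g <- 0.555
  st <- phase2_closed_form(1, lam_r, p, g, log(2) / 13, 8)
  expect_equal(st$v_t, exp((lam_r * p - g) * 8), tolerance = 1e-12)
  expect_equal(st$v_t, 0.0127, tolerance = 2e-3)
  # degenerate a = -eta: limit form vs independent RK4 oracle
  eta <- 0.3; a <- -eta
  g2 <- 0.25; p2 <- 0.5
  lr <- (a + g2) / p2  # engineered so lam_r p - g = -eta exactly
  f <- function(t, y) c((lr * p2 - g2) * y[1], g2 * y[1] - eta * y[2])
  y_or <- oracle_rk4(f, c(1, 0), 0, 5, n_steps = 20000)
  st2 <- phase2_closed_form(1, lr, p2, g2, eta, 5)
  expect_equal(st2$v_t, y_or[1], tolerance = 1e-8)
  expect_equal(st2$v_nd, y_or[2], tolerance = 1e-8)
})

test_that("trajectory state is continuous at both phase boundaries", {
  cfg <- clinical_case_configs()[[2]]
  tr <- cfg$treatment
  eps <- 1e-8
  times <- sort(c(tr$t_r - eps, tr$t_r, tr$t_r + tr$tau_rad - eps,
                  tr$t_r + tr$tau_rad, tr$t_r + tr$tau_rad + eps))
  traj <- simulate_response(cfg, times)
  expect_equal(traj$v_total_cm3[1], traj$v_total_cm3[2], tolerance = 1e-6)
  expect_equal(traj$v_total_cm3[3], traj$v_total_cm3[4], tolerance = 1e-6)
  expect_equal(traj$v_t_cm3[4], traj$v_t_cm3[5], tolerance = 1e-6)
  expect_true(all(traj$v_t_cm3 >= 0 & traj$v_nd_cm3 >= 0))
})

test_that("standard model jumps by the LQ survival fraction and conserves volume", {
  cfg <- rat_case_configs()[[2]]  # 10 Gy, alpha 0.30 -> chi = 6
  tr <- cfg$treatment
  eps <- 1e-9
  times <- c(0, tr$t_r - eps, tr$t_r, tr$t_r + 20)
  traj <- simulate_standard_model(cfg, times)
  v_pre <- traj$v_t_cm3[2]
  expect_equal(traj$v_t_cm3[3] / v_pre, exp(-6), tolerance = 1e-6)
  # total conserved across the jump
  expect_equal(traj$v_total_cm3[3], v_pre, tolerance = 1e-6)
  # no freeze: lambda keeps decaying through t_R
  expect_equal(traj$lambda_per_day, growth_rate_at(times, cfg$growth))
  # zero dose: no jump at all
  ctrl <- rat_case_configs()[[1]]
  traj0 <- simulate_standard_model(ctrl, seq(0, 40, 1))
  expect_equal(traj0$v_total_cm3, gompertz_volume(seq(0, 40, 1), ctrl$growth))
})

test_that("vanishing effect window converges to no-effect growth", {
  base <- clinical_case_configs()[[3]]
  cfg <- suppressWarnings(case_config(
    base$label, base$growth, base$radio,
    treatment_spec(base$treatment$dose, base$treatment$t_r,
                   tau_rad = 1e-9, t_cl = base$treatment$t_cl)))
  times <- seq(0, 80, by = 1)
  traj <- simulate_response(cfg, times)
  expect_equal(traj$v_total_cm3, gompertz_volume(times, cfg$growth),
               tolerance = 1e-6)
})

test_that("doubling-time override replaces the simulated rate at t_R", {
  base <- clinical_case_configs()[[1]]
  tr <- base$treatment
  times <- sort(c(seq(0, 80, 1), tr$t_r))
  traj <- simulate_response(base, times)
  i <- match(tr$t_r, traj$t_days)
  expect_equal(traj$lambda_per_day[i], log(2) / base$td_at_treatment)
  # without the override, lambda at t_R follows the decay law
  no_ov <- case_config(base$label, base$growth, base$radio, base$treatment)
  traj2 <- simulate_response(no_ov, times)
  expect_equal(traj2$lambda_per_day[i], growth_rate_at(tr$t_r, base$growth))
})

test_that("closed form, adaptive integrator, and RK4 oracle agree", {
  for (cfg in list(rat_case_configs()[[4]], clinical_case_configs()[[5]])) {
    tr <- cfg$treatment
    times <- sort(unique(c(seq(0, 120, by = 3), tr$t_r, tr$t_r + tr$tau_rad)))
    a <- simulate_response(cfg, times)
    b <- integrate_numeric(cfg, times)
    expect_lt(max(abs(a$v_total_cm3 - b$v_total_cm3) / a$v_total_cm3), 1e-6)
    # spot-check one post-treatment state against the independent oracle
    y <- oracle_state(cfg, tr$t_r + 30, n_steps = 20000)
    ar <- simulate_response(cfg, tr$t_r + 30)
    expect_equal(ar$v_t_cm3, y[1], tolerance = 1e-6)
    expect_equal(ar$v_nd_cm3, y[2], tolerance = 1e-6)
  }
})

test_that("closed-form output is invariant to grid refinement", {
  cfg <- rat_case_configs()[[3]]
  probe <- c(5, 15, 25, 40)
  coarse <- simulate_response(cfg, sort(unique(c(probe, seq(0, 40, 10)))))
  fine <- simulate_response(cfg, sort(unique(c(probe, seq(0, 40, 0.01)))))
  ic <- match(probe, coarse$t_days); iff <- match(probe, fine$t_days)
  expect_equal(coarse$v_total_cm3[ic], fine$v_total_cm3[iff])
})

test_that("non-dividing pool only shrinks after the window and drains to zero", {
  cfg <- rat_case_configs()[[5]]
  tr <- cfg$treatment
  times <- sort(unique(c(seq(0, 400, 1), tr$t_r + tr$tau_rad)))
  traj <- simulate_response(cfg, times)
  post <- traj$t_days >= tr$t_r + tr$tau_rad
  expect_true(all(diff(traj$v_nd_cm3[post]) <= 0))
  expect_lt(tail(traj$v_nd_cm3, 1), 1e-12)
})

test_that("misconfigured irradiation day is rejected", {
  cfg <- rat_case_configs()[[2]]  # t_r = 11
  expect_error(simulate_response(cfg, seq(0, 10, 1)), "t_r")
  expect_error(integrate_numeric(cfg, seq(0, 10, 1)), "t_r")
})
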