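# Independent fixed-step RK4 oracle for the three-phase system. Deliberately
# separate from both package engines (piecewise closed form, adaptive CK45):
# plain classical RK4 on a fine uniform grid, phase switching handled by
# integrating each phase on its own grid.
oracle_rk4 <- function(f, y0, t0, t1, n_steps = 4000) {
  h <- (t1 - t0) / n_steps
  y <- y0
  t <- t0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# trajectory of the proposed model at time `t_eval` via the RK4 oracle,
# everything recomputed from first principles (no package internals)
oracle_state <- function(cfg, t_eval, n_steps = 4000) {
  gp <- cfg$growth; tr <- cfg$treatment; rc <- cfg$radio
  lam0 <- log(2) / gp$td0
  k <- (1 - gp$theta) * lam0
  chi <- if (tr$dose == 0) 0 else
    rc$alpha * tr$dose * (1 + tr$dose / rc$alpha_beta)
  p <- min(max(1 - rc$t_star / (3 * rc$t_m) * chi, 0), 1)
  g <- chi / (3 * rc$t_m)
  eta <- if (is.infinite(tr$t_cl)) 0 else log(2) / tr$t_cl
  lam_r <- if (!is.null(cfg$td_at_treatment)) log(2) / cfg$td_at_treatment
           else lam0 * exp(-k * tr$t_r)

  f1 <- function(t, y) c(y[3] * y[1], 0, -k * y[3])
  f2 <- function(t, y) c((y[3] * p - g) * y[1], g * y[1] - eta * y[2], 0)
  f3 <- function(t, y) c(y[3] * y[1], -eta * y[2], -k * y[3])

  y <- c(gp$v0, 0, lam0)
  if (tr$dose == 0 || t_eval <= tr$t_r)
    return(oracle_rk4(f1, y, 0, t_eval, n_steps))
  y <- oracle_rk4(f1, y, 0, tr$t_r, n_steps)
  y[3] <- lam_r
  t2 <- tr$t_r + tr$tau_rad
  if (t_eval <= t2) return(oracle_rk4(f2, y, tr$t_r, t_eval, n_steps))
  y <- oracle_rk4(f2, y, tr$t_r, t2, n_steps)
  oracle_rk4(f3, y, t2, t_eval, n_steps)
}

# all ten fixture configurations
all_fixture_configs <- function() c(rat_case_configs(), clinical_case_configs())

rat_3000 <- function() rat_case_configs()[[4]]
rat_3000_truth <- c(alpha = 0.16, theta = 0.795, td0 = 1.35, t_cl = 4)
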