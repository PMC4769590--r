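#' Single-fraction treatment specification
#'
#' Dose and timing of one radiation fraction: dose `dose` (Gy), irradiation
#' day `t_r` (days from series start), active radiation-effect time `tau_rad`
#' (days; the window during which the division probability p(D) and kill rate
#' g(D) act and the growth rate is held constant), and cell clearance time
#' `t_cl` (days). The clearance rate is \eqn{\eta_{cl} = \ln 2 / T_{cl}};
#' `t_cl = Inf` disables clearance (used by consistency checks against the
#' instantaneous-kill model).
#'
#' The model's working range for `tau_rad` is 3 to 10 days; values outside it
#' are accepted with a warning so that the \eqn{\tau_{rad} = 3 T_m}
#' equivalence with the instantaneous-kill model can be exercised.
#'
#' @param dose Dose in Gy (>= 0).
#' @param t_r Irradiation day (>= 0).
#' @param tau_rad Active radiation-effect time, days (> 0). Default 8.
#' @param t_cl Cell clearance time, days (> 0, may be `Inf`).
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(dose, t_r, tau_rad = 8, t_cl) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (t_r < 0) stop("t_r must be >= 0", call. = FALSE)
  if (tau_rad <= 0) stop("tau_rad must be > 0", call. = FALSE)
  if (tau_rad < 3 || tau_rad > 10)
    warning("tau_rad outside the model's stated 3-10 day range", call. = FALSE)
  if (t_cl <= 0) stop("t_cl must be > 0", call. = FALSE)
  structure(list(dose = as.numeric(dose), t_r = as.numeric(t_r),
                 tau_rad = as.numeric(tau_rad), t_cl = as.numeric(t_cl)),
            class = "treatment_spec")
}

#' Complete case configuration
#'
#' Everything needed to simulate one tumor: growth parameters, radiobiology
#' constants, treatment schedule, and an optional doubling-time override at
#' the instant of irradiation. When `td_at_treatment` is given, the growth
#' rate at \eqn{t_R} is taken as \eqn{\ln 2 /} `td_at_treatment` instead of
#' the value the decay law would give — the clinical fixtures print the
#' doubling time observed at radiosurgery, which is not always consistent
#' with decay from baseline.
#'
#' @param label Character identifier.
#' @param growth A [growth_params()] object.
#' @param radio A [radiobiology_constants()] object.
#' @param treatment A [treatment_spec()] object.
#' @param td_at_treatment Optional doubling time at `t_r`, days (> 0).
#' @param meta Optional named list of fixture metadata (response labels,
#'   provenance notes); never used by the simulator.
#' @return An object of class `case_config`.
#' @export
case_config <- function(label, growth, radio, treatment,
                        td_at_treatment = NULL, meta = list()) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(radio, "radiobiology_constants"),
            inherits(treatment, "treatment_spec"))
  if (!is.null(td_at_treatment) && td_at_treatment <= 0)
    stop("td_at_treatment must be > 0", call. = FALSE)
  if (treatment$dose > 0 && is.na(radio$alpha))
    stop("alpha is NA but dose > 0", call. = FALSE)
  structure(list(label = as.character(label), growth = growth, radio = radio,
                 treatment = treatment,
                 td_at_treatment = if (is.null(td_at_treatment)) NULL
                                   else as.numeric(td_at_treatment),
                 meta = meta),
            class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("<case_config '%s'>\n", x$label))
  print(x$growth)
  print(x$radio)
  tr <- x$treatment
  cat(sprintf("Treatment: %g Gy at day %g, tau_rad = %g d, T_cl = %g d\n",
              tr$dose, tr$t_r, tr$tau_rad, tr$t_cl))
  if (!is.null(x$td_at_treatment))
    cat(sprintf("Doubling-time override at t_R: %g d\n", x$td_at_treatment))
  invisible(x)
}

# ---- internal: resolved scalar coefficients of one case -------------------

.case_coefs <- function(config) {
  gp <- config$growth; tr <- config$treatment; rc <- config$radio
  lam0 <- log(2) / gp$td0
  k <- .lambda_decay_const(gp)
  lam_r <- if (!is.null(config$td_at_treatment))
    log(2) / config$td_at_treatment else lam0 * exp(-k * tr$t_r)
  chi <- lethality_exponent(tr$dose, rc)
  list(
    lam0 = lam0, k = k, lam_r = lam_r,
    p = min(max(1 - rc$t_star / (3 * rc$t_m) * chi, 0), 1),
    g = chi / (3 * rc$t_m),
    eta = if (is.infinite(tr$t_cl)) 0 else log(2) / tr$t_cl,
    surv = exp(-chi)
  )
}

.new_trajectory <- function(times, v_t, v_nd, lam) {
  structure(
    data.frame(t_days = times, v_t_cm3 = v_t, v_nd_cm3 = v_nd,
               lambda_per_day = lam, v_total_cm3 = v_t + v_nd),
    class = c("trajectory", "data.frame"))
}

#' Closed-form two-compartment state during the radiation-effect window
#'
#' Evaluates the constant-coefficient phase-2 system
#' \eqn{dV_T/dt = (\lambda_R p - g) V_T}, \eqn{dV_{ND}/dt = g V_T - \eta V_{ND}}
#' analytically from the state \eqn{(V_T(t_R), 0)}:
#' \eqn{V_T = V_T(t_R) e^{a\,dt}} with \eqn{a = \lambda_R p - g}, and
#' \eqn{V_{ND} = g V_T(t_R) (e^{a\,dt} - e^{-\eta\,dt})/(a+\eta)}, switching
#' to the limit \eqn{g V_T(t_R)\,dt\,e^{-\eta\,dt}} when \eqn{|a+\eta|} is
#' below tolerance.
#'
#' @param v_t_at_tr Dividing-cell volume at the start of the window, cm^3.
#' @param lam_r Frozen growth rate \eqn{\lambda_R}, 1/day.
#' @param p Division probability in \[0, 1\].
#' @param g Death rate, 1/day.
#' @param eta Clearance rate, 1/day.
#' @param dt Time since the start of the window, days (vectorized).
#' @return A list with components `v_t` and `v_nd`.
#' @export
phase2_closed_form <- function(v_t_at_tr, lam_r, p, g, eta, dt) {
  a <- lam_r * p - g
  v_t <- v_t_at_tr * exp(a * dt)
  s <- a + eta
  v_nd <- if (abs(s) < 1e-12) {
    g * v_t_at_tr * dt * exp(-eta * dt)
  } else {
    g * v_t_at_tr * (exp(a * dt) - exp(-eta * dt)) / s
  }
  list(v_t = v_t, v_nd = v_nd)
}

#' Simulate the proposed three-phase radiation response
#'
#' Piecewise closed-form trajectory of the two-compartment model. Phase 1
#' (\eqn{t < t_R}): pure Gompertz-type growth, no non-dividing cells. Phase 2
#' (\eqn{t_R \le t < t_R + \tau_{rad}}): the growth rate is frozen at
#' \eqn{\lambda_R}, dividing cells grow at \eqn{\lambda_R p(D)} and die into
#' the non-dividing pool at \eqn{g(D)}, which clears at \eqn{\eta_{cl}}.
#' Phase 3: the radiation effect is over (\eqn{p = 1}, \eqn{g = 0}); the
#' growth rate resumes exponential decay from \eqn{\lambda_R} and the
#' non-dividing pool decays to zero. All three state functions are continuous
#' at the phase boundaries, so the observable total volume
#' \eqn{V_T + V_{ND}} has no jumps.
#'
#' @param config A [case_config()] object.
#' @param times Numeric vector of output times, days (>= 0).
#' @return A `trajectory` data frame with columns `t_days`, `v_t_cm3`,
#'   `v_nd_cm3`, `lambda_per_day`, `v_total_cm3`.
#' @seealso [simulate_standard_model()] for the instantaneous-kill
#'   comparator, [integrate_numeric()] for the numerical cross-check.
#' @examples
#' cfg <- rat_case_configs()[[4]]  # 3000 rad
#' tr <- simulate_response(cfg, seq(0, 40, by = 0.5))
#' r40(simulate_response(cfg, seq(0, 60, by = 0.5)), t_r = 11)
#' @export
simulate_response <- function(config, times) {
  stopifnot(inherits(config, "case_config"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  tr <- config$treatment
  if (tr$dose > 0 && tr$t_r > max(times))
    stop("irradiation day t_r lies outside the requested time grid",
         call. = FALSE)
  co <- .case_coefs(config)
  gp <- config$growth

  if (tr$dose == 0) {
    # p = 1, g = 0: the equations decouple to the pure growth law
    return(.new_trajectory(times, gompertz_volume(times, gp),
                           rep(0, length(times)),
                           growth_rate_at(times, gp)))
  }

  v_t <- numeric(length(times)); v_nd <- numeric(length(times))
  lam <- numeric(length(times))
  t_end2 <- tr$t_r + tr$tau_rad
  ph1 <- times < tr$t_r
  ph2 <- !ph1 & times < t_end2
  ph3 <- times >= t_end2

  v_at_tr <- gompertz_volume(tr$t_r, gp)

  if (any(ph1)) {
    v_t[ph1] <- gompertz_volume(times[ph1], gp)
    lam[ph1] <- growth_rate_at(times[ph1], gp)
  }
  if (any(ph2)) {
    st <- phase2_closed_form(v_at_tr, co$lam_r, co$p, co$g, co$eta,
                             times[ph2] - tr$t_r)
    v_t[ph2] <- st$v_t; v_nd[ph2] <- st$v_nd
    lam[ph2] <- co$lam_r
  }
  if (any(ph3)) {
    st2 <- phase2_closed_form(v_at_tr, co$lam_r, co$p, co$g, co$eta,
                              tr$tau_rad)
    s <- times[ph3] - t_end2
    lam[ph3] <- co$lam_r * exp(-co$k * s)
    v_t[ph3] <- st2$v_t * exp(.int_decaying_rate(co$lam_r, co$k, s))
    v_nd[ph3] <- st2$v_nd * exp(-co$eta * s)
  }
  .new_trajectory(times, v_t, v_nd, lam)
}

#' Simulate the standard instantaneous-kill comparator model
#'
#' The conventional two-compartment response: at the instant of irradiation
#' the dividing volume jumps to \eqn{S(D) V_T(t_-)} and the killed fraction
#' \eqn{(1-S) V_T(t_-)} moves to the non-dividing pool (total volume is
#' conserved across the jump); thereafter the survivors regrow with the
#' decaying growth rate (no freeze) and the dead pool clears at
#' \eqn{\eta_{cl}}.
#'
#' @inheritParams simulate_response
#' @return A `trajectory` data frame; see [simulate_response()].
#' @export
simulate_standard_model <- function(config, times) {
  stopifnot(inherits(config, "case_config"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  tr <- config$treatment
  if (tr$dose > 0 && tr$t_r > max(times))
    stop("irradiation day t_r lies outside the requested time grid",
         call. = FALSE)
  gp <- config$growth
  co <- .case_coefs(config)
  v_t <- gompertz_volume(times, gp)
  lam <- growth_rate_at(times, gp)
  v_nd <- rep(0, length(times))
  if (tr$dose > 0) {
    post <- times >= tr$t_r
    v_at_tr <- gompertz_volume(tr$t_r, gp)
    dt <- times[post] - tr$t_r
    # survivors regrow from S * V_T(t_-); lambda keeps decaying through t_R
    lam_tr <- growth_rate_at(tr$t_r, gp)
    v_t[post] <- co$surv * v_at_tr *
      exp(.int_decaying_rate(lam_tr, co$k, dt))
    v_nd[post] <- (1 - co$surv) * v_at_tr * exp(-co$eta * dt)
  }
  .new_trajectory(times, v_t, v_nd, lam)
}

# Fast scalar-parameter predictor of the observable total volume, used by the
# optimizer: same mathematics as simulate_response but without object
# plumbing. `fixed` carries dose, t_r, tau_rad, alpha_beta, t_star, t_m, v0.
.predict_total <- function(alpha, theta, td0, t_cl, fixed, times) {
  lam0 <- log(2) / td0
  k <- (1 - theta) * lam0
  chi <- alpha * fixed$dose * (1 + fixed$dose / fixed$alpha_beta)
  p <- min(max(1 - fixed$t_star / (3 * fixed$t_m) * chi, 0), 1)
  g <- chi / (3 * fixed$t_m)
  eta <- if (is.infinite(t_cl)) 0 else log(2) / t_cl
  t_r <- fixed$t_r; tau <- fixed$tau_rad
  lam_r <- lam0 * exp(-k * t_r)
  int0 <- function(t) if (k == 0) lam0 * t else lam0 * (1 - exp(-k * t)) / k
  v_at_tr <- fixed$v0 * exp(int0(t_r))
  a <- lam_r * p - g
  s_ae <- a + eta

  out <- numeric(length(times))
  ph1 <- times < t_r
  ph2 <- !ph1 & times < t_r + tau
  ph3 <- times >= t_r + tau
  if (any(ph1)) out[ph1] <- fixed$v0 * exp(int0(times[ph1]))
  p2 <- function(dt) {
    vt <- v_at_tr * exp(a * dt)
    vnd <- if (abs(s_ae) < 1e-12) g * v_at_tr * dt * exp(-eta * dt)
           else g * v_at_tr * (exp(a * dt) - exp(-eta * dt)) / s_ae
    list(vt = vt, vnd = vnd)
  }
  if (any(ph2)) {
    st <- p2(times[ph2] - t_r)
    out[ph2] <- st$vt + st$vnd
  }
  if (any(ph3)) {
    st2 <- p2(tau)
    s <- times[ph3] - t_r - tau
    intr <- if (k == 0) lam_r * s else lam_r * (1 - exp(-k * s)) / k
    out[ph3] <- st2$vt * exp(intr) + st2$vnd * exp(-eta * s)
  }
  out
}
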