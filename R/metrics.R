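# log-linear interpolation of a positive trajectory column at one time
.log_interp <- function(times, values, at) {
  if (at < min(times) - 1e-9 || at > max(times) + 1e-9)
    stop("trajectory does not cover the requested time", call. = FALSE)
  exp(stats::approx(times, log(values), xout = at, rule = 2)$y)
}

#' 40-day volume ratio after irradiation
#'
#' \eqn{R_{40}}: the total model volume 40 days after irradiation divided by
#' the total volume at irradiation — the post-treatment response endpoint.
#' Off-grid times are interpolated linearly in log-volume, matching the
#' exponential structure of the model. Invariant to uniform volume rescaling.
#'
#' @param traj A `trajectory` from [simulate_response()] or friends, covering
#'   \[`t_r`, `t_r` + 40\].
#' @param t_r Irradiation day, days.
#' @return Dimensionless ratio.
#' @export
r40 <- function(traj, t_r) {
  stopifnot(inherits(traj, "trajectory"))
  if (max(traj$t_days) < t_r + 40 || min(traj$t_days) > t_r)
    stop("trajectory must cover [t_r, t_r + 40]", call. = FALSE)
  .log_interp(traj$t_days, traj$v_total_cm3, t_r + 40) /
    .log_interp(traj$t_days, traj$v_total_cm3, t_r)
}

#' Dividing-cell survival over the active radiation-effect window
#'
#' The fraction of the dividing compartment remaining at the end of the
#' radiation-effect window, \eqn{V_T(t_R + \tau_{rad}) / V_T(t_R)}. Equals 1
#' for unirradiated cases; for a frozen growth rate of zero and
#' \eqn{\tau_{rad} = 3 T_m} it reduces to the LQ survival fraction
#' \eqn{e^{-\chi(D)}}. An unirradiated trajectory has no radiation-effect
#' window at all — it is recognized by its empty non-dividing compartment —
#' and scores exactly 1. This is the package's operational definition; the
#' analogous printed table rows were not desk-reproducible under any tested
#' definition and are not claimed to match (see the methods vignette).
#'
#' @param traj A `trajectory` covering \[`t_r`, `t_r` + `tau_rad`\].
#' @param t_r Irradiation day, days.
#' @param tau_rad Active radiation-effect time, days.
#' @return Fraction in (0, 1\] for the proposed model.
#' @export
survival_after_effect <- function(traj, t_r, tau_rad) {
  stopifnot(inherits(traj, "trajectory"))
  if (max(traj$t_days) < t_r + tau_rad || min(traj$t_days) > t_r)
    stop("trajectory must cover [t_r, t_r + tau_rad]", call. = FALSE)
  if (all(traj$v_nd_cm3 == 0)) return(1)  # never irradiated
  .log_interp(traj$t_days, traj$v_t_cm3, t_r + tau_rad) /
    .log_interp(traj$t_days, traj$v_t_cm3, t_r)
}

#' Second-order polynomial regression p-values for outcome screening
#'
#' Fits \eqn{y = b_0 + b_1 x + b_2 x^2} by ordinary least squares and returns
#' the p-value of the overall F-test of the full model against the
#' intercept-only model, together with the same test for the linear-only
#' model — the two rows of the predictor-screening table. A coefficient-wise
#' t-test alternative is available via `method = "coefficient_t"` (p-value of
#' the highest-order coefficient), since the originating regression tool's
#' exact definition is ambiguous.
#'
#' @param x Predictor values (>= 4 points, not all equal).
#' @param y Response values.
#' @param method `"overall_f"` (default) or `"coefficient_t"`.
#' @return A list with `p_quadratic` and `p_linear`, each in \[0, 1\].
#' @export
quadratic_regression_pvalue <- function(x, y,
                                        method = c("overall_f", "coefficient_t")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must match in length", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("rank-deficient design: x needs at least 3 distinct values",
         call. = FALSE)
  if (stats::var(y) < .Machine$double.eps^0.5 * max(1, mean(y)^2))
    return(list(p_quadratic = 1, p_linear = 1))  # no explainable variance
  d <- data.frame(x = x, y = y)
  fit2 <- stats::lm(y ~ x + I(x^2), data = d)
  fit1 <- stats::lm(y ~ x, data = d)
  pval <- function(fit, coef_name) {
    if (method == "coefficient_t") {
      co <- stats::summary.lm(fit)$coefficients
      if (!coef_name %in% rownames(co)) return(1)
      unname(co[coef_name, 4])
    } else {
      fs <- stats::summary.lm(fit)$fstatistic
      if (is.null(fs)) return(1)  # no explained variance (constant y)
      unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    }
  }
  list(p_quadratic = pval(fit2, "I(x^2)"), p_linear = pval(fit1, "x"))
}

#' Per-case outcome metric report
#'
#' Convenience wrapper assembling the clinically oriented summaries of one
#' simulated case: \eqn{R_{40}}, dividing-cell survival over the effect
#' window, and the doubling time and volume at treatment.
#'
#' @param config A [case_config()].
#' @param t_end End of the simulation grid, days; defaults to
#'   `t_r + 60`.
#' @param dt Grid spacing, days.
#' @return A one-row data frame with columns `label`, `r40`,
#'   `survival_after_effect`, `td_at_treatment_days`, `v_at_treatment_cm3`.
#' @export
case_metrics <- function(config, t_end = NULL, dt = 0.25) {
  stopifnot(inherits(config, "case_config"))
  tr <- config$treatment
  if (is.null(t_end)) t_end <- tr$t_r + 60
  times <- sort(unique(c(seq(0, t_end, by = dt), tr$t_r,
                         tr$t_r + tr$tau_rad, tr$t_r + 40)))
  traj <- simulate_response(config, times)
  lam_r <- .case_coefs(config)$lam_r
  data.frame(
    label = config$label,
    r40 = r40(traj, tr$t_r),
    survival_after_effect = survival_after_effect(traj, tr$t_r, tr$tau_rad),
    td_at_treatment_days = doubling_time(lam_r),
    v_at_treatment_cm3 = gompertz_volume(tr$t_r, config$growth))
}
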