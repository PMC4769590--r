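#' Rat rhabdomyosarcoma parameter fixtures
#'
#' The five single-fraction rat rhabdomyosarcoma configurations (control and
#' 1000/2000/3000/4000 rad, i.e. 0/10/20/30/40 Gy). Shared values: initial
#' volume 0.0157 cm^3, irradiation at day 11, initial doubling time 1.35 d,
#' clearance time 4 d, tau_rad 8 d, alpha/beta 10 Gy, T* 1 d, T_m 10 d.
#' Per-dose fitted (alpha, theta): control has no alpha (stored `NA`, never
#' used at dose 0) and theta 0.72; the irradiated cases carry
#' (0.30, 0.72), (0.20, 0.74), (0.16, 0.795), (0.145, 0.838). Observation
#' counts of the original series (11/11/19/18/14) ride along as metadata.
#'
#' @return List of five [case_config()] objects.
#' @export
rat_case_configs <- function() {
  doses <- c(0, 10, 20, 30, 40)
  alphas <- c(NA, 0.30, 0.20, 0.16, 0.145)
  thetas <- c(0.72, 0.72, 0.74, 0.795, 0.838)
  n_obs <- c(11L, 11L, 19L, 18L, 14L)
  labels <- c("rat-control", "rat-1000", "rat-2000", "rat-3000", "rat-4000")
  lapply(seq_along(doses), function(i) {
    case_config(
      label = labels[i],
      growth = growth_params(v0 = 0.0157, td0 = 1.35, theta = thetas[i]),
      radio = radiobiology_constants(alpha = alphas[i], alpha_beta = 10,
                                     t_star = 1, t_m = 10),
      treatment = treatment_spec(dose = doses[i], t_r = 11, tau_rad = 8,
                                 t_cl = 4),
      meta = list(series = "rat-rhabdomyosarcoma", n_obs = n_obs[i]))
  })
}

#' Clinical Gamma Knife radiosurgery case fixtures
#'
#' Five metastatic brain tumor cases treated with single-fraction Gamma
#' Knife stereotactic radiosurgery, with fitted model parameters and
#' treatment metadata. All cases share alpha/beta 10 Gy, tau_rad 8 d,
#' T* 1 d, T_m 10 d; doses are mean target doses. Each case carries the
#' observed doubling time at radiosurgery as `td_at_treatment` (the override
#' used when reproducing the 40-day response ratios) and its local-control
#' label (CR/PR/PR/SD/PD) as metadata. For cases 3 and 4 the two source
#' tables disagree on the irradiation day; the value printed beside the
#' model parameters (22 and 78 d) is the default and the alternate reading
#' (137 and 8 d) is kept as `t_r_alt_days` metadata.
#'
#' @return List of five [case_config()] objects.
#' @export
clinical_case_configs <- function() {
  alphas <- c(0.09, 0.19, 0.19, 0.10, 0.05)
  td0 <- c(29.0, 6.0, 9.0, 6.6, 7.8)
  t_cl <- c(13.0, 38.0, 40.0, 10.0, 20.0)
  thetas <- c(0.62, 0.77, 0.53, 0.78, 0.99)
  dose <- c(38.3, 21.2, 26.0, 22.0, 24.3)
  v0 <- c(0.126, 0.0065, 0.271, 0.031, 0.101)
  t_r <- c(34, 117, 22, 78, 29)
  t_r_alt <- c(34, 117, 137, 8, 29)
  td_gksrs <- c(32.6, 28.0, 11.2, 16.1, 7.9)
  control <- c("CR", "PR", "PR", "SD", "PD")
  lapply(1:5, function(i) {
    case_config(
      label = sprintf("gksrs-case-%d", i),
      growth = growth_params(v0 = v0[i], td0 = td0[i], theta = thetas[i]),
      radio = radiobiology_constants(alpha = alphas[i], alpha_beta = 10,
                                     t_star = 1, t_m = 10),
      treatment = treatment_spec(dose = dose[i], t_r = t_r[i], tau_rad = 8,
                                 t_cl = t_cl[i]),
      td_at_treatment = td_gksrs[i],
      meta = c(list(series = "gksrs", local_control = control[i]),
               if (t_r_alt[i] != t_r[i]) list(t_r_alt_days = t_r_alt[i])))
  })
}

#' Observation-noise specification for synthetic series
#'
#' Two noise models for emulating measured volume trajectories:
#' `multiplicative_lognormal` scales each true volume by a mean-one
#' lognormal factor with coefficient of variation `cv` (volume errors grow
#' with size, as for both caliper and MRI measurements);
#' `sphere_radius` perturbs the radius of the equivalent sphere by a
#' Uniform(-`dr_mm`, +`dr_mm`) amount and recomputes the volume, emulating
#' the +/- 1 mm delineation-uncertainty construction used for MRI error
#' bars.
#'
#' @param mode `"multiplicative_lognormal"` or `"sphere_radius"`.
#' @param cv Coefficient of variation of the lognormal factor (>= 0).
#' @param dr_mm Radius perturbation half-width in mm (>= 0).
#' @param seed RNG seed (required).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("multiplicative_lognormal", "sphere_radius"),
                       cv = 0, dr_mm = 0, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (dr_mm < 0) stop("dr_mm must be >= 0", call. = FALSE)
  structure(list(mode = mode, cv = as.numeric(cv), dr_mm = as.numeric(dr_mm),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthesize a noisy observation series from a configuration
#'
#' Simulates the total volume at the requested times and perturbs it
#' according to the noise specification. With `cv = 0` (lognormal mode) or
#' `dr_mm = 0` (sphere mode) the exact model values are returned.
#' Deterministic given the seed; the global RNG state is restored on exit.
#'
#' @param config A [case_config()].
#' @param times Observation times, days (strictly increasing).
#' @param noise A [noise_spec()].
#' @return A [volume_series()].
#' @export
synthesize_observations <- function(config, times, noise) {
  stopifnot(inherits(config, "case_config"), inherits(noise, "noise_spec"))
  truth <- simulate_response(config, times)$v_total_cm3

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(noise$seed)

  if (noise$mode == "multiplicative_lognormal") {
    if (noise$cv == 0) return(volume_series(times, truth))
    sdlog <- sqrt(log(1 + noise$cv^2))
    fac <- stats::rlnorm(length(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    volume_series(times, truth * fac, sigma = truth * noise$cv)
  } else {
    if (noise$dr_mm == 0) return(volume_series(times, truth))
    dr_cm <- noise$dr_mm / 10
    r <- (3 * truth / (4 * pi))^(1 / 3)
    r_obs <- pmax(r + stats::runif(length(r), -dr_cm, dr_cm), 1e-6)
    volume_series(times, 4 / 3 * pi * r_obs^3,
                  sigma = 4 / 3 * pi * ((r + dr_cm)^3 - r^3))
  }
}
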