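# numbers that must survive JSON round trips, including Inf
.num_out <- function(x) if (is.finite(x)) x else as.character(x)
.num_in <- function(x) as.numeric(x)

#' Serialize a case configuration to JSON
#'
#' Writes (or returns) the JSON form of a configuration. Keys:
#' `label`, `growth` (`v0_cm3`, `td0_days`, `theta`), `radio` (`alpha`,
#' `alpha_beta`, `t_star`, `t_m`), `treatment` (`dose_gy`, `t_r_days`,
#' `tau_rad_days`, `t_cl_days`), optional `td_at_treatment_days`, and
#' `meta`. Round-trips losslessly through [read_case_config()].
#'
#' @param config A [case_config()].
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or a JSON string.
#' @export
write_case_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "case_config"))
  obj <- list(
    label = config$label,
    growth = list(v0_cm3 = config$growth$v0, td0_days = config$growth$td0,
                  theta = config$growth$theta),
    radio = list(alpha = config$radio$alpha,
                 alpha_beta = config$radio$alpha_beta,
                 t_star = config$radio$t_star, t_m = config$radio$t_m),
    treatment = list(dose_gy = config$treatment$dose,
                     t_r_days = config$treatment$t_r,
                     tau_rad_days = config$treatment$tau_rad,
                     t_cl_days = .num_out(config$treatment$t_cl)))
  if (!is.null(config$td_at_treatment))
    obj$td_at_treatment_days <- config$td_at_treatment
  if (length(config$meta)) obj$meta <- config$meta
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                            pretty = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a case configuration from JSON
#'
#' Inverse of [write_case_config()]; all structural validation happens in
#' the constructors, so a malformed or incomplete file fails loudly.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A [case_config()].
#' @export
read_case_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("label", "growth", "radio", "treatment")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("config is missing required keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  alpha <- obj$radio$alpha
  if (is.null(alpha)) alpha <- NA_real_
  suppressWarnings(case_config(
    label = obj$label,
    growth = growth_params(obj$growth$v0_cm3, obj$growth$td0_days,
                           obj$growth$theta),
    radio = radiobiology_constants(alpha, obj$radio$alpha_beta,
                                   obj$radio$t_star, obj$radio$t_m),
    treatment = treatment_spec(obj$treatment$dose_gy, obj$treatment$t_r_days,
                               obj$treatment$tau_rad_days,
                               .num_in(obj$treatment$t_cl_days)),
    td_at_treatment = obj$td_at_treatment_days,
    meta = if (is.null(obj$meta)) list() else as.list(obj$meta)))
}

#' Write a trajectory to CSV
#'
#' Columns: `t_days`, `v_t_cm3`, `v_nd_cm3`, `lambda_per_day`,
#' `v_total_cm3`. Plain comma-separated values with a header row.
#'
#' @param traj A `trajectory` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read or write an observed volume series as CSV
#'
#' Columns `t_days`, `volume_cm3`, and optionally `sigma_cm3`. Times are
#' days from the first observation (day 0 = first radiology exam).
#'
#' @param path CSV path.
#' @return [read_volume_series()]: a [volume_series()].
#' @export
read_volume_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_days", "volume_cm3")
  if (!all(need %in% names(d)))
    stop("series CSV must have columns t_days, volume_cm3", call. = FALSE)
  volume_series(d$t_days, d$volume_cm3,
                sigma = if ("sigma_cm3" %in% names(d)) d$sigma_cm3)
}

#' @rdname read_volume_series
#' @param series A [volume_series()].
#' @export
write_volume_series <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  d <- data.frame(t_days = series$times, volume_cm3 = series$volumes)
  if (!is.null(series$sigma)) d$sigma_cm3 <- series$sigma
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Records the fitted parameters, residual sum of squares, evaluation count,
#' and the seed and bounds needed to reproduce the run. The accepted-state
#' trace stays in the R object only.
#'
#' @param fit A `fit_result` from [fit_simulated_annealing()].
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or a JSON string.
#' @export
write_fit_result <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(best_params = as.list(fit$best_params), rss = fit$rss,
              n_evals = fit$n_evals, n_accepted = nrow(fit$trace),
              seed = fit$seed, bounds = fit$bounds)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
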