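#' Observed tumor-volume series
#'
#' The fitting target: strictly increasing observation times (days), positive
#' volumes (cm^3), and optional per-point uncertainties (cm^3, metadata only
#' — the least-squares objective is unweighted, matching the estimation
#' procedure the model was built with).
#'
#' @param times Observation times, days.
#' @param volumes Observed volumes, cm^3 (> 0).
#' @param sigma Optional per-point uncertainty, cm^3.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(times, volumes, sigma = NULL) {
  if (length(times) != length(volumes))
    stop("times and volumes must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (!is.null(sigma) && length(sigma) != length(times))
    stop("sigma must match times in length", call. = FALSE)
  structure(list(times = as.numeric(times), volumes = as.numeric(volumes),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %d points over [%g, %g] days\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Default feasible parameter region for fitting
#'
#' The closed intervals used by the annealing benchmark:
#' alpha in (0.01, 0.2) 1/Gy, theta in (0, 1), T_d in (0.5, 15) days,
#' T_cl in (1, 50) days. theta's lower edge is nudged off zero since the
#' model requires theta > 0.
#'
#' @return Named list of `c(lower, upper)` bounds for
#'   `alpha`, `theta`, `td0`, `t_cl`.
#' @export
default_fit_bounds <- function() {
  list(alpha = c(0.01, 0.2), theta = c(1e-6, 1),
       td0 = c(0.5, 15), t_cl = c(1, 50))
}

#' Fitting specification
#'
#' @param bounds Named list of `c(lower, upper)` intervals for the free
#'   parameters (any of `alpha`, `theta`, `td0`, `t_cl`). Defaults to
#'   [default_fit_bounds()].
#' @param steps Number of annealing iterations (>= 1).
#' @param seed RNG seed (required; there is no hidden global randomness).
#' @param fixed Named list of treatment/radiobiology values held constant,
#'   overriding the template config (e.g. `tau_rad`).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(bounds = default_fit_bounds(), steps = 100000, seed,
                     fixed = list()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(bounds) == 0) stop("bounds must be nonempty", call. = FALSE)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  bad <- !names(bounds) %in% c("alpha", "theta", "td0", "t_cl")
  if (any(bad))
    stop("unknown parameters in bounds: ",
         paste(names(bounds)[bad], collapse = ", "), call. = FALSE)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] >= b[2])
      stop("empty feasible region for ", nm, call. = FALSE)
  }
  structure(list(bounds = bounds, steps = as.integer(steps),
                 seed = as.integer(seed), fixed = fixed),
            class = "fit_spec")
}

# merge a named parameter vector into the scalar set .predict_total needs
.fixed_from_config <- function(config, fixed = list()) {
  out <- list(
    dose = config$treatment$dose, t_r = config$treatment$t_r,
    tau_rad = config$treatment$tau_rad,
    alpha_beta = config$radio$alpha_beta, t_star = config$radio$t_star,
    t_m = config$radio$t_m, v0 = config$growth$v0)
  for (nm in names(fixed)) out[[nm]] <- fixed[[nm]]
  out
}

.full_params <- function(params, config) {
  full <- c(alpha = config$radio$alpha, theta = config$growth$theta,
            td0 = config$growth$td0, t_cl = config$treatment$t_cl)
  full[names(params)] <- params
  full
}

#' Residual sum of squares against an observed series
#'
#' The absolute least-squares objective
#' \eqn{\sum_i (y_i - \hat y_i(p))^2} where \eqn{\hat y} is the simulated
#' total volume at the observation times. Note this is deliberately distinct
#' from [msd()], which scores relative residuals.
#'
#' @param params Named numeric vector giving any of `alpha`, `theta`, `td0`,
#'   `t_cl`; unnamed entries fall back to the template configuration.
#' @param series A [volume_series()].
#' @param config_template A [case_config()] supplying everything not in
#'   `params`.
#' @return Residual sum of squares, cm^6.
#' @export
residual_ss <- function(params, series, config_template) {
  stopifnot(inherits(series, "volume_series"),
            inherits(config_template, "case_config"))
  full <- .full_params(params, config_template)
  fixed <- .fixed_from_config(config_template)
  pred <- .predict_total(full[["alpha"]], full[["theta"]], full[["td0"]],
                         full[["t_cl"]], fixed, series$times)
  sum((series$volumes - pred)^2)
}

#' Least-squares parameter estimation by simulated annealing
#'
#' Minimizes [residual_ss()] over the feasible region with simulated
#' annealing: a uniformly drawn initial state, Gaussian proposals with
#' per-parameter scale 5\% of the bound width reflected at the bounds, and
#' geometric cooling from the initial objective value down to 1e-4 of it over
#' the configured number of steps. Deterministic given the seed; the global
#' RNG state is restored on exit. Returns the best state ever visited, never
#' a worse one.
#'
#' @param series A [volume_series()] with at least as many points as free
#'   parameters.
#' @param spec A [fit_spec()].
#' @param config_template A [case_config()] supplying the fixed structure
#'   (dose, schedule, radiobiology constants, v0).
#' @return An object of class `fit_result`: `best_params` (named vector),
#'   `rss`, `trace` (data frame of accepted states), `n_evals`, `seed`,
#'   `bounds`.
#' @export
fit_simulated_annealing <- function(series, spec, config_template) {
  stopifnot(inherits(series, "volume_series"), inherits(spec, "fit_spec"),
            inherits(config_template, "case_config"))
  free <- names(spec$bounds)
  if (length(series$times) < length(free))
    stop("series has fewer points than free parameters", call. = FALSE)

  lo <- vapply(spec$bounds, `[`, numeric(1), 1)
  up <- vapply(spec$bounds, `[`, numeric(1), 2)
  width <- up - lo
  prop_sd <- 0.05 * width

  fixed <- .fixed_from_config(config_template, spec$fixed)
  full0 <- .full_params(numeric(0), config_template)
  obj <- function(x) {
    full <- full0
    full[free] <- x
    pred <- .predict_total(full[["alpha"]], full[["theta"]], full[["td0"]],
                           full[["t_cl"]], fixed, series$times)
    sum((series$volumes - pred)^2)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  reflect <- function(x) {
    # fold back into [lo, up]; loop handles rare multi-width excursions
    for (i in seq_along(x)) {
      while (x[i] < lo[i] || x[i] > up[i]) {
        if (x[i] < lo[i]) x[i] <- 2 * lo[i] - x[i]
        if (x[i] > up[i]) x[i] <- 2 * up[i] - x[i]
      }
    }
    x
  }

  x <- lo + stats::runif(length(free)) * width
  fx <- obj(x)
  best <- x; fbest <- fx
  temp <- max(fx, .Machine$double.eps)
  cool <- (1e-4)^(1 / spec$steps)

  trace_mat <- matrix(NA_real_, spec$steps + 1, length(free) + 2)
  trace_mat[1, ] <- c(0, x, fx)
  n_acc <- 1L

  for (j in seq_len(spec$steps)) {
    cand <- reflect(x + stats::rnorm(length(free), 0, prop_sd))
    fc <- obj(cand)
    if (fc <= fx || stats::runif(1) < exp(-(fc - fx) / temp)) {
      x <- cand; fx <- fc
      n_acc <- n_acc + 1L
      trace_mat[n_acc, ] <- c(j, x, fx)
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    temp <- temp * cool
  }

  trace <- as.data.frame(trace_mat[seq_len(n_acc), , drop = FALSE])
  names(trace) <- c("step", free, "rss")
  names(best) <- free
  structure(list(best_params = best, rss = fbest, trace = trace,
                 n_evals = spec$steps + 1L, seed = spec$seed,
                 bounds = spec$bounds),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  best: ",
      paste(sprintf("%s = %.4g", names(x$best_params), x$best_params),
            collapse = ", "),
      sprintf("\n  rss = %.6g (%d evaluations, seed %d)\n",
              x$rss, x$n_evals, x$seed))
  invisible(x)
}

#' Mean squared relative difference between model and data
#'
#' \eqn{MSD = \frac{1}{N}\sum_n ((\hat y_n - Y_n)/Y_n)^2}: the fit-quality
#' score, a mean of squared relative errors — not the absolute objective the
#' optimizer minimizes.
#'
#' @param observed A [volume_series()] or a positive numeric vector.
#' @param predicted Numeric vector of model volumes, same length.
#' @return Dimensionless MSD >= 0.
#' @export
msd <- function(observed, predicted) {
  y <- if (inherits(observed, "volume_series")) observed$volumes
       else as.numeric(observed)
  if (length(y) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (any(y == 0)) stop("observed volumes must be nonzero", call. = FALSE)
  mean(((predicted - y) / y)^2)
}

#' Akaike information criterion from an MSD score
#'
#' \eqn{AIC = N \ln(MSD) + 2k} with `k` the number of model parameters
#' (5 for the full model: alpha, theta, T_d, T_cl, tau_rad; fewer when some
#' are held fixed — `k` is the caller's choice).
#'
#' @param score_msd MSD value (> 0), see [msd()].
#' @param n Number of observations.
#' @param k Number of model parameters. Default 5.
#' @return AIC value.
#' @export
aic <- function(score_msd, n, k = 5) {
  if (any(score_msd <= 0)) stop("msd must be > 0", call. = FALSE)
  n * log(score_msd) + 2 * k
}

#' Bundle an MSD and its AIC into a model score
#'
#' @inheritParams aic
#' @return An object of class `model_score` with fields `msd`, `aic`, `n`, `k`.
#' @export
model_score <- function(score_msd, n, k = 5) {
  structure(list(msd = score_msd, aic = aic(score_msd, n, k),
                 n = as.integer(n), k = as.integer(k)),
            class = "model_score")
}
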