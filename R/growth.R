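#' Unirradiated growth parameters
#'
#' The three numbers that fix the pre-treatment growth curve: initial volume
#' `v0` (cm^3), initial volume doubling time `td0` (days), and the vascular
#' growth retardation factor `theta` (dimensionless, 0 < theta <= 1). The
#' initial growth rate is \eqn{\lambda(0) = \ln 2 / T_d(0)}. theta is the
#' ratio of the vascular to the tumor specific growth rate; theta < 1 makes
#' the growth rate decay (Gompertzian saturation), theta = 1 gives pure
#' exponential growth.
#'
#' @param v0 Initial tumor volume, cm^3 (> 0).
#' @param td0 Initial volume doubling time, days (> 0).
#' @param theta Vascular growth retardation factor, in (0, 1].
#' @return An object of class `growth_params`.
#' @examples
#' gp <- growth_params(v0 = 0.0157, td0 = 1.35, theta = 0.72)
#' gompertz_volume(11, gp)
#' @export
growth_params <- function(v0, td0, theta) {
  if (v0 <= 0) stop("v0 must be > 0", call. = FALSE)
  if (td0 <= 0) stop("td0 must be > 0", call. = FALSE)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  structure(list(v0 = as.numeric(v0), td0 = as.numeric(td0),
                 theta = as.numeric(theta)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth params: v0 = %g cm^3, Td(0) = %g d, theta = %g\n",
              x$v0, x$td0, x$theta))
  invisible(x)
}

# decay constant of the growth rate: lambda(t) = lambda0 * exp(-k t)
# with k = (1 - theta) * lambda0 (zero for pure exponential growth)
.lambda_decay_const <- function(gp) (1 - gp$theta) * log(2) / gp$td0

#' Tumor growth rate at time t
#'
#' The specific growth rate \eqn{\lambda(t) = \lambda(0)\,e^{-(1-\theta)\lambda(0) t}}
#' with \eqn{\lambda(0) = \ln 2 / T_d(0)}. The decay follows from assuming the
#' growth rate proportional to the vascular-to-tumor volume ratio, with the
#' vasculature growing theta times as fast as the tumor. Constant when
#' theta = 1.
#'
#' @param t Time, days (>= 0). Vectorized.
#' @param gp A [growth_params()] object.
#' @return Growth rate in 1/day.
#' @export
growth_rate_at <- function(t, gp) {
  stopifnot(inherits(gp, "growth_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lam0 <- log(2) / gp$td0
  lam0 * exp(-.lambda_decay_const(gp) * t)
}

#' Gompertz-type tumor volume
#'
#' Closed-form solution of \eqn{dV/dt = \lambda(t) V} with the decaying growth
#' rate of [growth_rate_at()]:
#' \deqn{V(t) = V_0 \exp\left[\frac{1}{1-\theta}\left(1 - e^{-(1-\theta)\lambda(0) t}\right)\right]}
#' for \eqn{\theta < 1}, and \eqn{V_0 e^{\lambda(0) t}} in the continuous
#' limit \eqn{\theta = 1}. Strictly increasing, with asymptote
#' \eqn{V_0 e^{1/(1-\theta)}} as \eqn{t \to \infty}.
#'
#' @inheritParams growth_rate_at
#' @return Volume in cm^3. Vectorized over `t`.
#' @export
gompertz_volume <- function(t, gp) {
  stopifnot(inherits(gp, "growth_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lam0 <- log(2) / gp$td0
  k <- .lambda_decay_const(gp)
  gp$v0 * exp(.int_decaying_rate(lam0, k, t))
}

# integral of lam0 * exp(-k u) du over [0, t]; exact in the k -> 0 limit
.int_decaying_rate <- function(lam, k, t) {
  if (k == 0) lam * t else lam * (1 - exp(-k * t)) / k
}

#' Volume doubling time from a growth rate
#'
#' \eqn{T_d = \ln 2 / \lambda}. The model quotes doubling times rather than
#' rates throughout, so this tiny helper keeps the convention in one place.
#'
#' @param lam Growth rate, 1/day (> 0). Vectorized.
#' @return Doubling time in days.
#' @export
doubling_time <- function(lam) {
  if (any(lam <= 0)) stop("growth rate must be > 0", call. = FALSE)
  log(2) / lam
}
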