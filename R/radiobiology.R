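#' Radiobiological constants for the linear-quadratic formalism
#'
#' Bundles the dose-independent constants that convert a physical dose into
#' the delayed-death quantities of the model: the radiosensitivity
#' \eqn{\alpha} (1/Gy), the LQ ratio \eqn{\alpha/\beta} (Gy), the
#' characteristic (cell-cycle) time \eqn{T^*} (days), and the colony-counting
#' or observation time \eqn{T_m} (days). \eqn{\beta} is never an independent
#' parameter; it is always \eqn{\alpha / (\alpha/\beta)}.
#'
#' @param alpha Radiosensitivity, 1/Gy. Must be >= 0. `NA` is tolerated for
#'   unirradiated (dose 0) configurations where alpha never enters a formula.
#' @param alpha_beta LQ dose ratio, Gy. Default 10.
#' @param t_star Characteristic time \eqn{T^*} (identified with the cell
#'   cycle time), days. Default 1.
#' @param t_m Observation / colony-counting time \eqn{T_m}, days. Default 10.
#' @return An object of class `radiobiology_constants`.
#' @examples
#' rc <- radiobiology_constants(alpha = 0.30)
#' lethality_exponent(10, rc)  # 6
#' @export
radiobiology_constants <- function(alpha, alpha_beta = 10, t_star = 1, t_m = 10) {
  if (!is.na(alpha) && alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (alpha_beta <= 0) stop("alpha_beta must be > 0", call. = FALSE)
  if (t_star <= 0) stop("t_star must be > 0", call. = FALSE)
  if (t_m <= 0) stop("t_m must be > 0", call. = FALSE)
  structure(
    list(alpha = as.numeric(alpha), alpha_beta = as.numeric(alpha_beta),
         t_star = as.numeric(t_star), t_m = as.numeric(t_m)),
    class = "radiobiology_constants"
  )
}

#' @export
print.radiobiology_constants <- function(x, ...) {
  cat(sprintf(
    "Radiobiology constants: alpha = %s /Gy, alpha/beta = %g Gy, T* = %g d, Tm = %g d\n",
    format(x$alpha), x$alpha_beta, x$t_star, x$t_m))
  invisible(x)
}

#' Lethality exponent of the linear-quadratic model
#'
#' \eqn{\chi(D) = \alpha D (1 + D / (\alpha/\beta))}, the negative log of the
#' LQ survival fraction. Zero at zero dose and strictly increasing in dose
#' for \eqn{\alpha > 0}.
#'
#' @param dose Dose in Gy, >= 0. Vectorized.
#' @param consts A [radiobiology_constants()] object.
#' @return \eqn{\chi(D)}, dimensionless.
#' @export
lethality_exponent <- function(dose, consts) {
  stopifnot(inherits(consts, "radiobiology_constants"))
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  # dose 0 never touches alpha, so NA alpha is legal for controls
  out <- numeric(length(dose))
  nz <- dose > 0
  if (any(nz)) {
    if (is.na(consts$alpha))
      stop("alpha is NA but dose > 0", call. = FALSE)
    out[nz] <- consts$alpha * dose[nz] * (1 + dose[nz] / consts$alpha_beta)
  }
  out
}

#' Division probability during the active radiation-effect window
#'
#' Probability that an irradiated cell completes a division per cell cycle,
#' \eqn{p(D) = 1 - (T^*/(3 T_m))\,\chi(D)}, clamped to \[0, 1\]. A warning is
#' emitted when the unclamped value is negative (possible for large
#' \eqn{\alpha D} excursions during optimization).
#'
#' @inheritParams lethality_exponent
#' @return Probability in \[0, 1\]. Vectorized over `dose`.
#' @export
division_probability <- function(dose, consts) {
  chi <- lethality_exponent(dose, consts)
  p <- 1 - consts$t_star / (3 * consts$t_m) * chi
  if (any(p < 0))
    warning("division probability clamped to 0 (chi exceeds 3*Tm/T*)", call. = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Radiation-induced death rate
#'
#' Transition rate from the dividing to the non-dividing compartment,
#' \eqn{g(D) = \chi(D) / (3 T_m)} (1/day). Zero at zero dose, nondecreasing
#' in dose.
#'
#' @inheritParams lethality_exponent
#' @return Rate in 1/day. Vectorized over `dose`.
#' @export
death_rate <- function(dose, consts) {
  lethality_exponent(dose, consts) / (3 * consts$t_m)
}

#' Linear-quadratic survival fraction
#'
#' \eqn{S(D) = e^{-\chi(D)}}, the clonogenic survival fraction of the LQ
#' model. Used by the instantaneous-kill comparator model.
#'
#' @inheritParams lethality_exponent
#' @return Fraction in (0, 1\]. Vectorized over `dose`.
#' @export
lq_survival <- function(dose, consts) {
  exp(-lethality_exponent(dose, consts))
}
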