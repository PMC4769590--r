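# Adaptive embedded Runge-Kutta (Cash-Karp 4(5)) integrator. This is the
# validation route for the closed-form engine; no ODE-solver package is
# available in the target environment, and the piecewise system here is
# smooth and non-stiff within each phase (rates of order 0.01-1 /day), so an
# embedded explicit pair with tight tolerances is entirely adequate.

.ck_a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
.ck_b <- list(
  NULL,
  c(1/5),
  c(3/40, 9/40),
  c(3/10, -9/10, 6/5),
  c(-11/54, 5/2, -70/27, 35/27),
  c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
.ck_c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
.ck_c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)

# integrate y' = f(t, y) from t0, landing exactly on each of out_times
# (sorted, all >= t0); returns a matrix with one row per output time
.rk45_integrate <- function(f, y0, t0, out_times, rtol = 1e-10, atol = 1e-14) {
  y <- y0
  t <- t0
  out <- matrix(NA_real_, length(out_times), length(y0))
  h <- NA_real_
  for (j in seq_along(out_times)) {
    tf <- out_times[j]
    if (tf <= t + 1e-14) { out[j, ] <- y; next }
    if (is.na(h)) h <- (tf - t) / 10
    while (t < tf - 1e-14) {
      h <- min(h, tf - t)
      ks <- vector("list", 6)
      ks[[1]] <- f(t, y)
      for (i in 2:6) {
        yi <- y + h * as.vector(
          Reduce(`+`, Map(`*`, .ck_b[[i]], ks[seq_len(i - 1)])))
        ks[[i]] <- f(t + .ck_a[i] * h, yi)
      }
      y5 <- y + h * as.vector(Reduce(`+`, Map(`*`, .ck_c5, ks)))
      y4 <- y + h * as.vector(Reduce(`+`, Map(`*`, .ck_c4, ks)))
      err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
      if (!is.finite(err)) stop("numeric integration diverged", call. = FALSE)
      if (err <= 1) {
        t <- t + h
        y <- y5
        h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
      } else {
        h <- h * max(0.1, 0.9 * err^(-0.25))
        if (h < 1e-12) stop("numeric integration step underflow", call. = FALSE)
      }
    }
    out[j, ] <- y
  }
  out
}

#' Numerically integrated trajectory (validation path)
#'
#' Integrates the three-phase two-compartment system with an adaptive
#' embedded Runge-Kutta method, restarting cleanly at the phase boundaries
#' \eqn{t_R} and \eqn{t_R + \tau_{rad}} (where the right-hand side switches)
#' and applying the same growth-rate override convention as
#' [simulate_response()]. Exists to cross-check the closed-form engine; the
#' two must agree to a relative error far below any data uncertainty.
#'
#' @inheritParams simulate_response
#' @param rtol,atol Relative and absolute local error tolerances.
#' @return A `trajectory` data frame; see [simulate_response()].
#' @export
integrate_numeric <- function(config, times, rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(config, "case_config"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE))
    stop("times must be sorted", call. = FALSE)
  tr <- config$treatment
  if (tr$dose > 0 && tr$t_r > max(times))
    stop("irradiation day t_r lies outside the requested time grid",
         call. = FALSE)
  gp <- config$growth
  co <- .case_coefs(config)
  k0 <- co$k
  lam0 <- co$lam0

  f_grow <- function(t, y) c(y[3] * y[1], 0, -k0 * y[3])
  f_win  <- function(t, y) c((y[3] * co$p - co$g) * y[1],
                             co$g * y[1] - co$eta * y[2], 0)
  f_post <- function(t, y) c(y[3] * y[1], -co$eta * y[2], -k0 * y[3])

  y0 <- c(gp$v0, 0, lam0)
  n <- length(times)
  res <- matrix(NA_real_, n, 3)

  if (tr$dose == 0) {
    res[] <- .rk45_integrate(f_grow, y0, 0, times, rtol, atol)
    return(.new_trajectory(times, res[, 1], res[, 2], res[, 3]))
  }

  t_b1 <- tr$t_r
  t_b2 <- tr$t_r + tr$tau_rad
  i1 <- times < t_b1
  i2 <- !i1 & times < t_b2
  i3 <- times >= t_b2

  y <- y0
  if (any(i1)) res[i1, ] <- .rk45_integrate(f_grow, y, 0, times[i1], rtol, atol)
  y <- drop(.rk45_integrate(f_grow, y0, 0, t_b1, rtol, atol))
  y[3] <- co$lam_r  # override (or continuous value) at the instant of t_R
  if (any(i2)) res[i2, ] <- .rk45_integrate(f_win, y, t_b1, times[i2], rtol, atol)
  y <- drop(.rk45_integrate(f_win, y, t_b1, t_b2, rtol, atol))
  if (any(i3)) res[i3, ] <- .rk45_integrate(f_post, y, t_b2, times[i3], rtol, atol)
  .new_trajectory(times, res[, 1], res[, 2], res[, 3])
}
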