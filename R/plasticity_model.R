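#' Synaptic-efficacy model parameters
#'
#' Bundles the five coefficients of the modified bistable synaptic-efficacy
#' model for one electrode site. The state variable \eqn{\rho} is the
#' dimensionless synaptic efficacy (the ratio index of the evoked-LFP
#' negative peak); its drift is
#' \deqn{d\rho/dt = \left[-(\rho-\alpha)(2-\rho)(\rho_U-\rho)
#'   - \gamma_d(\rho-\alpha)\right]/\tau .}
#'
#' `alpha` is the lower stable state reached after long-term depression,
#' `rho_U` the cubic-root parameter that (with `gamma_d`) controls whether an
#' upper potentiated state exists, `gamma_d` the depression rate, `tau` the
#' time constant in seconds, and `rho_0` the initial efficacy anchored to the
#' measured ratio index 10 min after tetanic stimulation.
#'
#' The coefficients must satisfy \eqn{0 < \alpha < \rho_U < 2},
#' \eqn{\tau > 0}, \eqn{\gamma_d > 0} and \eqn{\rho_0 > 0}. `rho_0` values
#' below `1e-6` are clipped to that floor: a measured ratio index can fall
#' arbitrarily close to zero while the drift remains well defined there.
#'
#' @param alpha Dimensionless lower stable state, in (0, `rho_U`).
#' @param tau Time constant in seconds, positive.
#' @param gamma_d Dimensionless depression rate, positive.
#' @param rho_U Dimensionless cubic-root parameter, in (`alpha`, 2).
#' @param rho_0 Dimensionless initial efficacy (ratio index at the 10-min
#'   anchor), positive.
#' @return An object of class `efficacy_params` (a named list of the five
#'   coefficients).
#' @examples
#' p <- efficacy_params(alpha = 0.3, tau = 600, gamma_d = 0.1,
#'                      rho_U = 1.0, rho_0 = 0.5)
#' efficacy_drift(0.3, p)  # zero at the lower stable state
#' @export
efficacy_params <- function(alpha, tau, gamma_d, rho_U, rho_0) {
  stopifnot(is.numeric(alpha), is.numeric(tau), is.numeric(gamma_d),
            is.numeric(rho_U), is.numeric(rho_0),
            length(alpha) == 1L, length(tau) == 1L, length(gamma_d) == 1L,
            length(rho_U) == 1L, length(rho_0) == 1L)
  vals <- c(alpha, tau, gamma_d, rho_U, rho_0)
  if (any(!is.finite(vals)))
    stop("efficacy_params: all coefficients must be finite")
  if (!(alpha > 0 && alpha < rho_U && rho_U < 2))
    stop("efficacy_params: need 0 < alpha < rho_U < 2 (got alpha = ",
         alpha, ", rho_U = ", rho_U, ")")
  if (tau <= 0) stop("efficacy_params: tau must be positive")
  if (gamma_d <= 0) stop("efficacy_params: gamma_d must be positive")
  if (rho_0 <= 0) stop("efficacy_params: rho_0 must be positive")
  rho_0 <- max(rho_0, 1e-6)
  structure(list(alpha = alpha, tau = tau, gamma_d = gamma_d,
                 rho_U = rho_U, rho_0 = rho_0),
            class = "efficacy_params")
}

#' @export
print.efficacy_params <- function(x, ...) {
  cat("Synaptic-efficacy model parameters\n")
  cat(sprintf("  alpha = %g, tau = %g s, gamma_d = %g, rho_U = %g, rho_0 = %g\n",
              x$alpha, x$tau, x$gamma_d, x$rho_U, x$rho_0))
  d <- efficacy_discriminant(x)
  cat(sprintf("  discriminant D = %g (%s)\n", d,
              if (d > 0) "bistable" else "monostable"))
  invisible(x)
}

#' Drift of the synaptic-efficacy model
#'
#' Evaluates \eqn{f(\rho) = [-(\rho-\alpha)(2-\rho)(\rho_U-\rho)
#' - \gamma_d(\rho-\alpha)]/\tau}, the right-hand side of the efficacy
#' differential equation, in units of 1/second.
#'
#' @param rho Numeric vector of efficacy values (dimensionless).
#' @param params An [efficacy_params] object.
#' @return Numeric vector of drift rates (1/s), same length as `rho`.
#' @export
efficacy_drift <- function(rho, params) {
  stopifnot(inherits(params, "efficacy_params"))
  if (!is.numeric(rho) || any(!is.finite(rho)))
    stop("efficacy_drift: rho must be finite numeric")
  (-(rho - params$alpha) * (2 - rho) * (params$rho_U - rho) -
     params$gamma_d * (rho - params$alpha)) / params$tau
}

#' Potential landscape of the synaptic-efficacy model
#'
#' The potential \eqn{V(\rho) = -\int_0^\rho f(u)\,du} associated with the
#' drift, evaluated from its closed-form quartic expansion so that
#' \eqn{V(0) = 0} exactly. Stable fixed points of the dynamics sit at local
#' minima of `V` (a single well when monostable, a double well when
#' bistable); the unstable separatrix sits at the barrier maximum.
#'
#' Expanding the drift numerator gives
#' \eqn{-(\rho-\alpha)[(2-\rho)(\rho_U-\rho) + \gamma_d] =
#'   -(\rho^3 - (2+\rho_U+\alpha)\rho^2
#'   + (2\rho_U + \gamma_d + \alpha(2+\rho_U))\rho
#'   - \alpha(2\rho_U+\gamma_d))},
#' whose negative antiderivative divided by \eqn{\tau} is the quartic used
#' here.
#'
#' @inheritParams efficacy_drift
#' @return Numeric vector of potential values (dimensionless), same length
#'   as `rho`.
#' @export
efficacy_potential <- function(rho, params) {
  stopifnot(inherits(params, "efficacy_params"))
  if (!is.numeric(rho) || any(!is.finite(rho)))
    stop("efficacy_potential: rho must be finite numeric")
  a <- params$alpha; rU <- params$rho_U; gd <- params$gamma_d
  (rho^4 / 4 -
     (2 + rU + a) * rho^3 / 3 +
     (2 * rU + gd + a * (2 + rU)) * rho^2 / 2 -
     a * (2 * rU + gd) * rho) / params$tau
}

#' Discriminant of the efficacy fixed-point equation
#'
#' The non-trivial fixed points of the drift solve the quadratic
#' \eqn{\rho^2 - (2+\rho_U)\rho + 2\rho_U + \gamma_d = 0}, whose
#' discriminant is \eqn{D = (2-\rho_U)^2 - 4\gamma_d}. `D > 0` yields two
#' additional fixed points (bistable dynamics, a double-well potential);
#' `D <= 0` leaves the single stable state at `alpha` (monostable).
#'
#' @param params An [efficacy_params] object.
#' @return The discriminant `D` (dimensionless scalar).
#' @export
efficacy_discriminant <- function(params) {
  stopifnot(inherits(params, "efficacy_params"))
  (2 - params$rho_U)^2 - 4 * params$gamma_d
}

#' Fixed points and stability class of the efficacy dynamics
#'
#' Returns the always-present stable point at `alpha` together with, when
#' the discriminant is positive, the upper stable point
#' \eqn{\rho_+ = [(2+\rho_U) + \sqrt{D}]/2} and the unstable separatrix
#' \eqn{\rho_- = [(2+\rho_U) - \sqrt{D}]/2} between the depression and
#' potentiation basins. `D <= 0` is classified monostable.
#'
#' @param params An [efficacy_params] object.
#' @return An object of class `fixed_point_set`: a list with elements
#'   `discriminant`, `stability_class` (`"monostable"` or `"bistable"`),
#'   `rho_alpha`, and `rho_minus` / `rho_plus` (`NA` when monostable).
#' @examples
#' fp <- fixed_points(efficacy_params(0.3, 600, 0.1, 1.0, 0.5))
#' fp$stability_class  # "bistable"
#' @export
fixed_points <- function(params) {
  stopifnot(inherits(params, "efficacy_params"))
  d <- efficacy_discriminant(params)
  if (d > 0) {
    s <- sqrt(d)
    rm <- ((2 + params$rho_U) - s) / 2
    rp <- ((2 + params$rho_U) + s) / 2
    cls <- "bistable"
  } else {
    rm <- NA_real_
    rp <- NA_real_
    cls <- "monostable"
  }
  structure(list(discriminant = d, stability_class = cls,
                 rho_alpha = params$alpha, rho_minus = rm, rho_plus = rp),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("Fixed points (%s, D = %g)\n", x$stability_class,
              x$discriminant))
  cat(sprintf("  stable rho = alpha = %g\n", x$rho_alpha))
  if (x$stability_class == "bistable")
    cat(sprintf("  unstable rho- = %g, stable rho+ = %g\n",
                x$rho_minus, x$rho_plus))
  invisible(x)
}

#' Integrate the synaptic-efficacy differential equation
#'
#' Solves \eqn{d\rho/dt} = [efficacy_drift] from the initial condition
#' `rho_0` at the first requested time point. By convention the trajectory
#' is anchored at t = 600 s, the 10-min post-tetanus ratio-index sample that
#' fixes `rho_0`. The deterministic equation is integrated with an adaptive,
#' stiffness-switching solver (relative tolerance `1e-8`, absolute
#' `1e-10`); small time constants on the fitting grid make the equation
#' stiff, which rules out a fixed explicit scheme here.
#'
#' @param params An [efficacy_params] object.
#' @param times Strictly increasing numeric vector of times in seconds;
#'   the solution carries `rho = rho_0` at `times[1]`. Defaults to the
#'   10--60 min post-tetanus window sampled every 10 s.
#' @return An object of class `efficacy_trajectory`: list with `times`
#'   (seconds) and `rho` (dimensionless), both of length `length(times)`.
#' @export
simulate_efficacy <- function(params, times = seq(600, 3600, by = 10)) {
  stopifnot(inherits(params, "efficacy_params"))
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("simulate_efficacy: times must be finite numeric")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("simulate_efficacy: times must be strictly increasing")
  rho <- if (length(times) == 1L) {
    params$rho_0
  } else {
    rhs <- function(t, y, p)
      list((-(y - p$alpha) * (2 - y) * (p$rho_U - y) -
              p$gamma_d * (y - p$alpha)) / p$tau)
    sol <- deSolve::lsoda(c(rho = params$rho_0), times, rhs, params,
                          rtol = 1e-8, atol = 1e-10)
    if (nrow(sol) != length(times) || any(!is.finite(sol[, 2L])))
      stop("simulate_efficacy: integration failed (non-finite solution); ",
           "params: alpha=", params$alpha, " tau=", params$tau,
           " gamma_d=", params$gamma_d, " rho_U=", params$rho_U)
    as.numeric(sol[, 2L])
  }
  structure(list(times = as.numeric(times), rho = rho),
            class = "efficacy_trajectory")
}

#' @export
print.efficacy_trajectory <- function(x, ...) {
  cat(sprintf("Efficacy trajectory: %d points, t in [%g, %g] s, rho in [%g, %g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$rho), max(x$rho)))
  invisible(x)
}

#' @param x An `efficacy_trajectory` object.
#' @param ... Passed to [plot.default()].
#' @rdname simulate_efficacy
#' @export
plot.efficacy_trajectory <- function(x, ...) {
  graphics::plot(x$times / 60, x$rho, type = "l",
                 xlab = "time after TS (min)", ylab = expression(rho), ...)
  invisible(x)
}
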