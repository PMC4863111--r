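#' Tissue diffusion parameters
#'
#' Governs glucose diffusion within the interstitial space, modeled as a
#' semi-infinite one-dimensional medium with the capillary wall at x = 0.
#' The distance `x` is interpreted as the effective center-of-capillary to
#' evaluation-point distance; capillary radius and wall thickness are
#' absorbed into it, since a single effective distance is what gets fitted.
#'
#' The default D = 600 um^2/min is a package choice of order-of-magnitude
#' literature value for glucose in tissue, not a measured constant.
#'
#' @param D Diffusion coefficient (um^2/min), > 0.
#' @param x Diffusion distance (um), >= 0.
#' @param C_isf0 Initial, spatially uniform ISF concentration (mg/dL), >= 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(D = 600, x = 24, C_isf0 = 100) {
  if (!is.finite(D) || D <= 0) stop("tissue_params: D must be > 0", call. = FALSE)
  if (!is.finite(x) || x < 0) stop("tissue_params: x must be >= 0", call. = FALSE)
  if (!is.finite(C_isf0) || C_isf0 < 0) {
    stop("tissue_params: C_isf0 must be >= 0", call. = FALSE)
  }
  structure(list(D = D, x = x, C_isf0 = C_isf0), class = "tissue_params")
}

#' Error function
#'
#' `erf(z) = (2/sqrt(pi)) * integral_0^z exp(-u^2) du`, evaluated through the
#' normal CDF (`2*pnorm(z*sqrt(2)) - 1`). Odd, bounded by (-1, 1).
#'
#' @param z Numeric vector.
#' @return erf(z).
#' @examples
#' erf_value(1) # 0.8427
#' @export
erf_value <- function(z) {
  if (anyNA(z) || any(!is.finite(z))) stop("erf_value: z must be finite", call. = FALSE)
  2 * stats::pnorm(z * sqrt(2)) - 1
}

#' Step response of semi-infinite diffusion
#'
#' Concentration at depth x and time t when the boundary is held at a
#' constant value `C_b` from t = 0 and the medium starts uniformly at
#' `C_isf0`:
#'
#'   `C(x, t) = C_b - (C_b - C_isf0) * erf(x / (2 * sqrt(D * t)))`
#'
#' At t = 0 (and x > 0) the initial condition `C_isf0` is returned; at x = 0
#' the boundary value is returned for all t > 0.
#'
#' @param boundary_value Constant boundary concentration `C_b` (mg/dL).
#' @param tissue A [tissue_params()].
#' @param t Time(s) since the boundary step (min), >= 0.
#' @return Concentration(s) at depth `tissue$x`.
#' @export
erf_step_response <- function(boundary_value, tissue, t) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (any(!is.finite(t))) stop("erf_step_response: t must be finite", call. = FALSE)
  if (any(t < 0)) stop("erf_step_response: t must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  zero_t <- t == 0
  if (tissue$x == 0) {
    out[] <- boundary_value
    out[zero_t] <- boundary_value # boundary owns x = 0 even at t = 0
    return(out)
  }
  out[zero_t] <- tissue$C_isf0
  tt <- t[!zero_t]
  arg <- tissue$x / (2 * sqrt(tissue$D * tt))
  out[!zero_t] <- boundary_value - (boundary_value - tissue$C_isf0) * erf_value(arg)
  out
}

# Unit step response fraction f(tau) = 1 - erf(x/(2*sqrt(D*tau))), with
# f(tau <= 0) = 0; the fraction of a boundary jump felt at depth x after tau.
step_fraction <- function(tau, D, x) {
  f <- numeric(length(tau))
  pos <- tau > 0
  if (x == 0) {
    f[pos] <- 1
    return(f)
  }
  f[pos] <- 1 - erf_value(x / (2 * sqrt(D * tau[pos])))
  f
}

#' Tissue response to a time-varying boundary concentration
#'
#' Evaluates the concentration at depth `tissue$x` driven by a time-varying
#' boundary series `C(0, t)`.
#'
#' * `"superposition"` (default): Duhamel's principle -- the boundary is
#'   discretized into increments on a fine internal grid and the responses of
#'   the individual steps are superposed. Exact for a truly step-wise
#'   boundary and convergent for continuous ones; this is the physically
#'   correct solution for a time-varying boundary.
#' * `"quasi_static"`: the constant-source formula is evaluated at each
#'   output time using the instantaneous boundary value and elapsed time.
#'   Cheaper, and what a direct per-time-point use of the constant-source
#'   solution amounts to.
#'
#' Both modes coincide exactly when the boundary is constant.
#'
#' @param boundary A [glucose_series()] giving the boundary concentration;
#'   linearly interpolated onto the internal grid.
#' @param tissue A [tissue_params()].
#' @param mode `"superposition"` or `"quasi_static"`.
#' @param dt Internal time step (min), default 0.1.
#' @param out_times Times at which to report; defaults to the boundary times.
#' @return A [glucose_series()] labeled `"isf"`.
#' @export
erf_series_response <- function(boundary, tissue,
                                mode = c("superposition", "quasi_static"),
                                dt = 0.1, out_times = NULL) {
  stopifnot(inherits(boundary, "glucose_series"), inherits(tissue, "tissue_params"))
  mode <- match.arg(mode)
  if (is.null(out_times)) out_times <- boundary$times
  t0 <- boundary$times[1L]
  t1 <- max(boundary$times[length(boundary$times)], max(out_times))
  tg <- internal_grid(t0, t1, dt)
  b <- series_at(boundary, tg)
  isf <- diffuse_profile(b, tg - t0, tissue, mode)
  glucose_series(out_times,
                 stats::approx(tg, isf, xout = out_times, rule = 2)$y,
                 label = "isf")
}

internal_grid <- function(t0, t1, dt) {
  stopifnot(dt > 0)
  tg <- seq(t0, t1, by = dt)
  if (tg[length(tg)] < t1) tg <- c(tg, t1)
  tg
}

# Core propagator: boundary values b on elapsed-time grid tau (tau[1] == 0),
# returns ISF concentration at depth tissue$x on the same grid.
diffuse_profile <- function(b, tau, tissue, mode) {
  n <- length(tau)
  C0 <- tissue$C_isf0
  if (tissue$x == 0) return(b)
  if (mode == "quasi_static") {
    isf <- b - (b - C0) * (1 - step_fraction(tau, tissue$D, tissue$x))
    isf[tau == 0] <- C0
    return(isf)
  }
  # Duhamel: jump b[1]-C0 at tau 0, then increments applied at midpoints
  jump_times <- c(tau[1L], (tau[-n] + tau[-1L]) / 2)
  dB <- c(b[1L] - C0, diff(b))
  isf <- numeric(n)
  isf[1L] <- C0
  for (i in 2:n) {
    f <- step_fraction(tau[i] - jump_times[1:i], tissue$D, tissue$x)
    isf[i] <- C0 + sum(dB[1:i] * f)
  }
  isf
}

#' Finite-difference oracle for tissue diffusion
#'
#' Independent validator for [erf_series_response()]: solves
#' `dC/dt = D * d2C/dx2` on `[0, L]` with a Crank-Nicolson scheme
#' (Rannacher-smoothed: the first steps are backward Euler to damp the
#' start-up discontinuity), Dirichlet boundary `C(0,t) = boundary(t)`,
#' far-field `C(L,t) = C_isf0`, initial condition `C_isf0`. The spatial grid
#' is built so that the evaluation depth `tissue$x` falls exactly on a node.
#'
#' @param boundary A [glucose_series()] for the x = 0 boundary.
#' @param tissue A [tissue_params()] with `x > 0`.
#' @param grid List of `dx` (um), `dt` (min) and `L_factor` (domain length as
#'   a multiple of `x`, >= 10). `dx` defaults to `x/24`.
#' @return A [glucose_series()] at the boundary's times, labeled `"isf"`.
#' @export
fd_oracle <- function(boundary, tissue, grid = list()) {
  stopifnot(inherits(boundary, "glucose_series"), inherits(tissue, "tissue_params"))
  if (tissue$x <= 0) stop("fd_oracle: requires x > 0", call. = FALSE)
  g <- utils::modifyList(list(dx = tissue$x / 24, dt = 0.05, L_factor = 10), grid)
  if (g$L_factor < 10) stop("fd_oracle: L_factor must be >= 10", call. = FALSE)
  # force a node exactly at x
  m <- max(1L, as.integer(round(tissue$x / g$dx)))
  dx <- tissue$x / m
  # domain must dwarf both the evaluation depth and the diffusion length over
  # the simulated span, or the far-field Dirichlet value contaminates C(x, t)
  span <- diff(range(boundary$times))
  L <- max(g$L_factor * tissue$x, 6 * sqrt(tissue$D * max(span, 1)))
  nx <- as.integer(ceiling(L / dx))
  xs <- seq(0, nx * dx, by = dx)
  t0 <- boundary$times[1L]
  t1 <- boundary$times[length(boundary$times)]
  tg <- internal_grid(t0, t1, g$dt)
  bvals <- series_at(boundary, tg)
  r <- tissue$D * g$dt / dx^2

  u <- rep(tissue$C_isf0, nx + 1L)
  u[1L] <- bvals[1L]
  keep <- numeric(length(tg))
  keep[1L] <- u[m + 1L]
  n_int <- nx - 1L
  n_rannacher <- 8L
  # precompute Thomas forward-elimination coefficients for both schemes
  coefs <- lapply(c(1, 0.5), function(theta) {
    a <- -theta * r; bb <- 1 + 2 * theta * r
    cp <- numeric(n_int)
    cp[1L] <- a / bb
    for (i in 2:n_int) cp[i] <- a / (bb - a * cp[i - 1L])
    list(theta = theta, a = a, b = bb, cp = cp)
  })
  for (nstep in 2:length(tg)) {
    dt_i <- tg[nstep] - tg[nstep - 1L]
    sc <- dt_i / g$dt # internal_grid may append a short final step
    co <- coefs[[if (nstep - 1L <= n_rannacher) 1L else 2L]]
    theta <- co$theta
    ri <- r * sc
    a <- -theta * ri; bb <- 1 + 2 * theta * ri
    # rhs from explicit part
    interior <- 2:nx
    lap <- u[interior - 1L] - 2 * u[interior] + u[interior + 1L]
    d <- u[interior] + (1 - theta) * ri * lap
    # fold Dirichlet values at the new time level into the rhs
    d[1L] <- d[1L] + theta * ri * bvals[nstep]
    d[n_int] <- d[n_int] + theta * ri * tissue$C_isf0
    if (abs(sc - 1) < 1e-12) {
      cp <- co$cp
    } else {
      cp <- numeric(n_int)
      cp[1L] <- a / bb
      for (i in 2:n_int) cp[i] <- a / (bb - a * cp[i - 1L])
    }
    dp <- numeric(n_int)
    dp[1L] <- d[1L] / bb
    for (i in 2:n_int) dp[i] <- (d[i] - a * dp[i - 1L]) / (bb - a * cp[i - 1L])
    unew <- numeric(n_int)
    unew[n_int] <- dp[n_int]
    for (i in (n_int - 1L):1L) unew[i] <- dp[i] - cp[i] * unew[i + 1L]
    u[interior] <- unew
    u[1L] <- bvals[nstep]
    u[nx + 1L] <- tissue$C_isf0
    keep[nstep] <- u[m + 1L]
  }
  vals <- stats::approx(tg, keep, xout = boundary$times, rule = 2)$y
  glucose_series(boundary$times, pmax(vals, 0), label = "isf")
}
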