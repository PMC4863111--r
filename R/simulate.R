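#' Route weights for the two transcapillary transport mechanisms
#'
#' The wall-side boundary concentration is a convex combination of the Fick
#' (concentration-gradient) and Starling (pressure-gradient) routes; the
#' weights are nonnegative and sum to one. The default 0.5/0.5 reflects that
#' only the sum constraint is physically fixed.
#'
#' @param R_fick Weight of the Fick route, >= 0.
#' @param R_starling Weight of the Starling route, >= 0.
#' @return An object of class `model_weights`.
#' @export
model_weights <- function(R_fick = 0.5, R_starling = 1 - R_fick) {
  if (!is.finite(R_fick) || !is.finite(R_starling) ||
      R_fick < 0 || R_starling < 0) {
    stop("model_weights: weights must be finite and >= 0", call. = FALSE)
  }
  if (abs(R_fick + R_starling - 1) > 1e-12) {
    stop("model_weights: R_fick + R_starling must equal 1", call. = FALSE)
  }
  structure(list(R_fick = R_fick, R_starling = R_starling),
            class = "model_weights")
}

#' Full model configuration
#'
#' Aggregates all parameters of the blood-to-ISF predictor.
#'
#' @param capillary A [capillary_params()].
#' @param starling A [starling_params()].
#' @param tissue A [tissue_params()].
#' @param weights A [model_weights()].
#' @param mode Diffusion mode, `"superposition"` (default, Duhamel) or
#'   `"quasi_static"`.
#' @param dt Internal time step (min), > 0; the blood input is linearly
#'   interpolated onto this grid.
#' @return An object of class `model_config`.
#' @export
model_config <- function(capillary = capillary_params(),
                         starling = starling_params(),
                         tissue = tissue_params(),
                         weights = model_weights(),
                         mode = c("superposition", "quasi_static"),
                         dt = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(capillary, "capillary_params"),
            inherits(starling, "starling_params"),
            inherits(tissue, "tissue_params"),
            inherits(weights, "model_weights"))
  if (!is.finite(dt) || dt <= 0) {
    stop("model_config: dt must be > 0", call. = FALSE)
  }
  structure(list(capillary = capillary, starling = starling, tissue = tissue,
                 weights = weights, mode = mode, dt = dt),
            class = "model_config")
}

#' Wall-side boundary concentration from both transport routes
#'
#' Combines the Fick and Starling wall concentrations pointwise:
#'
#'   `C_wall(t) = R_fick * C_fick(t) + R_starling * C_starling(t)`
#'
#' The previous ISF concentration enters both routes: the Starling mixing by
#' construction, and the Fick route through its back-concentration argument
#' (see [fick_isf_concentration()]), so the combined stage is a convex
#' combination of blood and previous ISF, and equilibrium is preserved.
#'
#' @param blood A [glucose_series()] of blood concentrations.
#' @param isf_prev A [glucose_series()] of ISF concentrations on the same
#'   time grid (typically the previous iterate).
#' @param config A [model_config()].
#' @return A [glucose_series()] labeled `"boundary"`.
#' @export
boundary_concentration <- function(blood, isf_prev, config) {
  stopifnot(inherits(blood, "glucose_series"),
            inherits(isf_prev, "glucose_series"),
            inherits(config, "model_config"))
  if (length(blood) != length(isf_prev) ||
      max(abs(blood$times - isf_prev$times)) > 1e-8) {
    stop("boundary_concentration: blood and isf_prev must share a time grid",
         call. = FALSE)
  }
  fl <- starling_fluxes(config$starling)
  vals <- boundary_value(blood$values, isf_prev$values, config, fl)
  glucose_series(blood$times, vals, label = "boundary")
}

# vectorized core used by both boundary_concentration() and simulate_isf()
boundary_value <- function(c_blood, c_isf_prev, config, fluxes) {
  c_fick <- fick_isf_concentration(c_blood, config$capillary, c_isf = c_isf_prev)
  c_star <- starling_mix(c_blood, c_isf_prev, fluxes)
  config$weights$R_fick * c_fick + config$weights$R_starling * c_star
}

#' Simulate the ISF glucose time course from a blood glucose input
#'
#' The end-to-end predictor. The blood series is linearly interpolated onto
#' the internal grid (`config$dt`); at each step the wall boundary
#' concentration is computed from the current blood value and the previous
#' step's simulated ISF value (initialized at `C_isf0`), and the tissue
#' concentration at depth `x` is advanced through the chosen diffusion mode.
#' The result is sampled back at the blood series' times.
#'
#' Every stage is a convex combination, so the output never leaves the
#' interval spanned by the blood values and `C_isf0`, and a series in
#' equilibrium with the tissue (`blood == C_isf0` everywhere) is a fixed
#' point.
#'
#' @param blood A [glucose_series()] of blood concentrations.
#' @param config A [model_config()].
#' @param out_times Optional times (min) at which to report; defaults to the
#'   blood series' times.
#' @return A [glucose_series()] labeled `"isf"`.
#' @export
simulate_isf <- function(blood, config, out_times = NULL) {
  stopifnot(inherits(blood, "glucose_series"), inherits(config, "model_config"))
  if (is.null(out_times)) out_times <- blood$times
  tis <- config$tissue
  fl <- starling_fluxes(config$starling)
  t0 <- blood$times[1L]
  t1 <- max(blood$times[length(blood$times)], max(out_times))
  tg <- internal_grid(t0, t1, config$dt)
  bg <- series_at(blood, tg)
  tau <- tg - t0
  n <- length(tg)
  C0 <- tis$C_isf0
  isf <- numeric(n)
  B <- numeric(n)
  B[1L] <- boundary_value(bg[1L], C0, config, fl)
  isf[1L] <- if (tis$x == 0) B[1L] else C0
  if (config$mode == "quasi_static") {
    for (i in 2:n) {
      B[i] <- boundary_value(bg[i], isf[i - 1L], config, fl)
      f <- step_fraction(tau[i], tis$D, tis$x)
      isf[i] <- C0 + (B[i] - C0) * f
    }
  } else {
    # Duhamel superposition over boundary increments; increment j is applied
    # at the midpoint of step j for near-second-order accuracy
    jump_times <- numeric(n)
    dB <- numeric(n)
    jump_times[1L] <- tau[1L]
    dB[1L] <- B[1L] - C0
    for (i in 2:n) {
      B[i] <- boundary_value(bg[i], isf[i - 1L], config, fl)
      jump_times[i] <- (tau[i - 1L] + tau[i]) / 2
      dB[i] <- B[i] - B[i - 1L]
      f <- step_fraction(tau[i] - jump_times[1:i], tis$D, tis$x)
      isf[i] <- C0 + sum(dB[1:i] * f)
    }
  }
  vals <- stats::approx(tg, isf, xout = out_times, rule = 2)$y
  glucose_series(out_times, pmax(vals, 0), label = "isf")
}
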