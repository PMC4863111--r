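#' Relative prediction errors
#'
#' Pointwise `e_i = |measured_i - predicted_i| / measured_i`; returns the
#' maximum and the mean, the two summary statistics used to score model fits.
#' Scale-invariant: multiplying both series by the same positive constant
#' leaves the errors unchanged.
#'
#' @param measured A [glucose_series()] with strictly positive values.
#' @param predicted A [glucose_series()] on the same time grid.
#' @return Named list with `max`, `mean` and the pointwise vector `errors`.
#' @examples
#' m <- glucose_series(c(0, 10), c(100, 200))
#' p <- glucose_series(c(0, 10), c(110, 190))
#' relative_errors(m, p) # max 0.10, mean 0.075
#' @export
relative_errors <- function(measured, predicted) {
  stopifnot(inherits(measured, "glucose_series"),
            inherits(predicted, "glucose_series"))
  if (length(measured) != length(predicted) ||
      max(abs(measured$times - predicted$times)) > 1e-8) {
    stop("relative_errors: series must share a time grid", call. = FALSE)
  }
  if (any(measured$values <= 0)) {
    stop("relative_errors: measured values must be > 0", call. = FALSE)
  }
  e <- abs(measured$values - predicted$values) / measured$values
  list(max = max(e), mean = mean(e), errors = e)
}

#' Estimate the ISF lag time
#'
#' Operationalizes the delay of ISF glucose behind blood glucose in one of
#' two ways:
#'
#' * `"shift"` (default): the nonnegative time shift `tau` minimizing the
#'   mean squared difference between `blood(t)` and `isf(t + tau)` over their
#'   overlap, searched on a 0.1-min grid with linear interpolation. Ties go
#'   to the smallest `tau`.
#' * `"peak"`: the difference between the times of the two series' maxima,
#'   floored at 0.
#'
#' The two definitions answer different questions (whole-curve alignment vs.
#' peak delay) and generally differ on asymmetric transients.
#'
#' @param blood A [glucose_series()].
#' @param isf A [glucose_series()].
#' @param method `"shift"` or `"peak"`.
#' @param tau_max Largest shift considered (min); default
#'   `min(30, 0.45 * overlap span)`.
#' @param resolution Shift grid step (min), default 0.1.
#' @return Estimated lag in minutes (scalar, >= 0).
#' @export
estimate_lag <- function(blood, isf, method = c("shift", "peak"),
                         tau_max = NULL, resolution = 0.1) {
  stopifnot(inherits(blood, "glucose_series"), inherits(isf, "glucose_series"))
  method <- match.arg(method)
  if (stats::sd(blood$values) == 0 || stats::sd(isf$values) == 0) {
    stop("estimate_lag: constant series carries no feature to align",
         call. = FALSE)
  }
  if (method == "peak") {
    t_b <- blood$times[which.max(blood$values)]
    t_i <- isf$times[which.max(isf$values)]
    return(max(t_i - t_b, 0))
  }
  b0 <- blood$times[1L]; b1 <- blood$times[length(blood$times)]
  i0 <- isf$times[1L]; i1 <- isf$times[length(isf$times)]
  span <- min(b1, i1) - max(b0, i0)
  if (span <= 0) stop("estimate_lag: series do not overlap", call. = FALSE)
  if (is.null(tau_max)) tau_max <- min(30, 0.45 * span)
  taus <- seq(0, tau_max, by = resolution)
  score <- vapply(taus, function(tau) {
    lo <- max(b0, i0 - tau); hi <- min(b1, i1 - tau)
    if (hi - lo < resolution) return(Inf)
    tt <- seq(lo, hi, by = resolution)
    mean((series_at(blood, tt) - series_at(isf, tt + tau))^2)
  }, numeric(1))
  taus[which.min(score)]
}

#' Fit the effective diffusion distance by grid search
#'
#' For each candidate distance the full predictor [simulate_isf()] is run on
#' the blood input and scored against the measured ISF series; the candidate
#' minimizing the objective (mean relative error by default) wins. The lag of
#' the winning simulation relative to blood is reported alongside the
#' per-candidate error table. Optionally the winner is refined continuously
#' by golden-section search between the neighboring grid points.
#'
#' The default candidate grid is `c(18, 24, 30)` um.
#'
#' @param blood A [glucose_series()] of blood concentrations (model input).
#' @param isf_measured A [glucose_series()] of measured ISF concentrations.
#' @param config A [model_config()]; its `tissue$x` is overridden per
#'   candidate.
#' @param grid Candidate diffusion distances (um), nonempty.
#' @param objective `"mean_relative"` (default) or `"rmse"`.
#' @param lag_method Passed to [estimate_lag()] for the winning candidate.
#' @param refine Golden-section refinement of x beyond the grid.
#' @return An object of class `fit_result`: `x_star`, `grid`, `lag_min`,
#'   `max_relative_error`, `mean_relative_error`, `objective`, and `table`
#'   (one row per candidate).
#' @export
fit_diffusion_distance <- function(blood, isf_measured, config,
                                   grid = c(18, 24, 30),
                                   objective = c("mean_relative", "rmse"),
                                   lag_method = "shift",
                                   refine = FALSE) {
  stopifnot(inherits(blood, "glucose_series"),
            inherits(isf_measured, "glucose_series"),
            inherits(config, "model_config"))
  objective <- match.arg(objective)
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid < 0)) {
    stop("fit_diffusion_distance: grid must be nonempty, finite, >= 0",
         call. = FALSE)
  }
  grid <- sort(unique(grid))
  score_x <- function(x) {
    cfg <- config
    cfg$tissue$x <- x
    sim <- simulate_isf(blood, cfg, out_times = isf_measured$times)
    re <- relative_errors(isf_measured, sim)
    rmse <- sqrt(mean((isf_measured$values - sim$values)^2))
    list(sim = sim, max_rel = re$max, mean_rel = re$mean, rmse = rmse,
         obj = if (objective == "mean_relative") re$mean else rmse)
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rows[[i]] <- tryCatch(score_x(grid[i]), error = function(e) {
      warning(sprintf("fit_diffusion_distance: candidate x = %g failed (%s); skipped",
                      grid[i], conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("fit_diffusion_distance: all candidates failed", call. = FALSE)
  tab <- data.frame(
    x = grid[ok],
    max_relative_error = vapply(rows[ok], `[[`, numeric(1), "max_rel"),
    mean_relative_error = vapply(rows[ok], `[[`, numeric(1), "mean_rel"),
    rmse = vapply(rows[ok], `[[`, numeric(1), "rmse"),
    objective_value = vapply(rows[ok], `[[`, numeric(1), "obj")
  )
  best_i <- which.min(tab$objective_value)
  x_star <- tab$x[best_i]
  best <- rows[ok][[best_i]]
  if (refine && length(tab$x) >= 2L) {
    lo <- if (best_i > 1L) tab$x[best_i - 1L] else tab$x[best_i]
    hi <- if (best_i < nrow(tab)) tab$x[best_i + 1L] else tab$x[best_i]
    if (hi > lo) {
      opt <- stats::optimize(function(x) score_x(x)$obj, c(lo, hi), tol = 0.05)
      if (opt$objective < best$obj) {
        x_star <- opt$minimum
        best <- score_x(x_star)
      }
    }
  }
  lag <- tryCatch(estimate_lag(blood, best$sim, method = lag_method),
                  error = function(e) NA_real_)
  structure(list(
    x_star = x_star,
    grid = grid,
    lag_min = lag,
    max_relative_error = best$max_rel,
    mean_relative_error = best$mean_rel,
    objective = objective,
    table = tab
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> x* = %g um, lag = %.1f min, mean rel. error = %.3f (max %.3f)\n",
              x$x_star, x$lag_min, x$mean_relative_error, x$max_relative_error))
  cat("candidates:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
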