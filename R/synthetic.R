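#' Calibrate the diffusion coefficient to a target step half-rise time
#'
#' After a boundary step, the concentration at depth x reaches half of its
#' final change when `erf(x / (2*sqrt(D*t))) = 1/2`, i.e. at
#' `t_half = x^2 / (4 * D * eta^2)` with `erf(eta) = 1/2`
#' (eta = 0.47694). Inverting gives the D that realizes a target half-rise
#' time at a given depth; used to build scenario worlds whose diffusion time
#' scale matches a reported ISF lag.
#'
#' @param t_half Target half-rise time (min), > 0.
#' @param x Depth (um), > 0.
#' @return Diffusion coefficient (um^2/min).
#' @examples
#' calibrate_D(2.4, 24) # about 264
#' @export
calibrate_D <- function(t_half, x = 24) {
  if (!is.finite(t_half) || t_half <= 0) {
    stop("calibrate_D: t_half must be > 0", call. = FALSE)
  }
  if (!is.finite(x) || x <= 0) stop("calibrate_D: x must be > 0", call. = FALSE)
  eta <- stats::uniroot(function(z) erf_value(z) - 0.5, c(0.3, 0.7),
                        tol = 1e-12)$root
  x^2 / (4 * t_half * eta^2)
}

#' Glucose tolerance test (GTT) blood profile parameters
#'
#' Parametric shape of the blood glucose excursion after a glucose bolus:
#' baseline before injection, a smooth monotone rise to the peak, then an
#' exponential-like relaxation to a stationary concentration, reached (to
#' within about 1% of the stationary value) at `t_stationary`. Default
#' timing follows the intravenous GTT pattern: peak at 20 min, stationary
#' phase by 80 min. Concentration defaults (baseline 100, peak 350,
#' stationary 150 mg/dL) are package choices typical of rodent GTTs.
#'
#' @param baseline Pre-injection concentration (mg/dL).
#' @param t_injection Injection time (min), default 0.
#' @param t_peak Time of the peak (min), > `t_injection`.
#' @param peak Peak concentration (mg/dL), > baseline.
#' @param t_stationary Time the stationary phase is reached (min), > `t_peak`.
#' @param stationary Stationary concentration (mg/dL), > 0 and < peak.
#' @return An object of class `gtt_params`.
#' @export
gtt_params <- function(baseline = 100, t_injection = 0, t_peak = 20,
                       peak = 350, t_stationary = 80, stationary = 150) {
  if (!(t_injection < t_peak && t_peak < t_stationary)) {
    stop("gtt_params: need t_injection < t_peak < t_stationary", call. = FALSE)
  }
  if (peak <= baseline) stop("gtt_params: peak must exceed baseline", call. = FALSE)
  if (stationary <= 0 || stationary >= peak) {
    stop("gtt_params: stationary must be in (0, peak)", call. = FALSE)
  }
  if (baseline < 0) stop("gtt_params: baseline must be >= 0", call. = FALSE)
  structure(list(baseline = baseline, t_injection = t_injection,
                 t_peak = t_peak, peak = peak,
                 t_stationary = t_stationary, stationary = stationary),
            class = "gtt_params")
}

# Noise-free GTT shape. Rise is a raised-cosine (zero slope at both ends);
# decay rate is set so the curve sits within 1% of the stationary value at
# t_stationary.
gtt_value <- function(params, t) {
  p <- params
  out <- numeric(length(t))
  pre <- t <= p$t_injection
  rise <- t > p$t_injection & t <= p$t_peak
  fall <- t > p$t_peak
  out[pre] <- p$baseline
  s <- (t[rise] - p$t_injection) / (p$t_peak - p$t_injection)
  out[rise] <- p$baseline + (p$peak - p$baseline) * sin(pi * s / 2)^2
  rate <- log((p$peak - p$stationary) / (0.01 * p$stationary)) /
    (p$t_stationary - p$t_peak)
  out[fall] <- p$stationary + (p$peak - p$stationary) * exp(-rate * (t[fall] - p$t_peak))
  out
}

#' Generate a synthetic blood glucose GTT series
#'
#' Samples the parametric GTT shape at a fixed cadence and applies
#' multiplicative lognormal noise with the requested coefficient of
#' variation (mean-one noise). Deterministic for a fixed seed.
#'
#' @param params A [gtt_params()].
#' @param sample_interval Sampling cadence (min), default 10.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 gives the exact shape.
#' @param t_start,t_end Sampling window (min); defaults 0 and
#'   `t_stationary + 20`.
#' @return A [glucose_series()] labeled `"blood"`.
#' @export
generate_blood_gtt <- function(params = gtt_params(), sample_interval = 10,
                               seed = NULL, noise_cv = 0,
                               t_start = 0, t_end = NULL) {
  stopifnot(inherits(params, "gtt_params"))
  if (!is.finite(sample_interval) || sample_interval <= 0) {
    stop("generate_blood_gtt: sample_interval must be > 0", call. = FALSE)
  }
  if (noise_cv < 0) stop("generate_blood_gtt: noise_cv must be >= 0", call. = FALSE)
  if (is.null(t_end)) t_end <- params$t_stationary + 20
  times <- seq(t_start, t_end, by = sample_interval)
  vals <- gtt_value(params, times)
  if (noise_cv > 0) {
    vals <- vals * with_seed(seed, lognormal_factors(length(vals), noise_cv))
  }
  glucose_series(times, vals, label = "blood")
}

# mean-one multiplicative lognormal factors with coefficient of variation cv
lognormal_factors <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Fluorescent sensor parameters
#'
#' One-site competitive quenching: glucose competitively displaces the
#' fluorophore from the boronate polymer, so intensity decreases
#' hyperbolically with concentration, `I(C) = I0 * K / (K + C)`. `K` is the
#' half-quench concentration; the default 180 mg/dL (10 mM) is typical of
#' boronic-acid glucose receptors and centers the sensitive range on the
#' physiological band.
#'
#' @param I0 Zero-glucose intensity (arbitrary units), > 0.
#' @param K Half-quench concentration (mg/dL), > 0.
#' @param cv Multiplicative measurement noise CV, >= 0; default 0.05.
#' @return An object of class `fluorescence_params`.
#' @export
fluorescence_params <- function(I0 = 1000, K = 180, cv = 0.05) {
  if (!is.finite(I0) || I0 <= 0) stop("fluorescence_params: I0 must be > 0", call. = FALSE)
  if (!is.finite(K) || K <= 0) stop("fluorescence_params: K must be > 0", call. = FALSE)
  if (!is.finite(cv) || cv < 0) stop("fluorescence_params: cv must be >= 0", call. = FALSE)
  structure(list(I0 = I0, K = K, cv = cv), class = "fluorescence_params")
}

#' Fluorescent readout of a glucose series
#'
#' Applies the strictly decreasing intensity response `I(C) = I0*K/(K+C)`
#' with multiplicative lognormal noise (always positive, so no resampling is
#' ever needed in practice; a guard resamples should a non-positive intensity
#' occur). Invert with [calibrate_fluorescence()].
#'
#' @param glucose A [glucose_series()] of concentrations.
#' @param params A [fluorescence_params()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [glucose_series()]-shaped object with `units = "au"` holding
#'   intensities.
#' @export
fluorescence_readout <- function(glucose, params = fluorescence_params(),
                                 seed = NULL) {
  stopifnot(inherits(glucose, "glucose_series"),
            inherits(params, "fluorescence_params"))
  intensity <- params$I0 * params$K / (params$K + glucose$values)
  if (params$cv > 0) {
    intensity <- with_seed(seed, {
      out <- intensity * lognormal_factors(length(intensity), params$cv)
      while (any(out <= 0)) { # unreachable for lognormal noise; kept as a guard
        bad <- out <= 0
        out[bad] <- intensity[bad] * lognormal_factors(sum(bad), params$cv)
      }
      out
    })
  }
  structure(list(times = glucose$times, values = intensity,
                 label = "fluorescence", units = "au"),
            class = "glucose_series")
}

#' Calibrate a fluorescent readout back to concentrations
#'
#' Algebraic inverse of the noiseless readout: `C = K * (I0/I - 1)`. Noise
#' that pushes an intensity above `I0` would imply a negative concentration;
#' such values are clamped to 0 with a warning.
#'
#' @param intensity The intensity series from [fluorescence_readout()].
#' @param params The same [fluorescence_params()] used for the readout.
#' @return A [glucose_series()] of concentrations, labeled `"isf"`.
#' @export
calibrate_fluorescence <- function(intensity, params = fluorescence_params()) {
  stopifnot(inherits(intensity, "glucose_series"),
            inherits(params, "fluorescence_params"))
  if (any(intensity$values <= 0)) {
    stop("calibrate_fluorescence: intensities must be > 0", call. = FALSE)
  }
  conc <- params$K * (params$I0 / intensity$values - 1)
  conc <- clamp_concentration(conc, "calibrate_fluorescence")
  glucose_series(intensity$times, conc, label = "isf")
}

#' Isotope-tracer readout of paired blood/ISF series
#'
#' Tracer activities proportional to concentration (`activity =
#' specific_activity * C`) with Poisson counting noise. Noise off, the
#' activity ratio equals the concentration ratio at every time point, which
#' is the relation used to convert activities back to concentrations.
#'
#' The default specific activity of 2 counts/min per mg/dL puts expected
#' counts in the few-hundred range, i.e. a counting CV of roughly 5%,
#' comparable to the fluorescent channel.
#'
#' @param c_blood,c_isf Paired [glucose_series()] on a common time grid.
#' @param specific_activity Counts/min per mg/dL, > 0.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise Poisson counting noise on/off.
#' @return List of two `glucose_series` with `units = "counts"`:
#'   `t_blood`, `t_isf`.
#' @export
isotope_readout <- function(c_blood, c_isf, specific_activity = 2,
                            seed = NULL, noise = TRUE) {
  stopifnot(inherits(c_blood, "glucose_series"), inherits(c_isf, "glucose_series"))
  if (length(c_blood) != length(c_isf) ||
      max(abs(c_blood$times - c_isf$times)) > 1e-8) {
    stop("isotope_readout: series must share a time grid", call. = FALSE)
  }
  if (!is.finite(specific_activity) || specific_activity <= 0) {
    stop("isotope_readout: specific_activity must be > 0", call. = FALSE)
  }
  lam_b <- specific_activity * c_blood$values
  lam_i <- specific_activity * c_isf$values
  if (noise) {
    draws <- with_seed(seed, {
      list(b = stats::rpois(length(lam_b), lam_b),
           i = stats::rpois(length(lam_i), lam_i))
    })
    lam_b <- draws$b; lam_i <- draws$i
  }
  list(
    t_blood = glucose_series(c_blood$times, lam_b, label = "blood", units = "counts"),
    t_isf = glucose_series(c_isf$times, lam_i, label = "isf", units = "counts")
  )
}

#' Convert isotope activities to an ISF concentration
#'
#' Uses the proportionality of tracer activity and concentration across
#' compartments, `T_blood / T_isf = C_blood / C_isf`, i.e.
#' `C_isf = C_blood * T_isf / T_blood`.
#'
#' @param t_blood Blood activity (counts/min), > 0; vectorized.
#' @param t_isf ISF activity (counts/min), >= 0.
#' @param c_blood Blood concentration (mg/dL).
#' @return ISF concentration(s) (mg/dL).
#' @examples
#' isotope_to_concentration(2000, 1000, 180) # 90
#' @export
isotope_to_concentration <- function(t_blood, t_isf, c_blood) {
  if (any(!is.finite(t_blood)) || any(t_blood <= 0)) {
    stop("isotope_to_concentration: t_blood must be > 0", call. = FALSE)
  }
  if (any(t_isf < 0)) {
    stop("isotope_to_concentration: t_isf must be >= 0", call. = FALSE)
  }
  c_blood * t_isf / t_blood
}

#' Build a complete synthetic measurement scenario
#'
#' Bundles a species-appropriate blood GTT profile, the true ISF time course
#' simulated at the default diffusion distance of 24 um, and a noisy measured
#' ISF series obtained through the species' readout chemistry:
#'
#' * `"mouse"`: intraperitoneal bolus (slower rise, peak at 30 min), sampling
#'   every 10 min from injection; ISF read out through the fluorescent sensor
#'   and calibrated back to concentration.
#' * `"rat"`: intravenous bolus (peak at 20 min), first sample 5 min after
#'   injection then every 10 min; ISF read out as tracer activities with
#'   Poisson counting noise and converted through the activity ratio.
#'
#' Fully deterministic for a fixed seed.
#'
#' The default configuration uses x = 24 um and a species-calibrated
#' diffusion coefficient chosen so that the diffusion step half-rise time at
#' x = 24 um equals the lag the study reports for that species (2.0 min
#' mouse, 2.4 min rat), i.e. `D = x^2 / (4 * t_half * eta^2)` with
#' `erf(eta) = 1/2`: about 317 um^2/min (mouse) and 264 um^2/min (rat). See
#' [calibrate_D()].
#'
#' @param species `"mouse"` or `"rat"`.
#' @param seed Integer seed.
#' @param config A [model_config()]; defaults to x = 24 um with the
#'   species-calibrated D.
#' @param noise_cv Readout noise CV for the fluorescent channel, default 0.05.
#' @param specific_activity Isotope channel dose, default 2 counts/min per mg/dL.
#' @param gtt Optional [gtt_params()] override.
#' @return An object of class `glucose_scenario`: `species`, `seed`, `blood`,
#'   `isf_true`, `isf_measured`, `readout` (intensities or activities),
#'   `config`.
#' @export
make_scenario <- function(species = c("mouse", "rat"), seed = 1,
                          config = NULL, noise_cv = 0.05,
                          specific_activity = 2, gtt = NULL) {
  species <- match.arg(species)
  if (is.null(config)) {
    t_half <- if (species == "mouse") 2.0 else 2.4
    config <- model_config(
      tissue = tissue_params(D = calibrate_D(t_half, x = 24), x = 24,
                             C_isf0 = 100)
    )
  }
  stopifnot(inherits(config, "model_config"))
  if (is.null(gtt)) {
    gtt <- if (species == "mouse") gtt_params(t_peak = 30) else gtt_params(t_peak = 20)
  }
  sample_times <- if (species == "mouse") seq(0, 100, by = 10) else c(0, seq(5, 95, by = 10))
  blood <- glucose_series(sample_times, gtt_value(gtt, sample_times), label = "blood")
  isf_true <- simulate_isf(blood, config)
  measured_times <- if (species == "mouse") sample_times else sample_times[-1L]
  if (species == "mouse") {
    fp <- fluorescence_params(cv = noise_cv)
    readout <- fluorescence_readout(isf_true, fp, seed = seed)
    isf_measured <- calibrate_fluorescence(readout, fp)
  } else {
    truth_at <- glucose_series(measured_times,
                               series_at(isf_true, measured_times), label = "isf")
    blood_at <- glucose_series(measured_times,
                               series_at(blood, measured_times), label = "blood")
    readout <- isotope_readout(blood_at, truth_at,
                               specific_activity = specific_activity,
                               seed = seed, noise = TRUE)
    conc <- isotope_to_concentration(pmax(readout$t_blood$values, 1),
                                     readout$t_isf$values,
                                     blood_at$values)
    isf_measured <- glucose_series(measured_times, conc, label = "isf")
  }
  structure(list(species = species, seed = seed, blood = blood,
                 isf_true = isf_true, isf_measured = isf_measured,
                 readout = readout, config = config, gtt = gtt),
            class = "glucose_scenario")
}

#' @export
print.glucose_scenario <- function(x, ...) {
  cat(sprintf("<glucose_scenario> species=%s, seed=%d, n=%d samples, x=%g um\n",
              x$species, x$seed, length(x$blood), x$config$tissue$x))
  invisible(x)
}
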