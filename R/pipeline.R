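#' Read a model configuration from YAML
#'
#' Recognized keys (all optional; package defaults fill the rest):
#' `permeability`, `area`, `flow` (capillary); `K_f`, `sigma_pi_c`, `P_a`,
#' `P_v` (Starling); `D_um2_per_min`, `x_um`, `C_ISF0` (tissue); `r_fick`
#' (route weight), `mode` (`superposition`/`quasi_static`), `dt` (min).
#'
#' @param path Path to a YAML file.
#' @return A [model_config()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_model_config: file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' Build a model configuration from a plain named list
#'
#' @param raw Named list with the keys documented in [read_model_config()].
#' @return A [model_config()].
#' @export
config_from_list <- function(raw) {
  if (is.null(raw)) raw <- list()
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  cap_def <- capillary_params()
  st_def <- starling_params()
  tis_def <- tissue_params()
  model_config(
    capillary = capillary_params(
      permeability = pick("permeability", cap_def$permeability),
      area = pick("area", cap_def$area),
      flow = pick("flow", cap_def$flow)
    ),
    starling = starling_params(
      K_f = pick("K_f", st_def$K_f),
      sigma_pi_c = pick("sigma_pi_c", st_def$sigma_pi_c),
      P_a = pick("P_a", st_def$P_a),
      P_v = pick("P_v", st_def$P_v)
    ),
    tissue = tissue_params(
      D = pick("D_um2_per_min", tis_def$D),
      x = pick("x_um", tis_def$x),
      C_isf0 = pick("C_ISF0", tis_def$C_isf0)
    ),
    weights = model_weights(R_fick = pick("r_fick", 0.5)),
    mode = pick("mode", "superposition"),
    dt = pick("dt", 0.1)
  )
}

#' Write a model configuration to YAML
#'
#' @param config A [model_config()].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  yaml::write_yaml(list(
    permeability = config$capillary$permeability,
    area = config$capillary$area,
    flow = config$capillary$flow,
    K_f = config$starling$K_f,
    sigma_pi_c = config$starling$sigma_pi_c,
    P_a = config$starling$P_a,
    P_v = config$starling$P_v,
    D_um2_per_min = config$tissue$D,
    x_um = config$tissue$x,
    C_ISF0 = config$tissue$C_isf0,
    r_fick = config$weights$R_fick,
    mode = config$mode,
    dt = config$dt
  ), path)
  invisible(path)
}

resolve_config <- function(config) {
  if (is.null(config)) return(model_config())
  if (inherits(config, "model_config")) return(config)
  if (is.character(config)) return(read_model_config(config))
  if (is.list(config)) return(config_from_list(config))
  stop("run_pipeline: cannot interpret the 'config' option", call. = FALSE)
}

write_manifest <- function(out_dir, command, opts, extra = list()) {
  manifest <- c(list(
    command = command,
    package = "glucolag",
    version = as.character(utils::packageVersion("glucolag")),
    seed = opts$seed,
    options = opts[!vapply(opts, is.object, logical(1))]
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run a pipeline stage
#'
#' Top-level driver tying the stages together; each call writes its artifacts
#' plus a JSON run manifest (command, options, seed, package version) into
#' `out_dir`. All randomness flows from the single `seed` option.
#'
#' Commands and their options:
#' * `"synth"`: `species`, `seed`, `out_dir` -- writes `blood.csv`,
#'   `isf_true.csv`, `measured.csv` (mouse) or `activities.csv` (rat), and
#'   `config.yaml`.
#' * `"simulate"`: `blood` (CSV path), `config` (YAML path, list or
#'   [model_config()]), `out_dir` -- writes `isf.csv`.
#' * `"fit"`: `blood`, `isf`, `config`, `grid` (numeric, default 18/24/30),
#'   `out_dir` -- writes `fit.json`.
#' * `"lag"`: `blood`, `isf`, `method` (`shift`/`peak`), `out_dir` -- writes
#'   `lag.json`.
#'
#' @param command One of `"synth"`, `"simulate"`, `"fit"`, `"lag"`.
#' @param opts Named list of options, see above.
#' @return Invisibly, a list of the artifacts produced (paths plus the main
#'   result object).
#' @export
run_pipeline <- function(command = c("synth", "simulate", "fit", "lag"),
                         opts = list()) {
  command <- tryCatch(match.arg(command),
                      error = function(e) stop("run_pipeline: unknown command",
                                               call. = FALSE))
  out_dir <- opts$out_dir
  if (is.null(out_dir)) stop("run_pipeline: 'out_dir' is required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(opts$seed) && (opts$seed < 0 || opts$seed != round(opts$seed))) {
    stop("run_pipeline: seed must be a nonnegative integer", call. = FALSE)
  }
  need <- function(key) {
    if (is.null(opts[[key]])) {
      stop(sprintf("run_pipeline: option '%s' is required for '%s'", key, command),
           call. = FALSE)
    }
    opts[[key]]
  }
  if (command == "synth") {
    species <- need("species")
    seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
    config <- resolve_config(opts$config)
    sc <- make_scenario(species = species, seed = seed, config = config)
    write_timeseries(sc$blood, file.path(out_dir, "blood.csv"))
    write_timeseries(sc$isf_true, file.path(out_dir, "isf_true.csv"))
    if (species == "mouse") {
      write_timeseries(sc$isf_measured, file.path(out_dir, "measured.csv"))
    } else {
      write_timeseries(sc$readout$t_blood, file.path(out_dir, "activities_blood.csv"))
      write_timeseries(sc$readout$t_isf, file.path(out_dir, "activities_isf.csv"))
      write_timeseries(sc$isf_measured, file.path(out_dir, "measured.csv"))
    }
    write_model_config(sc$config, file.path(out_dir, "config.yaml"))
    write_manifest(out_dir, command, utils::modifyList(opts, list(seed = seed)))
    return(invisible(list(scenario = sc, out_dir = out_dir)))
  }
  if (command == "simulate") {
    blood <- read_timeseries(need("blood"))
    config <- resolve_config(opts$config)
    isf <- simulate_isf(blood, config)
    write_timeseries(isf, file.path(out_dir, "isf.csv"))
    write_manifest(out_dir, command, opts)
    return(invisible(list(isf = isf, out_dir = out_dir)))
  }
  if (command == "fit") {
    blood <- read_timeseries(need("blood"))
    isf <- read_timeseries(need("isf"))
    config <- resolve_config(opts$config)
    grid <- if (is.null(opts$grid)) c(18, 24, 30) else as.numeric(opts$grid)
    fit <- fit_diffusion_distance(blood, isf, config, grid = grid)
    fit_path <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(
      x_star = fit$x_star, grid = fit$grid, lag_min = fit$lag_min,
      max_relative_error = fit$max_relative_error,
      mean_relative_error = fit$mean_relative_error,
      objective = fit$objective, table = fit$table
    ), fit_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    write_manifest(out_dir, command, opts, extra = list(x_star = fit$x_star))
    return(invisible(list(fit = fit, out_dir = out_dir)))
  }
  # lag
  blood <- read_timeseries(need("blood"))
  isf <- read_timeseries(need("isf"))
  method <- if (is.null(opts$method)) "shift" else opts$method
  lag <- estimate_lag(blood, isf, method = method)
  jsonlite::write_json(list(lag_min = lag, method = method),
                       file.path(out_dir, "lag.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, command, opts, extra = list(lag_min = lag))
  invisible(list(lag = lag, out_dir = out_dir))
}
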