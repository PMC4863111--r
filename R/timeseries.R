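#' Glucose (or activity) time series
#'
#' The universal currency between pipeline stages: a set of strictly
#' increasing time points (minutes since injection, t = 0 at injection) with
#' nonnegative values. Concentrations are in mg/dL; isotope activities are in
#' counts/min (`units = "counts"`).
#'
#' @param times Numeric vector of times in minutes, strictly increasing.
#' @param values Numeric vector of the same length, all values >= 0.
#' @param label Free-text compartment label, typically `"blood"` or `"isf"`.
#' @param units `"mg/dL"` for concentrations, `"counts"` for activities.
#' @return An object of class `glucose_series`.
#' @examples
#' gs <- glucose_series(c(0, 10, 20), c(100, 250, 300), label = "blood")
#' gs
#' @export
glucose_series <- function(times, values, label = "blood", units = "mg/dL") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L) {
    stop("glucose_series: empty series", call. = FALSE)
  }
  if (length(times) != length(values)) {
    stop("glucose_series: times and values must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values) || any(!is.finite(times)) || any(!is.finite(values))) {
    stop("glucose_series: non-finite entries", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("glucose_series: times must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("glucose_series: values must be nonnegative", call. = FALSE)
  }
  structure(
    list(times = times, values = values,
         label = as.character(label)[1L], units = units),
    class = "glucose_series"
  )
}

#' @export
length.glucose_series <- function(x) length(x$times)

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> label=%s, n=%d, t=[%g, %g] min, %s in [%g, %g]\n",
              x$label, length(x$times), min(x$times), max(x$times),
              x$units, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.glucose_series <- function(x, ...) {
  value_col <- if (identical(x$units, "counts")) "counts" else "glucose_mg_dl"
  out <- data.frame(time_min = x$times, value = x$values)
  names(out)[2L] <- value_col
  out
}

#' Interpolate a series at arbitrary times
#'
#' Linear interpolation inside the observed window, constant extrapolation at
#' the edges (rule = 2), matching the linear-interpolation convention used to
#' feed blood glucose into the simulator.
#'
#' @param series A [glucose_series()].
#' @param times Times (min) at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
series_at <- function(series, times) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series$times) == 1L) {
    return(rep(series$values, length(times)))
  }
  stats::approx(series$times, series$values, xout = times, rule = 2)$y
}

#' Read a time series from CSV
#'
#' Expects a UTF-8 CSV with header `time_min,glucose_mg_dl` (concentrations)
#' or `time_min,counts` (isotope activities), dot decimal separator, and an
#' optional third column `label`. Strictly increasing times are enforced.
#'
#' @param path Path to a CSV file.
#' @return A [glucose_series()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_timeseries: file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("read_timeseries: malformed CSV %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (ncol(df) < 2L || names(df)[1L] != "time_min" ||
      !(names(df)[2L] %in% c("glucose_mg_dl", "counts"))) {
    stop(sprintf(paste0("read_timeseries: malformed header in %s; expected ",
                        "'time_min,glucose_mg_dl' or 'time_min,counts'"), path),
         call. = FALSE)
  }
  units <- if (names(df)[2L] == "counts") "counts" else "mg/dL"
  for (j in 1:2) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop(sprintf("read_timeseries: non-numeric cell in %s, column '%s', line %d",
                   path, names(df)[j], (if (is.na(bad)) 1L else bad) + 1L),
           call. = FALSE)
    }
  }
  if (nrow(df) > 1L) {
    bad <- which(diff(df$time_min) <= 0)
    if (length(bad) > 0L) {
      # +2: one for the header line, one because diff index i flags row i+1
      stop(sprintf("read_timeseries: times not strictly increasing in %s at line %d",
                   path, bad[1L] + 2L), call. = FALSE)
    }
  }
  label <- if ("label" %in% names(df)) as.character(df$label[1L]) else
    if (units == "counts") "activity" else "blood"
  glucose_series(df$time_min, df[[2L]], label = label, units = units)
}

#' Write a time series to CSV
#'
#' Values are written with 6 significant digits; the header matches what
#' [read_timeseries()] expects, so write/read roundtrips are stable to 1e-5
#' relative. The series label is stored in a third column when
#' `include_label = TRUE`.
#'
#' @param series A [glucose_series()].
#' @param path Output path.
#' @param include_label Write the label as a third CSV column.
#' @return Invisibly, the path written.
#' @export
write_timeseries <- function(series, path, include_label = FALSE) {
  stopifnot(inherits(series, "glucose_series"))
  df <- as.data.frame(series)
  df[[2L]] <- signif(df[[2L]], 6)
  df$time_min <- signif(df$time_min, 10)
  if (include_label) df$label <- series$label
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("write_timeseries: cannot write %s", path), call. = FALSE)
  invisible(path)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
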