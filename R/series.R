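#' Concentration-time series
#'
#' A concentration series is an ordinary tibble with columns `time_s`
#' (seconds, strictly increasing), `concentration` (non-negative, in `unit`)
#' and `unit` (text, e.g. "mg/L", "ng/mL", or "normalized").
#' `concentration_series()` builds and validates one;
#' `read_series_csv()`/`write_series_csv()` round-trip the CSV interchange
#' format with header `time_s,concentration,unit`.
#'
#' @param time_s sample times, s.
#' @param concentration concentrations, same length as `time_s`.
#' @param unit unit label.
#' @return A tibble with columns `time_s`, `concentration`, `unit`.
#' @examples
#' concentration_series(c(0, 3600, 7200), c(0, 1.2, 0.8), "mg/L")
#' @export
concentration_series <- function(time_s, concentration, unit = "mg/L") {
  out <- tibble::tibble(
    time_s = as.numeric(time_s),
    concentration = as.numeric(concentration),
    unit = as.character(unit)
  )
  validate_series(out)
}

validate_series <- function(x, sort = TRUE) {
  if (!all(c("time_s", "concentration") %in% names(x))) {
    abort("A concentration series needs columns time_s and concentration.")
  }
  if (nrow(x) < 1) abort("A concentration series needs at least one row.")
  if (anyNA(x$time_s) || anyNA(x$concentration)) {
    abort("Concentration series must not contain missing values.")
  }
  if (sort) x <- dplyr::arrange(x, .data$time_s)
  if (any(diff(x$time_s) <= 0)) {
    abort("Sample times must be strictly increasing (no duplicates).")
  }
  if (any(x$concentration < 0)) {
    abort("Concentrations must be non-negative.")
  }
  if (!"unit" %in% names(x)) x$unit <- "mg/L"
  tibble::as_tibble(x[, c("time_s", "concentration", "unit")])
}

#' @param path file path.
#' @rdname concentration_series
#' @export
read_series_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_series(x)
}

#' @param series a concentration series tibble.
#' @rdname concentration_series
#' @export
write_series_csv <- function(series, path) {
  series <- validate_series(series)
  readr::write_csv(series, path)
  invisible(series)
}

# Interpolate a (dense) simulated series onto arbitrary times with a
# monotone cubic spline; used when matching simulations to observation
# instants.
interp_series <- function(series, times) {
  if (min(times) < min(series$time_s) - 1e-9 ||
      max(times) > max(series$time_s) + 1e-9) {
    abort("Requested times fall outside the simulated range.")
  }
  if (nrow(series) < 3) {
    return(approx(series$time_s, series$concentration, xout = times,
                  rule = 2)$y)
  }
  f <- splinefun(series$time_s, series$concentration, method = "monoH.FC")
  pmax(f(times), 0)
}

#' Agreement metrics between two paired concentration series
#'
#' Pairs the two series on common sample times and reports the root mean
#' square error, the coefficient of determination r^2 (squared Pearson
#' correlation of paired values), and the peak concentration `Cmax` and peak
#' time `Tmax` of each series.
#'
#' @param a,b concentration series tibbles sharing at least two sample times.
#' @return A one-row tibble: `rmse`, `r2`, `cmax_a`, `tmax_a`, `cmax_b`,
#'   `tmax_b`, `n`.
#' @examples
#' s1 <- concentration_series(0:3 * 3600, c(0, 2, 3, 1))
#' s2 <- concentration_series(0:3 * 3600, c(0, 2, 3, 1) + 0.5)
#' series_metrics(s1, s2)
#' @export
series_metrics <- function(a, b) {
  a <- validate_series(a)
  b <- validate_series(b)
  m <- dplyr::inner_join(
    dplyr::select(a, "time_s", va = "concentration"),
    dplyr::select(b, "time_s", vb = "concentration"),
    by = "time_s"
  )
  if (nrow(m) < 2) abort("series_metrics needs at least 2 paired values.")
  tibble::tibble(
    rmse = sqrt(mean((m$va - m$vb)^2)),
    r2 = cor(m$va, m$vb)^2,
    cmax_a = max(a$concentration),
    tmax_a = a$time_s[which.max(a$concentration)],
    cmax_b = max(b$concentration),
    tmax_b = b$time_s[which.max(b$concentration)],
    n = nrow(m)
  )
}
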