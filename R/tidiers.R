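#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted absorption model
#'
#' @param x a `gut_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`
#'   (absolute SI units) and `estimate_tabulated` (lambda on the 1e-3 m^2/s
#'   scale, kd on the 1e-5 1/s scale).
#' @method tidy gut_fit
#' @export
tidy.gut_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda_j", "lambda_ic", "kd"),
    estimate = c(x$params$lambda_j, x$params$lambda_ic, x$params$kd),
    estimate_tabulated = c(x$params$lambda_j * 1e3, x$params$lambda_ic * 1e3,
                           x$params$kd * 1e5)
  )
}

#' Glance at a fitted absorption model
#'
#' @param x a `gut_fit` object.
#' @param ... unused.
#' @return A one-row tibble: `objective`, `converged`, `n_starts`, `n_obs`,
#'   `dose_mg`.
#' @method glance gut_fit
#' @export
glance.gut_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    converged = x$converged,
    n_starts = x$n_starts,
    n_obs = nrow(x$obs),
    dose_mg = x$dose_mg
  )
}
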