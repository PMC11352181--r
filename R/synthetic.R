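#' Generate synthetic observed concentration curves
#'
#' Runs the full forward model at known "true" absorption parameters and
#' samples the peripheral concentration at the requested times, optionally
#' corrupted by multiplicative Gaussian noise
#' (`value * (1 + eps)`, `eps ~ N(0, noise_cv)`, clamped at 0). Plasma-assay
#' error is roughly proportional to concentration, hence the multiplicative
#' (coefficient-of-variation) noise model. The generator stands in for
#' clinical concentration-time datasets in tests and examples; it is
#' deterministic for a fixed `seed`.
#'
#' @param drug a `gut_drug`.
#' @param true_params a `gut_absorption`: the parameters generating the data.
#' @param sampling_times_s strictly increasing sample times, s.
#' @param dose_mg dose, mg.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed integer seed.
#' @param phys physiology from [default_physiology()].
#' @param ... passed to [simulate_gut()] (e.g. `predissolved`, `dt_int`).
#' @return A concentration series tibble (`time_s`, `concentration`, `unit`).
#' @examples
#' \donttest{
#' drug <- drug_properties("Aprepitant", dose_mg = 80)
#' obs <- generate_observations(drug, published_params("Aprepitant"),
#'                              sampling_times_s = 3600 * c(1, 2, 4, 8, 12),
#'                              noise_cv = 0.05, seed = 42)
#' }
#' @export
generate_observations <- function(drug, true_params, sampling_times_s,
                                  dose_mg = drug$dose_mg, noise_cv = 0,
                                  seed = 0, phys = default_physiology(), ...) {
  if (noise_cv < 0) abort("noise_cv must be >= 0.")
  if (any(diff(sampling_times_s) <= 0)) {
    abort("sampling_times_s must be strictly increasing.")
  }
  sim <- simulate_gut(drug, true_params, phys, dose_mg = dose_mg,
                      t_end = max(sampling_times_s), ...)
  values <- interp_series(sim$series, sampling_times_s)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    values <- pmax(values * (1 + rnorm(length(values), 0, noise_cv)), 0)
  }
  concentration_series(sampling_times_s, values, "mg/L")
}
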