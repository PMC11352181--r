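test_that("the normalized objective matches hand-computed sums", {
  obs <- concentration_series(c(0, 3600), c(1, 0.5))
  sim <- concentration_series(c(0, 3600), c(0.5, 1))
  expect_equal(objective_phi(obs, sim), 0.5)
  expect_equal(objective_phi(obs, obs), 0)
  expect_error(objective_phi(concentration_series(0:1, c(0, 0)), sim),
               "all zero")
})

test_that("the objective is invariant to rescaling either series", {
  set.seed(7)
  t <- sort(runif(12, 0, 86400))
  obs <- concentration_series(t, runif(12, 0.1, 5))
  sim <- concentration_series(t, runif(12, 0.1, 5))
  base <- objective_phi(obs, sim)
  for (c1 in c(1e-3, 0.37, 42, 1e6)) {
    o2 <- dplyr::mutate(obs, concentration = concentration * c1)
    s2 <- dplyr::mutate(sim, concentration = concentration * (1 / c1))
    expect_equal(objective_phi(o2, sim), base, tolerance = 1e-14)
    expect_equal(objective_phi(obs, s2), base, tolerance = 1e-14)
  }
})

test_that("series metrics report RMSE, r2 and the peaks", {
  a <- concentration_series(c(0, 60, 120), c(1, 2, 3))
  b <- concentration_series(c(0, 60, 120), c(1, 2, 4))
  m <- series_metrics(a, b)
  expect_equal(m$rmse, sqrt(1 / 3))
  m2 <- series_metrics(a, a)
  expect_equal(m2$rmse, 0)
  expect_equal(m2$r2, 1)
  shifted <- dplyr::mutate(a, concentration = concentration + 0.7)
  m3 <- series_metrics(a, shifted)
  expect_equal(m3$rmse, 0.7)
  expect_equal(m3$r2, 1)
  expect_equal(m3$cmax_a, 3)
  expect_equal(m3$tmax_a, 120)
  expect_error(series_metrics(a, concentration_series(500, 1)), "2 paired")
})

test_that("effective permeability: closed form equals adaptive quadrature", {
  phys <- default_physiology()
  quad_peff <- function(params) {
    p <- gutsim:::resolve_peaks(params, phys)
    Lic <- phys$Li + phys$Lc
    Ij <- integrate(function(x) p$lambda_j / (pi * (1 + (x - p$Ltilde_j)^2)),
                    0, phys$Lj, rel.tol = 1e-13)$value
    Iic <- integrate(function(x) p$lambda_ic / (pi * (1 + (x - p$Ltilde_ic)^2)),
                     0, Lic, rel.tol = 1e-13)$value
    (phys$rint / phys$Lj * Ij + phys$rint / Lic * Iic) * 100
  }
  for (d in c("Aprepitant", "Fenofibrate", "Ibuprofen", "Irbesartan")) {
    params <- published_params(d)
    pe <- effective_permeability(params, phys)
    expect_equal(pe$peff_cm_s, quad_peff(params), tolerance = 1e-10)
    expect_equal(pe$peff_cm_s,
                 pe$peff_jejunum_cm_s + pe$peff_ileocolon_cm_s)
  }
  # linear in the scales, zero at zero
  expect_equal(effective_permeability(absorption_params(0, 0, 0))$peff_cm_s, 0)
  p1 <- effective_permeability(absorption_params(2e-3, 3e-3, 1e-5))
  p2 <- effective_permeability(absorption_params(4e-3, 6e-3, 1e-5))
  expect_equal(p2$peff_cm_s, 2 * p1$peff_cm_s)
})

test_that("a fit bracketed near the truth converges to phi ~ 0", {
  drug <- aprepitant()
  true <- absorption_params(5.157e-3, 5.1e-3, 2.012e-5)
  times <- 3600 * c(1, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24)
  obs <- generate_observations(drug, true, times)
  bounds <- list(lower = c(5.157e-3, 5.1e-3, 2.012e-5) * 0.9,
                 upper = c(5.157e-3, 5.1e-3, 2.012e-5) * 1.1)
  fit <- fit_absorption(obs, drug, bounds = bounds, n_starts = 1, seed = 3,
                        profile = FALSE)
  expect_lt(fit$objective, 1e-6)
  expect_equal(unname(fit$params$lambda_j), 5.157e-3, tolerance = 1e-2)
  expect_equal(unname(fit$params$kd), 2.012e-5, tolerance = 1e-2)
})

test_that("fitting is deterministic for a fixed seed", {
  drug <- aprepitant()
  true <- absorption_params(5.157e-3, 5.1e-3, 2.012e-5)
  times <- 3600 * c(1, 2, 4, 6, 9, 12, 18, 24)
  obs <- generate_observations(drug, true, times, noise_cv = 0.05, seed = 11)
  f1 <- fit_absorption(obs, drug, n_starts = 2, seed = 5, profile = FALSE)
  f2 <- fit_absorption(obs, drug, n_starts = 2, seed = 5, profile = FALSE)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$starts, f2$starts)
})

test_that("noisy observations still pin down the peak time", {
  drug <- aprepitant()
  true <- absorption_params(5.157e-3, 5.1e-3, 2.012e-5)
  times <- 3600 * seq(1, 24, by = 1.64)
  obs <- generate_observations(drug, true, times, noise_cv = 0.05, seed = 21)
  fit <- fit_absorption(obs, drug, n_starts = 4, seed = 2)
  truth <- simulate_gut(drug, true, t_end = max(times))
  tmax_true <- gutsim:::summarize_peak(truth$series)$tmax_s
  tmax_fit <- gutsim:::summarize_peak(fit$fitted)$tmax_s
  # recovered peak within one sampling interval of the true curve's peak
  expect_lte(abs(tmax_fit - tmax_true), 1.64 * 3600)
})

test_that("dose prediction reuses the parameters and scales as expected", {
  drug <- aprepitant()
  params <- published_params("Aprepitant")
  base <- simulate_gut(drug, params, dose_mg = 80, t_end = 8 * 3600,
                       predissolved = TRUE)
  pred_same <- predict_dose(params, 80, drug = drug, t_end = 8 * 3600,
                            predissolved = TRUE)
  expect_equal(pred_same$series$concentration, base$series$concentration)
  pred_double <- predict_dose(params, 160, drug = drug, t_end = 8 * 3600,
                              predissolved = TRUE)
  nz <- base$series$concentration > 0
  expect_equal(pred_double$series$concentration[nz] /
                 base$series$concentration[nz],
               rep(2, sum(nz)), tolerance = 1e-9)
})

test_that("tidy and glance summarize a fit", {
  drug <- aprepitant()
  obs <- generate_observations(drug, published_params("Aprepitant"),
                               3600 * c(2, 4, 8, 16, 24))
  fit <- fit_absorption(obs, drug, n_starts = 1, seed = 1, profile = FALSE)
  td <- tidy(fit)
  expect_identical(td$term, c("lambda_j", "lambda_ic", "kd"))
  expect_equal(td$estimate_tabulated[1], td$estimate[1] * 1e3)
  gl <- glance(fit)
  expect_identical(gl$n_obs, 5L)
  expect_identical(gl$dose_mg, 80)
})
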