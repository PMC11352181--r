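#' Axial permeability profile
#'
#' The wall-transfer coefficient varies along the intestine as a Cauchy-shaped
#' bump per segment:
#' \deqn{\alpha_l(x) = \frac{\lambda_l}{\pi\,(1 + (x - \tilde L_l)^2)},
#'   \qquad l \in \{j, ic\},}
#' with `x` the global axial coordinate in m from the jejunum inlet. In the
#' ileum-colon the coordinate is segment-local (`x - Lj`), so the default peak
#' `(Lj+Li+Lc)/5` sits 1.5 m past the ileum inlet and its tail covers the
#' colon. The squared term carries an implicit 1 m^2 scale, making alpha's
#' units those of lambda (1/s once the implicit length scales cancel).
#'
#' @param x global axial position(s), m, in `[0, Lj+Li+Lc]`.
#' @param params a `gut_absorption` object.
#' @param phys physiology from [default_physiology()].
#' @return alpha values, 1/s, same length as `x`.
#' @examples
#' phys <- default_physiology()
#' params <- published_params("Aprepitant")
#' alpha_profile(phys$Lj / 3, params, phys) # jejunal peak = lambda_j / pi
#' @export
alpha_profile <- function(x, params, phys = default_physiology()) {
  stopifnot(inherits(params, "gut_absorption"))
  params <- resolve_peaks(params, phys)
  Ltot <- phys$Lj + phys$Li + phys$Lc
  if (any(x < 0 | x > Ltot)) {
    abort("x outside the intestine [0, Lj + Li + Lc].")
  }
  ifelse(
    x < phys$Lj,
    params$lambda_j / (pi * (1 + (x - params$Ltilde_j)^2)),
    params$lambda_ic / (pi * (1 + ((x - phys$Lj) - params$Ltilde_ic)^2))
  )
}

#' Per-contact transfer coefficient
#'
#' Couples the bolus-side exchange rate alpha to the blood-side concentration
#' jump:
#' \deqn{K = \frac{\alpha\,V_{bol}}{\pi r_{bol}^2 (u + v_b)},}
#' with the bolus volume in m^3. By construction the drug mass leaving a
#' bolus, \eqn{V_{bol}\alpha (C_i - C_b^{i-1})}, equals the mass picked up by
#' the blood stream, \eqn{\pi r_{bol}^2 (u+v_b)(C_b^i - C_b^{i-1})}.
#'
#' @param alpha wall-transfer coefficient, 1/s.
#' @param Vbol_L bolus volume, L.
#' @param phys physiology from [default_physiology()].
#' @return Dimensionless transfer coefficient K.
#' @examples
#' K_from_alpha(5.157e-3 / pi, 0.05)
#' @export
K_from_alpha <- function(alpha, Vbol_L, phys = default_physiology()) {
  if (any(alpha < 0) || any(Vbol_L <= 0)) {
    abort("alpha must be >= 0 and Vbol_L > 0.")
  }
  V_m3 <- Vbol_L * 1e-3
  rbol <- (3 * V_m3 / (4 * pi))^(1 / 3)
  alpha * V_m3 / (pi * rbol^2 * (phys$u + phys$vb))
}

#' Countercurrent blood chain recursion
#'
#' Blood entering the intestine at concentration `Cb0` contacts the boluses
#' in sequence; after the i-th contact
#' \deqn{C_b^i = C_b^{i-1} + K_i\,(C_i - C_b^{i-1}).}
#' The chain is algebraic and solved by forward recursion. With no boluses
#' the outlet equals `Cb0`.
#'
#' @param C_bolus bolus concentrations in contact order (first element is the
#'   first contact, i.e. the most distal bolus under countercurrent flow).
#' @param K transfer coefficients, same length.
#' @param Cb0 inlet blood concentration.
#' @return A list: `chain` (blood concentration after each contact) and
#'   `outlet` (the last value, feeding the peripheral pool).
#' @examples
#' blood_chain(c(1, 1), c(0.5, 0.5), 0) # chain 0.5, 0.75
#' @export
blood_chain <- function(C_bolus, K, Cb0 = 0) {
  stopifnot(length(C_bolus) == length(K))
  chain <- numeric(length(K))
  cb <- Cb0
  for (i in seq_along(K)) {
    cb <- cb + K[i] * (C_bolus[i] - cb)
    chain[i] <- cb
  }
  list(chain = chain, outlet = if (length(K)) cb else Cb0)
}

#' Exchange rate of a single bolus
#'
#' \deqn{\frac{dC_i}{dt} = -\alpha_i\,(C_i - C_b^{i-1}).}
#' Drug flows blood-to-bolus when the upstream blood concentration exceeds
#' the bolus concentration.
#'
#' @param Ci bolus concentration, mg/L.
#' @param Cb_upstream blood concentration before this contact, mg/L.
#' @param alpha wall-transfer coefficient at the bolus position, 1/s.
#' @return dCi/dt, mg/L/s.
#' @export
bolus_rate <- function(Ci, Cb_upstream, alpha) {
  -alpha * (Ci - Cb_upstream)
}

#' Peripheral compartment rate
#'
#' The peripheral circulation is a stirred pool with volume `Vb`, fed by the
#' splanchnic outlet and subject to first-order elimination:
#' \deqn{\frac{d\bar C_b}{dt} = \frac{Q_b}{V_b}(C_b^{out} - \bar C_b)
#'   - k_d\,\bar C_b.}
#'
#' @param Cbar peripheral concentration, mg/L.
#' @param outlet splanchnic outlet concentration, mg/L.
#' @param kd elimination rate constant, 1/s.
#' @param phys physiology from [default_physiology()].
#' @return dCbar/dt, mg/L/s.
#' @export
peripheral_rate <- function(Cbar, outlet, kd, phys = default_physiology()) {
  phys$Qb / phys$Vb * (outlet - Cbar) - kd * Cbar
}

#' Simulate bolus transit and absorption through the intestine
#'
#' Advances a train of boluses (from [run_gastroduodenal()] or supplied
#' directly) through the jejunum and ileum-colon. Each bolus enters at its
#' emission time, moves at velocity `u`, exchanges drug with the
#' countercurrent splanchnic blood chain, and is retired once it passes the
#' end of the colon (any residual drug is logged as unabsorbed). The
#' peripheral pool receives the chain outlet and recirculates into the
#' intestine with transit delay `delta`.
#'
#' @param emissions tibble with columns `time_s`, `volume_L`, `concentration`
#'   (mg/L). Emission times must be multiples of the integration step.
#' @param params a `gut_absorption` object.
#' @param phys physiology from [default_physiology()].
#' @param t_end simulation end time, s.
#' @param dt_out output sampling step, s (rounded to a multiple of the
#'   internal step).
#' @param dt_int requested integration step, s; internally bounded by
#'   `delta/3` (when `delta > 0`) and snapped to a divisor of `Te`.
#' @param chain_order `"distal_first"` (countercurrent; default) or
#'   `"proximal_first"` (sensitivity check).
#' @param alpha_mode `"track"` re-evaluates alpha at the moving bolus
#'   position (default); `"frozen"` keeps the entry value.
#' @param traces if TRUE, per-bolus position/concentration traces are
#'   collected on the output grid.
#' @return A list of class `gut_sim` with elements `series` (tibble `time_s`,
#'   `concentration` = peripheral mg/L, `unit`), `boluses` (per-bolus entry,
#'   exit and residual summary), `audit` (mass bookkeeping and the maximum
#'   relative error of the per-contact transfer identity), `traces`
#'   (tibble or NULL), and the configuration used.
#' @export
simulate_intestine <- function(emissions, params, phys = default_physiology(),
                               t_end = 86400, dt_out = 300, dt_int = 30,
                               chain_order = c("distal_first", "proximal_first"),
                               alpha_mode = c("track", "frozen"),
                               traces = FALSE) {
  stopifnot(inherits(params, "gut_absorption"))
  chain_order <- match.arg(chain_order)
  alpha_mode <- match.arg(alpha_mode)
  params <- resolve_peaks(params, phys)
  if (!all(c("time_s", "volume_L", "concentration") %in% names(emissions))) {
    abort("emissions needs columns time_s, volume_L, concentration.")
  }
  emissions <- emissions[emissions$volume_L > 0, , drop = FALSE]

  h <- dt_int
  if (phys$delta > 0) h <- min(h, phys$delta / 3)
  h <- phys$Te / ceiling(phys$Te / h)       # divisor of the emptying period
  out_every <- max(1L, as.integer(round(dt_out / h)))
  nsteps <- as.integer(ceiling(t_end / h - 1e-9))
  nsteps <- as.integer(ceiling(nsteps / out_every)) * out_every
  t_end_eff <- nsteps * h

  if (nrow(emissions) > 0 &&
      any(abs(emissions$time_s / h - round(emissions$time_s / h)) > 1e-6)) {
    abort("Emission times must be multiples of the integration step.")
  }

  cap <- bolus_capacity(phys)
  res <- cpp_bolus_train(
    em_t = emissions$time_s, em_V = emissions$volume_L,
    em_C = emissions$concentration,
    lambda_j = params$lambda_j, lambda_ic = params$lambda_ic, kd = params$kd,
    Ltilde_j = params$Ltilde_j, Ltilde_ic = params$Ltilde_ic,
    Lj = phys$Lj, Lic = phys$Li + phys$Lc,
    u = phys$u, vb = phys$vb, Qb = phys$Qb, Vb = phys$Vb,
    delta = phys$delta, t_end = t_end_eff, h = h, out_every = out_every,
    n_max = cap$n_max, distal_first = chain_order == "distal_first",
    alpha_track = alpha_mode == "track", traces = traces
  )
  if (res$n_overflow > 0) {
    warn(paste0(res$n_overflow, " bolus(es) exceeded intestinal capacity ",
                "and were retired early; residual drug logged as unabsorbed."))
  }

  series <- concentration_series(res$time_s, pmax(res$cbar, 0), "mg/L")
  boluses <- tibble::tibble(
    bolus = seq_len(nrow(emissions)),
    t_entry_s = emissions$time_s,
    volume_L = emissions$volume_L,
    C_entry = emissions$concentration,
    C_final = res$C_final,
    retired = res$retired,
    overflowed = res$overflowed,
    t_exit_s = res$retire_time,
    residual_mg = ifelse(res$retired, res$C_at_exit * emissions$volume_L,
                         NA_real_)
  )
  mass_in <- sum(emissions$volume_L * emissions$concentration)
  mass_now <- sum(emissions$volume_L * res$C_final)
  audit <- list(
    mass_entered_mg = mass_in,
    mass_in_boluses_mg = mass_now,
    absorbed_mg = res$absorbed_mg,
    net_blood_in_mg = res$net_in_mg,
    eliminated_mg = res$eliminated_mg,
    peripheral_mg = phys$Vb * series$concentration[nrow(series)],
    bolus_balance_relerr = if (mass_in > 0) {
      abs(mass_in - mass_now - res$absorbed_mg) / mass_in
    } else 0,
    max_contact_relerr = res$max_contact_relerr,
    n_overflow = res$n_overflow
  )
  trc <- if (traces && !is.null(res$traces)) tibble::as_tibble(res$traces)
         else NULL

  structure(
    list(series = series, boluses = boluses, audit = audit, traces = trc,
         params = params, phys = phys,
         config = list(h = h, dt_out = out_every * h, t_end = t_end_eff,
                       chain_order = chain_order, alpha_mode = alpha_mode)),
    class = "gut_sim"
  )
}

#' Full forward simulation: tablet to peripheral blood concentration
#'
#' Runs the gastro-duodenal stage ([run_gastroduodenal()]) and feeds the
#' emitted boluses into the intestinal absorption stage
#' ([simulate_intestine()]), returning the peripheral blood concentration
#' curve sampled on a regular grid.
#'
#' @inheritParams run_gastroduodenal
#' @inheritParams simulate_intestine
#' @param t_end total simulated time, s.
#' @param ... passed on to [simulate_intestine()].
#' @return A `gut_sim` object (see [simulate_intestine()]) with the
#'   gastro-duodenal stage attached as `$gastroduodenal`.
#' @examples
#' \donttest{
#' drug <- drug_properties("Aprepitant", dose_mg = 80)
#' sim <- simulate_gut(drug, published_params("Aprepitant"),
#'                     t_end = 12 * 3600)
#' head(sim$series)
#' }
#' @export
simulate_gut <- function(drug, params, phys = default_physiology(),
                         dose_mg = drug$dose_mg, Vs0 = 1,
                         t_end = 86400, dt_out = 300, dt_int = 30,
                         predissolved = FALSE, ...) {
  gd <- run_gastroduodenal(drug, phys, dose_mg = dose_mg, Vs0 = Vs0,
                           t_max = t_end, predissolved = predissolved)
  sim <- simulate_intestine(gd$emissions, params, phys, t_end = t_end,
                            dt_out = dt_out, dt_int = dt_int, ...)
  sim$gastroduodenal <- gd
  sim$drug <- drug
  sim$dose_mg <- dose_mg
  sim
}

#' @export
print.gut_sim <- function(x, ...) {
  pk <- summarize_peak(x$series)
  cat("<gut_sim>", if (!is.null(x$drug)) x$drug$name else "", "\n")
  cat(sprintf("  %d boluses, t_end = %.3g h, step %.3g s\n",
              nrow(x$boluses), x$config$t_end / 3600, x$config$h))
  cat(sprintf("  Cmax = %.4g mg/L at Tmax = %.3g h\n",
              pk$cmax, pk$tmax_s / 3600))
  invisible(x)
}

summarize_peak <- function(series) {
  i <- which.max(series$concentration)
  list(cmax = series$concentration[i], tmax_s = series$time_s[i])
}

#' @method as_tibble gut_sim
#' @export
as_tibble.gut_sim <- function(x, ...) x$series
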