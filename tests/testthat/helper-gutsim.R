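# Shared fixtures for the test suite. All inputs are constructed in code.

aprepitant <- function(dose = 80) drug_properties("Aprepitant", dose_mg = dose)

# physiology without secretions: volumes decay geometrically, closed forms hold
dry_physiology <- function(...) default_physiology(Qgj = 0, Qpj = 0, ...)

# a single bolus handed straight to the intestine stage
one_bolus <- function(time_s = 0, volume_L = 0.05, concentration = 100) {
  tibble::tibble(time_s = time_s, volume_L = volume_L,
                 concentration = concentration)
}

# independently coded dense-ODE reference for one bolus moving through the
# intestine (zero or positive delay), used as the integrator oracle
reference_single_bolus <- function(params, phys, Vbol_L, C0, t_out) {
  p <- gutsim:::resolve_peaks(params, phys)
  V <- Vbol_L * 1e-3
  rb <- (3 * V / (4 * pi))^(1 / 3)
  alpha <- function(x) {
    if (x < phys$Lj) {
      p$lambda_j / (pi * (1 + (x - p$Ltilde_j)^2))
    } else {
      p$lambda_ic / (pi * (1 + ((x - phys$Lj) - p$Ltilde_ic)^2))
    }
  }
  rhs <- function(t, y, parms) {
    a <- alpha(min(phys$u * t, phys$Lj + phys$Li + phys$Lc - 1e-12))
    K <- a * V / (pi * rb^2 * (phys$u + phys$vb))
    Cb0 <- if (phys$delta > 0) {
      if (t <= phys$delta) 0 else deSolve::lagvalue(t - phys$delta, 2)
    } else {
      y[2]
    }
    outlet <- Cb0 + K * (y[1] - Cb0)
    list(c(-a * (y[1] - Cb0),
           phys$Qb / phys$Vb * (outlet - y[2]) - p$kd * y[2]))
  }
  solver <- if (phys$delta > 0) deSolve::dede else deSolve::lsoda
  out <- solver(c(C = C0, Cbar = 0), times = t_out, func = rhs, parms = NULL,
                rtol = 1e-11, atol = 1e-14)
  out[, "Cbar"]
}
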