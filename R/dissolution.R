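#' pH-adjusted solubility (Henderson-Hasselbalch scaling)
#'
#' Scales the intrinsic solubility by the ionized fraction implied by the
#' Henderson-Hasselbalch relation:
#' \deqn{S_s = S_0\,(1 + 10^{\,pH - pKa}).}
#' The result is never below `S0`; the exponent is clamped to \eqn{\pm 30}
#' (with a warning) to avoid overflow for extreme pH/pKa combinations.
#'
#' @param S0 intrinsic solubility (any concentration unit; the result keeps it).
#' @param pH medium pH.
#' @param pKa drug pKa.
#' @return Adjusted solubility `Ss` in the unit of `S0`.
#' @examples
#' solubility_hh(1, pH = 7, pKa = 7) # doubles at pH == pKa
#' @export
solubility_hh <- function(S0, pH, pKa) {
  if (any(S0 <= 0)) abort("S0 must be positive.")
  expo <- pH - pKa
  if (any(abs(expo) > 30)) {
    warn("pH - pKa exponent clamped to +/-30 to avoid overflow.")
    expo <- pmin(pmax(expo, -30), 30)
  }
  S0 * (1 + 10^expo)
}

#' Dissolution rate constant (Noyes-Whitney form)
#'
#' \deqn{k_{sd} = \frac{3 D S_s}{4 \pi \rho}.}
#' Computed in the package's working units (D in m^2/s, `Ss` in mg/L, `rho`
#' in g/mL); the product `ksd * (Ss - Cs)` is used as a mg/s source term in
#' the gastric drug balance, so `ksd` carries the units that make that term
#' mg/s.
#'
#' @param D diffusion coefficient in gastric fluid, m^2/s.
#' @param Ss pH-adjusted solubility, mg/L.
#' @param rho solid drug density, g/mL.
#' @return Dissolution rate constant.
#' @examples
#' ksd_noyes_whitney(0.63e-9, 1e4, 1.51)
#' @export
ksd_noyes_whitney <- function(D, Ss, rho) {
  if (any(D < 0) || any(Ss < 0) || any(rho <= 0)) {
    abort("D and Ss must be >= 0 and rho > 0.")
  }
  3 * D * Ss / (4 * pi * rho)
}

#' Tablet radius shrink rate
#'
#' \deqn{\frac{dr_p}{dt} = -4\pi\rho\,r_p^2\,k_{sd}\,(S_s - C_s),}
#' evaluated as printed (note the \eqn{r_p^2} dependence). The rate is 0 when
#' no tablet remains (`rp = 0`) and is clamped at 0 when `Cs > Ss`
#' (supersaturation never re-grows the tablet).
#'
#' @param rp tablet radius, m.
#' @param ksd dissolution rate constant from [ksd_noyes_whitney()].
#' @param Ss pH-adjusted solubility, mg/L.
#' @param Cs gastric drug concentration, mg/L.
#' @param rho solid drug density, g/mL.
#' @return dr_p/dt, m/s (non-positive).
#' @export
radius_rate <- function(rp, ksd, Ss, Cs, rho) {
  if (any(rp < 0)) abort("rp must be >= 0.")
  rate <- -4 * pi * rho * rp^2 * ksd * (Ss - Cs)
  pmin(rate, 0)
}

#' Initial tablet radius from dose
#'
#' The whole dose is modeled as a single sphere of solid drug:
#' \deqn{r_p(0) = \left(\frac{3\,V_{tab}}{4\pi}\right)^{1/3}, \quad
#'   V_{tab} = \frac{dose}{\rho}.}
#'
#' @param dose_mg dose, mg.
#' @param rho solid drug density, g/mL.
#' @return Initial radius, m.
#' @examples
#' initial_radius(4 * pi / 3, 1) # 1 mm sphere
#' @export
initial_radius <- function(dose_mg, rho) {
  if (any(dose_mg <= 0) || any(rho <= 0)) abort("dose_mg and rho must be > 0.")
  v_m3 <- dose_mg / (rho * 1000) * 1e-6 # mg / (mg/mL) = mL -> m^3
  (3 * v_m3 / (4 * pi))^(1 / 3)
}
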