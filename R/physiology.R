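#' Default gastrointestinal physiology
#'
#' Returns the physiological constants used by the simulator: transit and
#' emptying parameters for the gastro-duodenal stage, geometry and velocities
#' for the intestinal stage, and the peripheral-circulation constants. The
#' defaults describe a fasted adult with a ~1 L gastric load.
#'
#' @details
#' Fields (all SI except where noted):
#' \describe{
#'   \item{delta}{peripheral-circulation transit delay, s (default 90;
#'     0 disables the recirculation lag, a limit used in verification).}
#'   \item{Te}{gastric emptying period, s (default 600; the emptying
#'     frequency is \code{fe = 1/Te}).}
#'   \item{emptying_fraction}{fraction of the gastric volume discharged into
#'     the duodenum at each emptying event (default 1/20).}
#'   \item{vb}{blood velocity in the intestinal wall circulation, m/s
#'     (default 0.21).}
#'   \item{u}{bolus transit velocity, m/s (default 1 m/h = 1/3600 m/s).}
#'   \item{Qb}{intestinal blood flow rate, L/s (default 0.033).}
#'   \item{Lj, Li, Lc}{jejunum, ileum and colon lengths, m (2, 4, 1.5).}
#'   \item{Vb}{peripheral blood volume, L (default 4).}
#'   \item{rint}{intestinal radius, m (default 0.01).}
#'   \item{gastric_pH}{fasted gastric pH used by the pH-dependent solubility
#'     (default 2.0).}
#'   \item{Qgj, Qpj}{gastric and pancreatic juice secretion rates, L/s
#'     (defaults 2.3e-5 and 1.2e-5, roughly 2 L/day and 1 L/day). Set both
#'     to 0 for a pure-emptying stomach/duodenum.}
#'   \item{V_stop_frac}{gastro-duodenal simulation stops once the gastric
#'     volume falls below this fraction of its initial value (default 0.01).}
#' }
#'
#' @param ... named overrides for any field above.
#' @return A named list of class `gut_physiology`.
#' @examples
#' phys <- default_physiology(Qgj = 0, Qpj = 0)
#' phys$u * 3600 # bolus velocity in m/h
#' @export
default_physiology <- function(...) {
  phys <- list(
    delta = 90,
    Te = 600,
    emptying_fraction = 1 / 20,
    vb = 0.21,
    u = 1 / 3600,
    Qb = 0.033,
    Lj = 2,
    Li = 4,
    Lc = 1.5,
    Vb = 4,
    rint = 0.01,
    gastric_pH = 2.0,
    Qgj = 2.3e-5,
    Qpj = 1.2e-5,
    V_stop_frac = 0.01
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(phys))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0(
        "Unknown physiology field(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    phys <- modifyList(phys, dots)
  }
  validate_physiology(phys)
}

validate_physiology <- function(phys) {
  pos <- c(
    "Te", "vb", "u", "Qb", "Lj", "Li", "Lc", "Vb", "rint"
  )
  for (f in pos) {
    if (!is.numeric(phys[[f]]) || length(phys[[f]]) != 1 ||
        !is.finite(phys[[f]]) || phys[[f]] <= 0) {
      abort(paste0("Physiology field '", f, "' must be a positive number."))
    }
  }
  for (f in c("Qgj", "Qpj", "delta")) {
    if (!is.numeric(phys[[f]]) || phys[[f]] < 0) {
      abort(paste0("Physiology field '", f, "' must be >= 0."))
    }
  }
  for (f in c("emptying_fraction", "V_stop_frac")) {
    v <- phys[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      abort(paste0("Physiology field '", f, "' must lie in (0, 1)."))
    }
  }
  structure(phys, class = "gut_physiology")
}

#' @export
print.gut_physiology <- function(x, ...) {
  cat("<gut_physiology>\n")
  cat(sprintf("  emptying: every %g s, fraction %.4g; stop below %g%% of Vs(0)\n",
              x$Te, x$emptying_fraction, 100 * x$V_stop_frac))
  cat(sprintf("  intestine: Lj=%g m, Li=%g m, Lc=%g m, r=%g m, u=%g m/s\n",
              x$Lj, x$Li, x$Lc, x$rint, x$u))
  cat(sprintf("  blood: vb=%g m/s, Qb=%g L/s, Vb=%g L, delay=%g s\n",
              x$vb, x$Qb, x$Vb, x$delta))
  cat(sprintf("  secretions: Qgj=%g L/s, Qpj=%g L/s; gastric pH %g\n",
              x$Qgj, x$Qpj, x$gastric_pH))
  invisible(x)
}

#' Maximum number of boluses the intestine can hold
#'
#' Boluses enter the jejunum every emptying period `Te` and travel at
#' velocity `u`, so a segment of length L holds at most
#' `floor(L / (u * Te))` boluses at any one time.
#'
#' @param phys physiology from [default_physiology()].
#' @return A tibble with one row: `n_max_ileocolon` (ileum + colon) and
#'   `n_max` (whole intestine).
#' @examples
#' bolus_capacity(default_physiology())
#' @export
bolus_capacity <- function(phys = default_physiology()) {
  fe <- 1 / phys$Te
  tibble::tibble(
    n_max_ileocolon = as.integer(floor((phys$Li + phys$Lc) * fe / phys$u)),
    n_max = as.integer(floor((phys$Lj + phys$Li + phys$Lc) * fe / phys$u))
  )
}
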