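#' Simulate the stomach and duodenum with discrete emptying events
#'
#' The stomach and duodenum are continuously stirred compartments punctuated
#' by discrete emptying events every `Te` seconds. Between events the gastric
#' volume grows with gastric juice secretion (`dVs/dt = Qgj`), the gastric
#' drug mass grows with tablet dissolution
#' (`d(Vs Cs)/dt = ksd (Ss - Cs)`), the duodenal volume grows with pancreatic
#' juice (`dVd/dt = Qpj`) and the duodenal drug mass is constant. The tablet
#' radius shrinks in parallel per [radius_rate()]. At each event time
#' `tk = k Te`, in order: the duodenum discharges its whole content into the
#' jejunum as a bolus (volume `Vd(tk-)`, concentration `Cd(tk-)`); the
#' stomach transfers a fraction `emptying_fraction` of its volume to the
#' duodenum, so `Vs(tk+) = (1 - f) Vs(tk-)`, `Vd(tk+) = f Vs(tk-)`, and the
#' new duodenal concentration equals the (continuous) gastric concentration
#' `Cs(tk-)`.
#'
#' Dissolution terminates when either the cumulative dissolved mass reaches
#' the dose (hard mass cap) or the tablet radius reaches zero, whichever
#' happens first; the triggering event is recorded. The stage stops at
#' `t_max` or once the gastric volume falls below `V_stop_frac * Vs0`.
#'
#' @param drug a `gut_drug`, see [drug_properties()].
#' @param phys physiology from [default_physiology()].
#' @param dose_mg dose in mg (defaults to `drug$dose_mg`).
#' @param Vs0 initial gastric volume, L (meal + fluid).
#' @param t_max maximum simulated time, s.
#' @param predissolved if TRUE the whole dose starts dissolved in the gastric
#'   fluid (`Cs(0) = dose/Vs0`, no tablet); if FALSE (default) the dose starts
#'   as an undissolved tablet and `Cs(0) = 0`.
#' @param dt_traj trajectory output step, s.
#' @return A list of class `gut_gd`:
#' \describe{
#'   \item{emissions}{tibble of boluses handed to the intestine: `time_s`,
#'     `volume_L`, `concentration` (mg/L). Zero-volume discharges are dropped.}
#'   \item{events}{tibble logging every emptying event (volumes and
#'     concentrations immediately before/after, emitted bolus).}
#'   \item{trajectory}{tibble of `time_s`, `Vs_L`, `Cs_mg_L`, `Vd_L`,
#'     `Cd_mg_L`, `rp_m`, `dissolved_mg`.}
#'   \item{dissolution}{list: `terminated`, `reason`, `time_s`.}
#' }
#' @examples
#' drug <- drug_properties("Aprepitant", dose_mg = 80)
#' gd <- run_gastroduodenal(drug, default_physiology(Qgj = 0, Qpj = 0),
#'                          t_max = 7200)
#' gd$emissions
#' @export
run_gastroduodenal <- function(drug, phys = default_physiology(),
                               dose_mg = drug$dose_mg, Vs0 = 1,
                               t_max = 86400, predissolved = FALSE,
                               dt_traj = 60) {
  stopifnot(inherits(drug, "gut_drug"), inherits(phys, "gut_physiology"))
  if (is.null(dose_mg)) abort("dose_mg is required (drug fixture has none).")
  if (!is.numeric(Vs0) || Vs0 <= 0) abort("Vs0 must be > 0.")
  if (!is.numeric(t_max) || t_max <= 0 || !is.finite(t_max)) {
    abort("t_max must be a positive finite time in seconds.")
  }

  Ss <- solubility_hh(drug$S0_mg_L, phys$gastric_pH, drug$pKa)
  p <- list(
    Qgj = phys$Qgj, Qpj = phys$Qpj, rho = drug$rho, dose = dose_mg,
    Ss = Ss,
    ksd = ksd_noyes_whitney(drug$D, Ss, drug$rho)
  )

  # state: Vs, Ms (= Vs*Cs), Vd, Md, rp, mdis
  if (predissolved) {
    y <- c(Vs = Vs0, Ms = dose_mg, Vd = 0, Md = 0, rp = 0, mdis = dose_mg)
    diss_active <- FALSE
  } else {
    y <- c(Vs = Vs0, Ms = 0, Vd = 0, Md = 0,
           rp = initial_radius(dose_mg, drug$rho), mdis = 0)
    diss_active <- TRUE
  }

  rhs <- function(t, y, parms) {
    Cs <- y[2] / y[1]
    s <- if (parms$active) max(parms$ksd * (parms$Ss - Cs), 0) else 0
    drp <- if (parms$active) {
      radius_rate(max(y[5], 0), parms$ksd, parms$Ss, Cs, parms$rho)
    } else 0
    list(c(parms$Qgj, s, parms$Qpj, 0, drp, s))
  }
  rootfun <- function(t, y, parms) c(parms$dose - y[6], y[5])

  diss_info <- list(terminated = predissolved,
                    reason = if (predissolved) "predissolved" else NA_character_,
                    time_s = if (predissolved) 0 else NA_real_)

  integrate_interval <- function(y, t0, t1) {
    times <- unique(c(seq(t0, t1, by = dt_traj), t1))
    segs <- list()
    while (TRUE) {
      p$active <- diss_active
      sol <- deSolve::lsodar(
        y = y, times = times, func = rhs, parms = p,
        rootfunc = if (diss_active) rootfun else NULL,
        rtol = 1e-8, atol = 1e-12
      )
      if (any(!is.finite(sol[nrow(sol), -1]))) {
        abort("Non-finite gastro-duodenal state; aborting.")
      }
      segs[[length(segs) + 1]] <- sol
      t_last <- sol[nrow(sol), 1]
      if (diss_active && t_last < t1 - 1e-9) {
        # dissolution-termination root hit inside the interval
        y <- sol[nrow(sol), -1]
        hit_cap <- abs(p$dose - y[["mdis"]]) <= abs(y[["rp"]])
        y[["mdis"]] <- min(y[["mdis"]], p$dose)
        y[["rp"]] <- max(y[["rp"]], 0)
        diss_active <<- FALSE
        diss_info <<- list(
          terminated = TRUE,
          reason = if (hit_cap) "dose_cap" else "radius_zero",
          time_s = t_last
        )
        times <- unique(c(t_last, times[times > t_last], t1))
        next
      }
      break
    }
    traj <- do.call(rbind, lapply(segs, function(s) s[, , drop = FALSE]))
    list(y = traj[nrow(traj), -1], traj = traj[!duplicated(traj[, 1]), ])
  }

  f <- phys$emptying_fraction
  events <- list()
  traj <- list()
  t_now <- 0
  k <- 0
  repeat {
    tk <- (k + 1) * phys$Te
    if (tk > t_max + 1e-9) break
    res <- integrate_interval(y, t_now, tk)
    y <- res$y
    traj[[length(traj) + 1]] <- res$traj
    k <- k + 1
    # event: duodenum empties fully, then stomach transfers fraction f
    Vs_m <- y[["Vs"]]; Ms_m <- y[["Ms"]]
    Vd_m <- y[["Vd"]]; Md_m <- y[["Md"]]
    Cs_m <- Ms_m / Vs_m
    bolus_V <- Vd_m
    bolus_C <- if (Vd_m > 0) Md_m / Vd_m else 0
    y[["Vd"]] <- f * Vs_m
    y[["Md"]] <- f * Ms_m
    y[["Vs"]] <- (1 - f) * Vs_m
    y[["Ms"]] <- (1 - f) * Ms_m
    events[[k]] <- tibble::tibble(
      k = k, time_s = tk,
      Vs_before_L = Vs_m, Vs_after_L = y[["Vs"]],
      Cs_mg_L = Cs_m,
      Vd_before_L = Vd_m, Cd_before_mg_L = bolus_C,
      Vd_after_L = y[["Vd"]], Cd_after_mg_L = Cs_m,
      bolus_volume_L = bolus_V, bolus_concentration_mg_L = bolus_C,
      emitted = bolus_V > 0
    )
    t_now <- tk
    if (y[["Vs"]] < phys$V_stop_frac * Vs0) break
  }

  events <- if (length(events)) dplyr::bind_rows(events) else tibble::tibble(
    k = integer(), time_s = numeric(), Vs_before_L = numeric(),
    Vs_after_L = numeric(), Cs_mg_L = numeric(), Vd_before_L = numeric(),
    Cd_before_mg_L = numeric(), Vd_after_L = numeric(),
    Cd_after_mg_L = numeric(), bolus_volume_L = numeric(),
    bolus_concentration_mg_L = numeric(), emitted = logical()
  )
  emissions <- events |>
    dplyr::filter(.data$emitted) |>
    dplyr::transmute(
      time_s = .data$time_s,
      volume_L = .data$bolus_volume_L,
      concentration = .data$bolus_concentration_mg_L
    )

  traj <- do.call(rbind, traj)
  trajectory <- tibble::tibble(
    time_s = traj[, "time"],
    Vs_L = traj[, "Vs"], Cs_mg_L = traj[, "Ms"] / traj[, "Vs"],
    Vd_L = traj[, "Vd"],
    Cd_mg_L = ifelse(traj[, "Vd"] > 0, traj[, "Md"] / traj[, "Vd"], 0),
    rp_m = traj[, "rp"], dissolved_mg = traj[, "mdis"]
  )

  structure(
    list(
      emissions = emissions, events = events, trajectory = trajectory,
      dissolution = diss_info,
      final_state = y, dose_mg = dose_mg, Vs0 = Vs0, drug = drug, phys = phys,
      predissolved = predissolved
    ),
    class = "gut_gd"
  )
}

#' @export
print.gut_gd <- function(x, ...) {
  cat("<gut_gd> gastro-duodenal stage:", x$drug$name, "\n")
  cat(sprintf("  %d emptying events, %d boluses emitted, final Vs = %.4g L\n",
              nrow(x$events), nrow(x$emissions), x$final_state[["Vs"]]))
  cat(sprintf("  dissolved %.4g of %.4g mg%s\n",
              min(x$final_state[["mdis"]], x$dose_mg), x$dose_mg,
              if (isTRUE(x$dissolution$terminated) &&
                  !is.na(x$dissolution$reason))
                paste0(" (", x$dissolution$reason, ")") else ""))
  invisible(x)
}
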