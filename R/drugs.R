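#' Packaged drug property fixtures
#'
#' Nine drugs ship with the package, each described by its intrinsic water
#' solubility `S0` (mol/L), diffusion coefficient in gastric fluid `D`
#' (m\eqn{^2}/s), solid density `rho` (g/mL), `pKa`, and molar mass (g/mol,
#' used to convert molar solubilities to mg/L). `drug_fixtures()` lists all
#' of them; `drug_properties()` loads one by name.
#'
#' @param name drug name (case-insensitive). "Ketokenazole" is accepted as
#'   an alias for Ketoconazole.
#' @param dose_mg administered dose in mg; optional at load time, required
#'   before simulating.
#' @return `drug_properties()`: a list of class `gut_drug` with fields
#'   `name`, `S0`, `D`, `rho`, `pKa`, `molar_mass`, `dose_mg` and the derived
#'   `S0_mg_L`. `drug_fixtures()`: a tibble with one row per packaged drug.
#' @examples
#' drug_properties("Aprepitant", dose_mg = 80)
#' drug_fixtures()
#' @export
drug_properties <- function(name, dose_mg = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  key <- tolower(name)
  if (key == "ketokenazole") key <- "ketoconazole"
  dir <- system.file("extdata", "drugs", package = "gutsim")
  files <- list.files(dir, pattern = "\\.json$")
  avail <- sub("\\.json$", "", files)
  if (!key %in% avail) {
    abort(paste0(
      "Unknown drug '", name, "'. Packaged fixtures: ",
      paste(sort(tools::toTitleCase(avail)), collapse = ", "), "."
    ))
  }
  rec <- jsonlite::read_json(file.path(dir, paste0(key, ".json")),
                             simplifyVector = TRUE)
  new_gut_drug(rec, dose_mg)
}

new_gut_drug <- function(rec, dose_mg = NULL) {
  needed <- c("name", "S0", "D", "rho", "pKa", "molar_mass")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    abort(paste0("Drug record lacks field(s): ", paste(missing, collapse = ", ")))
  }
  for (f in c("S0", "D", "rho", "molar_mass")) {
    if (!is.numeric(rec[[f]]) || rec[[f]] <= 0) {
      abort(paste0("Drug field '", f, "' must be positive."))
    }
  }
  if (rec$pKa <= -2 || rec$pKa >= 20) {
    abort("Drug pKa outside the plausible range (-2, 20).")
  }
  if (!is.null(dose_mg)) {
    if (!is.numeric(dose_mg) || dose_mg <= 0) abort("dose_mg must be positive.")
  }
  structure(
    list(
      name = rec$name,
      S0 = rec$S0,
      D = rec$D,
      rho = rec$rho,
      pKa = rec$pKa,
      molar_mass = rec$molar_mass,
      dose_mg = dose_mg,
      S0_mg_L = mol_per_L_to_mg_per_L(rec$S0, rec$molar_mass)
    ),
    class = "gut_drug"
  )
}

#' @rdname drug_properties
#' @export
drug_fixtures <- function() {
  dir <- system.file("extdata", "drugs", package = "gutsim")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  purrr::map_dfr(files, function(f) {
    rec <- jsonlite::read_json(f, simplifyVector = TRUE)
    tibble::as_tibble(rec)
  }) |>
    dplyr::arrange(.data$name)
}

#' @export
print.gut_drug <- function(x, ...) {
  cat("<gut_drug> ", x$name, "\n", sep = "")
  cat(sprintf("  S0 = %g mol/L (%.4g mg/L), D = %g m^2/s, rho = %g g/mL, pKa = %g\n",
              x$S0, x$S0_mg_L, x$D, x$rho, x$pKa))
  cat(sprintf("  molar mass = %g g/mol; dose = %s\n", x$molar_mass,
              if (is.null(x$dose_mg)) "unset" else paste0(x$dose_mg, " mg")))
  invisible(x)
}

#' Absorption parameters of the intestinal model
#'
#' The intestinal wall permeability profile is a Cauchy-shaped function of
#' the axial coordinate in each segment,
#' \deqn{\alpha_l(x) = \frac{\lambda_l}{\pi\,(1 + (x - \tilde L_l)^2)},}
#' with scale \eqn{\lambda_j} in the jejunum and \eqn{\lambda_{ic}} in the
#' ileum-colon, and `kd` the first-order elimination rate in the peripheral
#' circulation. These three are the quantities estimated from observed
#' concentration curves by [fit_absorption()].
#'
#' All values are in absolute SI units: `lambda_j`, `lambda_ic` in m\eqn{^2}/s
#' (published tables often quote them on a 1e-3 scale), `kd` in 1/s. Peak
#' locations `Ltilde_j` and `Ltilde_ic` are segment-local coordinates in m;
#' when `NULL` they default to `Lj/3` and `(Lj+Li+Lc)/5` at simulation time.
#'
#' @param lambda_j jejunal Cauchy scale, m^2/s.
#' @param lambda_ic ileum-colon Cauchy scale, m^2/s.
#' @param kd peripheral elimination rate constant, 1/s.
#' @param Ltilde_j jejunal peak location, m from the jejunum inlet, or NULL.
#' @param Ltilde_ic ileum-colon peak location, m from the ileum inlet, or NULL.
#' @return A list of class `gut_absorption`.
#' @examples
#' absorption_params(5.157e-3, 5.100e-3, 2.012e-5)
#' @export
absorption_params <- function(lambda_j, lambda_ic, kd,
                              Ltilde_j = NULL, Ltilde_ic = NULL) {
  for (v in list(lambda_j, lambda_ic, kd)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort("lambda_j, lambda_ic and kd must be single non-negative numbers.")
    }
  }
  for (v in list(Ltilde_j, Ltilde_ic)) {
    if (!is.null(v) && (!is.numeric(v) || v < 0)) {
      abort("Peak locations must be non-negative or NULL.")
    }
  }
  structure(
    list(lambda_j = lambda_j, lambda_ic = lambda_ic, kd = kd,
         Ltilde_j = Ltilde_j, Ltilde_ic = Ltilde_ic),
    class = "gut_absorption"
  )
}

#' @export
print.gut_absorption <- function(x, ...) {
  cat("<gut_absorption>\n")
  cat(sprintf("  lambda_j  = %.6g m^2/s (%.4g on the 1e-3 scale)\n",
              x$lambda_j, x$lambda_j * 1e3))
  cat(sprintf("  lambda_ic = %.6g m^2/s (%.4g on the 1e-3 scale)\n",
              x$lambda_ic, x$lambda_ic * 1e3))
  cat(sprintf("  kd        = %.6g 1/s (%.4g on the 1e-5 scale)\n",
              x$kd, x$kd * 1e5))
  if (!is.null(x$Ltilde_j) || !is.null(x$Ltilde_ic)) {
    cat(sprintf("  peaks: Ltilde_j = %s m, Ltilde_ic = %s m (segment-local)\n",
                format(x$Ltilde_j %||% NA), format(x$Ltilde_ic %||% NA)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fill peak-location defaults from physiology (segment-local coordinates).
resolve_peaks <- function(params, phys) {
  params$Ltilde_j <- params$Ltilde_j %||% (phys$Lj / 3)
  params$Ltilde_ic <- params$Ltilde_ic %||% ((phys$Lj + phys$Li + phys$Lc) / 5)
  if (params$Ltilde_j > phys$Lj) {
    abort("Ltilde_j outside the jejunum [0, Lj].")
  }
  if (params$Ltilde_ic > phys$Li + phys$Lc) {
    abort("Ltilde_ic outside the ileum-colon [0, Li + Lc].")
  }
  params
}

#' Published absorption-parameter estimates
#'
#' Fitted `(lambda_j, lambda_ic, kd)` triples for ten drugs, as published
#' (lambda on the 1e-3 m^2/s scale, kd on the 1e-5 1/s scale in the source
#' table; returned here converted to absolute SI units). These make
#' realistic test points for forward simulation; they are not refit targets.
#'
#' @param name drug name (case-insensitive; "Ketokenazole" maps to
#'   Ketoconazole).
#' @return A `gut_absorption` object.
#' @examples
#' published_params("Fenofibrate")
#' @export
published_params <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  path <- system.file("extdata", "fitted_params.json", package = "gutsim")
  tbl <- jsonlite::read_json(path, simplifyVector = TRUE)$drugs
  key <- tolower(name)
  if (key == "ketokenazole") key <- "ketoconazole"
  hit <- match(key, tolower(names(tbl)))
  if (is.na(hit)) {
    abort(paste0(
      "No published parameter estimates for '", name, "'. Available: ",
      paste(sort(names(tbl)), collapse = ", "), "."
    ))
  }
  rec <- tbl[[hit]]
  absorption_params(
    lambda_j = rec$lambda_j * 1e-3,
    lambda_ic = rec$lambda_ic * 1e-3,
    kd = rec$kd * 1e-5
  )
}
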