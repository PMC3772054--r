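#' Geometry and conversion constants
#'
#' Constants describing the in-vitro culture geometry and the membrane
#' conversion factors used to couple per-cell molecule counts to molar
#' concentrations. Defaults correspond to 25,000 NK cells cultured in
#' 200 uL of media, an endosomal volume of 1e-14 L per cell, and the
#' surface/endosomal membrane-shell conversion factors.
#'
#' @param N_A Avogadro's number (mol^-1).
#' @param V_m culture media volume (L).
#' @param V_e total endosomal volume per cell (L).
#' @param N_tot number of NK cells in the culture.
#' @param xi_surf surface conversion factor (M per molecule): effective molar
#'   concentration contributed by one membrane-bound molecule at the cell
#'   surface.
#' @param xi_endo endosomal membrane conversion factor (M per molecule).
#' @param MW_IL15 effective molar mass of IL-15 (g/mol); 15,000 reproduces the
#'   standard dose table (1 ng/ml = 0.0667 nM, 2000 ng/ml = 133 nM).
#' @return An object of class `il15_geometry` (a named list).
#' @export
geometry_constants <- function(N_A = 6.022e23,
                               V_m = 2e-4,
                               V_e = 1e-14,
                               N_tot = 25000,
                               xi_surf = 1.1e-9,
                               xi_endo = 1.5e-8,
                               MW_IL15 = 15000) {
  g <- list(N_A = N_A, V_m = V_m, V_e = V_e, N_tot = N_tot,
            xi_surf = xi_surf, xi_endo = xi_endo, MW_IL15 = MW_IL15)
  if (any(!vapply(g, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
                  logical(1)))) {
    stop("all geometry constants must be single strictly positive numbers")
  }
  structure(g, class = "il15_geometry")
}

#' IL-15 dose
#'
#' A tagged concentration of soluble IL-15 in the culture media.
#'
#' @param value non-negative scalar concentration.
#' @param unit one of `"ng/ml"`, `"nM"`, `"M"`.
#' @return An object of class `il15_dose`.
#' @export
dose <- function(value, unit = c("ng/ml", "nM", "M")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop("dose value must be a single non-negative number")
  }
  structure(list(value = value, unit = unit), class = "il15_dose")
}

#' @export
print.il15_dose <- function(x, ...) {
  cat(sprintf("IL-15 dose: %g %s\n", x$value, x$unit))
  invisible(x)
}

as_dose <- function(d) {
  if (inherits(d, "il15_dose")) return(d)
  if (is.numeric(d) && length(d) == 1L) return(dose(d, "ng/ml"))
  stop("expected an `il15_dose` or a single number of ng/ml")
}

#' Convert a dose to molar concentration
#'
#' Mass concentrations (ng/ml) are converted through the effective molar mass
#' of IL-15; molar units are rescaled directly.
#'
#' @param d an [dose()] object (a bare number is taken as ng/ml).
#' @param g [geometry_constants()].
#' @return Concentration in mol/L.
#' @export
dose_to_molar <- function(d, g = geometry_constants()) {
  d <- as_dose(d)
  switch(d$unit,
    "ng/ml" = d$value * 1e-6 / g$MW_IL15,  # ng/ml = 1e-6 g/L
    "nM"    = d$value * 1e-9,
    "M"     = d$value,
    stop("unknown dose unit: ", d$unit)
  )
}

#' Convert a molar concentration back to a dose
#'
#' Inverse of [dose_to_molar()]; round-trips are exact to floating-point
#' precision.
#'
#' @param molar concentration in mol/L.
#' @param unit target unit.
#' @inheritParams dose_to_molar
#' @return An [dose()] object.
#' @export
molar_to_dose <- function(molar, unit = c("ng/ml", "nM", "M"),
                          g = geometry_constants()) {
  unit <- match.arg(unit)
  if (!is.numeric(molar) || length(molar) != 1L || is.na(molar) || molar < 0) {
    stop("molar concentration must be a single non-negative number")
  }
  value <- switch(unit,
    "ng/ml" = molar * g$MW_IL15 / 1e-6,
    "nM"    = molar / 1e-9,
    "M"     = molar
  )
  dose(value, unit)
}

#' Effective molar concentration of a membrane species
#'
#' A per-cell membrane molecule count is converted to an effective molar
#' concentration in the membrane shell via a conversion factor (M per
#' molecule). Used to let a membrane ligand enter a mass-action term with a
#' rate constant in M^-1 h^-1.
#'
#' @param count molecules per cell (non-negative; vectorized).
#' @param xi conversion factor, M per molecule.
#' @return Effective concentration in M.
#' @export
surface_effective_conc <- function(count, xi) {
  if (any(count < 0, na.rm = TRUE)) stop("molecule count must be non-negative")
  count * xi
}

#' Convert a per-cell molecular flux to a bulk media rate
#'
#' Couples per-cell surface fluxes (molecules/cell/h) to the bulk ligand
#' balance: the total molecular flux over `N_tot` cells divided by Avogadro's
#' number and the media volume. Linear and sign-preserving.
#'
#' @param flux molecules/cell/h (vectorized; may be negative).
#' @inheritParams dose_to_molar
#' @return Rate in M/h.
#' @export
percell_flux_to_media_rate <- function(flux, g = geometry_constants()) {
  if (any(!is.finite(flux))) stop("flux must be finite")
  flux * g$N_tot / (g$N_A * g$V_m)
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` (or `key: value`) lines, one per line; `#` starts a
#' comment. Keys use the field's symbol names (N_tot, V_m, V_e, xi_surf,
#' xi_endo, k_f, k_r, ...). Values are numeric; scientific notation accepted.
#'
#' @param path path to the config file.
#' @return Named numeric vector.
#' @export
read_param_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, character(1), 2L))))
  if (any(is.na(vals))) stop("non-numeric config value(s) for: ",
                             paste(keys[is.na(vals)], collapse = ", "))
  stats::setNames(vals, keys)
}
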