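#' @importFrom deSolve lsoda
NULL

#' Initial state of the intermediate-affinity model
#'
#' 800 free surface receptors per cell, no complexes, no endosomal content,
#' ligand at the stimulating concentration.
#'
#' @param L0 initial media ligand concentration (M).
#' @param R_s0 initial free surface receptors per cell.
#' @return Named numeric state vector.
#' @export
intermediate_initial_state <- function(L0, R_s0 = 800) {
  c(R_s = R_s0, C_s = 0, R_e = 0, C_e = 0, L = L0, L_e = 0,
    deg_R = 0, deg_C = 0, syn_total = 0)
}

#' Time derivative of the intermediate-affinity system
#'
#' Mass-action binding at the surface (`k_f`, `k_r`) and in the endosome
#' (`k_fe`, `k_re`), constitutive (`k_endo`) and ligand-induced (`k_int`)
#' internalization, endosomal ligand recycling (`k_rec`), lysosomal
#' degradation of endosomal receptors and complexes (`k_deg`, destroying the
#' complexed ligand with the complex), and constitutive plus complex-induced
#' receptor synthesis (`k_s`, `k_syn`). Per-cell surface fluxes couple to the
#' bulk ligand through [percell_flux_to_media_rate()]; endosomal
#' concentrations live in the per-cell endosomal volume `V_e`.
#'
#' @param state named state vector (see [intermediate_initial_state()]).
#' @param p [intermediate_params()].
#' @param g [geometry_constants()].
#' @return Named vector of time derivatives (per hour).
#' @export
intermediate_rhs <- function(state, p, g = geometry_constants()) {
  if (any(!is.finite(state))) stop("non-finite state")
  if (any(state[INTERMEDIATE_SPECIES] < 0)) stop("negative species in state")
  drv <- intermediate_deriv(0, state, list(p = p, g = g))[[1]]
  names(drv) <- names(state)[seq_along(drv)]
  drv
}

# deSolve-format derivative; shared by intermediate_rhs and the integrator.
intermediate_deriv <- function(t, y, parms) {
  p <- parms$p
  g <- parms$g
  bind_s <- p$k_f * y[["L"]] * y[["R_s"]]          # molecules/cell/h
  bind_e <- p$k_fe * y[["L_e"]] * y[["R_e"]]
  dR_s <- p$k_s + p$k_syn * y[["C_s"]] - bind_s + p$k_r * y[["C_s"]] -
    p$k_endo * y[["R_s"]]
  dC_s <- bind_s - (p$k_r + p$k_int) * y[["C_s"]]
  dR_e <- p$k_endo * y[["R_s"]] + p$k_re * y[["C_e"]] - bind_e -
    p$k_deg * y[["R_e"]]
  dC_e <- p$k_int * y[["C_s"]] + bind_e - (p$k_re + p$k_deg) * y[["C_e"]]
  dL <- percell_flux_to_media_rate(p$k_r * y[["C_s"]] - bind_s, g) +
    p$k_rec * y[["L_e"]] * (g$V_e * g$N_tot / g$V_m)
  dL_e <- (p$k_re * y[["C_e"]] - bind_e) / (g$N_A * g$V_e) -
    p$k_rec * y[["L_e"]]
  list(c(dR_s, dC_s, dR_e, dC_e, dL, dL_e,
         p$k_deg * y[["R_e"]],
         p$k_deg * y[["C_e"]],
         p$k_s + p$k_syn * y[["C_s"]]))
}

integrate_model <- function(deriv, y0, times, p, g, rtol = 1e-10,
                            label = "model") {
  atol <- ifelse(names(y0) %in% c("L", "L_e"), 1e-24, 1e-10)
  out <- try(deSolve::lsoda(y = y0, times = times, func = deriv,
                            parms = list(p = p, g = g), rtol = rtol,
                            atol = atol, maxsteps = 50000), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    stop(sprintf("%s integration failed (L0 = %g M); parameters: %s", label,
                 y0[["L"]],
                 paste(sprintf("%s=%g", names(p)[vapply(p, is.numeric, TRUE)],
                               unlist(p[vapply(p, is.numeric, TRUE)])),
                       collapse = ", ")))
  }
  out
}

new_timecourse <- function(out, d, p, g, species, accum) {
  df <- as.data.frame(out)
  names(df)[1] <- "time_h"
  structure(list(times = df$time_h, states = df, dose = d, params = p,
                 geometry = g, species = species, accumulators = accum),
            class = "il15_timecourse")
}

#' @export
print.il15_timecourse <- function(x, ...) {
  cat(sprintf("IL-15 model timecourse: %g %s, t in [0, %g] h, %d points\n",
              x$dose$value, x$dose$unit, max(x$times), length(x$times)))
  last <- x$states[nrow(x$states), x$species]
  cat("final state:\n")
  print(round(unlist(last), 4))
  invisible(x)
}

#' Simulate the intermediate-affinity model
#'
#' Stiff-capable integration (lsoda, relative tolerance 1e-10) from the
#' standard initial conditions. Species are reported clipped at zero
#' (integrator noise only); the derivative itself never clips.
#'
#' @param d IL-15 dose ([dose()] or a number of ng/ml).
#' @param p [intermediate_params()].
#' @param g [geometry_constants()].
#' @param t_end end time (h).
#' @param times optional explicit output grid (h), starting at 0.
#' @return An `il15_timecourse`: `$states` is a wide data.frame with a
#'   `time_h` column, per-cell counts, molar ligand columns, and cumulative
#'   degradation/synthesis accumulators.
#' @export
simulate_intermediate <- function(d, p = intermediate_params(),
                                  g = geometry_constants(),
                                  t_end = 48, times = NULL) {
  d <- as_dose(d)
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = 241)
  }
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  y0 <- intermediate_initial_state(dose_to_molar(d, g))
  out <- integrate_model(intermediate_deriv, y0, times, p, g,
                         label = "intermediate model")
  out[, -1][out[, -1] < 0 & out[, -1] > -1e-9] <- 0
  new_timecourse(out, d, p, g, INTERMEDIATE_SPECIES, INTERMEDIATE_ACCUM)
}

#' Algebraic steady state of the intermediate-affinity model
#'
#' Solves the surface balance with the media ligand held at the dose (ligand
#' depletion is negligible; see the ligand non-depletion property):
#' \deqn{C_s = k_f L R_s / (k_r + k_int)}
#' \deqn{k_s + (k_syn + k_r) C_s = (k_f L + k_endo) R_s}
#' Endosomal fixed points follow with rebinding neglected (`k_fe L_e` is
#' vanishingly small at default values). A finite steady state requires the
#' net surface drain to exceed induced synthesis; otherwise complexes grow
#' without bound and an error is raised.
#'
#' @inheritParams simulate_intermediate
#' @return An `il15_steady_state` list: `R_s`, `C_s`, `R_e`, `C_e`, `L_e`,
#'   `total_surface` (= R_s + C_s), `dose`, `converged`.
#' @export
steady_state_intermediate <- function(d, p = intermediate_params(),
                                      g = geometry_constants()) {
  d <- as_dose(d)
  L <- dose_to_molar(d, g)
  kfl <- p$k_f * L
  ratio <- kfl / (p$k_r + p$k_int)              # C_s = ratio * R_s
  denom <- (kfl + p$k_endo) - (p$k_syn + p$k_r) * ratio
  if (denom <= 0) {
    stop("no finite steady state: induced synthesis outpaces complex drain ",
         "(requires k_int > k_syn at saturating ligand)")
  }
  R_s <- p$k_s / denom
  C_s <- ratio * R_s
  C_e <- p$k_int * C_s / (p$k_re + p$k_deg)
  R_e <- (p$k_endo * R_s + p$k_re * C_e) / p$k_deg
  L_e <- p$k_re * C_e / (g$N_A * g$V_e * p$k_rec)
  structure(list(R_s = R_s, C_s = C_s, R_e = R_e, C_e = C_e, L_e = L_e,
                 total_surface = R_s + C_s, dose = d, converged = TRUE),
            class = "il15_steady_state")
}

#' @export
print.il15_steady_state <- function(x, ...) {
  cat(sprintf("Steady state at %g %s:\n", x$dose$value, x$dose$unit))
  flds <- setdiff(names(x), c("dose", "converged"))
  print(round(unlist(x[flds]), 4))
  invisible(x)
}

#' Saturating-complex limit of the intermediate model
#'
#' Closed-form limit of the steady-state surface complex number as the ligand
#' concentration grows without bound: `k_s / (k_int - k_syn)`.
#'
#' @inheritParams steady_state_intermediate
#' @return Complexes per cell.
#' @export
saturating_complexes <- function(p = intermediate_params()) {
  if (p$k_int <= p$k_syn) stop("saturating limit requires k_int > k_syn")
  p$k_s / (p$k_int - p$k_syn)
}

#' Write a timecourse as tidy CSV
#'
#' Long format: `time_h`, `species`, `value`, `unit`, `dose_ng_ml`.
#'
#' @param tc an `il15_timecourse`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  st <- tc$states
  cols <- setdiff(names(st), "time_h")
  long <- do.call(rbind, lapply(cols, function(s) {
    data.frame(time_h = st$time_h, species = s, value = st[[s]],
               unit = if (s %in% c("L", "L_e")) "M" else "molecules/cell",
               dose_ng_ml = dose_to_molar(tc$dose, tc$geometry) /
                 dose_to_molar(dose(1, "ng/ml"), tc$geometry))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
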