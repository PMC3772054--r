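#' Initial state of the high-affinity model
#'
#' As [intermediate_initial_state()], with zero initial trimeric complexes
#' (`C_s_p`, `C_e_p`) and zero initial high-affinity ligand (`Lam_s`,
#' `Lam_e`): activated NK cells start from the quiescent surface phenotype
#' and upregulate IL-15Ra only in response to complex signaling.
#'
#' @inheritParams intermediate_initial_state
#' @return Named numeric state vector.
#' @export
high_affinity_initial_state <- function(L0, R_s0 = 800) {
  c(R_s = R_s0, C_s = 0, R_e = 0, C_e = 0, L = L0, L_e = 0,
    C_s_p = 0, C_e_p = 0, Lam_s = 0, Lam_e = 0,
    deg_R = 0, deg_C = 0, syn_total = 0, deg_C_p = 0, syn_alpha = 0)
}

#' Time derivative of the high-affinity system
#'
#' Extends [intermediate_rhs()] with the membrane-bound high-affinity ligand
#' Lambda (IL-15/IL-15Ra, created pre-loaded with IL-15 since all IL-15Ra is
#' assumed IL-15-bound). Lambda binds free IL-15Rbg at the surface through
#' its effective concentration `xi_surf * Lam_s` with rate `k_f_p`, forming
#' the trimeric complex `C_s_p`; both complex classes share trafficking rates
#' and both induce receptor synthesis (`k_syn`) and IL-15Ra synthesis
#' (`k_syn_p`). Free Lambda is constitutively internalized (`k_endo`),
#' recycles from the endosome (`k_rec`) and is never degraded on its own;
#' trimeric complexes degrade as a unit (`k_deg`).
#'
#' @param state named state vector (see [high_affinity_initial_state()]).
#' @param p [high_affinity_params()].
#' @param g [geometry_constants()].
#' @return Named vector of time derivatives (per hour).
#' @export
high_affinity_rhs <- function(state, p, g = geometry_constants()) {
  if (any(!is.finite(state))) stop("non-finite state")
  if (any(state[HIGH_SPECIES] < 0)) stop("negative species in state")
  drv <- high_affinity_deriv(0, state, list(p = p, g = g))[[1]]
  names(drv) <- names(state)[seq_along(drv)]
  drv
}

high_affinity_deriv <- function(t, y, parms) {
  p <- parms$p
  g <- parms$g
  bind_s <- p$k_f * y[["L"]] * y[["R_s"]]
  bind_e <- p$k_fe * y[["L_e"]] * y[["R_e"]]
  # Lambda binding: surface via effective molar concentration; endosome via
  # per-molecule pseudo-rate (printed units) or explicit xi_endo conversion.
  bind_s_p <- p$k_f_p * (g$xi_surf * y[["Lam_s"]]) * y[["R_s"]]
  bind_e_p <- if (identical(p$kfe_p_mode, "molar")) {
    p$k_fe_p * (g$xi_endo * y[["Lam_e"]]) * y[["R_e"]]
  } else {
    p$k_fe_p * y[["Lam_e"]] * y[["R_e"]]
  }
  syn_ind <- p$k_syn * (y[["C_s"]] + y[["C_s_p"]])
  dR_s <- p$k_s + syn_ind - bind_s + p$k_r * y[["C_s"]] -
    p$k_endo * y[["R_s"]] - bind_s_p + p$k_r_p * y[["C_s_p"]]
  dC_s <- bind_s - (p$k_r + p$k_int) * y[["C_s"]]
  dC_s_p <- bind_s_p - (p$k_r_p + p$k_int) * y[["C_s_p"]]
  dLam_s <- p$k_syn_p * (y[["C_s"]] + y[["C_s_p"]]) - bind_s_p +
    p$k_r_p * y[["C_s_p"]] - p$k_endo * y[["Lam_s"]] + p$k_rec * y[["Lam_e"]]
  dR_e <- p$k_endo * y[["R_s"]] + p$k_re * y[["C_e"]] - bind_e -
    p$k_deg * y[["R_e"]] - bind_e_p + p$k_re_p * y[["C_e_p"]]
  dC_e <- p$k_int * y[["C_s"]] + bind_e - (p$k_re + p$k_deg) * y[["C_e"]]
  dC_e_p <- p$k_int * y[["C_s_p"]] + bind_e_p -
    (p$k_re_p + p$k_deg) * y[["C_e_p"]]
  dLam_e <- p$k_endo * y[["Lam_s"]] + p$k_re_p * y[["C_e_p"]] - bind_e_p -
    p$k_rec * y[["Lam_e"]]
  dL <- percell_flux_to_media_rate(p$k_r * y[["C_s"]] - bind_s, g) +
    p$k_rec * y[["L_e"]] * (g$V_e * g$N_tot / g$V_m)
  dL_e <- (p$k_re * y[["C_e"]] - bind_e) / (g$N_A * g$V_e) -
    p$k_rec * y[["L_e"]]
  list(c(dR_s, dC_s, dR_e, dC_e, dL, dL_e, dC_s_p, dC_e_p, dLam_s, dLam_e,
         p$k_deg * y[["R_e"]],
         p$k_deg * y[["C_e"]],
         p$k_s + syn_ind,
         p$k_deg * y[["C_e_p"]],
         p$k_syn_p * (y[["C_s"]] + y[["C_s_p"]])))
}

#' Simulate the high-affinity model
#'
#' As [simulate_intermediate()] for the extended system. The IL-15Ra feedback
#' loop makes relaxation slower than in the intermediate model; if the 48 h
#' horizon has not converged the integration is extended to 96 h.
#'
#' @inheritParams simulate_intermediate
#' @param p [high_affinity_params()].
#' @param extend_if_unconverged extend the horizon to 96 h when the requested
#'   horizon has not reached steady state (default TRUE when `times` is
#'   unspecified).
#' @return An `il15_timecourse`.
#' @export
simulate_high_affinity <- function(d, p = high_affinity_params(),
                                   g = geometry_constants(),
                                   t_end = 48, times = NULL,
                                   extend_if_unconverged = is.null(times)) {
  d <- as_dose(d)
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = max(241, 5 * t_end + 1))
  }
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  y0 <- high_affinity_initial_state(dose_to_molar(d, g))
  out <- integrate_model(high_affinity_deriv, y0, times, p, g,
                         label = "high-affinity model")
  tc <- new_timecourse(out, d, p, g, HIGH_SPECIES, HIGH_ACCUM)
  if (extend_if_unconverged && max(times) < 96 &&
      classify_steady_state(tc) != "converged") {
    return(simulate_high_affinity(d, p, g, t_end = 96,
                                  extend_if_unconverged = FALSE))
  }
  tc$states[, -1][tc$states[, -1] < 0 & tc$states[, -1] > -1e-9] <- 0
  tc
}

#' Steady state of the high-affinity model
#'
#' Obtained by long-time integration (the IL-15Ra feedback couples all
#' species, so no closed form is used). Convergence is certified by
#' [classify_steady_state()].
#'
#' @inheritParams simulate_high_affinity
#' @param t_end integration horizon (h).
#' @return An `il15_steady_state` with the extended species and
#'   `total_surface_complexes` (= C_s + C_s_p).
#' @export
steady_state_high_affinity <- function(d, p = high_affinity_params(),
                                       g = geometry_constants(), t_end = 96) {
  tc <- simulate_high_affinity(d, p, g, t_end = t_end,
                               extend_if_unconverged = TRUE)
  status <- classify_steady_state(tc)
  last <- tc$states[nrow(tc$states), ]
  structure(list(R_s = last$R_s, C_s = last$C_s, R_e = last$R_e,
                 C_e = last$C_e, L_e = last$L_e, C_s_p = last$C_s_p,
                 C_e_p = last$C_e_p, Lam_s = last$Lam_s, Lam_e = last$Lam_e,
                 total_surface = last$R_s + last$C_s + last$C_s_p,
                 total_surface_complexes = last$C_s + last$C_s_p,
                 dose = tc$dose, converged = status == "converged"),
            class = "il15_steady_state")
}

#' Total signaling complexes at the cell surface
#'
#' Sum of intermediate (`C_s`) and trimeric (`C_s_p`) surface complexes, the
#' quantity taken as the surrogate for IL-15R signaling strength.
#'
#' @param s a named state vector, one row of a timecourse `$states`, or an
#'   `il15_steady_state`.
#' @return Complexes per cell.
#' @export
total_surface_complexes <- function(s) {
  if (inherits(s, "il15_steady_state")) {
    return(s$C_s + if (!is.null(s$C_s_p)) s$C_s_p else 0)
  }
  s <- unlist(s)
  unname(s[["C_s"]] + if ("C_s_p" %in% names(s)) s[["C_s_p"]] else 0)
}

#' Dose-wise amplification by IL-15Ra upregulation
#'
#' Ratio of total steady-state surface complexes in the high-affinity model
#' to steady-state surface complexes in the intermediate model, per dose.
#' Quantifies how much receptor-signal amplification IL-15Ra provides; the
#' amplification is largest at low IL-15 concentrations.
#'
#' @param doses_ng_ml numeric vector of IL-15 doses (ng/ml).
#' @param p_high [high_affinity_params()].
#' @param g [geometry_constants()].
#' @return data.frame with `dose_ng_ml`, `total_high`, `Cs_intermediate`,
#'   `fold_change`.
#' @export
fold_change_profile <- function(doses_ng_ml,
                                p_high = high_affinity_params(),
                                g = geometry_constants()) {
  p_int <- do.call(intermediate_params,
                   unclass(p_high)[names(formals(intermediate_params))])
  rows <- lapply(doses_ng_ml, function(dd) {
    hi <- steady_state_high_affinity(dd, p_high, g)
    lo <- steady_state_intermediate(dd, p_int, g)
    if (lo$C_s <= 0) stop("undefined fold change: intermediate C_s is zero at ",
                          dd, " ng/ml")
    data.frame(dose_ng_ml = dd,
               total_high = hi$total_surface_complexes,
               Cs_intermediate = lo$C_s,
               fold_change = hi$total_surface_complexes / lo$C_s)
  })
  do.call(rbind, rows)
}
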