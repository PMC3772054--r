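#' Cell-cycle threshold model
#'
#' Container for the constants that translate steady-state surface complex
#' numbers into population proliferation predictions. Defaults are the
#' printed constants: a cell-cycle threshold of 2198 complex-hours per cell
#' (58.2 surface complexes/cell sustained for the 37.8 h delay to first
#' division at 9 ng/ml), a maximum trigger stimulus of 16448 complex-hours
#' per cell (257 complexes/cell for the 64 h complete-recruitment time at
#' saturating IL-15), and a dose-independent 32 h delay used for division
#' counting.
#'
#' @param Cs_threshold cell-cycle threshold (complex-hours/cell).
#' @param max_stimulus stimulus for complete population recruitment
#'   (complex-hours/cell).
#' @param tau_first time delay to first division at low dose (h).
#' @param tau dose-independent time delay used for division counting (h).
#' @param t_full complete-recruitment time at saturating dose (h).
#' @return An object of class `il15_threshold_model`.
#' @export
threshold_model <- function(Cs_threshold = 2198, max_stimulus = 16448,
                            tau_first = 37.8, tau = 32, t_full = 64) {
  stopifnot(Cs_threshold > 0, max_stimulus > 0, tau_first > 0, tau > 0,
            t_full > 0, Cs_threshold < max_stimulus)
  structure(list(Cs_threshold = Cs_threshold, max_stimulus = max_stimulus,
                 tau_first = tau_first, tau = tau, t_full = t_full),
            class = "il15_threshold_model")
}

#' Derive the threshold model from ODE steady states
#'
#' Computes the threshold constants from the model's own outputs instead of
#' the printed values: threshold = C_s(9 ng/ml) * tau_first and maximum
#' stimulus = C_s(saturating dose) * t_full.
#'
#' @param p [intermediate_params()].
#' @param g [geometry_constants()].
#' @param dose_low low reference dose (ng/ml) at which the delay to first
#'   division was measured.
#' @param dose_sat saturating dose (ng/ml).
#' @inheritParams threshold_model
#' @return An `il15_threshold_model`.
#' @export
derive_threshold_model <- function(p = intermediate_params(),
                                   g = geometry_constants(),
                                   dose_low = 9, dose_sat = 2000,
                                   tau_first = 37.8, tau = 32, t_full = 64) {
  cs_low <- steady_state_intermediate(dose_low, p, g)$C_s
  cs_sat <- steady_state_intermediate(dose_sat, p, g)$C_s
  threshold_model(Cs_threshold = cell_cycle_threshold(cs_low, tau_first),
                  max_stimulus = max_trigger_stimulus(cs_sat, t_full),
                  tau_first = tau_first, tau = tau, t_full = t_full)
}

#' Cell-cycle threshold stimulus
#'
#' Minimum cumulative surface-complex exposure required for a quiescent NK
#' cell to commit to division: the steady-state surface complex number times
#' the time delay to first division (the area under C_s vs t at t = tau
#' when complexes equilibrate fast).
#'
#' @param Cs_ss steady-state surface complexes per cell (> 0).
#' @param tau_first time delay to first division (h, > 0).
#' @return Threshold in complex-hours per cell.
#' @export
cell_cycle_threshold <- function(Cs_ss, tau_first) {
  if (any(Cs_ss <= 0) || any(tau_first <= 0)) {
    stop("Cs_ss and tau_first must be positive")
  }
  Cs_ss * tau_first
}

#' Maximum trigger stimulus
#'
#' Cumulative complex exposure at which an entire NK population has been
#' recruited into the cell cycle: the saturating steady-state complex number
#' times the complete-recruitment time.
#'
#' @param Cs_sat saturating steady-state surface complexes per cell (>= 0).
#' @param t_full complete-recruitment time (h, > 0).
#' @return Stimulus in complex-hours per cell.
#' @export
max_trigger_stimulus <- function(Cs_sat, t_full) {
  if (any(Cs_sat < 0) || any(t_full <= 0)) {
    stop("Cs_sat must be non-negative and t_full positive")
  }
  Cs_sat * t_full
}

#' Fraction of the NK population recruited into division
#'
#' The net positive cell-cycle momentum (cumulative complex stimulus
#' `Cs_ss * t` in excess of the threshold) divided by the maximum trigger
#' stimulus, clipped to [0, 1]. Zero whenever the cumulative stimulus has not
#' crossed the threshold.
#'
#' @param Cs_ss steady-state surface complexes per cell.
#' @param t stimulation time(s) (h, >= 0; vectorized).
#' @param th [threshold_model()].
#' @return Fraction(s) in [0, 1].
#' @export
fractional_recruitment <- function(Cs_ss, t, th = threshold_model()) {
  stopifnot(all(t >= 0))
  pmin(pmax((Cs_ss * t - th$Cs_threshold) / th$max_stimulus, 0), 1)
}

#' Recruitment fraction without a cell-cycle threshold
#'
#' Alternative predictor: the ratio of cumulative triggered complexes to the
#' maximum trigger stimulus, without subtracting the threshold. Always at
#' least as large as [fractional_recruitment()]; retained for model
#' comparison.
#'
#' @inheritParams fractional_recruitment
#' @return Fraction(s) in [0, 1].
#' @export
fractional_recruitment_no_threshold <- function(Cs_ss, t,
                                                th = threshold_model()) {
  stopifnot(all(t >= 0))
  pmin(pmax(Cs_ss * t / th$max_stimulus, 0), 1)
}

#' Interdivision time of dividing NK cells
#'
#' Minimal time for a dividing cell to complete one division: the cell-cycle
#' threshold divided by the cell's total steady-state surface complexes.
#' Zero complexes signal an infinite interdivision time (returned as `Inf`
#' with a warning rather than an error, so dose grids containing zero
#' stimulation survive).
#'
#' @param total_Cs total steady-state surface complexes per cell (vectorized).
#' @param th [threshold_model()].
#' @return Interdivision time(s) in hours.
#' @export
interdivision_time <- function(total_Cs, th = threshold_model()) {
  if (any(total_Cs < 0)) stop("total_Cs must be non-negative")
  out <- th$Cs_threshold / total_Cs
  if (any(total_Cs == 0)) {
    warning("zero surface complexes: interdivision time is infinite")
  }
  out
}

#' Population mean division rate
#'
#' Division rates across asynchronously cycling cohorts span a roughly
#' Gaussian distribution from the maximum rate `1 / t_div` (the fastest
#' cohort) down to near zero (cells that have divided once); its mean is half
#' the maximum: `1 / (2 * t_div)`.
#'
#' @param t_div interdivision time(s) (h, > 0).
#' @return Mean division rate(s) in h^-1.
#' @export
mean_division_rate <- function(t_div) {
  if (any(t_div <= 0)) stop("t_div must be positive")
  1 / (2 * t_div)
}

#' Maximum number of divisions in a fixed period
#'
#' Number of interdivision times that fit into the time elapsed since
#' recruitment: `(t - tau) / t_div`, zero before the delay `tau`. The
#' real-valued count is returned; `floor = TRUE` gives the integer companion
#' comparable with CFSE peak counts.
#'
#' @param t elapsed stimulation time(s) (h; vectorized).
#' @param tau time delay before division counting starts (h).
#' @param t_div interdivision time (h, > 0).
#' @param floor return the floored integer count.
#' @return Division count(s).
#' @export
max_divisions <- function(t, tau = 32, t_div, floor = FALSE) {
  if (any(t_div <= 0)) stop("t_div must be positive")
  n <- pmax((t - tau) / t_div, 0)
  if (floor) base::floor(n) else n
}

#' Per-dose proliferation prediction table
#'
#' End-to-end summary: for each dose, the total steady-state surface
#' complexes of the high-affinity model, the interdivision time, the mean
#' division rate and the maximum divisions at a reference time.
#'
#' @param doses_ng_ml IL-15 doses (ng/ml).
#' @param p [high_affinity_params()].
#' @param g [geometry_constants()].
#' @param th [threshold_model()].
#' @param t_ref reference elapsed time for the division count (h).
#' @return data.frame with columns `dose_ng_ml`, `total_Cs`, `t_div_h`,
#'   `mean_rate_per_h`, `max_divisions`.
#' @export
division_table <- function(doses_ng_ml = c(9, 25, 50, 75),
                           p = high_affinity_params(),
                           g = geometry_constants(),
                           th = threshold_model(), t_ref = 90) {
  rows <- lapply(doses_ng_ml, function(dd) {
    tot <- steady_state_high_affinity(dd, p, g)$total_surface_complexes
    tdiv <- interdivision_time(tot, th)
    data.frame(dose_ng_ml = dd, total_Cs = tot, t_div_h = tdiv,
               mean_rate_per_h = mean_division_rate(tdiv),
               max_divisions = max_divisions(t_ref, th$tau, tdiv))
  })
  do.call(rbind, rows)
}
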