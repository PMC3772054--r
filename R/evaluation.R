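#' Normalized root-mean-square deviation
#'
#' `100 * RMSD(pred, obs) / (max(obs) - min(obs))`, a percentage; 0% is
#' absolute agreement. Range normalization is the default (the compared
#' series live on a bounded fraction scale); `normalize = "mean"` divides by
#' the observation mean instead.
#'
#' @param pred predicted series.
#' @param obs observed series, same length, at least 2 points, not constant
#'   under range normalization.
#' @param normalize `"range"` (default) or `"mean"`.
#' @return NRMSD in percent.
#' @export
nrmsd <- function(pred, obs, normalize = c("range", "mean")) {
  normalize <- match.arg(normalize)
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(obs) < 2) stop("at least 2 points required")
  denom <- switch(normalize,
                  range = diff(range(obs)),
                  mean = mean(obs))
  if (denom == 0) stop("undefined normalization: constant observations")
  100 * sqrt(mean((pred - obs)^2)) / denom
}

#' Compare recruitment predictions with observations
#'
#' Scores the thresholded (or threshold-free) recruitment model against a
#' recruitment dataset by NRMSD.
#'
#' @param data recruitment observations ([gen_recruitment_obs()] output or a
#'   data.frame with `time_h` and `observed`).
#' @param Cs_ss steady-state surface complexes per cell (defaults to the
#'   value recorded with synthetic data).
#' @param th [threshold_model()].
#' @param mode `"threshold"` or `"no_threshold"`.
#' @return A one-row `il15_fit_report` data.frame: `dose_ng_ml`, `mode`,
#'   `n_points`, `nrmsd_pct`; residuals in `attr(, "residuals")`.
#' @export
compare_recruitment <- function(data, Cs_ss = attr(data, "Cs_ss"),
                                th = threshold_model(),
                                mode = c("threshold", "no_threshold")) {
  mode <- match.arg(mode)
  if (is.null(Cs_ss)) stop("Cs_ss must be supplied for non-synthetic data")
  pred <- if (mode == "threshold") {
    fractional_recruitment(Cs_ss, data$time_h, th)
  } else {
    fractional_recruitment_no_threshold(Cs_ss, data$time_h, th)
  }
  out <- data.frame(dose_ng_ml = data$dose_ng_ml[1], mode = mode,
                    n_points = nrow(data),
                    nrmsd_pct = nrmsd(pred, data$observed))
  attr(out, "residuals") <- pred - data$observed
  class(out) <- c("il15_fit_report", "data.frame")
  out
}

#' Recover the cell-cycle threshold from recruitment data
#'
#' Bounded one-dimensional least squares: with the maximum trigger stimulus
#' held fixed, the threshold enters the analytic recruitment formula
#' monotonically, so the squared-error objective is well behaved and
#' [stats::optimize()] suffices. No ODE solve is involved.
#'
#' @param data recruitment observations across doses: a data.frame with
#'   columns `dose_ng_ml`, `time_h`, `observed` and `Cs_ss` (per-dose
#'   steady-state complexes), e.g. `rbind` of [gen_recruitment_obs()] outputs
#'   with a `Cs_ss` column added, or any observed dataset in that layout.
#' @param th [threshold_model()] supplying the fixed `max_stimulus` and the
#'   search interval.
#' @param interval search interval for the threshold (complex-hours/cell).
#' @return list: `Cs_threshold` (estimate), `sse`, `n`.
#' @export
recover_threshold <- function(data, th = threshold_model(),
                              interval = c(1, th$max_stimulus)) {
  need <- c("dose_ng_ml", "time_h", "observed", "Cs_ss")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(data$dose_ng_ml)) < 2) stop("at least 2 doses required")
  if (stats::var(data$time_h) == 0) {
    stop("degenerate design: a single time point cannot identify the threshold")
  }
  obj <- function(thr) {
    thm <- threshold_model(Cs_threshold = thr, max_stimulus = th$max_stimulus,
                           tau_first = th$tau_first, tau = th$tau,
                           t_full = th$t_full)
    pred <- fractional_recruitment(data$Cs_ss, data$time_h, thm)
    sum((pred - data$observed)^2)
  }
  fit <- stats::optimize(obj, interval = interval, tol = 1e-6)
  list(Cs_threshold = fit$minimum, sse = fit$objective, n = nrow(data))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: intermediate and high-affinity steady states at the
#' requested doses, threshold constants (derived from the model or printed),
#' the per-dose proliferation table, recruitment predictions, seeded
#' synthetic observations and their NRMSD report. Deterministic given the
#' seed; writes CSV and JSON when `out_dir` is given.
#'
#' @param config list (or path to a YAML file) with any of: `doses`
#'   (ng/ml; default 9, 25, 50, 75), `times` (h; default 40-90 h grid),
#'   `seed` (default 1), `noise_sd` (default 0.05), `threshold_mode`
#'   (`"printed"` or `"derived"`), `params` (named list of rate-constant
#'   overrides applied to both models, e.g. `list(k_syn_p = 0)`), `out_dir`
#'   (optional output directory).
#' @return list of class `il15_pipeline_report`: `steady_states`,
#'   `threshold`, `division_table`, `recruitment_fits`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(doses = c(9, 25, 50, 75), times = seq(40, 90, by = 10), seed = 1,
         noise_sd = 0.05, threshold_mode = "printed", params = list(),
         out_dir = NULL),
    config)
  ov <- cfg$params
  p_int <- do.call(intermediate_params,
                   ov[intersect(names(ov), names(formals(intermediate_params)))])
  p_high <- do.call(high_affinity_params,
                    ov[intersect(names(ov),
                                 c(names(formals(high_affinity_params)),
                                   names(formals(intermediate_params))))])
  g <- geometry_constants()
  th <- switch(cfg$threshold_mode,
               printed = threshold_model(),
               derived = derive_threshold_model(p_int, g),
               stop("pipeline stage [threshold]: unknown threshold_mode '",
                    cfg$threshold_mode, "'"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage [%s]: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ss <- run_stage("steady_states", do.call(rbind, lapply(cfg$doses, function(dd) {
    lo <- steady_state_intermediate(dd, p_int, g)
    hi <- steady_state_high_affinity(dd, p_high, g)
    data.frame(dose_ng_ml = dd, Cs_intermediate = lo$C_s,
               Rs_intermediate = lo$R_s,
               total_Cs_high = hi$total_surface_complexes,
               high_converged = hi$converged)
  })))
  div <- run_stage("division_table",
                   division_table(cfg$doses, p_high, g, th))
  fits <- run_stage("recruitment", do.call(rbind, lapply(seq_along(cfg$doses), function(i) {
    dd <- cfg$doses[i]
    cs <- ss$Cs_intermediate[i]
    dat <- gen_recruitment_obs(dd, cfg$times, sd = cfg$noise_sd,
                               seed = cfg$seed + i, th = th, Cs_ss = cs)
    rbind(compare_recruitment(dat, cs, th, "threshold"),
          compare_recruitment(dat, cs, th, "no_threshold"))
  })))
  report <- structure(list(steady_states = ss, threshold = th,
                           division_table = div, recruitment_fits = fits,
                           config = cfg),
                      class = "il15_pipeline_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ss, file.path(cfg$out_dir, "steady_states.csv"),
                     row.names = FALSE)
    utils::write.csv(div, file.path(cfg$out_dir, "division_table.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(cfg$out_dir, "recruitment_fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(threshold = unclass(th),
                              config = cfg[setdiff(names(cfg), "out_dir")]),
                         file.path(cfg$out_dir, "pipeline.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.il15_pipeline_report <- function(x, ...) {
  cat("IL-15 NK proliferation pipeline report\n")
  cat(sprintf("threshold: %.0f complex-h/cell (max stimulus %.0f)\n",
              x$threshold$Cs_threshold, x$threshold$max_stimulus))
  cat("\nsteady states:\n"); print(x$steady_states)
  cat("\ndivision table:\n"); print(x$division_table)
  cat("\nrecruitment NRMSD (%):\n"); print(x$recruitment_fits)
  invisible(x)
}
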