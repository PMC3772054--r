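#' Default one-at-a-time perturbation grid
#'
#' Symmetric factor grid spanning two orders of magnitude either side of the
#' nominal value.
#'
#' @export
default_factor_grid <- function() c(1/100, 1/33, 1/10, 1/3, 1, 3, 10, 33, 100)

#' Classify the convergence of a timecourse
#'
#' `"converged"`: the maximum relative change of every dynamical species over
#' the final 1 h window is below 1e-5 per hour. (Genuine runaway growth sits
#' orders of magnitude above this threshold, while the residual quasi-steady
#' drift that slow ligand turnover imposes on every trajectory sits safely
#' below it, so the regimes separate cleanly.) `"diverging"`: the surface
#' complex pool is still growing super-linearly at the horizon (its increments
#' over successive windows are increasing), the signature of induced synthesis
#' outpacing complex drain. `"non_converged"` otherwise.
#'
#' @param tc an `il15_timecourse` covering at least 24 h.
#' @param rel_tol relative-change-per-hour threshold for convergence.
#' @return One of `"converged"`, `"non_converged"`, `"diverging"`.
#' @export
classify_steady_state <- function(tc, rel_tol = 1e-5) {
  stopifnot(inherits(tc, "il15_timecourse"))
  t_max <- max(tc$times)
  if (t_max < 24) stop("classification requires a horizon of at least 24 h")
  st <- tc$states
  sp <- tc$species
  i_end <- nrow(st)
  i_1h <- max(which(st$time_h <= t_max - 1))
  dt <- st$time_h[i_end] - st$time_h[i_1h]
  a <- unlist(st[i_1h, sp])
  b <- unlist(st[i_end, sp])
  scale <- pmax(abs(b), 1e-6)
  rate <- max(abs(b - a) / scale) / dt
  if (rate < rel_tol) return("converged")
  cs <- st$C_s + if ("C_s_p" %in% names(st)) st$C_s_p else 0
  i_2h <- max(which(st$time_h <= t_max - 2))
  inc1 <- cs[i_1h] - cs[i_2h]
  inc2 <- cs[i_end] - cs[i_1h]
  if (inc2 > 0 && inc2 >= inc1 * 1.01) "diverging" else "non_converged"
}

scan_models <- list(
  intermediate = list(params = intermediate_params,
                      simulate = simulate_intermediate),
  high = list(params = high_affinity_params,
              simulate = simulate_high_affinity)
)

#' One-at-a-time parameter sensitivity scan
#'
#' Rescales a single rate constant over a factor grid, holding all others at
#' their nominal values, and records the steady state reached from the
#' standard initial conditions at the given dose. Runs that do not reach
#' steady state within the horizon are flagged, not errored: a sufficiently
#' reduced complex internalization rate lets surface complexes accumulate
#' without bound.
#'
#' @param model `"intermediate"` or `"high"`.
#' @param name parameter to perturb (e.g. `"k_f"`, `"k_int"`).
#' @param factors multiplicative factor grid (default [default_factor_grid()]).
#' @param d IL-15 dose (default 25 ng/ml, the reference scan condition).
#' @param p baseline parameter set (defaults per model).
#' @param g [geometry_constants()].
#' @param t_end simulation horizon per factor (h).
#' @return data.frame of class `il15_scan`, long format: `param`, `factor`,
#'   `species`, `value`, `flag`.
#' @export
scan_parameter <- function(model = c("intermediate", "high"), name,
                           factors = default_factor_grid(), d = 25,
                           p = NULL, g = geometry_constants(), t_end = 48) {
  model <- match.arg(model)
  m <- scan_models[[model]]
  if (is.null(p)) p <- m$params()
  if (!name %in% names(p) || !is.numeric(p[[name]])) {
    stop("unknown rate constant: ", name)
  }
  stopifnot(all(factors > 0))
  rows <- lapply(factors, function(f) {
    pf <- p
    pf[[name]] <- p[[name]] * f
    tc <- m$simulate(d, pf, g, t_end = t_end)
    flag <- classify_steady_state(tc)
    last <- tc$states[nrow(tc$states), ]
    vals <- unlist(last[tc$species])
    vals <- c(vals, total_surface_complexes = total_surface_complexes(last),
              total_surface = unname(vals["R_s"] + vals["C_s"] +
                                       if ("C_s_p" %in% names(vals)) vals["C_s_p"] else 0))
    data.frame(param = name, factor = f, species = names(vals),
               value = unname(vals), flag = flag, row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("il15_scan", "data.frame"))
}

#' Covary on/off rates at fixed equilibrium dissociation constant
#'
#' Scales `k_f` and `k_r` together by the same factor so that
#' `K_d = k_r / k_f` is invariant, isolating the kinetic (residence-time)
#' contribution of binding from the equilibrium one. The complex gain with
#' increasing on-rate is partially blunted relative to the `k_f`-only scan.
#'
#' @inheritParams scan_parameter
#' @return data.frame of class `il15_scan` with an additional `K_d` column.
#' @export
scan_kf_kr_fixed_kd <- function(factors = default_factor_grid(), d = 25,
                                p = intermediate_params(),
                                g = geometry_constants(), t_end = 48) {
  stopifnot(all(factors > 0))
  rows <- lapply(factors, function(f) {
    pf <- p
    pf$k_f <- p$k_f * f
    pf$k_r <- p$k_r * f
    tc <- simulate_intermediate(d, pf, g, t_end = t_end)
    flag <- classify_steady_state(tc)
    last <- tc$states[nrow(tc$states), ]
    vals <- unlist(last[tc$species])
    data.frame(param = "k_f+k_r", factor = f, species = names(vals),
               value = unname(vals), flag = flag, K_d = pf$k_r / pf$k_f,
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("il15_scan", "data.frame"))
}

#' Extract one species' profile from a scan
#'
#' @param scan an `il15_scan`.
#' @param species species name (e.g. `"C_s"`).
#' @return data.frame with `factor`, `value`, `flag`, ordered by factor.
#' @export
scan_profile <- function(scan, species) {
  out <- scan[scan$species == species, c("factor", "value", "flag")]
  out[order(out$factor), , drop = FALSE]
}
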