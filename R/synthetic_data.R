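# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate synthetic fractional-recruitment observations
#'
#' Pseudo-experimental recruitment data: the ground truth is the thresholded
#' recruitment curve [fractional_recruitment()] evaluated at the observation
#' times; observations add zero-mean Gaussian noise and are clipped to
#' [0, 1]. The truth never depends on the noise parameters; identical seeds
#' give identical data.
#'
#' @param d IL-15 dose (ng/ml or [dose()]), recorded with the data.
#' @param times observation times (h, non-empty).
#' @param sd noise standard deviation on the fraction scale (>= 0).
#' @param seed integer seed.
#' @param th [threshold_model()].
#' @param Cs_ss steady-state surface complexes per cell driving the truth.
#' @return data.frame of class `il15_recruitment_data`: `dose_ng_ml`,
#'   `time_h`, `truth`, `observed`; attributes `sd`, `seed`, `Cs_ss`.
#' @export
gen_recruitment_obs <- function(d, times, sd = 0.05, seed = 1,
                                th = threshold_model(), Cs_ss) {
  d <- as_dose(d)
  if (length(times) == 0) stop("empty time grid")
  stopifnot(sd >= 0, all(times >= 0))
  truth <- fractional_recruitment(Cs_ss, times, th)
  obs <- with_seed(seed, pmin(pmax(truth + stats::rnorm(length(times), 0, sd), 0), 1))
  structure(data.frame(dose_ng_ml = d$value, time_h = times, truth = truth,
                       observed = obs),
            sd = sd, seed = seed, Cs_ss = Cs_ss,
            class = c("il15_recruitment_data", "data.frame"))
}

#' Generate synthetic maximum-division-number observations
#'
#' Integer CFSE-style division counts: the truth is [max_divisions()]; the
#' observation is its floor, optionally jittered by -1/0/+1, and capped at 8
#' (CFSE dilution limits division tracking to 7-8 rounds).
#'
#' @param d IL-15 dose, recorded with the data.
#' @param times observation times (h, each >= `th$tau`).
#' @param th [threshold_model()].
#' @param t_div interdivision time at this dose (h).
#' @param seed integer seed.
#' @param jitter probability of a +/-1 miscount per observation (default 0).
#' @param cap maximum trackable division number.
#' @return data.frame: `dose_ng_ml`, `time_h`, `truth`, `observed` (integer).
#' @export
gen_max_division_obs <- function(d, times, th = threshold_model(), t_div,
                                 seed = 1, jitter = 0, cap = 8) {
  d <- as_dose(d)
  stopifnot(all(times >= th$tau), jitter >= 0, jitter <= 1)
  truth <- max_divisions(times, th$tau, t_div)
  obs <- floor(truth)
  if (jitter > 0) {
    obs <- with_seed(seed, {
      flip <- stats::runif(length(obs)) < jitter
      obs + ifelse(flip, sample(c(-1L, 1L), length(obs), replace = TRUE), 0L)
    })
  }
  obs <- pmin(pmax(obs, 0), cap)
  data.frame(dose_ng_ml = d$value, time_h = times, truth = truth,
             observed = as.integer(obs))
}

#' Generate a CFSE-like intensity profile
#'
#' A dividing NK population imaged by CFSE dilution: cohort `i` (cells that
#' divided `i` times) sits at a 2-fold lower dye intensity than cohort
#' `i - 1`, i.e. at unit spacing on a log2-intensity axis. The profile is a
#' Gaussian mixture over cohorts 1..n (the undivided peak is excluded),
#' sampled as `n_events` seeded flow events and binned on a fixed grid.
#'
#' @param n_divisions number of dividing cohorts (>= 1).
#' @param weights cohort fractions, summing to 1 (default equal).
#' @param cv coefficient of variation of each cohort's intensity (linear
#'   scale); cohort sd on the log2 axis is `cv / log(2)`.
#' @param seed integer seed.
#' @param n_events flow events sampled.
#' @param log2_peak0 log2 intensity of the undivided population; cohort `i`
#'   centers at `log2_peak0 - i`.
#' @param grid_n grid resolution.
#' @return list of class `il15_cfse_profile`: `grid` (log2 intensity),
#'   `density` (integrates to 1), `means`, `sd`, `weights`, `seed`.
#' @export
gen_cfse_profile <- function(n_divisions, weights = NULL, cv = 0.05, seed = 1,
                             n_events = 50000, log2_peak0 = 10,
                             grid_n = 512) {
  stopifnot(n_divisions >= 1, cv > 0)
  if (is.null(weights)) weights <- rep(1 / n_divisions, n_divisions)
  if (any(weights < 0)) stop("negative cohort weights")
  if (abs(sum(weights) - 1) > 1e-8) stop("cohort weights must sum to 1")
  means <- log2_peak0 - seq_len(n_divisions)
  sdv <- cv / log(2)
  events <- with_seed(seed, {
    cohort <- sample.int(n_divisions, n_events, replace = TRUE, prob = weights)
    stats::rnorm(n_events, mean = means[cohort], sd = sdv)
  })
  lo <- min(means) - 0.75
  hi <- max(means) + 0.75
  breaks <- seq(lo, hi, length.out = grid_n + 1)
  h <- graphics::hist(pmin(pmax(events, lo), hi), breaks = breaks, plot = FALSE)
  structure(list(grid = h$mids, density = h$density, means = means, sd = sdv,
                 weights = weights, seed = seed),
            class = "il15_cfse_profile")
}

#' Decompose a CFSE profile into division cohorts
#'
#' Peak detection on the smoothed density (fixed-width moving average) gives
#' the number of cohorts = maximum division number; the fraction of the
#' population in each cohort is the area under its peak (the density
#' partitioned at the minima between adjacent peaks) relative to the total
#' area.
#'
#' @param profile an `il15_cfse_profile` (or a list with `grid` and
#'   `density`).
#' @param smooth_width moving-average window as a fraction of the grid span
#'   (fixed smoothing scale; default 2% of the span).
#' @param min_prominence minimum peak height relative to the tallest peak.
#' @return list: `weights` (sum to 1, ordered from fewest divisions, i.e.
#'   highest intensity, to most), `n_divisions`, `peak_positions`.
#' @export
estimate_cohort_fractions <- function(profile, smooth_width = 0.02,
                                      min_prominence = 0.02) {
  x <- profile$grid
  y <- profile$density
  if (length(x) < 5 || max(y) <= 0 || diff(range(y)) / max(y) < 1e-6) {
    stop("flat profile: no detectable CFSE peak")
  }
  k <- max(3L, 2L * floor(smooth_width * length(x) / 2) + 1L)
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- 0
  ys <- as.numeric(ys)
  n <- length(ys)
  is_peak <- vapply(seq(2, n - 1), function(i) {
    ys[i] > ys[i - 1] && ys[i] >= ys[i + 1] && ys[i] >= min_prominence * max(ys)
  }, logical(1))
  idx <- which(is_peak) + 1L
  # merge plateau-adjacent detections closer than the smoothing window
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(idx) > k)
    idx <- idx[keep]
  }
  if (length(idx) == 0) stop("flat profile: no detectable CFSE peak")
  bounds <- c(1L, vapply(seq_len(length(idx) - 1), function(j) {
    seg <- idx[j]:idx[j + 1]
    seg[which.min(ys[seg])]
  }, integer(1)), n)
  dx <- mean(diff(x))
  areas <- vapply(seq_along(idx), function(j) {
    sum(y[bounds[j]:bounds[j + 1]]) * dx
  }, numeric(1))
  w <- areas / sum(areas)
  ord <- order(x[idx], decreasing = TRUE)  # highest intensity = fewest divisions
  list(weights = w[ord], n_divisions = length(idx),
       peak_positions = x[idx][ord])
}
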