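#' Define a replicate-well growth experiment
#'
#' Describes the layout a synthetic (or real) growth experiment follows:
#' exact initial cell numbers per condition, replicate wells per condition,
#' observation horizon and sampling interval, additive measurement-noise
#' scales on the per-timepoint mean and variance, and the master seed.
#'
#' @param initial_counts Integer vector of exact seeding numbers N0.
#' @param replicates Replicate wells per condition (>= 2).
#' @param horizon Total observation time in hours; must be a positive
#'   multiple of `sampling_interval`.
#' @param sampling_interval Observation spacing in hours (default 4, the
#'   imaging cadence of the experimental design emulated here).
#' @param noise_sd_mean,noise_sd_variance Standard deviations of the
#'   additive Gaussian noise applied to the summary mean (cells) and
#'   variance (cells^2) series by [perturb_summaries()].
#' @param seed Master seed; every random draw in the design flows from it.
#' @return A list of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(c(3, 5, 10), replicates = 100, seed = 1)
experiment_design <- function(initial_counts, replicates, horizon = 328,
                              sampling_interval = 4, noise_sd_mean = 0.5,
                              noise_sd_variance = 5, seed = 1L) {
  stopifnot(all(initial_counts >= 1), replicates >= 2,
            horizon > 0, sampling_interval > 0)
  if (abs(horizon / sampling_interval - round(horizon / sampling_interval)) > 1e-9) {
    stop("horizon must be a multiple of sampling_interval", call. = FALSE)
  }
  if (noise_sd_mean < 0 || noise_sd_variance < 0) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  structure(list(initial_counts = as.integer(initial_counts),
                 replicates = as.integer(replicates),
                 horizon = horizon,
                 sampling_interval = sampling_interval,
                 noise_sd_mean = noise_sd_mean,
                 noise_sd_variance = noise_sd_variance,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Preset experimental designs
#'
#' Three ready-made design/model/parameter bundles:
#' \describe{
#'   \item{simulation_study}{N0 = 3, 5, 10 with 5,000 replicates each,
#'     generated from the strong-Allee-on-birth model with b = 0.0238,
#'     d = 0.005, A = 2, sampled every 4 h over 328 h.}
#'   \item{bt474_like}{N0 = 2, 4, 10 with 30 replicates each from the
#'     extended (weak) Allee-on-birth model at the best-fit parameters for
#'     the BT-474 experiment: b = 0.0101, d = 4.3613e-5, A = -3.1576,
#'     tau = 7.480; no summary-level noise (the counts are the data).}
#'   \item{high_density}{N0 = 512 and 1024 with 30 replicates each from
#'     the simple birth-death model (b = 0.0118, d = 5e-4).}
#' }
#'
#' @param name One of `"simulation_study"`, `"bt474_like"`, `"high_density"`.
#' @param replicates Optional override of the preset replicate count
#'   (e.g. for reduced-scale runs).
#' @param seed Master seed stored in the design.
#' @return A list with elements `design`, `model`, `params`.
#' @export
#' @examples
#' preset_design("simulation_study", replicates = 100)$params$A
preset_design <- function(name = c("simulation_study", "bt474_like", "high_density"),
                          replicates = NULL, seed = 1L) {
  name <- match.arg(name)
  out <- switch(name,
    simulation_study = list(
      design = experiment_design(c(3L, 5L, 10L), replicates %||% 5000L,
                                 horizon = 328, sampling_interval = 4,
                                 seed = seed),
      model = "strongA_birth",
      params = rate_params(b = 0.0238, d = 0.005, A = 2)
    ),
    bt474_like = list(
      design = experiment_design(c(2L, 4L, 10L), replicates %||% 30L,
                                 horizon = 328, sampling_interval = 4,
                                 noise_sd_mean = 0, noise_sd_variance = 0,
                                 seed = seed),
      model = "extA_birth",
      params = rate_params(b = 0.0101, d = 4.3613e-5, A = -3.1576, tau = 7.480)
    ),
    high_density = list(
      design = experiment_design(c(512L, 1024L), replicates %||% 30L,
                                 horizon = 328, sampling_interval = 4,
                                 seed = seed),
      model = "simple_bd",
      params = rate_params(b = 0.0118, d = 5e-4)
    )
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one exact stochastic trajectory
#'
#' Draws a single sample path of the chosen birth-death model with the
#' Gillespie algorithm: exponentially distributed waiting times at the
#' total rate, event type chosen proportionally to the birth and death
#' propensities. The path terminates at the horizon or on absorption at 0.
#'
#' @inheritParams propensities
#' @param N0 Initial cell count (>= 0 integer).
#' @param horizon End of simulation, hours.
#' @param grid Optional observation grid (hours); if supplied, counts are
#'   sampled onto it by last-value carry-forward.
#' @param max_events Safety cap on the number of simulated events.
#' @return A list with `event_times`, `counts`, and (when `grid` is given)
#'   `grid_times`, `grid_counts`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_trajectory("simple_bd", rate_params(0.0238, 0.005),
#'                           N0 = 5, horizon = 200)
#' range(tr$counts)
simulate_trajectory <- function(model, params, N0, horizon, grid = NULL,
                                max_events = 5e6) {
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  if (N0 < 0 || N0 != floor(N0)) stop("N0 must be a non-negative integer", call. = FALSE)
  code <- .model_code(spec$id)
  A <- if (is.na(params$A)) 0 else params$A
  tau <- if (is.na(params$tau)) 0 else params$tau
  path <- ssa_path_cpp(code, params$b, params$d, A, tau, as.integer(N0),
                       horizon, as.integer(max_events))
  out <- list(event_times = path$event_times, counts = path$counts)
  if (!is.null(grid)) {
    idx <- findInterval(grid, path$event_times)
    out$grid_times <- grid
    out$grid_counts <- path$counts[pmax(idx, 1L)]
  }
  out
}

#' Simulate a seeded replicate-well ensemble
#'
#' Generates independent Gillespie trajectories for every condition of an
#' [experiment_design()], sampled onto the design's uniform observation
#' grid. The design's master seed expands into one sub-seed per trajectory
#' (drawn sequentially), so increasing the replicate count leaves earlier
#' trajectories bit-identical.
#'
#' @param design An [experiment_design()].
#' @param model,params Generating model and [rate_params()].
#' @return A list of class `trajectory_ensemble`: `times`, `conditions`
#'   (per-N0 list with a `counts` matrix of replicates x timepoints),
#'   `model`, `params`, `design`.
#' @export
#' @examples
#' d <- experiment_design(c(3, 5), replicates = 10, horizon = 40, seed = 7)
#' e <- simulate_ensemble(d, "simple_bd", rate_params(0.0238, 0.005))
#' dim(e$conditions[[1]]$counts)
simulate_ensemble <- function(design, model, params) {
  stopifnot(inherits(design, "experiment_design"))
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  code <- .model_code(spec$id)
  A <- if (is.na(params$A)) 0 else params$A
  tau <- if (is.na(params$tau)) 0 else params$tau
  times <- seq(0, design$horizon, by = design$sampling_interval)
  n_traj <- length(design$initial_counts) * design$replicates
  set.seed(design$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_traj)
  conditions <- vector("list", length(design$initial_counts))
  k <- 0L
  for (ci in seq_along(design$initial_counts)) {
    n0 <- design$initial_counts[ci]
    counts <- matrix(0L, nrow = design$replicates, ncol = length(times))
    for (r in seq_len(design$replicates)) {
      k <- k + 1L
      set.seed(sub_seeds[k])
      counts[r, ] <- ssa_grid_cpp(code, params$b, params$d, A, tau,
                                  n0, times)
    }
    conditions[[ci]] <- list(n0 = n0, counts = counts)
  }
  structure(list(times = times, conditions = conditions, model = spec$id,
                 params = params, design = design),
            class = "trajectory_ensemble")
}

#' Convert an ensemble to the long count-table format
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @return A data.frame with columns `well_id`, `n0`, `time_h`, `count`,
#'   the schema shared with [read_count_table()].
#' @export
as_count_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  pieces <- lapply(ensemble$conditions, function(cond) {
    reps <- nrow(cond$counts)
    data.frame(
      well_id = rep(sprintf("n0%d_w%03d", cond$n0, seq_len(reps)),
                    each = length(ensemble$times)),
      n0 = cond$n0,
      time_h = rep(ensemble$times, times = reps),
      count = as.integer(t(cond$counts)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

#' Add constant measurement noise to summary series
#'
#' Adds i.i.d. zero-mean Gaussian noise of fixed scale to the per-timepoint
#' mean and variance series, emulating the additive measurement noise of an
#' imaging system. The seeding timepoint `t = 0` is left exact and the
#' perturbed variance is floored at 0.
#'
#' @param summaries Summary data.frame from [empirical_moments()].
#' @param noise_sd_mean,noise_sd_variance Noise standard deviations in
#'   cells and cells^2 (>= 0).
#' @param seed Optional seed for the perturbation draws.
#' @return The perturbed summary data.frame.
#' @export
perturb_summaries <- function(summaries, noise_sd_mean = 0.5,
                              noise_sd_variance = 5, seed = NULL) {
  if (noise_sd_mean < 0 || noise_sd_variance < 0) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- summaries
  later <- out$time_h > 0
  n <- sum(later)
  out$mean[later] <- out$mean[later] + rnorm(n, 0, noise_sd_mean)
  out$variance[later] <- pmax(out$variance[later] +
                                rnorm(n, 0, noise_sd_variance), 0)
  out
}
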