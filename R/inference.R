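# Moment-based likelihood machinery.
#
# The measured per-timepoint mean and variance are treated as normally
# distributed around the model's moment-closure mean mu(t, theta) and
# variance Sigma(t, theta), with normal-theory sampling standard
# deviations computed from the model variance itself:
#   sd(sample mean)     = sqrt(Sigma / R)
#   sd(sample variance) = sqrt(2) * Sigma / sqrt(R - 1)
# both floored at 1e-6. The seeding timepoint t = 0 is excluded (both the
# empirical and the model variance are exactly 0 there, which makes the
# Gaussian terms singular).

.SD_FLOOR <- 1e-6
.NLL_PENALTY <- 1e10

#' Sampling standard deviations of the summary statistics
#'
#' Normal-theory standard deviations of the sample mean and sample
#' variance of `R` replicate wells, evaluated at the model variance.
#'
#' @param model_variance Model variance series Sigma(t, theta) (>= 0).
#' @param R Replicate count (>= 2).
#' @param noise_sd_mean,noise_sd_variance Known additive measurement-noise
#'   scales on the observed mean and variance series (cells, cells^2);
#'   combined with the sampling variability in quadrature. Defaults 0,
#'   i.e. pure sampling standard deviations. Set these to the generating
#'   design's noise scales when fitting deliberately noise-perturbed
#'   summaries, otherwise the near-zero model variance at early
#'   timepoints makes those terms dominate the likelihood.
#' @return A list with `sd_mean` and `sd_variance`, floored at 1e-6.
#' @export
#' @examples
#' sampling_sd(2, R = 5)
sampling_sd <- function(model_variance, R, noise_sd_mean = 0,
                        noise_sd_variance = 0) {
  if (R < 2) stop("R must be >= 2", call. = FALSE)
  if (any(model_variance < 0)) stop("model variance must be >= 0", call. = FALSE)
  list(sd_mean = pmax(sqrt(model_variance / R + noise_sd_mean^2), .SD_FLOOR),
       sd_variance = pmax(sqrt(2 * model_variance^2 / (R - 1) +
                                 noise_sd_variance^2), .SD_FLOOR))
}

#' Negative log likelihood of summary series under a moment model
#'
#' Evaluates the Gaussian negative log likelihood of the per-condition
#' mean and variance series, weighting both equally, with the model
#' moments obtained from [solve_moments()] per condition and the sampling
#' standard deviations from [sampling_sd()]. Contributions are summed over
#' conditions and timepoints; `t = 0` is excluded by default.
#'
#' @inheritParams propensities
#' @param summaries Summary data.frame (`n0`, `time_h`, `mean`, `variance`,
#'   `n_replicates`) as produced by [empirical_moments()].
#' @param include_t0 Include the seeding timepoint in the likelihood.
#' @param use_variance Include the variance terms (setting `FALSE` ablates
#'   the likelihood to mean-only, which degrades the identifiability of
#'   `b + d`).
#' @param noise_sd Length-2 vector of known additive measurement-noise
#'   scales on the summary mean and variance, passed to [sampling_sd()].
#' @return The scalar NLL.
#' @export
negative_log_likelihood <- function(model, params, summaries,
                                    include_t0 = FALSE, use_variance = TRUE,
                                    noise_sd = c(0, 0)) {
  spec <- if (is.list(model)) model else model_spec(model)
  total <- 0
  for (g in split(summaries, summaries$n0)) {
    times <- g$time_h
    solve_times <- if (times[1] == 0) times else c(0, times)
    mom <- solve_moments(spec, params, N0 = g$n0[1], times = solve_times)
    mom <- mom[match(times, mom$time), ]
    keep <- if (include_t0) rep(TRUE, nrow(g)) else g$time_h > 0
    sds <- sampling_sd(mom$variance[keep], g$n_replicates[1],
                       noise_sd[1], noise_sd[2])
    rm_ <- (mom$mean[keep] - g$mean[keep]) / sds$sd_mean
    total <- total + 0.5 * sum(log(2 * pi * sds$sd_mean^2) + rm_^2)
    if (use_variance) {
      rv <- (mom$variance[keep] - g$variance[keep]) / sds$sd_variance
      total <- total + 0.5 * sum(log(2 * pi * sds$sd_variance^2) + rv^2)
    }
  }
  total
}

#' Initial parameter guess for the optimizer
#'
#' The net growth rate is seeded with the pooled OLS slope of `log(mean)`
#' on time (per-condition intercepts), the death rate with 5e-4 per hour,
#' the Allee threshold with 1 (strong family) or -1 (extended family), and
#' `tau` with 2 -- deliberately conservative starting values.
#'
#' @inheritParams negative_log_likelihood
#' @return A named numeric vector of starting parameters for `model`.
#' @export
initial_guess <- function(summaries, model) {
  spec <- if (is.list(model)) model else model_spec(model)
  df <- summaries[summaries$mean > 0, ]
  fml <- if (length(unique(df$n0)) > 1L) {
    log(mean) ~ time_h + factor(n0)
  } else {
    log(mean) ~ time_h
  }
  g0 <- unname(coef(lm(fml, data = df))["time_h"])
  if (!is.finite(g0) || g0 < 1e-8) {
    warning("non-positive pooled growth-rate slope; flooring initial g at 1e-4",
            call. = FALSE)
    g0 <- 1e-4
  }
  start <- c(b = g0 + 5e-4, d = 5e-4)
  if (spec$family == "strong_allee") start <- c(start, A = 1)
  if (spec$family == "extended_allee") start <- c(start, A = -1, tau = 2)
  start
}

# parameter transforms ------------------------------------------------------
# b, d are log-transformed; A and tau are affinely normalised to [0, 1]
# over configurable domains (defaults A in [-20, 20], tau in [0, 50]).
# The simplex runs unconstrained in the transformed coordinates; the
# domains set the scale, they are not hard bounds.

.to_opt <- function(theta, spec, A_domain, tau_domain) {
  u <- c(log(theta[["b"]]), log(theta[["d"]]))
  if ("A" %in% spec$par_names) {
    u <- c(u, (theta[["A"]] - A_domain[1]) / diff(A_domain))
  }
  if ("tau" %in% spec$par_names) {
    u <- c(u, (theta[["tau"]] - tau_domain[1]) / diff(tau_domain))
  }
  unname(u)
}

.from_opt <- function(u, spec, A_domain, tau_domain) {
  theta <- c(b = exp(u[1]), d = exp(u[2]))
  i <- 3L
  if ("A" %in% spec$par_names) {
    theta <- c(theta, A = A_domain[1] + u[i] * diff(A_domain)); i <- i + 1L
  }
  if ("tau" %in% spec$par_names) {
    theta <- c(theta, tau = tau_domain[1] + u[i] * diff(tau_domain))
  }
  theta
}

.theta_to_params <- function(theta, spec) {
  rate_params(b = theta[["b"]], d = theta[["d"]],
              A = if ("A" %in% spec$par_names) theta[["A"]] else NA_real_,
              tau = if ("tau" %in% spec$par_names) theta[["tau"]] else NA_real_)
}

# Penalised objective used by the simplex: invalid parameter regions and
# integration failures return a large finite value so the search recovers.
.make_objective <- function(spec, summaries, A_domain, tau_domain,
                            include_t0 = FALSE, use_variance = TRUE,
                            noise_sd = c(0, 0)) {
  force(spec); force(summaries)
  n0_min <- min(summaries$n0)
  function(u) {
    theta <- .from_opt(u, spec, A_domain, tau_domain)
    if (any(!is.finite(theta))) return(.NLL_PENALTY)
    if ("tau" %in% spec$par_names && theta[["tau"]] <= -1 + 1e-9) {
      return(.NLL_PENALTY)
    }
    # A >= smallest N0 sends that condition's mean into decline towards the
    # Allee-factor singularity; reject without integrating
    if ("A" %in% spec$par_names && theta[["A"]] >= n0_min) {
      return(.NLL_PENALTY)
    }
    val <- tryCatch(
      negative_log_likelihood(spec, .theta_to_params(theta, spec), summaries,
                              include_t0 = include_t0,
                              use_variance = use_variance,
                              noise_sd = noise_sd),
      error = function(e) .NLL_PENALTY)
    if (!is.finite(val)) .NLL_PENALTY else val
  }
}

# Nelder-Mead minimisation (Brent for one free coordinate).
.minimise <- function(par, fn, control) {
  if (length(par) == 1L) {
    optim(par, fn, method = "Brent", lower = par - 25, upper = par + 25)
  } else {
    optim(par, fn, method = "Nelder-Mead",
          control = list(maxit = control$maxit, reltol = control$reltol))
  }
}
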