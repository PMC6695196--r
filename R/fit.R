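#' Fit a stochastic growth model to summary series
#'
#' Maximum-likelihood fit of one of the seven stochastic birth-death
#' models to per-condition mean/variance summary series, by Nelder-Mead
#' minimisation of the moment-based negative log likelihood
#' ([negative_log_likelihood()]). Rate constants are optimised on the log
#' scale; `A` and `tau` are affinely normalised to `[0, 1]` over
#' `A_domain` and `tau_domain`. The fit is deterministic given the data
#' and settings.
#'
#' @param summaries Summary data.frame (`n0`, `time_h`, `mean`,
#'   `variance`, `n_replicates`), e.g. from [empirical_moments()].
#' @param model Model identifier (see [allee_models()]).
#' @param start Optional named starting vector; defaults to
#'   [initial_guess()].
#' @param A_domain,tau_domain Normalisation domains for the Allee
#'   parameters.
#' @param include_t0,use_variance,noise_sd Likelihood options, see
#'   [negative_log_likelihood()]. When fitting summaries that carry known
#'   injected measurement noise (a simulation-study design), pass the
#'   design's noise scales as `noise_sd` so the observation model matches
#'   the data-generating process.
#' @param control List with `maxit` (default 5000) and `reltol`
#'   (default 1e-8) for the simplex.
#' @param restarts Maximum number of deterministic simplex restarts from
#'   the incumbent optimum (the restart loop stops early once a restart
#'   improves the NLL by less than 1e-6).
#' @return An object of class `allee_fit` with methods `print`,
#'   `summary`, `coef`, `logLik`, `nobs`, `predict`, `residuals`, `plot`,
#'   `simulate`, `profile` and `confint`.
#' @seealso [compare_models()] for BIC selection across fits,
#'   [profile.allee_fit()] for profile-likelihood intervals.
#' @export
#' @examples
#' pd <- preset_design("simulation_study", replicates = 40, seed = 42)
#' ens <- simulate_ensemble(pd$design, pd$model, pd$params)
#' sm <- empirical_moments(as_count_table(ens))
#' fit <- allee_fit(sm, "simple_bd")
#' coef(fit)
allee_fit <- function(summaries, model = "simple_bd", start = NULL,
                      A_domain = c(-20, 20), tau_domain = c(0, 50),
                      include_t0 = FALSE, use_variance = TRUE,
                      noise_sd = c(0, 0),
                      control = list(maxit = 5000, reltol = 1e-8),
                      restarts = 3L) {
  spec <- if (is.list(model)) model else model_spec(model)
  control <- utils::modifyList(list(maxit = 5000, reltol = 1e-8), control)
  summaries <- summaries[order(summaries$n0, summaries$time_h), ]
  if (any(summaries$n_replicates < 2)) {
    stop("every condition needs at least 2 replicates", call. = FALSE)
  }
  if (is.null(start)) start <- initial_guess(summaries, spec)
  obj <- .make_objective(spec, summaries, A_domain, tau_domain,
                         include_t0 = include_t0, use_variance = use_variance,
                         noise_sd = noise_sd)
  u0 <- .to_opt(as.list(start), spec, A_domain, tau_domain)
  opt <- optim(u0, obj, method = "Nelder-Mead",
               control = list(maxit = control$maxit, reltol = control$reltol))
  evals <- opt$counts
  for (r in seq_len(restarts)) {
    opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                  control = list(maxit = control$maxit,
                                 reltol = control$reltol))
    evals <- evals + opt2$counts
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-6) break
  }
  opt$counts <- evals
  theta <- .from_opt(opt$par, spec, A_domain, tau_domain)
  n_used <- sum(if (include_t0) rep(TRUE, nrow(summaries)) else summaries$time_h > 0)
  n_data <- n_used * (if (use_variance) 2L else 1L)
  structure(list(
    call = match.call(),
    model = spec,
    coefficients = theta,
    g = unname(theta[["b"]] - theta[["d"]]),
    nll = opt$value,
    converged = opt$convergence == 0L,
    counts = opt$counts,
    n_data = n_data,
    conditions = sort(unique(summaries$n0)),
    summaries = summaries,
    settings = list(A_domain = A_domain, tau_domain = tau_domain,
                    include_t0 = include_t0, use_variance = use_variance,
                    noise_sd = noise_sd, control = control, start = start)
  ), class = "allee_fit")
}

#' Fit one model separately to each initial condition
#'
#' Applies [allee_fit()] to every condition in turn (typically with the
#' simple birth-death model, to expose trends of `b` and `d` with N0 that
#' signal an Allee effect).
#'
#' @inheritParams allee_fit
#' @param ... Passed on to [allee_fit()].
#' @return A named list of `allee_fit` objects, keyed by N0, with a
#'   `trend` attribute: a data.frame of per-condition `b`, `d`, `g`.
#' @export
fit_per_condition <- function(summaries, model = "simple_bd", ...) {
  fits <- lapply(split(summaries, summaries$n0), allee_fit, model = model, ...)
  trend <- do.call(rbind, lapply(names(fits), function(nm) {
    cf <- coef(fits[[nm]])
    data.frame(n0 = as.numeric(nm), b = cf[["b"]], d = cf[["d"]],
               g = cf[["b"]] - cf[["d"]])
  }))
  rownames(trend) <- NULL
  attr(fits, "trend") <- trend
  fits
}

# methods -------------------------------------------------------------------

#' @export
print.allee_fit <- function(x, digits = 4, ...) {
  cat("Stochastic growth model fit:", x$model$id,
      sprintf("(%s family)\n", x$model$family))
  cat("Conditions N0:", paste(x$conditions, collapse = ", "),
      " | fitted observations:", x$n_data, "\n")
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("Net growth g = b - d: %.*g per hour\n", digits, x$g))
  cat(sprintf("NLL: %.*g | BIC: %.*g | converged: %s\n",
              digits, x$nll, digits, BIC(x), x$converged))
  invisible(x)
}

#' @export
coef.allee_fit <- function(object, ...) object$coefficients

#' @export
logLik.allee_fit <- function(object, ...) {
  structure(-object$nll, df = object$model$n_params, nobs = object$n_data,
            class = "logLik")
}

#' @export
nobs.allee_fit <- function(object, ...) object$n_data

#' @export
summary.allee_fit <- function(object, ...) {
  out <- list(fit = object,
              regime = if (object$model$family == "exponential") "none"
                       else classify_regime(.theta_to_params(object$coefficients,
                                                             object$model)))
  class(out) <- "summary.allee_fit"
  out
}

#' @export
print.summary.allee_fit <- function(x, ...) {
  print(x$fit)
  cat("Allee regime at the MLE:", x$regime, "\n")
  invisible(x)
}

#' Model mean and variance at the fitted parameters
#'
#' @param object An `allee_fit`.
#' @param times Optional time grid (defaults to the fitted grid).
#' @param n0 Optional initial conditions (defaults to the fitted ones).
#' @param ... Unused.
#' @return data.frame `n0`, `time_h`, `mean`, `variance`.
#' @export
predict.allee_fit <- function(object, times = NULL, n0 = NULL, ...) {
  params <- .theta_to_params(object$coefficients, object$model)
  n0 <- n0 %||% object$conditions
  out <- do.call(rbind, lapply(n0, function(nn) {
    tt <- times %||% sort(unique(object$summaries$time_h[object$summaries$n0 == nn]))
    if (tt[1] != 0) tt <- c(0, tt)
    mom <- solve_moments(object$model, params, N0 = nn, times = tt)
    data.frame(n0 = nn, time_h = mom$time, mean = mom$mean,
               variance = mom$variance)
  }))
  rownames(out) <- NULL
  out
}

#' Standardised residuals of the summary fit
#'
#' @param object An `allee_fit`.
#' @param ... Unused.
#' @return data.frame with `n0`, `time_h`, `statistic` (`"mean"` or
#'   `"variance"`), `residual` (data minus model, in sampling-sd units).
#' @export
residuals.allee_fit <- function(object, ...) {
  params <- .theta_to_params(object$coefficients, object$model)
  out <- do.call(rbind, lapply(split(object$summaries, object$summaries$n0),
    function(g) {
      keep <- if (object$settings$include_t0) rep(TRUE, nrow(g)) else g$time_h > 0
      tt <- g$time_h
      mom <- solve_moments(object$model, params, N0 = g$n0[1],
                           times = if (tt[1] == 0) tt else c(0, tt))
      mom <- mom[match(tt, mom$time), ]
      sds <- sampling_sd(mom$variance[keep], g$n_replicates[1])
      rbind(
        data.frame(n0 = g$n0[1], time_h = tt[keep], statistic = "mean",
                   residual = (g$mean[keep] - mom$mean[keep]) / sds$sd_mean),
        data.frame(n0 = g$n0[1], time_h = tt[keep], statistic = "variance",
                   residual = (g$variance[keep] - mom$variance[keep]) / sds$sd_variance)
      )
    }))
  rownames(out) <- NULL
  out
}

#' Plot data and fitted moments
#'
#' Two base-graphics panels: per-condition empirical mean and variance
#' series with the fitted model moments overlaid.
#'
#' @param x An `allee_fit`.
#' @param ... Unused.
#' @export
plot.allee_fit <- function(x, ...) {
  pred <- predict(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- seq_along(x$conditions)
  for (stat in c("mean", "variance")) {
    graphics::plot(NA, xlim = range(x$summaries$time_h),
                   ylim = range(c(x$summaries[[stat]], pred[[stat]])),
                   xlab = "time (h)", ylab = paste(stat, "cell number"),
                   main = x$model$id)
    for (i in seq_along(x$conditions)) {
      g <- x$summaries[x$summaries$n0 == x$conditions[i], ]
      p <- pred[pred$n0 == x$conditions[i], ]
      graphics::points(g$time_h, g[[stat]], col = cols[i], pch = 16, cex = 0.4)
      graphics::lines(p$time_h, p[[stat]], col = cols[i], lwd = 2)
    }
    graphics::legend("topleft", legend = paste0("N0=", x$conditions),
                     col = cols, lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Simulate replicate trajectories at the fitted parameters
#'
#' @param object An `allee_fit`.
#' @param nsim Replicates per condition.
#' @param seed Master seed.
#' @param ... Unused.
#' @return A count table (`well_id`, `n0`, `time_h`, `count`).
#' @export
simulate.allee_fit <- function(object, nsim = 30, seed = 1L, ...) {
  times <- sort(unique(object$summaries$time_h))
  dt <- unique(diff(times))[1]
  design <- experiment_design(object$conditions, replicates = nsim,
                              horizon = max(times), sampling_interval = dt,
                              seed = seed)
  params <- .theta_to_params(object$coefficients, object$model)
  as_count_table(simulate_ensemble(design, object$model, params))
}
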