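#' Profile-likelihood uncertainty analysis
#'
#' For each requested parameter, fixes it on a grid expanding outward from
#' the MLE, refits all remaining free parameters at every fixed value
#' (warm-started from the neighbouring solution), and locates the 95%
#' confidence interval as the set of values whose profiled NLL stays
#' within `qchisq(level, 1)/2` (1.92 at 95%) of the minimum, with linear
#' interpolation at the threshold crossings. Profiling is done on the
#' natural parameter scale; rate parameters are bounded below at 0. A side
#' on which the threshold is never crossed (domain boundary or step limit)
#' is returned as `NA` and flagged practically unidentifiable on that
#' side.
#'
#' @param fitted An [allee_fit()] object.
#' @param which Parameter names to profile (default: all).
#' @param level Confidence level (default 0.95).
#' @param max_steps Maximum grid points per side.
#' @param ... Unused.
#' @return An object of class `allee_profile`: a named list with, per
#'   parameter, `points` (data.frame `value`, `nll`), `ci`, `flags`;
#'   plus attributes `level`, `nll_min`, `estimate`.
#' @export
#' @examples
#' \donttest{
#' pd <- preset_design("simulation_study", replicates = 60, seed = 3)
#' ens <- simulate_ensemble(pd$design, pd$model, pd$params)
#' fit <- allee_fit(empirical_moments(as_count_table(ens)), "simple_bd")
#' pr <- profile(fit, which = "b")
#' confint(pr)
#' }
profile.allee_fit <- function(fitted, which = NULL, level = 0.95,
                              max_steps = 40L, ...) {
  spec <- fitted$model
  pars <- spec$par_names
  which <- which %||% pars
  stopifnot(all(which %in% pars))
  threshold <- qchisq(level, df = 1) / 2
  theta_hat <- fitted$coefficients
  sett <- fitted$settings
  out <- list()
  for (pn in which) {
    out[[pn]] <- .profile_one(fitted, pn, threshold, max_steps)
  }
  structure(out, class = "allee_profile", level = level,
            nll_min = fitted$nll, estimate = theta_hat, model = spec$id)
}

# Profile a single parameter: adaptive outward walk on each side.
.profile_one <- function(fitted, pn, threshold, max_steps) {
  spec <- fitted$model
  sett <- fitted$settings
  theta_hat <- fitted$coefficients
  free <- setdiff(spec$par_names, pn)
  est <- theta_hat[[pn]]
  nll_min <- fitted$nll

  # reduced spec: same model, but pn held fixed during refits
  refit <- function(fix_value, warm_theta) {
    obj_full <- .make_objective(spec, fitted$summaries, sett$A_domain,
                                sett$tau_domain, sett$include_t0,
                                sett$use_variance, sett$noise_sd %||% c(0, 0))
    # optimise over the free coordinates only
    u_warm <- .to_opt(as.list(warm_theta), spec, sett$A_domain, sett$tau_domain)
    idx_fixed <- match(pn, spec$par_names)
    theta_fix <- warm_theta
    theta_fix[[pn]] <- fix_value
    u_fix_all <- .to_opt(as.list(theta_fix), spec, sett$A_domain, sett$tau_domain)
    fn <- function(u_free) {
      u <- u_fix_all
      u[-idx_fixed] <- u_free
      obj_full(u)
    }
    opt <- .minimise(u_fix_all[-idx_fixed], fn, sett$control)
    u <- u_fix_all
    u[-idx_fixed] <- opt$par
    list(nll = opt$value,
         theta = .from_opt(u, spec, sett$A_domain, sett$tau_domain))
  }

  step0 <- switch(pn,
    b = max(abs(est) * 0.02, 2e-6),
    d = max(abs(est) * 0.02, 2e-6),
    A = max(abs(est) * 0.02, 0.02),
    tau = max(abs(est) * 0.02, 0.05))
  lower_bound <- if (pn %in% c("b", "d")) 0 else -Inf

  walk <- function(dir) {
    pts <- data.frame(value = numeric(0), nll = numeric(0))
    step <- step0
    val <- est
    warm <- theta_hat
    hit_bound <- FALSE
    for (i in seq_len(max_steps)) {
      val2 <- val + dir * step
      if (val2 < lower_bound) {
        val2 <- lower_bound
        hit_bound <- TRUE
      }
      r <- refit(val2, warm)
      pts <- rbind(pts, data.frame(value = val2, nll = r$nll))
      warm <- r$theta
      dnll <- r$nll - nll_min
      if (is.finite(dnll) && dnll > threshold + 0.5) break
      if (hit_bound) break
      if (is.finite(dnll) && dnll < 0.3 * threshold) step <- step * 1.7
      val <- val2
    }
    list(points = pts, hit_bound = hit_bound)
  }

  lo <- walk(-1)
  hi <- walk(+1)
  pts <- rbind(lo$points[rev(seq_len(nrow(lo$points))), , drop = FALSE],
               data.frame(value = est, nll = nll_min),
               hi$points)
  rownames(pts) <- NULL

  ci_side <- function(side_pts, bound_hit) {
    dn <- side_pts$nll - nll_min
    crossed <- which(dn > threshold)
    if (!length(crossed)) {
      return(list(bound = NA_real_,
                  flag = if (bound_hit) "bounded" else "not_crossed"))
    }
    j <- crossed[1]
    if (j == 1L) {
      x0 <- est; y0 <- 0
    } else {
      x0 <- side_pts$value[j - 1L]; y0 <- dn[j - 1L]
    }
    x1 <- side_pts$value[j]; y1 <- dn[j]
    list(bound = x0 + (threshold - y0) / (y1 - y0) * (x1 - x0), flag = "ok")
  }
  lo_ci <- ci_side(lo$points, lo$hit_bound)
  hi_ci <- ci_side(hi$points, hi$hit_bound)

  list(parameter = pn, estimate = est, points = pts,
       ci = c(lower = lo_ci$bound, upper = hi_ci$bound),
       flags = c(lower = lo_ci$flag, upper = hi_ci$flag))
}

#' @export
print.allee_profile <- function(x, digits = 4, ...) {
  cat("Profile likelihood for model", attr(x, "model"),
      sprintf("(%.0f%% CIs, chi-square threshold %.3g)\n",
              100 * attr(x, "level"), qchisq(attr(x, "level"), 1) / 2))
  ci <- confint(x)
  print(signif(ci, digits))
  for (pn in names(x)) {
    fl <- x[[pn]]$flags
    if (any(fl != "ok")) {
      cat(sprintf("  %s: %s\n", pn, paste(names(fl)[fl != "ok"],
                                          fl[fl != "ok"], collapse = "; ")))
    }
  }
  invisible(x)
}

#' @export
confint.allee_profile <- function(object, parm = NULL, level = NULL, ...) {
  parm <- parm %||% names(object)
  out <- t(vapply(object[parm], function(p) c(p$estimate, p$ci), numeric(3)))
  colnames(out) <- c("estimate", "lower", "upper")
  out
}

#' @export
confint.allee_fit <- function(object, parm = NULL, level = 0.95, ...) {
  confint(profile(object, which = parm, level = level, ...))
}

#' @export
plot.allee_profile <- function(x, ...) {
  np <- length(x)
  op <- graphics::par(mfrow = c(1, np), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  thr <- qchisq(attr(x, "level"), 1) / 2
  for (pn in names(x)) {
    p <- x[[pn]]
    dn <- p$points$nll - attr(x, "nll_min")
    graphics::plot(p$points$value, dn, type = "b", pch = 16, cex = 0.6,
                   xlab = pn, ylab = expression(Delta * NLL), main = pn)
    graphics::abline(h = thr, lty = 2)
    graphics::abline(v = p$estimate, col = 2)
  }
  invisible(x)
}
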