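#' The seven candidate stochastic growth models
#'
#' Canonical identifiers of the stochastic birth-death models, grouped in
#' three families by their deterministic mean behaviour:
#' \describe{
#'   \item{exponential}{`simple_bd` -- constant per-capita birth and death
#'     rates `b`, `d`; mean grows as `N0 * exp((b - d) t)`.}
#'   \item{strong_allee}{`strongA_birth`, `strongA_death`, `strongA_both` --
#'     the net growth of the mean carries a factor `(1 - A/N)`, so
#'     populations below the Allee threshold `A > 0` decline on average.}
#'   \item{extended_allee}{`extA_birth`, `extA_death`, `extA_both` -- factor
#'     `(1 - (A + tau)/(N + tau))`; with `A < 0` and `tau > |A|` this is a
#'     weak Allee effect (growth positive everywhere but depressed at small
#'     `N`).}
#' }
#' Within each Allee family the `_birth`, `_death`, `_both` variants place
#' the Allee term on the birth rate, the death rate, or split it equally;
#' they share the same mean dynamics and differ only in their variance.
#'
#' @return Character vector of the 7 model identifiers.
#' @export
#' @examples
#' allee_models()
allee_models <- function() {
  c("simple_bd",
    "strongA_birth", "strongA_death", "strongA_both",
    "extA_birth", "extA_death", "extA_both")
}

# internal registry ---------------------------------------------------------

.model_table <- function() {
  data.frame(
    id = allee_models(),
    family = c("exponential", rep("strong_allee", 3), rep("extended_allee", 3)),
    effect = c("none", "birth", "death", "both", "birth", "death", "both"),
    n_params = c(2L, 3L, 3L, 3L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

.model_code <- function(id) {
  code <- match(id, allee_models()) - 1L
  if (is.na(code)) stop("unknown model id: ", id, call. = FALSE)
  code
}

#' Look up a model specification
#'
#' @param id One of the identifiers returned by [allee_models()].
#' @return A list with elements `id`, `family` (`exponential`,
#'   `strong_allee` or `extended_allee`), `effect` (`none`, `birth`,
#'   `death`, `both`), `n_params` (2, 3 or 4 free parameters) and
#'   `par_names`.
#' @export
#' @examples
#' model_spec("strongA_birth")
model_spec <- function(id) {
  tab <- .model_table()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1L) stop("unknown model id: ", id, call. = FALSE)
  par_names <- switch(row$family,
    exponential = c("b", "d"),
    strong_allee = c("b", "d", "A"),
    extended_allee = c("b", "d", "A", "tau")
  )
  list(id = row$id, family = row$family, effect = row$effect,
       n_params = row$n_params, par_names = par_names)
}

#' Rate parameters of a stochastic growth model
#'
#' Bundles and validates the rate constants: birth rate `b` and death rate
#' `d` (per cell per hour), Allee threshold `A` (cells; may be negative in
#' the extended family) and extended-family shape parameter `tau` (cells).
#' The net growth rate `g = b - d` is always derived, never stored.
#'
#' @param b,d Non-negative birth and death rate constants (per cell per hour).
#' @param A Allee threshold in cells (`NA` for the exponential family).
#' @param tau Shape parameter in cells; must exceed -1 so that `n + tau > 0`
#'   for every occupied state `n >= 1`.
#' @return A named list of class `rate_params` with a derived element `g`.
#' @export
#' @examples
#' p <- rate_params(b = 0.0238, d = 0.005, A = 2)
#' p$g
rate_params <- function(b, d, A = NA_real_, tau = NA_real_) {
  stopifnot(is.numeric(b), is.numeric(d), length(b) == 1L, length(d) == 1L)
  if (!is.finite(b) || b < 0) stop("b must be >= 0", call. = FALSE)
  if (!is.finite(d) || d < 0) stop("d must be >= 0", call. = FALSE)
  if (!is.na(tau) && tau <= -1) stop("tau must be > -1", call. = FALSE)
  structure(list(b = b, d = d, A = A, tau = tau, g = b - d),
            class = "rate_params")
}

.check_params_for <- function(spec, params) {
  if (!inherits(params, "rate_params")) {
    params <- do.call(rate_params, params[intersect(names(params),
                                                    c("b", "d", "A", "tau"))])
  }
  if (spec$family != "exponential" && is.na(params$A)) {
    stop("model ", spec$id, " requires an Allee threshold A", call. = FALSE)
  }
  if (spec$family == "extended_allee" && is.na(params$tau)) {
    stop("model ", spec$id, " requires the shape parameter tau", call. = FALSE)
  }
  params
}

# propensities --------------------------------------------------------------

#' Total birth and death event rates
#'
#' Evaluates the total propensities (events per hour) of the birth and
#' death channels at cell count `n`. The Allee term of the `_birth`,
#' `_death` and `_both` variants shifts the corresponding total rate by
#' `(b - d) A` (strong family) or `(b - d) n (A + tau)/(n + tau)` (extended
#' family), split in half for the `_both` variants. Raw rates that fall
#' below zero at small `n` are clamped to 0, and `n = 0` is absorbing
#' (both rates exactly 0), so extinction is permanent.
#'
#' @param model Model identifier (see [allee_models()]) or a [model_spec()].
#' @param params A [rate_params()] object (or a list with the same fields).
#' @param n Non-negative integer cell count(s); vectorised.
#' @return A two-column matrix with columns `birth` and `death`, one row
#'   per element of `n` (dropped to a named vector for scalar `n`).
#' @export
#' @examples
#' propensities("simple_bd", rate_params(0.0238, 0.005), n = 10)
#' propensities("strongA_birth", rate_params(0.0238, 0.005, A = 2), n = 0:3)
propensities <- function(model, params, n) {
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  if (any(n < 0) || any(n != floor(n))) {
    stop("n must be non-negative integer(s)", call. = FALSE)
  }
  out <- propensities_cpp(.model_code(spec$id), params$b, params$d,
                          if (is.na(params$A)) 0 else params$A,
                          if (is.na(params$tau)) 0 else params$tau,
                          as.numeric(n))
  colnames(out) <- c("birth", "death")
  if (length(n) == 1L) out[1L, ] else out
}

# deterministic laws --------------------------------------------------------

#' Deterministic per-family growth law
#'
#' Right-hand side dN/dt (cells per hour) of the deterministic growth
#' models: exponential `g N`, strong Allee `g (1 - A/N) N`, extended Allee
#' `g (1 - (A + tau)/(N + tau)) N`, with `g = b - d`.
#'
#' @param family One of `"exponential"`, `"strong_allee"`,
#'   `"extended_allee"`.
#' @param params A [rate_params()] object.
#' @param N Positive cell number (real-valued); vectorised.
#' @return dN/dt in cells per hour.
#' @export
deterministic_rhs <- function(family, params, N) {
  family <- match.arg(family, c("exponential", "strong_allee", "extended_allee"))
  if (any(N <= 0)) stop("N must be > 0", call. = FALSE)
  g <- params$b - params$d
  switch(family,
    exponential = g * N,
    strong_allee = g * (1 - params$A / N) * N,
    extended_allee = {
      if (any(N + params$tau <= 0)) stop("N + tau must be > 0", call. = FALSE)
      g * (1 - (params$A + params$tau) / (N + params$tau)) * N
    }
  )
}

#' Classify the Allee regime implied by (A, tau)
#'
#' A positive threshold `A` gives a strong Allee effect (deterministic
#' extinction below `A`); `A < 0` with `tau > |A|` gives a weak Allee
#' effect (growth positive everywhere but depressed at small n); `A = 0`
#' collapses the Allee factor to 1 (no effect). `A < 0` with
#' `tau <= |A|` does not correspond to either regime and is reported as
#' `"undefined"`.
#'
#' @param params A [rate_params()] object with `A` set (and `tau` for the
#'   extended family).
#' @return One of `"strong"`, `"weak"`, `"none"`, `"undefined"`.
#' @export
#' @examples
#' classify_regime(rate_params(0.0238, 0.005, A = 5, tau = 0))
#' classify_regime(rate_params(0.0101, 4.3613e-5, A = -3.1576, tau = 7.480))
classify_regime <- function(params) {
  A <- params$A
  tau <- if (is.na(params$tau)) 0 else params$tau
  if (is.na(A)) stop("A is not set", call. = FALSE)
  if (A > 0) "strong"
  else if (A == 0) "none"
  else if (tau > abs(A)) "weak"
  else "undefined"
}

# moment-closure ODEs -------------------------------------------------------

#' Moment-closure time derivatives of mean and variance
#'
#' The closed ODE system for the first two moments of each stochastic
#' model. All members of a family share the mean equation
#' `dM/dt = (b - d) M (1 - phi)` where `phi` is 0, `A/M`, or
#' `(A + tau)/(M + tau)`; the variance equations differ by where the Allee
#' term acts:
#' `dS/dt = 2 (b - d) S + (b + d) M + s (b - d) c`, with `c = A` (strong)
#' or `M phi` (extended) and `s = -1`, `+1`, `0` for the `_birth`,
#' `_death`, and `_both`/simple variants.
#'
#' @inheritParams propensities
#' @param mean Current mean cell number (> 0).
#' @param variance Current variance in cell number (>= 0).
#' @return Named numeric vector `c(dmean, dvariance)` (per hour).
#' @export
#' @examples
#' moment_rhs("simple_bd", rate_params(0.0238, 0.005), mean = 10, variance = 4)
moment_rhs <- function(model, params, mean, variance) {
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  if (spec$family == "extended_allee" && mean + params$tau <= 0) {
    stop("mean + tau must be > 0", call. = FALSE)
  }
  dy <- moment_rhs_cpp(.model_code(spec$id), params$b, params$d,
                       if (is.na(params$A)) 0 else params$A,
                       if (is.na(params$tau)) 0 else params$tau,
                       c(mean, variance))
  c(dmean = dy[1], dvariance = dy[2])
}

#' Integrate the moment-closure ODEs
#'
#' Solves the mean/variance system of [moment_rhs()] from the exact initial
#' condition `(N0, 0)` on a supplied time grid with a stiff-capable
#' adaptive integrator (`deSolve::lsoda`, rtol 1e-8, atol 1e-10). Tiny
#' negative variances produced by the closure near `t = 0` are clipped
#' at 0.
#'
#' @inheritParams propensities
#' @param N0 Initial cell number (>= 1).
#' @param times Strictly increasing time grid in hours starting at 0.
#' @param rtol,atol Integration tolerances.
#' @return A data.frame with columns `time`, `mean`, `variance`.
#' @export
#' @examples
#' solve_moments("simple_bd", rate_params(0.0238, 0.005), N0 = 5,
#'               times = seq(0, 100, by = 4))
solve_moments <- function(model, params, N0, times, rtol = 1e-8, atol = 1e-10) {
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  if (N0 < 1) stop("N0 must be >= 1", call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  code <- .model_code(spec$id)
  b <- params$b; d <- params$d
  A <- if (is.na(params$A)) 0 else params$A
  tau <- if (is.na(params$tau)) 0 else params$tau
  rhs <- function(t, y, p) list(moment_rhs_cpp(code, b, d, A, tau, y))
  sol <- try(suppressWarnings(
    deSolve::ode(y = c(N0, 0), times = times, func = rhs, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      any(!is.finite(sol[, 2:3]))) {
    stop(sprintf("moment integration failed for model %s (b=%.4g, d=%.4g, A=%.4g, tau=%.4g)",
                 spec$id, b, d, A, tau), call. = FALSE)
  }
  data.frame(time = sol[, 1], mean = sol[, 2], variance = pmax(sol[, 3], 0))
}

# master equation -----------------------------------------------------------

#' Solve the truncated master equation
#'
#' Direct integration of the probability distribution `p_n(t)` over the
#' truncated state space `n = 0..n_max` under the chosen model's birth and
#' death propensities. Used as an exact (up to truncation) oracle for the
#' moment-closure approximations. The birth channel out of `n_max` is
#' switched off so probability mass is conserved; the solution is rejected
#' if more than `1e-6` of the terminal mass sits in the top 0.1% of states,
#' which signals that `n_max` was chosen too small.
#'
#' @inheritParams solve_moments
#' @param n_max Truncation state (integer).
#' @return A list with `times`, `p` (matrix, rows = times, columns = states
#'   `0..n_max`), `mean` and `variance` derived from `p`.
#' @export
solve_master_equation <- function(model, params, N0, times, n_max,
                                  rtol = 1e-10, atol = 1e-12) {
  spec <- if (is.list(model)) model else model_spec(model)
  params <- .check_params_for(spec, params)
  if (N0 > n_max) stop("N0 exceeds n_max", call. = FALSE)
  states <- 0:n_max
  rates <- propensities(spec, params, states)
  br <- rates[, "birth"]; dr <- rates[, "death"]
  br[n_max + 1L] <- 0  # reflecting truncation keeps total mass at 1
  p0 <- numeric(n_max + 1L)
  p0[N0 + 1L] <- 1
  rhs <- function(t, p, parms) {
    inflow_birth <- c(0, br[-(n_max + 1L)] * p[-(n_max + 1L)])
    inflow_death <- c(dr[-1L] * p[-1L], 0)
    list(inflow_birth + inflow_death - (br + dr) * p)
  }
  sol <- deSolve::ode(y = p0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint", bandup = 1L,
                      banddown = 1L, rtol = rtol, atol = atol)
  p <- sol[, -1L, drop = FALSE]
  top <- states > 0.999 * n_max
  leak <- sum(p[nrow(p), top])
  if (leak > 1e-6) {
    stop(sprintf("probability mass %.3g in top states at final time; increase n_max (= %d)",
                 leak, n_max), call. = FALSE)
  }
  m <- as.vector(p %*% states)
  m2 <- as.vector(p %*% states^2)
  list(times = times, p = p, mean = m, variance = pmax(m2 - m^2, 0))
}
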