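#' BIC score of a fit
#'
#' `BIC = 2 NLL + k log(n_data)`, where `k` is the number of free
#' parameters and `n_data` counts every mean and every variance
#' observation entering the likelihood (both are separate likelihood
#' terms). Equivalent to `stats::BIC()` on the fit's `logLik`.
#'
#' @param nll Negative log likelihood at the MLE (or an `allee_fit`).
#' @param k Number of free parameters.
#' @param n_data Number of fitted observations.
#' @return The BIC value.
#' @export
#' @examples
#' bic_score(100, k = 3, n_data = 200)
bic_score <- function(nll, k = NULL, n_data = NULL) {
  if (inherits(nll, "allee_fit")) {
    fit <- nll
    return(bic_score(fit$nll, fit$model$n_params, fit$n_data))
  }
  stopifnot(is.finite(nll), n_data >= 1)
  2 * nll + k * log(n_data)
}

#' Compare fitted models by BIC
#'
#' Computes per-model BIC, differences to the best model
#' (`delta_bic = BIC_i - BIC_min`) and BIC weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`, ranks the models
#' (ascending BIC; ties broken by fewer parameters, then lexical id) and
#' names the selected model.
#'
#' @param fits A list of [allee_fit()] objects fitted to identical data.
#' @return A data.frame of class `allee_selection` with columns `model`,
#'   `k`, `nll`, `bic`, `delta_bic`, `bic_weight`, `rank`, ordered by
#'   rank, and attribute `selected`.
#' @export
#' @examples
#' \donttest{
#' pd <- preset_design("simulation_study", replicates = 50, seed = 5)
#' sm <- empirical_moments(as_count_table(
#'   simulate_ensemble(pd$design, pd$model, pd$params)))
#' fits <- lapply(c("simple_bd", "strongA_birth"), function(m)
#'   allee_fit(sm, m))
#' compare_models(fits)
#' }
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L)
  nd <- vapply(fits, function(f) f$n_data, numeric(1))
  conds <- lapply(fits, function(f) f$conditions)
  if (length(unique(nd)) != 1L ||
      !all(vapply(conds, identical, logical(1), y = conds[[1]]))) {
    stop("fits were not made on identical data", call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$id, character(1)),
    k = vapply(fits, function(f) f$model$n_params, numeric(1)),
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$bic <- 2 * tab$nll + tab$k * log(nd[1])
  tab$delta_bic <- tab$bic - min(tab$bic)
  w <- exp(-tab$delta_bic / 2)
  tab$bic_weight <- w / sum(w)
  # snap near-ties (float noise) so parsimony tie-breaking is deterministic
  ord <- order(round(tab$bic, 7), tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("allee_selection", "data.frame"),
            selected = tab$model[1], n_data = nd[1])
}

#' @export
print.allee_selection <- function(x, digits = 4, ...) {
  cat("Model selection over", nrow(x), "candidates (n_data =",
      attr(x, "n_data"), ")\n")
  df <- as.data.frame(x)
  df$nll <- signif(df$nll, digits)
  df$bic <- signif(df$bic, digits)
  df$delta_bic <- signif(df$delta_bic, digits)
  df$bic_weight <- signif(df$bic_weight, digits)
  print(df, row.names = FALSE)
  cat("Selected:", attr(x, "selected"), "\n")
  invisible(x)
}
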