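#' End-to-end simulation study
#'
#' Runs the full validation pipeline on synthetic data: simulate a seeded
#' Gillespie ensemble from the generating model, summarise each condition
#' into mean/variance series, add the design's constant measurement noise,
#' fit every candidate model, select by BIC, and profile the winner. All
#' randomness flows from the design's master seed, so a repeated run is
#' byte-identical.
#'
#' @param preset Name passed to [preset_design()], or `NULL` when `design`,
#'   `generating_model` and `params` are given explicitly.
#' @param design,generating_model,params Explicit design override.
#' @param replicates Optional replicate-count override of the preset.
#' @param seed Master seed.
#' @param models Candidate models to fit (default: all 7).
#' @param profile_best Profile the selected model's parameters.
#' @param profile_which Parameters of the winner to profile (default all).
#' @param outdir Optional directory; when given, writes `summaries.csv`,
#'   `fits.csv`, `selection.csv`, `profiles.csv` and `run.json`.
#' @return A list with `summaries`, `fits`, `selection`, `profiles`,
#'   `config`.
#' @export
run_simulation_study <- function(preset = "simulation_study", design = NULL,
                                 generating_model = NULL, params = NULL,
                                 replicates = NULL, seed = 1L,
                                 models = allee_models(), profile_best = TRUE,
                                 profile_which = NULL, outdir = NULL) {
  if (!is.null(preset)) {
    pd <- preset_design(preset, replicates = replicates, seed = seed)
    design <- design %||% pd$design
    generating_model <- generating_model %||% pd$model
    params <- params %||% pd$params
  }
  ens <- simulate_ensemble(design, generating_model, params)
  summaries <- empirical_moments(as_count_table(ens))
  summaries <- perturb_summaries(summaries, design$noise_sd_mean,
                                 design$noise_sd_variance,
                                 seed = design$seed + 1L)
  noise_sd <- c(design$noise_sd_mean, design$noise_sd_variance)
  fits <- lapply(models, function(m) allee_fit(summaries, m,
                                               noise_sd = noise_sd))
  names(fits) <- models
  selection <- compare_models(fits)
  winner <- attr(selection, "selected")
  profiles <- NULL
  if (profile_best) {
    profiles <- profile(fits[[winner]], which = profile_which)
  }
  config <- list(pipeline = "simulation_study", preset = preset,
                 generating_model = generating_model,
                 params = unclass(params), seed = design$seed,
                 replicates = design$replicates,
                 initial_counts = design$initial_counts,
                 horizon = design$horizon,
                 sampling_interval = design$sampling_interval,
                 noise_sd_mean = design$noise_sd_mean,
                 noise_sd_variance = design$noise_sd_variance,
                 models = models)
  report <- list(summaries = summaries, fits = fits, selection = selection,
                 profiles = profiles, config = config)
  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

#' End-to-end analysis of a count table
#'
#' The real-data pipeline: filter and bin wells, per-well exponential
#' growth rates, per-condition simple birth-death fits (the `b`/`d` trend
#' with N0), a combined fit of all candidate models, BIC selection, and
#' profiles of the winner.
#'
#' @param table A count table data.frame or a CSV path readable by
#'   [read_count_table()].
#' @param drop_nongrowing Apply the non-growing-well filter (default
#'   `TRUE`, matching the curation applied to imaging data).
#' @inheritParams run_simulation_study
#' @return A list with `growth_rates`, `growth_stats`, `per_condition`
#'   (fits + `trend`), `fits`, `selection`, `profiles`, `config`.
#' @export
run_data_pipeline <- function(table, drop_nongrowing = TRUE,
                              models = allee_models(), profile_best = TRUE,
                              profile_which = NULL, seed = 1L, outdir = NULL) {
  if (is.character(table)) table <- read_count_table(table)
  groups <- filter_and_bin_wells(table, drop_nongrowing = drop_nongrowing)
  kept <- do.call(rbind, groups)
  rates <- well_growth_rates(kept)
  gstats <- group_growth_stats(kept, rates)
  summaries <- empirical_moments(kept)
  per_cond <- fit_per_condition(summaries, "simple_bd")
  fits <- lapply(models, function(m) allee_fit(summaries, m))
  names(fits) <- models
  selection <- compare_models(fits)
  winner <- attr(selection, "selected")
  profiles <- NULL
  if (profile_best) {
    profiles <- profile(fits[[winner]], which = profile_which)
  }
  config <- list(pipeline = "data", drop_nongrowing = drop_nongrowing,
                 models = models, seed = seed,
                 n_wells = length(unique(kept$well_id)),
                 conditions = sort(unique(kept$n0)))
  report <- list(growth_rates = rates, growth_stats = gstats,
                 summaries = summaries, per_condition = per_cond,
                 fits = fits, selection = selection, profiles = profiles,
                 config = config)
  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

# Serialise a pipeline report: plain CSV tables plus a JSON-ish run record.
.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$summaries, file.path(outdir, "summaries.csv"),
            row.names = FALSE)
  fit_tab <- do.call(rbind, lapply(report$fits, function(f) {
    cf <- coef(f)
    data.frame(model = f$model$id,
               b = cf[["b"]], d = cf[["d"]],
               A = if ("A" %in% names(cf)) cf[["A"]] else NA,
               tau = if ("tau" %in% names(cf)) cf[["tau"]] else NA,
               nll = f$nll, converged = f$converged)
  }))
  write.csv(fit_tab, file.path(outdir, "fits.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$selection),
            file.path(outdir, "selection.csv"), row.names = FALSE)
  if (!is.null(report$profiles)) {
    ci <- confint(report$profiles)
    prof_tab <- data.frame(model = attr(report$profiles, "model"),
                           parameter = rownames(ci), ci)
    write.csv(prof_tab, file.path(outdir, "profiles.csv"), row.names = FALSE)
  }
  if (!is.null(report$growth_rates)) {
    write.csv(report$growth_rates, file.path(outdir, "well_growth_rates.csv"),
              row.names = FALSE)
  }
  cfg <- report$config
  json <- paste0("{", paste(vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    val <- if (is.character(v)) {
      paste0("[", paste0('"', v, '"', collapse = ","), "]")
    } else if (is.list(v)) {
      paste0("{", paste(sprintf('"%s": %s', names(v),
                                vapply(v, function(z)
                                  ifelse(is.na(z), "null", format(z, digits = 15)),
                                  character(1))), collapse = ", "), "}")
    } else {
      paste0("[", paste(format(v, digits = 15), collapse = ","), "]")
    }
    sprintf('"%s": %s', nm, val)
  }, character(1)), collapse = ", "), "}")
  writeLines(json, file.path(outdir, "run.json"))
  invisible(outdir)
}
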