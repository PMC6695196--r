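#' Read and validate a well-level count table
#'
#' Reads a CSV with columns `well_id,n0,time_h,count`: one row per well per
#' timepoint, `n0` the observed (exact) initial cell number the well is
#' binned into, counts non-negative integers. All wells must share the full
#' uniform time grid unless `allow_incomplete = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param allow_incomplete Permit wells that miss grid timepoints.
#' @return A validated data.frame.
#' @export
read_count_table <- function(path, allow_incomplete = FALSE) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_count_table(tab, allow_incomplete = allow_incomplete)
}

#' @rdname read_count_table
#' @param table A count-table data.frame to validate or write.
#' @export
validate_count_table <- function(table, allow_incomplete = FALSE) {
  need <- c("well_id", "n0", "time_h", "count")
  if (!all(need %in% names(table))) {
    stop("count table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  bad <- which(!is.finite(table$count) | table$count < 0 |
                 table$count != floor(table$count))
  if (length(bad)) {
    stop("invalid count at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": counts must be non-negative integers", call. = FALSE)
  }
  if (!allow_incomplete) {
    grid <- sort(unique(table$time_h))
    per_well <- tapply(table$time_h, table$well_id, function(t) length(t))
    incomplete <- names(per_well)[per_well != length(grid)]
    if (length(incomplete)) {
      stop("wells missing grid timepoints: ",
           paste(utils::head(incomplete, 5), collapse = ", "), call. = FALSE)
    }
  }
  table[order(table$n0, table$well_id, table$time_h), , drop = FALSE]
}

#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table, allow_incomplete = TRUE)
  write.csv(table[, c("well_id", "n0", "time_h", "count")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter non-growing wells and bin by initial cell number
#'
#' Optionally removes wells whose final count does not exceed their initial
#' count (the "died off / no growth" rule used when curating imaging data;
#' off by default for simulated data, where dropping extinct trajectories
#' would bias the summaries), then groups the remaining wells by observed
#' N0.
#'
#' @param table A count-table data.frame.
#' @param drop_nongrowing Apply the final <= initial removal rule.
#' @return A named list of per-condition count tables, keyed by N0.
#'   Conditions emptied by the filter are dropped with a warning.
#' @export
filter_and_bin_wells <- function(table, drop_nongrowing = FALSE) {
  table <- validate_count_table(table, allow_incomplete = TRUE)
  if (drop_nongrowing) {
    keep <- vapply(split(table, table$well_id), function(w) {
      w <- w[order(w$time_h), ]
      w$count[nrow(w)] > w$count[1]
    }, logical(1))
    dropped_wells <- names(keep)[!keep]
    table2 <- table[!(table$well_id %in% dropped_wells), , drop = FALSE]
    gone <- setdiff(unique(table$n0), unique(table2$n0))
    if (length(gone)) {
      warning("condition(s) N0 = ", paste(gone, collapse = ", "),
              " removed entirely by the growth filter", call. = FALSE)
    }
    table <- table2
  }
  split(table, table$n0)
}

#' Per-condition empirical mean and variance series
#'
#' Computes the per-timepoint arithmetic mean and sample variance
#' (denominator R - 1) of the replicate counts, per initial condition.
#'
#' @param table A count-table data.frame (any number of conditions), or a
#'   single condition from [filter_and_bin_wells()].
#' @return A data.frame with columns `n0`, `time_h`, `mean`, `variance`,
#'   `n_replicates` -- the summary-series format consumed by [allee_fit()].
#' @export
#' @examples
#' tab <- data.frame(well_id = rep(c("a", "b"), each = 2), n0 = 4,
#'                   time_h = c(0, 4, 0, 4), count = c(4, 4, 4, 6))
#' empirical_moments(tab)
empirical_moments <- function(table) {
  table <- validate_count_table(table, allow_incomplete = TRUE)
  groups <- split(table, table$n0)
  pieces <- lapply(groups, function(g) {
    wells <- unique(g$well_id)
    if (length(wells) < 2L) {
      stop("condition N0 = ", g$n0[1],
           " has fewer than 2 wells; variance undefined", call. = FALSE)
    }
    by_time <- split(g$count, g$time_h)
    times <- as.numeric(names(by_time))
    ord <- order(times)
    data.frame(
      n0 = g$n0[1],
      time_h = times[ord],
      mean = vapply(by_time, mean, numeric(1))[ord],
      variance = vapply(by_time, var, numeric(1))[ord],
      n_replicates = length(wells)
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Per-well exponential growth rates
#'
#' Fits each well to the exponential growth model by ordinary least squares
#' of `log(count)` on time, using all strictly positive counts (zeros are
#' excluded from the regression). Wells with fewer than two positive
#' observations are skipped with a warning.
#'
#' @param table A count-table data.frame.
#' @return A data.frame with one row per fitted well: `well_id`, `n0`, `g`
#'   (per hour).
#' @export
well_growth_rates <- function(table) {
  table <- validate_count_table(table, allow_incomplete = TRUE)
  wells <- split(table, table$well_id)
  rows <- lapply(wells, function(w) {
    w <- w[w$count > 0, ]
    if (nrow(w) < 2L) return(NULL)
    g <- unname(coef(lm(log(count) ~ time_h, data = w))[2])
    data.frame(well_id = w$well_id[1], n0 = w$n0[1], g = g,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    warning(skipped, " well(s) skipped: fewer than 2 positive counts",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname well_growth_rates
#' @description `group_growth_stats()` aggregates the per-well rates into
#'   a mean and standard deviation of `g` per initial condition.
#' @param rates Output of `well_growth_rates()` (computed from `table` if
#'   missing).
#' @export
group_growth_stats <- function(table, rates = NULL) {
  if (is.null(rates)) rates <- well_growth_rates(table)
  groups <- split(rates, rates$n0)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(n0 = g$n0[1], mean_g = mean(g$g), sd_g = sd(g$g),
               n_wells = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Down-sample a time series to a coarser interval
#'
#' Retains every k-th timepoint (always including `t = 0`) of a count
#' table or summary series whose native interval divides the target
#' interval exactly.
#'
#' @param x A count table or summary data.frame (anything with a `time_h`
#'   column on a uniform grid).
#' @param target_interval Desired spacing in hours; must be a positive
#'   multiple of the source spacing.
#' @return The thinned data.frame of the same type.
#' @export
#' @examples
#' tab <- data.frame(well_id = "a", n0 = 2, time_h = seq(0, 36, 4),
#'                   count = 2:11)
#' downsample_time(tab, 36)$time_h
downsample_time <- function(x, target_interval) {
  times <- sort(unique(x$time_h))
  src <- unique(diff(times))
  if (length(src) != 1L) stop("time grid is not uniform", call. = FALSE)
  ratio <- target_interval / src
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("target_interval must be a positive multiple of the source interval (",
         src, " h)", call. = FALSE)
  }
  keep_times <- times[seq(1L, length(times), by = round(ratio))]
  x[x$time_h %in% keep_times, , drop = FALSE]
}
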