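test_that("count tables round-trip through CSV unchanged", {
  tab <- toy_count_table()
  path <- tempfile(fileext = ".csv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  rownames(back) <- rownames(tab) <- NULL
  expect_equal(back[order(back$well_id, back$time_h), ],
               tab[order(tab$well_id, tab$time_h), ],
               ignore_attr = TRUE)
})

test_that("malformed tables are rejected with informative errors", {
  tab <- toy_count_table()
  tab$count[2] <- -1L
  expect_error(validate_count_table(tab), "non-negative")

  tab2 <- toy_count_table()[-2, ]  # w1 misses one timepoint
  expect_error(validate_count_table(tab2), "w1")
  expect_silent(validate_count_table(tab2, allow_incomplete = TRUE))
  expect_error(validate_count_table(data.frame(a = 1)), "columns")
})

test_that("the growth filter removes died-off / non-growing wells only when asked", {
  tab <- rbind(
    toy_count_table(),
    data.frame(well_id = "w4", n0 = 4L, time_h = c(0, 4, 8),
               count = c(4L, 3L, 2L))  # died off: final < initial
  )
  g_off <- filter_and_bin_wells(tab, drop_nongrowing = FALSE)
  expect_equal(sort(unique(do.call(rbind, g_off)$well_id)),
               c("w1", "w2", "w3", "w4"))
  g_on <- filter_and_bin_wells(tab, drop_nongrowing = TRUE)
  kept <- unique(do.call(rbind, g_on)$well_id)
  expect_false("w4" %in% kept)
  expect_true(all(c("w1", "w2", "w3") %in% kept))
  expect_equal(names(g_on), c("2", "4"))
  # a condition emptied by the filter is dropped with a warning
  lone <- data.frame(well_id = "w9", n0 = 8L, time_h = c(0, 4, 8),
                     count = c(8L, 8L, 8L))
  expect_warning(filter_and_bin_wells(rbind(tab, lone), drop_nongrowing = TRUE),
                 "N0 = 8")
})

test_that("empirical moments use the R - 1 sample variance", {
  tab <- data.frame(well_id = rep(c("a", "b"), each = 2), n0 = 4L,
                    time_h = rep(c(0, 4), 2), count = c(4L, 4L, 4L, 6L))
  sm <- empirical_moments(tab)
  expect_equal(sm$mean, c(4, 5))
  expect_equal(sm$variance, c(0, 2))  # denominator R - 1 = 1
  expect_equal(sm$n_replicates, c(2, 2))

  # identical wells -> zero variance everywhere
  tab2 <- toy_count_table()
  tab2$count <- rep(c(4L, 5L, 7L), 3)
  tab2$n0 <- 4L
  expect_true(all(empirical_moments(tab2)$variance == 0))

  # single well -> variance undefined
  one <- toy_count_table()[1:3, ]
  expect_error(empirical_moments(one), "fewer than 2")
})

test_that("per-well exponential fits recover exact exponential growth", {
  g_true <- log(2) / 4  # doubling every 4 h gives integer counts
  tab <- data.frame(well_id = "w1", n0 = 5L, time_h = seq(0, 16, 4),
                    count = as.integer(5 * 2^(0:4)))
  rates <- well_growth_rates(tab)
  expect_equal(rates$g, g_true, tolerance = 1e-12)

  flat <- data.frame(well_id = "w2", n0 = 3L, time_h = seq(0, 16, 4),
                     count = rep(3L, 5))
  expect_equal(well_growth_rates(flat)$g, 0)

  # zeros are excluded; a well with < 2 positive counts is skipped
  dead <- data.frame(well_id = c(rep("w3", 3), rep("w4", 3)),
                     n0 = 2L, time_h = rep(c(0, 4, 8), 2),
                     count = c(2L, 0L, 0L, 2L, 3L, 4L))
  expect_warning(r <- well_growth_rates(dead), "skipped")
  expect_equal(r$well_id, "w4")

  stats <- group_growth_stats(tab)
  expect_equal(stats$mean_g, g_true, tolerance = 1e-12)
})

test_that("time down-sampling keeps every k-th point including t = 0", {
  tab <- data.frame(well_id = "a", n0 = 2L, time_h = seq(0, 72, 4),
                    count = seq_len(19))
  thin <- downsample_time(tab, 36)
  expect_equal(thin$time_h, c(0, 36, 72))  # every 9th point
  expect_equal(downsample_time(tab, 4), tab)  # identity
  expect_error(downsample_time(tab, 10), "multiple")
})

test_that("summarising commutes with permutation and down-sampling", {
  sm_full <- sim_summaries("simple_bd", rate_params(0.03, 0.005), c(3, 5),
                           R = 12, seed = 31, horizon = 96)
  design <- experiment_design(c(3, 5), 12, horizon = 96, seed = 31)
  tab <- as_count_table(simulate_ensemble(design, "simple_bd",
                                          rate_params(0.03, 0.005)))
  shuffled <- tab[sample(nrow(tab)), ]
  sm_shuf <- empirical_moments(shuffled)
  expect_equal(sm_shuf, sm_full, ignore_attr = TRUE)

  # thin-then-summarise equals summarise-then-thin
  a <- empirical_moments(downsample_time(tab, 12))
  b <- downsample_time(empirical_moments(tab), 12)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("empirical moments of a large ensemble approach the closed form", {
  b <- 0.03; d <- 0.01; N0 <- 5; R <- 20000
  sm <- sim_summaries("simple_bd", rate_params(b, d), N0, R = R, seed = 17,
                      horizon = 120, interval = 40)
  cf <- bd_closed_form(b, d, N0, sm$time_h)
  se_mean <- sqrt(sm$variance / R)
  expect_true(all(abs(sm$mean[-1] - cf$mean[-1]) < 3 * se_mean[-1]))
  se_var <- sqrt(2 / (R - 1)) * sm$variance
  expect_true(all(abs(sm$variance[-1] - cf$variance[-1]) < 3 * se_var[-1]))
})
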