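test_that("pure-death and pure-birth paths are monotone", {
  set.seed(1)
  tr <- simulate_trajectory("simple_bd", rate_params(0, 0.01), N0 = 10,
                            horizon = 2000)
  expect_true(all(diff(tr$counts) == -1))
  expect_equal(tr$counts[length(tr$counts)], 0)

  tr2 <- simulate_trajectory("simple_bd", rate_params(0.02, 0), N0 = 3,
                             horizon = 300)
  expect_true(all(diff(tr2$counts) == 1))
})

test_that("grid sampling is last-value carry-forward of the event path", {
  set.seed(5)
  grid <- seq(0, 200, by = 4)
  tr <- simulate_trajectory("strongA_birth", rate_params(0.0238, 0.005, A = 2),
                            N0 = 5, horizon = 200, grid = grid)
  manual <- vapply(grid, function(t) {
    tr$counts[max(which(tr$event_times <= t))]
  }, numeric(1))
  expect_equal(tr$grid_counts, manual)
  expect_true(all(tr$counts >= 0))
})

test_that("ensembles are reproducible and extend without reshuffling", {
  d <- experiment_design(c(3, 5), replicates = 8, horizon = 60, seed = 11)
  e1 <- simulate_ensemble(d, "simple_bd", rate_params(0.0238, 0.005))
  e2 <- simulate_ensemble(d, "simple_bd", rate_params(0.0238, 0.005))
  expect_identical(e1$conditions, e2$conditions)

  # growing the replicate count leaves earlier trajectories bit-identical
  d2 <- experiment_design(c(3, 5), replicates = 12, horizon = 60, seed = 11)
  e3 <- simulate_ensemble(d2, "simple_bd", rate_params(0.0238, 0.005))
  expect_identical(e3$conditions[[1]]$counts[1:8, ], e1$conditions[[1]]$counts)
})

test_that("extinction fraction from one cell matches the branching-process formula", {
  b <- 0.0238; d <- 0.005
  design <- experiment_design(1, replicates = 20000, horizon = 400,
                              sampling_interval = 400, seed = 7)
  ens <- simulate_ensemble(design, "simple_bd", rate_params(b, d))
  extinct <- mean(ens$conditions[[1]]$counts[, 2] == 0)
  p_ext <- d / b  # (d/b)^N0 with N0 = 1
  se <- sqrt(p_ext * (1 - p_ext) / 20000)
  expect_lt(abs(extinct - p_ext), 3 * se)
})

test_that("ensemble mean tracks the closed-form mean within Monte-Carlo error", {
  b <- 0.0238; d <- 0.005
  design <- experiment_design(5, replicates = 5000, horizon = 328, seed = 13)
  ens <- simulate_ensemble(design, "simple_bd", rate_params(b, d))
  counts <- ens$conditions[[1]]$counts
  mu <- colMeans(counts)
  se <- apply(counts, 2, sd) / sqrt(nrow(counts))
  cf <- bd_closed_form(b, d, 5, ens$times)
  z <- (mu[-1] - cf$mean[-1]) / se[-1]
  expect_true(all(abs(z) < 3))
})

test_that("raising the death rate cannot lower the extinction fraction", {
  frac_extinct <- function(d) {
    design <- experiment_design(2, replicates = 10000, horizon = 300,
                                sampling_interval = 300, seed = 21)
    ens <- simulate_ensemble(design, "simple_bd", rate_params(0.02, d))
    mean(ens$conditions[[1]]$counts[, 2] == 0)
  }
  f1 <- frac_extinct(0.004)
  f2 <- frac_extinct(0.01)
  # one-sided two-proportion comparison at n = 10,000 each
  se_diff <- sqrt(f1 * (1 - f1) / 10000 + f2 * (1 - f2) / 10000)
  expect_gt(f2 - f1, 3 * se_diff)
})

test_that("summary perturbation adds seeded noise, floors variance, keeps t = 0 exact", {
  sm <- data.frame(n0 = 3, time_h = c(0, 4, 8), mean = c(3, 3.2, 3.5),
                   variance = c(0, 0.4, 0.9), n_replicates = 10)
  expect_equal(perturb_summaries(sm, 0, 0, seed = 1), sm)
  p1 <- perturb_summaries(sm, 0.5, 5, seed = 2)
  p2 <- perturb_summaries(sm, 0.5, 5, seed = 2)
  expect_identical(p1, p2)
  expect_equal(p1$mean[1], 3)        # seeding timepoint untouched
  expect_equal(p1$variance[1], 0)
  expect_true(all(p1$variance >= 0)) # floored
  expect_false(all(p1$mean == sm$mean))
  expect_error(perturb_summaries(sm, -1, 0), "noise")
})

test_that("preset designs encode the study conditions", {
  ps <- preset_design("simulation_study")
  expect_equal(ps$design$initial_counts, c(3L, 5L, 10L))
  expect_equal(ps$design$replicates, 5000L)
  expect_equal(ps$design$sampling_interval, 4)
  expect_equal(ps$model, "strongA_birth")
  expect_equal(unlist(ps$params[c("b", "d", "A")]),
               c(b = 0.0238, d = 0.005, A = 2))

  bt <- preset_design("bt474_like")
  expect_equal(bt$design$initial_counts, c(2L, 4L, 10L))
  expect_equal(bt$params$A, -3.1576)
  expect_equal(bt$params$tau, 7.480)
  expect_equal(bt$design$horizon, 328)
  expect_equal(classify_regime(bt$params), "weak")

  hd <- preset_design("high_density")
  expect_equal(hd$design$initial_counts, c(512L, 1024L))
  expect_error(preset_design("nope"))
})
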