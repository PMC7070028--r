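# Reporter-kinetics analysis: normalization, windowed OLS rates, group
# comparisons, linearity and adenylation inference.

toy_traj <- function(yfp, mcherry, times = seq_along(yfp) - 1, id = "oo1") {
  data.frame(oocyte_id = id, group = "G", adenylation_state = "na",
             time_h = times, yfp = yfp, mcherry = mcherry,
             stringsAsFactors = FALSE)
}

test_that("first-point normalization starts at 1 and tracks YFP for constant mCherry", {
  tr <- toy_traj(yfp = c(2, 4, 6, 8), mcherry = rep(5, 4))
  norm <- normalize_trajectory(tr, mode = "first-point")
  expect_equal(norm$signal[1], 1)
  expect_equal(norm$signal, c(2, 4, 6, 8) / 2)

  # joint rescaling of both channels changes nothing
  tr3 <- tr
  tr3$yfp <- tr3$yfp * 3
  tr3$mcherry <- tr3$mcherry * 3
  expect_equal(normalize_trajectory(tr3, mode = "first-point")$signal,
               norm$signal)
  expect_equal(normalize_trajectory(tr3, mode = "plateau")$signal,
               normalize_trajectory(tr, mode = "plateau")$signal)
})

test_that("non-positive mCherry is an error naming the timepoint", {
  tr <- toy_traj(yfp = c(1, 2, 3), mcherry = c(5, 0, 5))
  expect_error(normalize_trajectory(tr), "t = 1")
})

test_that("window rates are exact on noiseless lines and constants", {
  t <- 0:10
  fit <- fit_window_rate(t, 1 + 0.5 * t, c(0, 10))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 11L)

  flat <- fit_window_rate(t, rep(2, 11), c(0, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)

  expect_error(fit_window_rate(t, 1 + t, c(20, 30)), "fewer than 2 points")
})

test_that("OLS slope equals the covariance/variance closed form", {
  set.seed(71)
  for (i in 1:50) {
    x <- sort(runif(sample(3:20, 1), 0, 10))
    y <- rnorm(length(x))
    fit <- fit_window_rate(x, y, range(x))
    expect_equal(fit$slope, ols_slope_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("rate comparison is a Welch test, symmetric in its arguments", {
  a <- c(1, 1.1, 0.9, 1.05)
  expect_equal(rate_pair_test(a, a)$p.value, 1, tolerance = 1e-12)

  set.seed(73)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  r1 <- rate_pair_test(x, y)
  r2 <- rate_pair_test(y, x)
  expect_equal(r1$p.value, r2$p.value)
  expect_equal(r1$effect, -r2$effect)
  expect_error(rate_pair_test(1, c(1, 2)), "at least 2")
})

test_that("welch_test matches stats::t.test on random vectors", {
  set.seed(79)
  for (i in 1:100) {
    x <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    got <- welch_test(x, y)
    want <- t.test(x, y)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(want$parameter), tolerance = 1e-10)
  }
})

test_that("linearity is judged by full-span fit quality", {
  t <- seq(0, 10, by = 1)
  expect_equal(linearity_check(t, 2 + 0.3 * t)$call, "linear")

  # accelerating quadratic: the linear fit leaves > 5% of variance unexplained
  quad <- linearity_check(t, t^2)
  expect_equal(quad$call, "nonlinear")
  r2_analytic <- cor(t, t^2)^2
  expect_equal(quad$r_squared, r2_analytic, tolerance = 1e-10)
  expect_lt(r2_analytic, 0.95)

  expect_error(linearity_check(c(0, 1), c(0, 1)), "at least 3")

  # group context: equal early/late rates keep a good line linear
  lc <- linearity_check(t, 2 + 0.3 * t,
                        early_rates = c(0.3, 0.31, 0.29),
                        late_rates = c(0.3, 0.3, 0.31))
  expect_equal(lc$call, "linear")
})

test_that("adenylation inference applies the oligo/poly decision table", {
  fits <- function(early, late, state = "oligo") {
    n <- length(early)
    data.frame(oocyte_id = rep(sprintf("%s%02d", state, 1:n), 2),
               adenylation_state = state,
               window = rep(c("early", "late"), each = n),
               slope = c(early, late), stringsAsFactors = FALSE)
  }
  # late == early -> stable at ratio 0
  st <- infer_adenylation(fits(c(1, 1.2, 0.9), c(1, 1.2, 0.9)))
  expect_equal(st$call, "stable")
  expect_equal(st$mean_log2_ratio, 0)

  # oligo accelerates, poly flat -> adenylation
  ad <- infer_adenylation(fits(c(0.5, 0.6, 0.55), c(1.5, 1.7, 1.6)),
                          fits(c(1, 1.1, 0.9), c(1, 1.05, 0.95), "poly"))
  expect_equal(ad$call, "adenylation")
  expect_lt(abs(ad$poly_mean_log2_ratio), 0.5)

  # oligo accelerates but poly drifts too -> no adenylation call
  no <- infer_adenylation(fits(c(0.5, 0.6), c(1.5, 1.7)),
                          fits(c(1, 1.1), c(3, 3.2), "poly"))
  expect_equal(no$call, "stable")

  # slowing oligo -> deadenylation
  de <- infer_adenylation(fits(c(1.5, 1.7, 1.6), c(0.5, 0.6, 0.55)))
  expect_equal(de$call, "deadenylation")

  # non-positive early rates are excluded with a warning and counted
  expect_warning(
    mix <- infer_adenylation(fits(c(-0.1, 0.5, 0.6), c(1, 1.5, 1.7))),
    "excluded")
  expect_equal(mix$n_excluded, 1L)
  expect_equal(mix$n, 2L)
})

test_that("group summaries average oocytes pointwise with SEM", {
  tr1 <- toy_traj(yfp = c(1, 2, 3), mcherry = rep(1, 3), id = "a")
  tr2 <- toy_traj(yfp = c(1, 2, 3), mcherry = rep(1, 3), id = "b")
  both <- normalize_trajectory(rbind(tr1, tr2), "plateau")
  s <- summarize_group(both)
  expect_equal(s$n, rep(2L, 3))
  expect_equal(s$sem, rep(0, 3))
  expect_equal(s$mean, c(1, 2, 3))

  one <- summarize_group(normalize_trajectory(tr1, "plateau"))
  expect_equal(one$n, rep(1L, 3))
  expect_equal(one$sem, rep(0, 3))

  # differing grids are interpolated onto the shared range
  tr3 <- toy_traj(yfp = c(1, 3), mcherry = c(1, 1), times = c(0.5, 2.5), id = "c")
  expect_message(
    s2 <- summarize_group(normalize_trajectory(rbind(tr1, tr3), "plateau")),
    "interpolating")
  expect_equal(s2$mean[s2$time_h == 1], mean(c(2, 1.5)))

  tr4 <- toy_traj(yfp = c(1, 2), mcherry = c(1, 1), times = c(20, 21), id = "d")
  expect_error(summarize_group(normalize_trajectory(rbind(tr1, tr4), "plateau")),
               "disjoint")
})

test_that("group-mean fitted slopes recover planted rates on synthetic oocytes", {
  groups <- data.frame(group = "CON", rate_pre = 0.15, rate_post = 0.45,
                       adenylation_rate = 0, stringsAsFactors = FALSE)
  p <- trajectory_sim_params(groups, n_oocytes = 30, gvbd_time = 3,
                             states = "na", noise_cv = 0.02, seed = 83)
  ts <- simulate_trajectories(p)
  norm <- normalize_trajectory(ts$trajectories, "plateau")
  fits <- fit_all_rates(norm, list(pre = c(0, 2), post = c(4, 8)))
  expect_lt(abs(mean(fits$slope[fits$window == "pre"]) - 0.15) / 0.15, 0.05)
  expect_lt(abs(mean(fits$slope[fits$window == "post"]) - 0.45) / 0.45, 0.05)
})
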