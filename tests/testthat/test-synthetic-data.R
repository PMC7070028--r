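# Simulators: planted structure must be recoverable exactly, and every
# generator must be deterministic under a fixed seed.

test_that("generated UTRs carry planted elements verbatim at recorded positions", {
  g <- generate_utr_set(utr_spec(40, length_range = c(150L, 250L), seed = 7))
  for (i in seq_len(nrow(g$utrs))) {
    hits <- scan_sequence(g$utrs$seq[i], quiet = TRUE)
    want <- g$truth$elements[g$truth$elements$utr_id == g$utrs$utr_id[i], ]
    want <- want[order(want$start, want$motif), ]
    expect_equal(hits$motif, want$motif)
    expect_equal(hits$start, want$start)
    expect_equal(hits$end, want$end)
    expect_equal(hits$matched, want$instance)
  }
})

test_that("UTR generation is deterministic under a fixed seed", {
  a <- generate_utr_set(utr_spec(25, seed = 7))
  b <- generate_utr_set(utr_spec(25, seed = 7))
  expect_identical(a, b)
  c <- generate_utr_set(utr_spec(25, seed = 8))
  expect_false(identical(a$utrs$seq, c$utrs$seq))
})

test_that("scanner-measured carrier fraction matches the planted fraction", {
  frac <- 0.94
  n <- 500
  g <- generate_utr_set(utr_spec(n, length_range = c(200L, 400L),
                                 element_plan = list(
                                   DAZL = list(fraction = frac, copies = 1),
                                   PAS = list(fraction = 0.95, copies = 1)),
                                 seed = 21))
  ann <- annotate_utrs(g$utrs)$summary
  measured <- mean(ann$has_dazl)
  half <- 1.96 * sqrt(frac * (1 - frac) / n)
  expect_gt(measured, frac - half)
  expect_lt(measured, frac + half)
  # and the scan agrees with the planted truth exactly, not just on average
  expect_equal(ann$has_dazl, g$truth$carriers$carries_dazl)
})

test_that("infeasible UTR specs fail with a named constraint", {
  expect_error(generate_utr_set(utr_spec(1, length_range = c(3L, 4L))),
               "exceeds minimum UTR length")
})

test_that("null count simulation has centred log2 fold changes", {
  sim <- simulate_ribo_counts(count_sim_params(
    2000, library_size = 5e5, dispersion = 0.05,
    frac_up = 0, frac_down = 0, effect_fold = 1, seed = 5))
  meta <- sim$dataset$samples
  a <- meta$sample[meta$fraction == "IP" & meta$condition == "DAZL_MO" &
                     meta$timepoint == "6h"]
  b <- meta$sample[meta$fraction == "IP" & meta$condition == "CON" &
                     meta$timepoint == "6h"]
  lfc <- log2(rowMeans(sim$dataset$counts[, a] + 0.5) /
                rowMeans(sim$dataset$counts[, b] + 0.5))
  expect_lt(abs(mean(lfc)), 0.02)
  expect_true(all(sim$truth$class == "unchanged"))
})

test_that("input means are unaffected by planted IP effects", {
  sim <- simulate_ribo_counts(count_sim_params(
    3000, library_size = 1e6, dispersion = 0.01,
    frac_up = 0.2, frac_down = 0, effect_fold = 8, seed = 9))
  meta <- sim$dataset$samples
  up <- sim$truth$class == "up"
  inp_a <- rowMeans(sim$dataset$counts[, meta$sample[meta$fraction == "input" &
                                                       meta$condition == "DAZL_MO"]])
  inp_b <- rowMeans(sim$dataset$counts[, meta$sample[meta$fraction == "input" &
                                                       meta$condition == "CON"]])
  # planted genes shift IP only: input ratio stays near 1
  expect_lt(abs(mean(log2(inp_a[up] + 0.5) - log2(inp_b[up] + 0.5))), 0.1)
  ip_a <- rowMeans(sim$dataset$counts[, meta$sample[meta$fraction == "IP" &
                                                      meta$condition == "DAZL_MO" &
                                                      meta$timepoint == "6h"]])
  ip_b <- rowMeans(sim$dataset$counts[, meta$sample[meta$fraction == "IP" &
                                                      meta$condition == "CON" &
                                                      meta$timepoint == "6h"]])
  expect_equal(mean(log2(ip_a[up] / ip_b[up])), 3, tolerance = 0.05)
})

test_that("count marginals approach Poisson as dispersion vanishes", {
  sim <- simulate_ribo_counts(count_sim_params(
    1000, library_size = 1e6, dispersion = 0, frac_up = 0, frac_down = 0,
    n_replicates = 8L, seed = 13))
  meta <- sim$dataset$samples
  grp <- sim$dataset$counts[, meta$sample[meta$fraction == "input" &
                                            meta$condition == "CON" &
                                            meta$timepoint == "0h"]]
  vm <- apply(grp, 1, var) / rowMeans(grp)
  expect_equal(mean(vm), 1, tolerance = 0.05)
})

test_that("moment-estimated dispersion recovers the simulated value", {
  sim <- simulate_ribo_counts(count_sim_params(
    2000, library_size = 1e6, dispersion = 0.05, frac_up = 0, frac_down = 0,
    seed = 17))
  meta <- sim$dataset$samples
  ip <- meta$fraction == "IP"
  d <- estimate_dispersion(sim$dataset$counts[, meta$sample[ip]],
                           paste(meta$condition, meta$timepoint)[ip])
  expect_lt(abs(mean(d$phi) - 0.05) / 0.05, 0.25)
})

test_that("count simulator rejects invalid parameters", {
  expect_error(count_sim_params(100, library_size = 0), "positive")
  expect_error(count_sim_params(100, dispersion = -1), "non-negative")
  expect_error(count_sim_params(100, frac_up = 0.6, frac_down = 0.5), "< 1")
})

test_that("noiseless constant-rate trajectories are exactly linear", {
  groups <- data.frame(group = "G", rate_pre = 0.3, rate_post = 0.3,
                       adenylation_rate = 0, stringsAsFactors = FALSE)
  p <- trajectory_sim_params(groups, n_oocytes = 3, times = 0:10,
                             gvbd_time = Inf, states = "na",
                             oocyte_cv = 0, noise_cv = 0, scale_cv = 0, seed = 2)
  ts <- simulate_trajectories(p)
  norm <- normalize_trajectory(ts$trajectories, mode = "plateau")
  for (d in split(norm, norm$oocyte_id)) {
    fit <- fit_window_rate(d$time_h, d$signal, c(0, 10))
    expect_equal(fit$slope, 0.3, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("adenylating oligo reporters accelerate in every noiseless oocyte", {
  groups <- data.frame(group = "G", rate_pre = 0.3, rate_post = 0.3,
                       adenylation_rate = 6, stringsAsFactors = FALSE)
  p <- trajectory_sim_params(groups, n_oocytes = 10, gvbd_time = Inf,
                             states = "oligo", noise_cv = 0, seed = 3)
  ts <- simulate_trajectories(p)
  norm <- normalize_trajectory(ts$trajectories, mode = "plateau")
  fits <- fit_all_rates(norm, list(early = c(0, 3), late = c(7, 10)))
  early <- fits$slope[fits$window == "early"]
  late <- fits$slope[fits$window == "late"]
  expect_true(all(late > early))
})

test_that("trajectory simulator validates its grid and is deterministic", {
  groups <- data.frame(group = "G", rate_pre = 1, rate_post = 1,
                       adenylation_rate = 0, stringsAsFactors = FALSE)
  expect_error(trajectory_sim_params(groups, times = numeric(0)), "empty")
  expect_error(trajectory_sim_params(groups, times = c(0, 0, 1)),
               "strictly increasing")
  p <- trajectory_sim_params(groups, n_oocytes = 4, seed = 19)
  expect_identical(simulate_trajectories(p), simulate_trajectories(p))
})

test_that("RIP simulation separates targets and is deterministic", {
  genes <- sprintf("g%03d", 1:300)
  targets <- rep(c(TRUE, FALSE), c(60, 240))
  a <- simulate_rip_table(genes, targets, target_fold = 3, seed = 23)
  b <- simulate_rip_table(genes, targets, target_fold = 3, seed = 23)
  expect_identical(a, b)
  rip <- fold_enrichment(a$ab, a$igg)
  expect_equal(median(rip$fold[!targets]), 1, tolerance = 0.1)
  expect_gte(mean(rip$enriched[targets]), 0.95)

  null <- simulate_rip_table(genes, rep(FALSE, 300), seed = 29)
  rip0 <- fold_enrichment(null$ab, null$igg)
  expect_equal(median(rip0$fold), 1, tolerance = 0.1)
  expect_lt(mean(rip0$enriched), 0.03)
})
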