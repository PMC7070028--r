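# CPM/TE arithmetic, dispersion estimation, the conditional NB exact test
# and differential-loading classification.

two_group_meta <- function() {
  data.frame(sample = c("input_CON_6h_r1", "input_CON_6h_r2",
                        "input_DAZL_MO_6h_r1", "input_DAZL_MO_6h_r2",
                        "IP_CON_6h_r1", "IP_CON_6h_r2",
                        "IP_DAZL_MO_6h_r1", "IP_DAZL_MO_6h_r2"),
             fraction = rep(c("input", "IP"), each = 4),
             condition = rep(c("CON", "CON", "DAZL_MO", "DAZL_MO"), 2),
             timepoint = "6h", replicate = rep(1:2, 4),
             stringsAsFactors = FALSE)
}

test_that("CPM columns sum to one million and are depth invariant", {
  counts <- matrix(c(10L, 90L), ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.numeric(compute_cpm(counts)), c(1e5, 9e5))

  m <- matrix(rpois(200, 50), nrow = 20,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  cpm <- compute_cpm(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 10))
  expect_equal(compute_cpm(m * 2L), cpm)

  m[, 3] <- 0L
  expect_error(compute_cpm(m), "s3")
})

test_that("TE is the IP/input CPM ratio and is depth-rescaling invariant", {
  set.seed(1)
  counts <- matrix(rpois(50 * 8, 100), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), two_group_meta()$sample))
  ds <- make_dataset(counts, two_group_meta())

  # IP identical to input -> TE exactly 1
  eq <- counts
  eq[, 5:8] <- eq[, 1:4]
  te1 <- compute_te(make_dataset(eq, two_group_meta()))
  expect_true(all(te1$te == 1))

  # scaling both fractions' depth leaves TE unchanged
  te <- compute_te(ds)
  sc <- counts
  sc[, c(1, 5)] <- sc[, c(1, 5)] * 10L
  te_sc <- compute_te(make_dataset(sc, two_group_meta()))
  expect_equal(te_sc$te, te$te)

  # direct arithmetic: one gene, one replicate pair
  one <- matrix(c(100L, 900L, 200L, 800L), ncol = 2,
                dimnames = list(c("a", "b"),
                                c("input_CON_0h_r1", "IP_CON_0h_r1")))
  meta1 <- data.frame(sample = colnames(one), fraction = c("input", "IP"),
                      condition = "CON", timepoint = "0h", replicate = 1L,
                      stringsAsFactors = FALSE)
  te_one <- compute_te(make_dataset(one, meta1))
  expect_equal(te_one$te, c(2, 8 / 9))
})

test_that("zero input CPM flags TE undefined instead of dropping the gene", {
  counts <- matrix(c(0L, 100L, 50L, 100L), ncol = 2,
                   dimnames = list(c("a", "b"),
                                   c("input_CON_0h_r1", "IP_CON_0h_r1")))
  meta1 <- data.frame(sample = colnames(counts), fraction = c("input", "IP"),
                      condition = "CON", timepoint = "0h", replicate = 1L,
                      stringsAsFactors = FALSE)
  te <- compute_te(make_dataset(counts, meta1))
  expect_true(te$undefined[te$gene == "a"])
  expect_true(is.na(te$te[te$gene == "a"]))
  expect_false(te$undefined[te$gene == "b"])
})

test_that("dispersion estimation handles degenerate genes and lone replicates", {
  counts <- matrix(50L, nrow = 3, ncol = 4,
                   dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  d <- estimate_dispersion(counts, c("g1", "g1", "g2", "g2"))
  expect_false(any(is.na(d$phi)))
  expect_true(all(d$phi >= 1e-4))

  expect_error(estimate_dispersion(counts, c("g1", "g2", "g3", "g4")),
               "supply a dispersion")
})

test_that("Poisson counts drive dispersion estimates to the floor", {
  set.seed(31)
  counts <- matrix(rpois(2000 * 4, 500), nrow = 2000,
                   dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:4)))
  d <- estimate_dispersion(counts, c("g1", "g1", "g2", "g2"))
  expect_lt(median(d$phi), 0.003)
})

test_that("the exact NB test is symmetric, valid and errors on bad input", {
  expect_equal(exact_nb_test(c(5, 5), c(5, 5), 0.1), 1)
  expect_error(exact_nb_test(c(-1, 5), c(5, 5), 0.1), "non-negative")
  expect_error(exact_nb_test(c(1, 5), c(5, 5), -0.1), ">= 0")
  # all-zero counts: no evidence either way
  expect_equal(exact_nb_test(c(0, 0), c(0, 0), 0.05), 1)
  p <- exact_nb_test(c(400, 450), c(100, 110), 0.05)
  expect_lt(p, 0.05)
})

test_that("at zero dispersion the test equals the conditional binomial oracle", {
  set.seed(37)
  for (i in 1:200) {
    a <- rpois(2, 60); b <- rpois(2, 60)
    got <- exact_nb_test(a, b, 0)
    want <- binom_exact_oracle(sum(a), sum(b), 2, 2)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("null exact-test p-values are super-uniform at the true dispersion", {
  set.seed(41)
  n <- 1500
  p <- vapply(seq_len(n), function(i) {
    mu <- runif(1, 50, 2000)
    exact_nb_test(rnbinom(2, mu = mu, size = 20),
                  rnbinom(2, mu = mu, size = 20), 0.05)
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / n))
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(43)
  for (i in 1:50) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("differential loading recovers planted effects with correct direction", {
  sim <- simulate_ribo_counts(count_sim_params(
    1000, library_size = 1e6, dispersion = 0.05,
    frac_up = 0.1, frac_down = 0.1, effect_fold = 4, seed = 47))
  de <- differential_loading(sim$dataset)
  truth <- sim$truth
  called_up <- de$gene[de$class == "up"]
  called_down <- de$gene[de$class == "down"]
  sens <- (sum(called_up %in% truth$gene[truth$class == "up"]) +
             sum(called_down %in% truth$gene[truth$class == "down"])) /
    sum(truth$class != "unchanged")
  expect_gte(sens, 0.9)
  # every true positive has the right direction
  expect_equal(sum(called_up %in% truth$gene[truth$class == "down"]), 0)
  expect_equal(sum(called_down %in% truth$gene[truth$class == "up"]), 0)
})

test_that("classification respects threshold limits", {
  sim <- simulate_ribo_counts(count_sim_params(
    400, library_size = 5e5, dispersion = 0.05,
    frac_up = 0.1, frac_down = 0.1, effect_fold = 4, seed = 53))
  none <- differential_loading(sim$dataset, fold = Inf)
  expect_true(all(none$class == "unchanged"))

  f1 <- differential_loading(sim$dataset, fold = 1)
  sig <- !is.na(f1$fdr) & f1$fdr < 0.05
  expect_true(all(f1$class[sig] != "unchanged"))
  expect_true(all(f1$class[!sig] == "unchanged"))

  expect_error(differential_loading(sim$dataset, timepoint = "12h"),
               "contrast cell missing")
})

test_that("empirical FDR stays near nominal on mixed simulations", {
  fdrs <- vapply(1:8, function(s) {
    sim <- simulate_ribo_counts(count_sim_params(
      800, library_size = 8e5, dispersion = 0.05,
      frac_up = 0.05, frac_down = 0.05, effect_fold = 4, seed = 100 + s))
    de <- differential_loading(sim$dataset)
    called <- de$class != "unchanged"
    if (!any(called)) return(0)
    sum(called & sim$truth$class == "unchanged") / sum(called)
  }, numeric(1))
  expect_lte(mean(fdrs), 1.5 * 0.05)
})

test_that("fold enrichment applies the RIP cutoffs", {
  set.seed(59)
  ab <- matrix(rlnorm(40 * 3, log(100), 0.1), nrow = 40)
  rip_eq <- fold_enrichment(ab, ab)
  expect_true(all(rip_eq$fold == 1))
  expect_false(any(rip_eq$enriched))

  igg <- matrix(rlnorm(40 * 3, log(100), 0.1), nrow = 40)
  expect_false(any(fold_enrichment(ab, igg, fold_cutoff = Inf)$enriched))

  z <- matrix(0, nrow = 1, ncol = 3)
  undef <- fold_enrichment(matrix(1:3, nrow = 1), z)
  expect_true(undef$undefined)
  expect_true(is.na(undef$fold))
})

test_that("ddCt fold change matches direct ratio arithmetic", {
  expect_equal(ddct_fold(20, 20, 20, 20), 1)
  expect_equal(ddct_fold(19, 20, 20, 20), 2)
  set.seed(61)
  for (i in 1:20) {
    ct <- runif(4, 15, 30)
    direct <- (2^-ct[1] / 2^-ct[2]) / (2^-ct[3] / 2^-ct[4])
    expect_equal(ddct_fold(ct[1], ct[2], ct[3], ct[4]), direct,
                 tolerance = 1e-12)
  }
  expect_error(ddct_fold(NA, 1, 1, 1), "finite")
})
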