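# Translational efficiency and differential ribosome loading from paired
# IP/input count matrices: CPM normalization, moment/trend dispersion
# estimation, a conditional NB exact test, and threshold classification.

#' Counts per million
#'
#' @param counts Non-negative gene x sample matrix (or a `count_dataset`).
#' @return Matrix of CPM values; every column sums to 1e6.
#' @export
compute_cpm <- function(counts) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(colnames(counts)[zero], collapse = ", ")), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Translational efficiency per condition/timepoint
#'
#' TE is the ratio of IP CPM over the matching input CPM for each
#' replicate pair (same condition, timepoint, replicate), then averaged
#' across replicates (mean of per-replicate ratios). Genes with zero input
#' CPM in any contributing replicate are flagged `undefined` rather than
#' silently dropped.
#'
#' @param dataset A `count_dataset` with `fraction` metadata in
#'   `{input, IP}`.
#' @return Long data frame: `gene`, `condition`, `timepoint`, `te`,
#'   `n_replicates`, `undefined`.
#' @export
compute_te <- function(dataset) {
  stopifnot(inherits(dataset, "count_dataset"))
  cpm <- compute_cpm(dataset$counts)
  meta <- dataset$samples
  cells <- unique(meta[meta$fraction == "IP", c("condition", "timepoint")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; tp <- cells$timepoint[i]
    ip_meta <- meta[meta$fraction == "IP" & meta$condition == cond &
                      meta$timepoint == tp, ]
    ratios <- matrix(NA_real_, nrow = nrow(cpm), ncol = nrow(ip_meta))
    undef <- rep(FALSE, nrow(cpm))
    for (r in seq_len(nrow(ip_meta))) {
      inp <- meta$sample[meta$fraction == "input" & meta$condition == cond &
                           meta$timepoint == tp &
                           meta$replicate == ip_meta$replicate[r]]
      if (length(inp) != 1L) {
        stop(sprintf("no unique input sample pairs IP sample '%s'",
                     ip_meta$sample[r]), call. = FALSE)
      }
      denom <- cpm[, inp]
      bad <- denom == 0
      undef <- undef | bad
      ratios[, r] <- ifelse(bad, NA_real_, cpm[, ip_meta$sample[r]] / denom)
    }
    out[[i]] <- data.frame(gene = rownames(cpm), condition = cond,
                           timepoint = tp, te = rowMeans(ratios),
                           n_replicates = nrow(ip_meta), undefined = undef,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$te[res$undefined] <- NA_real_
  rownames(res) <- NULL
  res
}

#' Delta log2 translational efficiency between two conditions
#'
#' @param te Output of [compute_te()].
#' @param condition_a,condition_b Condition labels (A over B).
#' @param timepoint Timepoint label.
#' @return Data frame: `gene`, `te_a`, `te_b`, `delta_log2_te`.
#' @export
delta_log2_te <- function(te, condition_a, condition_b, timepoint) {
  a <- te[te$condition == condition_a & te$timepoint == timepoint, ]
  b <- te[te$condition == condition_b & te$timepoint == timepoint, ]
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  b <- b[match(a$gene, b$gene), ]
  data.frame(gene = a$gene, te_a = a$te, te_b = b$te,
             delta_log2_te = log2(a$te / b$te), stringsAsFactors = FALSE)
}

#' Per-gene NB dispersion by moments with trend shrinkage
#'
#' Counts are first scaled to a common library size. Within each replicate
#' group the method-of-moments estimate `(var - mean) / mean^2` is computed
#' and pooled across groups (weighted by degrees of freedom); per-gene
#' estimates are then shrunk toward a lowess mean-dispersion trend, the
#' standard remedy for the instability of per-gene moments at 2 replicates.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Factor/character vector of replicate-group labels per sample.
#' @param phi_min Dispersion floor (default 1e-4).
#' @param shrink_weight Weight on the trend in the shrinkage (default 0.8).
#' @return Data frame: `gene`, `mean_count` (common-scale), `phi_raw`,
#'   `phi_trend`, `phi` (shrunk, floored).
#' @export
estimate_dispersion <- function(counts, groups, phi_min = 1e-4,
                                shrink_weight = 0.8) {
  stopifnot(ncol(counts) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (all(sizes < 2)) {
    stop("no replicate group has >= 2 samples; supply a dispersion directly",
         call. = FALSE)
  }
  libs <- colSums(counts)
  common <- exp(mean(log(libs)))
  scaled <- sweep(counts, 2, common / libs, "*")

  num <- rep(0, nrow(counts)); den <- 0; mean_acc <- rep(0, nrow(counts)); ng <- 0
  for (g in names(sizes)[sizes >= 2]) {
    sub <- scaled[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    w <- ncol(sub) - 1
    phi_g <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + w * phi_g
    den <- den + w
    mean_acc <- mean_acc + m
    ng <- ng + 1
  }
  phi_raw <- num / den
  mu <- mean_acc / ng

  ok <- mu > 0
  phi_trend <- rep(0, nrow(counts))
  if (length(unique(mu[ok])) >= 2) {
    # iter = 0: a local mean. The robust iterations would downweight the long
    # right tail of the skewed per-gene moment estimates and bias the trend low.
    trend_fit <- stats::lowess(log10(mu[ok]), phi_raw[ok], f = 0.5, iter = 0)
    trend_fun <- stats::approxfun(trend_fit$x, trend_fit$y, rule = 2,
                                  ties = mean)
    phi_trend[ok] <- pmax(trend_fun(log10(mu[ok])), 0)
  } else if (any(ok)) {
    phi_trend[ok] <- max(mean(phi_raw[ok]), 0)
  }
  phi <- pmax(shrink_weight * phi_trend + (1 - shrink_weight) * pmax(phi_raw, 0),
              phi_min)
  data.frame(gene = rownames(counts), mean_count = mu, phi_raw = phi_raw,
             phi_trend = phi_trend, phi = phi, stringsAsFactors = FALSE)
}

# Median-of-ratios size factors (robust to a minority of changed genes, which
# would bias total-count normalization when effects are asymmetric). Scaled so
# their geometric mean equals the geometric-mean column total.
size_factor_libs <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10) return(colSums(counts))
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(sweep(counts[pos, , drop = FALSE], 1, ref, "/"), 2, stats::median)
  sf / exp(mean(log(sf))) * exp(mean(log(colSums(counts))))
}

# Quantile-to-quantile equalization of one count to a common library size
# under the NB (or Poisson) model, via the mid-probability transform.
q2q_equalize <- function(y, mu_own, mu_common, phi) {
  if (mu_own == mu_common) return(y)
  if (phi == 0) {
    pm <- stats::ppois(y - 1, mu_own) + 0.5 * stats::dpois(y, mu_own)
    stats::qpois(pmin(pmax(pm, 0), 1 - 1e-12), mu_common)
  } else {
    size <- 1 / phi
    pm <- stats::pnbinom(y - 1, mu = mu_own, size = size) +
      0.5 * stats::dnbinom(y, mu = mu_own, size = size)
    stats::qnbinom(pmin(pmax(pm, 0), 1 - 1e-12), mu = mu_common, size = size)
  }
}

#' Conditional NB exact test for one gene
#'
#' Two-sided exact test of equal means between two small replicate groups of
#' NB counts. Counts are quantile-equalized to a common library size, summed
#' within groups, and the test conditions on the total: the p-value is the
#' summed probability of all splits as or less likely than the observed one.
#' At `phi = 0` the conditional distribution is exactly binomial, so the test
#' reduces to the conditional Poisson (binomial) exact test.
#'
#' @param counts_a,counts_b Non-negative integer replicate counts.
#' @param phi NB dispersion (>= 0).
#' @param lib_a,lib_b Library sizes per replicate (default: all equal).
#' @return Two-sided p-value in (0, 1].
#' @export
exact_nb_test <- function(counts_a, counts_b, phi,
                          lib_a = rep(1, length(counts_a)),
                          lib_b = rep(1, length(counts_b))) {
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (phi < 0) stop("dispersion must be >= 0", call. = FALSE)
  na <- length(counts_a); nb <- length(counts_b)
  libs <- c(lib_a, lib_b)
  common <- exp(mean(log(libs)))
  phat <- sum(counts_a, counts_b) / sum(libs)
  ys <- c(counts_a, counts_b)
  pseudo <- vapply(seq_along(ys), function(i) {
    q2q_equalize(ys[i], phat * libs[i], phat * common, phi)
  }, numeric(1))
  a <- round(sum(pseudo[seq_len(na)]))
  b <- round(sum(pseudo[na + seq_len(nb)]))
  s <- a + b
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    logf <- stats::dbinom(k, s, na / (na + nb), log = TRUE)
  } else {
    mu <- s / (na + nb)
    logf <- stats::dnbinom(k, mu = na * mu, size = na / phi, log = TRUE) +
      stats::dnbinom(s - k, mu = nb * mu, size = nb / phi, log = TRUE)
  }
  pr <- exp(logf - max(logf))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[a + 1] * (1 + 1e-7)]))
}

#' Differential ribosome loading between two conditions
#'
#' Tests IP counts of `condition_a` against `condition_b` at one timepoint
#' with the conditional NB exact test ([exact_nb_test()]), using trend-shrunk
#' moment dispersions estimated across all IP replicate groups. Effective
#' library sizes for the contrast come from median-of-ratios size factors,
#' which stay calibrated when a minority of genes changes asymmetrically
#' (total-count normalization would shift the null log-fold-changes). P-values are
#' BH-adjusted across tested genes; transcripts are classified `up` when
#' `log2FC >= log2(fold)` and `fdr < alpha`, `down` symmetrically, otherwise
#' `unchanged`. Genes below the minimum summed count across tested samples
#' are excluded from testing and reported as filtered.
#'
#' @param dataset A `count_dataset`.
#' @param condition_a,condition_b Condition labels (A vs B, IP fraction).
#' @param timepoint Timepoint label (default `"6h"`).
#' @param fold Fold-change threshold (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @param min_count Minimum summed raw count across tested samples
#'   (default 10).
#' @param phi Optional fixed dispersion (scalar or per-gene vector);
#'   bypasses estimation.
#' @return Data frame: `gene`, `base_mean_cpm`, `log2fc`, `p`, `fdr`,
#'   `class` (up/down/unchanged), `filtered`.
#' @export
differential_loading <- function(dataset, condition_a = "DAZL_MO",
                                 condition_b = "CON", timepoint = "6h",
                                 fold = 2, alpha = 0.05, min_count = 10,
                                 phi = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  meta <- dataset$samples
  sel_a <- meta$fraction == "IP" & meta$condition == condition_a &
    meta$timepoint == timepoint
  sel_b <- meta$fraction == "IP" & meta$condition == condition_b &
    meta$timepoint == timepoint
  if (!any(sel_a) || !any(sel_b)) {
    stop(sprintf("contrast cell missing: %s/%s vs %s/%s (IP)",
                 condition_a, timepoint, condition_b, timepoint), call. = FALSE)
  }
  cts_a <- dataset$counts[, meta$sample[sel_a], drop = FALSE]
  cts_b <- dataset$counts[, meta$sample[sel_b], drop = FALSE]

  if (is.null(phi)) {
    ip <- meta$fraction == "IP"
    disp <- estimate_dispersion(
      dataset$counts[, meta$sample[ip], drop = FALSE],
      paste(meta$condition[ip], meta$timepoint[ip]))
    phi <- disp$phi
  } else if (length(phi) == 1L) {
    phi <- rep(phi, nrow(dataset$counts))
  }

  libs <- size_factor_libs(cbind(cts_a, cts_b))
  lib_a <- libs[seq_len(ncol(cts_a))]
  lib_b <- libs[ncol(cts_a) + seq_len(ncol(cts_b))]
  tested <- rowSums(cts_a) + rowSums(cts_b) >= min_count

  p <- rep(NA_real_, nrow(dataset$counts))
  for (i in which(tested)) {
    p[i] <- exact_nb_test(cts_a[i, ], cts_b[i, ], phi[i], lib_a, lib_b)
  }
  fdr <- bh_adjust(p)

  # log2FC on CPM with a small prior count for stability at low counts
  cpm_a <- sweep(cts_a + 0.5, 2, lib_a + 1, "/") * 1e6
  cpm_b <- sweep(cts_b + 0.5, 2, lib_b + 1, "/") * 1e6
  log2fc <- log2(rowMeans(cpm_a) / rowMeans(cpm_b))
  base_mean <- rowMeans(cbind(cpm_a, cpm_b))

  class <- rep("unchanged", nrow(dataset$counts))
  sig <- !is.na(fdr) & fdr < alpha
  lf <- log2(fold)
  class[sig & log2fc >= lf] <- "up"
  class[sig & log2fc <= -lf] <- "down"
  class[!tested] <- "unchanged"

  data.frame(gene = rownames(dataset$counts), base_mean_cpm = base_mean,
             log2fc = log2fc, p = p, fdr = fdr, class = class,
             filtered = !tested, stringsAsFactors = FALSE, row.names = NULL)
}
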