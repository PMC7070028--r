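# Reporter translation kinetics: per-oocyte normalization, windowed OLS
# rates, group comparisons, linearity assessment, and adenylation inference
# from oligo/poly reporter pairs.

split_oocytes <- function(traj) split(traj, traj$oocyte_id)

#' Normalize a dual-channel trajectory
#'
#' The translation signal is the YFP/mCherry ratio. In `"first-point"` mode
#' the ratio is further divided by its initial value so the series starts at
#' exactly 1 (fold accumulation over the GV starting point). In `"plateau"`
#' mode YFP is divided by the mCherry plateau estimate (mean of the last
#' quarter of the recording), keeping the series in absolute ratio units so
#' slopes are comparable across oocytes.
#'
#' @param traj Long data frame for one or more oocytes: `oocyte_id`,
#'   `time_h`, `yfp`, `mcherry` (plus any grouping columns, carried through).
#' @param mode `"first-point"` or `"plateau"`.
#' @return `traj` with a `signal` column added.
#' @export
normalize_trajectory <- function(traj, mode = c("first-point", "plateau")) {
  mode <- match.arg(mode)
  stopifnot(all(c("oocyte_id", "time_h", "yfp", "mcherry") %in% names(traj)))
  bad <- traj$mcherry <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("non-positive mCherry for oocyte %s at t = %g h",
                 traj$oocyte_id[i], traj$time_h[i]), call. = FALSE)
  }
  pieces <- lapply(split_oocytes(traj), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (mode == "first-point") {
      ratio <- d$yfp / d$mcherry
      d$signal <- ratio / ratio[1]
    } else {
      n <- nrow(d)
      plateau <- mean(d$mcherry[d$time_h >= stats::quantile(d$time_h, 0.75)])
      d$signal <- d$yfp / plateau
    }
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares rate over a time window
#'
#' Fits `signal ~ time` over points with time in the closed window
#' `[t0, t1]` and reports the slope (the translation rate), intercept, and
#' goodness of fit. A constant series fits perfectly (r-squared 1, slope 0).
#'
#' @param time,signal Numeric vectors (one oocyte's series).
#' @param window Numeric `c(t0, t1)` in hours.
#' @return Data frame row: `t0`, `t1`, `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_window_rate <- function(time, signal, window) {
  stopifnot(length(time) == length(signal), length(window) == 2L)
  sel <- time >= window[1] & time <= window[2] & !is.na(signal)
  if (sum(sel) < 2L) {
    stop(sprintf("fewer than 2 points in window [%g, %g]",
                 window[1], window[2]), call. = FALSE)
  }
  x <- time[sel]; y <- signal[sel]
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(y^2) || sse <= 1e-12 * max(sst, 1)) {
    if (sse <= max(sst, 1) * 1e-12) 1 else 0
  } else 1 - sse / sst
  data.frame(t0 = window[1], t1 = window[2],
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = min(max(r2, 0), 1), n_points = sum(sel))
}

#' Windowed rates for every oocyte in a trajectory table
#'
#' @param traj Normalized long data frame (must carry `signal`; see
#'   [normalize_trajectory()]).
#' @param windows Named list of `c(t0, t1)` windows, e.g.
#'   `list(early = c(0, 3), late = c(7, 10))`.
#' @return Data frame with one row per oocyte and window: `oocyte_id`,
#'   grouping columns, `window`, and the [fit_window_rate()] fields.
#' @export
fit_all_rates <- function(traj, windows) {
  stopifnot(is.list(windows), !is.null(names(windows)))
  keep <- intersect(c("group", "adenylation_state"), names(traj))
  rows <- lapply(split_oocytes(traj), function(d) {
    do.call(rbind, lapply(names(windows), function(w) {
      fit <- fit_window_rate(d$time_h, d$signal, windows[[w]])
      cbind(data.frame(oocyte_id = d$oocyte_id[1], stringsAsFactors = FALSE),
            d[1, keep, drop = FALSE], data.frame(window = w), fit)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch comparison of per-oocyte rates between two groups
#'
#' @param rates_a,rates_b Numeric vectors of per-oocyte slopes (>= 2 each).
#' @return List: `effect` (difference of means, a - b), `sem_a`, `sem_b`,
#'   `statistic`, `df`, `p.value`.
#' @export
rate_pair_test <- function(rates_a, rates_b) {
  if (length(rates_a) < 2L || length(rates_b) < 2L) {
    stop("need at least 2 rates per group", call. = FALSE)
  }
  w <- welch_test(rates_a, rates_b)
  list(effect = w$estimate, sem_a = standard_error(rates_a),
       sem_b = standard_error(rates_b), statistic = w$statistic,
       df = w$df, p.value = w$p.value)
}

#' Linearity of a reporter accumulation series
#'
#' A series is called linear when the full-span linear regression explains
#' at least `r2_threshold` of the variance; when per-oocyte early/late rates
#' for a group are supplied, they must additionally not differ (Welch p above
#' `alpha`). An accelerating (convex) series fails the r-squared criterion.
#'
#' @param time,signal One oocyte's series (>= 3 points).
#' @param r2_threshold Full-span r-squared threshold (default 0.95).
#' @param early_rates,late_rates Optional per-oocyte windowed rates for the
#'   oocyte's group.
#' @param alpha Significance level for the rate-difference check.
#' @return List: `call` ("linear"/"nonlinear"), `r_squared`, and
#'   `rate_change_p` when group rates were given.
#' @export
linearity_check <- function(time, signal, r2_threshold = 0.95,
                            early_rates = NULL, late_rates = NULL,
                            alpha = 0.05) {
  if (length(time) < 3L) stop("need at least 3 points to assess linearity",
                              call. = FALSE)
  fit <- fit_window_rate(time, signal, range(time))
  linear <- fit$r_squared >= r2_threshold
  p <- NULL
  if (!is.null(early_rates) && !is.null(late_rates)) {
    p <- rate_pair_test(early_rates, late_rates)$p.value
    linear <- linear && p >= alpha
  }
  out <- list(call = if (linear) "linear" else "nonlinear",
              r_squared = fit$r_squared)
  if (!is.null(p)) out$rate_change_p <- p
  out
}

#' Infer adenylation state change from oligo/poly reporter pairs
#'
#' For each oligo-reporter oocyte the log2 ratio of late to early window
#' rates is computed; oocytes with non-positive early rates have no defined
#' ratio and are excluded (with a warning and count). The group is called
#' `adenylation` when the oligo mean log2 ratio exceeds `+delta` while the
#' matched poly reporter (already fully adenylated, hence insensitive to
#' endogenous adenylation) stays within `±delta`; `deadenylation` is the
#' mirror image; anything else is `stable`. Without poly fits the call is
#' made from the oligo reporter alone.
#'
#' @param oligo_fits Data frame from [fit_all_rates()] for oligo reporters
#'   of one group, with windows named `early` and `late`.
#' @param poly_fits Optional matching data frame for the poly reporter.
#' @param delta Stable band half-width on the log2 scale (default 0.5).
#' @return List: `call`, `mean_log2_ratio`, `sem_log2_ratio`, `n`,
#'   `n_excluded`, `per_oocyte` (data frame `oocyte_id`, `log2_ratio`),
#'   and `poly_mean_log2_ratio` when poly fits were given.
#' @export
infer_adenylation <- function(oligo_fits, poly_fits = NULL, delta = 0.5) {
  ratio_table <- function(fits) {
    early <- fits[fits$window == "early", ]
    late <- fits[fits$window == "late", ]
    late <- late[match(early$oocyte_id, late$oocyte_id), ]
    ok <- early$slope > 0 & !is.na(late$slope) & late$slope > 0
    list(tab = data.frame(oocyte_id = early$oocyte_id[ok],
                          log2_ratio = log2(late$slope[ok] / early$slope[ok]),
                          stringsAsFactors = FALSE),
         n_excluded = sum(!ok))
  }
  rt <- ratio_table(oligo_fits)
  if (rt$n_excluded > 0) {
    warning(sprintf("%d oocyte(s) excluded (non-positive window rate)",
                    rt$n_excluded), call. = FALSE)
  }
  if (nrow(rt$tab) == 0) stop("no oocytes with defined rate ratios", call. = FALSE)
  m <- mean(rt$tab$log2_ratio)
  poly_m <- NA_real_
  if (!is.null(poly_fits)) {
    poly_rt <- ratio_table(poly_fits)
    if (nrow(poly_rt$tab) > 0) poly_m <- mean(poly_rt$tab$log2_ratio)
  }
  poly_stable <- is.na(poly_m) || abs(poly_m) <= delta
  call <- if (m > delta && poly_stable) "adenylation"
  else if (m < -delta && poly_stable) "deadenylation"
  else "stable"
  out <- list(call = call, mean_log2_ratio = m,
              sem_log2_ratio = standard_error(rt$tab$log2_ratio),
              n = nrow(rt$tab), n_excluded = rt$n_excluded,
              per_oocyte = rt$tab)
  if (!is.null(poly_fits)) out$poly_mean_log2_ratio <- poly_m
  out
}

#' Group mean ± SEM time course
#'
#' Pointwise mean and SEM of the normalized signal over the oocytes of one
#' group. Oocytes sampled on differing grids are linearly interpolated onto
#' the grid of timepoints common to the overlapping time range (logged via
#' message); disjoint time ranges are an error.
#'
#' @param traj Normalized long data frame for one group (`signal` present).
#' @return Data frame: `time_h`, `mean`, `sem`, `n`.
#' @export
summarize_group <- function(traj) {
  stopifnot("signal" %in% names(traj))
  oocytes <- split_oocytes(traj)
  if (length(oocytes) == 0) stop("no trajectories", call. = FALSE)
  spans <- vapply(oocytes, function(d) range(d$time_h), numeric(2))
  lo <- max(spans[1, ]); hi <- min(spans[2, ])
  if (lo > hi) stop("trajectories have disjoint time ranges", call. = FALSE)
  grids <- lapply(oocytes, function(d) sort(d$time_h))
  common <- Reduce(intersect, grids)
  if (length(common) < 2) {
    message("differing time grids: interpolating onto the shared range")
    common <- sort(unique(unlist(grids)))
    common <- common[common >= lo & common <= hi]
  }
  vals <- vapply(oocytes, function(d) {
    stats::approx(d$time_h, d$signal, xout = common)$y
  }, numeric(length(common)))
  vals <- matrix(vals, nrow = length(common))
  n <- ncol(vals)
  data.frame(time_h = common, mean = rowMeans(vals),
             sem = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else
               rep(0, length(common)),
             n = n)
}
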