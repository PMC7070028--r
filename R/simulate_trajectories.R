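# Dual-channel reporter time-course simulator. YFP accumulates as the time
# integral of an instantaneous translation rate that (i) switches at GVBD and
# (ii) is modulated by the reporter's poly(A) tail through a saturating
# coupling; mCherry is a constitutive, fully adenylated control already at
# plateau when recording starts (reporters are pre-incubated overnight).

#' Parameters for the reporter trajectory simulator
#'
#' @param groups Data frame with one row per experimental group: columns
#'   `group`, `rate_pre`, `rate_post` (base translation rates in
#'   normalized-ratio units per hour before/after GVBD) and
#'   `adenylation_rate` (poly(A) units per hour; negative = deadenylation).
#' @param n_oocytes Oocytes per group and adenylation state.
#' @param times Sampling times in hours, strictly increasing.
#' @param gvbd_time GVBD time in hours (`Inf` for GV-arrest designs: the
#'   pre-GVBD rate applies throughout).
#' @param states Adenylation states to simulate per group: any of
#'   `"oligo"` (short tail, initial length `a0_oligo`), `"poly"`
#'   (pre-adenylated, `a0_poly`), `"na"` (no poly(A) modulation).
#' @param a0_oligo,a0_poly Initial poly(A) lengths (default 20 / 150 A).
#' @param a_ref Saturation reference length: instantaneous rate =
#'   base rate * min(A(t)/a_ref, 1).
#' @param oocyte_cv Oocyte-to-oocyte lognormal CV on the base rate
#'   (mean-corrected so the group mean equals the planted rate).
#' @param noise_cv Multiplicative lognormal measurement noise CV per
#'   observation (fluorescence noise is scale-proportional).
#' @param mcherry_plateau mCherry plateau fluorescence (AU).
#' @param yfp0 Normalized YFP/mCherry ratio already accumulated at t = 0.
#' @param scale_cv Lognormal CV of the per-oocyte injection scale factor
#'   (applies jointly to both channels).
#' @param seed RNG seed.
#' @return Object of class `trajectory_sim_params`.
#' @export
trajectory_sim_params <- function(groups,
                                  n_oocytes = 30L,
                                  times = seq(0, 10, by = 0.25),
                                  gvbd_time = 3,
                                  states = c("oligo", "poly"),
                                  a0_oligo = 20, a0_poly = 150, a_ref = 75,
                                  oocyte_cv = 0.1, noise_cv = 0.05,
                                  mcherry_plateau = 100, yfp0 = 0.2,
                                  scale_cv = 0.2, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "rate_pre", "rate_post", "adenylation_rate")
                %in% names(groups)),
            n_oocytes >= 1)
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  states <- match.arg(states, c("oligo", "poly", "na"), several.ok = TRUE)
  structure(list(groups = groups, n_oocytes = as.integer(n_oocytes),
                 times = as.numeric(times), gvbd_time = gvbd_time,
                 states = states, a0_oligo = a0_oligo, a0_poly = a0_poly,
                 a_ref = a_ref, oocyte_cv = oocyte_cv, noise_cv = noise_cv,
                 mcherry_plateau = mcherry_plateau, yfp0 = yfp0,
                 scale_cv = scale_cv, seed = as.integer(seed)),
            class = "trajectory_sim_params")
}

# Cumulative YFP signal at `times` for one oocyte: exact trapezoidal integral
# of rate(t) = base(t) * min(A0 + a*t, a_ref)/a_ref (clamped at >= 0) on a
# grid refined with every breakpoint, so piecewise-linear segments integrate
# exactly.
integrate_yfp <- function(times, rate_pre, rate_post, gvbd_time,
                          a0, a_rate, a_ref) {
  breaks <- numeric(0)
  if (is.finite(gvbd_time)) breaks <- c(breaks, gvbd_time)
  if (a_rate != 0) {
    t_sat <- (a_ref - a0) / a_rate   # crossing of the saturation point
    t_zero <- -a0 / a_rate           # tail fully removed
    breaks <- c(breaks, t_sat, t_zero)
  }
  span <- range(times)
  breaks <- breaks[breaks > span[1] & breaks < span[2]]
  grid <- sort(unique(c(times, breaks, seq(span[1], span[2], length.out = 201))))
  base <- ifelse(grid < gvbd_time, rate_pre, rate_post)
  amod <- pmin(pmax(a0 + a_rate * grid, 0) / a_ref, 1)
  rate <- base * amod
  inc <- c(0, cumsum(diff(grid) * (rate[-length(rate)] + rate[-1]) / 2))
  inc[match(times, grid)]
}

#' Simulate dual-channel reporter trajectories
#'
#' For each group and adenylation state, `n_oocytes` oocytes are simulated.
#' Oligo and poly reporter pairs share every parameter except the initial
#' poly(A) state. Noiseless trajectories with a constant, saturated rate are
#' exactly linear in YFP/mCherry units.
#'
#' @param params A [trajectory_sim_params()].
#' @return List with `trajectories` (long data frame: `oocyte_id`, `group`,
#'   `adenylation_state`, `time_h`, `yfp`, `mcherry`) and `truth` (one row
#'   per oocyte: drawn base rates, adenylation rate, initial tail, and the
#'   exact noiseless mean rate over the early `[0, 3]` and late `[7, 10]`
#'   hour windows plus pre/post-GVBD windows `[0, 2]` / `[4, 8]`).
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "trajectory_sim_params"))
  p <- params
  with_seed(p$seed, {
    rows <- list(); truth <- list()
    counter <- 0L
    for (g in seq_len(nrow(p$groups))) {
      grp <- p$groups[g, ]
      for (state in p$states) {
        a0 <- switch(state, oligo = p$a0_oligo, poly = p$a0_poly, na = p$a_ref)
        a_rate <- if (state == "na") 0 else grp$adenylation_rate
        for (o in seq_len(p$n_oocytes)) {
          counter <- counter + 1L
          id <- sprintf("oo%04d", counter)
          jit <- if (p$oocyte_cv > 0) {
            s <- sqrt(log(1 + p$oocyte_cv^2))
            stats::rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
          } else 1
          rpre <- grp$rate_pre * jit
          rpost <- grp$rate_post * jit
          y <- p$yfp0 + integrate_yfp(p$times, rpre, rpost, p$gvbd_time,
                                      a0, a_rate, p$a_ref)
          scale <- if (p$scale_cv > 0) {
            s <- sqrt(log(1 + p$scale_cv^2))
            stats::rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
          } else 1
          noise <- function(n) {
            if (p$noise_cv == 0) rep(1, n) else {
              s <- sqrt(log(1 + p$noise_cv^2))
              stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
            }
          }
          nt <- length(p$times)
          rows[[counter]] <- data.frame(
            oocyte_id = id, group = grp$group, adenylation_state = state,
            time_h = p$times,
            yfp = scale * p$mcherry_plateau * y * noise(nt),
            mcherry = scale * p$mcherry_plateau * noise(nt),
            stringsAsFactors = FALSE)
          wrate <- function(t0, t1) {
            yy <- integrate_yfp(c(t0, t1), rpre, rpost, p$gvbd_time,
                                a0, a_rate, p$a_ref)
            (yy[2] - yy[1]) / (t1 - t0)
          }
          truth[[counter]] <- data.frame(
            oocyte_id = id, group = grp$group, adenylation_state = state,
            rate_pre = rpre, rate_post = rpost, adenylation_rate = a_rate,
            a0 = a0,
            rate_early = wrate(0, 3), rate_late = wrate(7, 10),
            rate_pre_window = wrate(0, 2), rate_post_window = wrate(4, 8),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(trajectories = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
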