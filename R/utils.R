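# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed; kept < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name), call. = FALSE)
  }
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance (Welch) t-test computed from the closed-form
#' statistic and Welch-Satterthwaite degrees of freedom. Unlike
#' [stats::t.test()], degenerate inputs (both groups constant) return a
#' defined p-value: 1 when the means coincide, 0 otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `estimate` (difference of means `x - y`), `se`,
#'   `statistic`, `df` and `p.value`.
#' @export
welch_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_test() needs at least 2 observations per group", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    return(list(estimate = mx - my, se = 0,
                statistic = if (mx == my) 0 else sign(mx - my) * Inf,
                df = nx + ny - 2,
                p.value = if (mx == my) 1 else 0))
  }
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(estimate = mx - my, se = sqrt(se2), statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across a vector of p-values. `NA` entries are
#' preserved and excluded from the adjustment, matching [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of BH-adjusted p-values (q-values), same length as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

standard_error <- function(x) {
  n <- sum(!is.na(x))
  if (n <= 1L) return(0)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
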