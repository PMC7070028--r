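# Independent oracles used to cross-check package implementations. These are
# deliberately naive (window loops, enumeration, textbook formulas) and share
# no code with the implementation under test.

IUPAC_TABLE <- c(
  A = "A", C = "C", G = "G", U = "U",
  R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
  B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU"
)

# Exhaustive window-by-window motif matching (0-based, half-open coordinates).
brute_scan <- function(seq, motifs) {
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (r in seq_len(nrow(motifs))) {
    pat <- strsplit(motifs$pattern[r], "")[[1]]
    w <- length(pat)
    if (w > length(chars)) next
    for (s in 0:(length(chars) - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!grepl(chars[s + j], IUPAC_TABLE[[pat[j]]], fixed = TRUE)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif = motifs$name[r], start = s, end = s + w,
          matched = paste(chars[(s + 1):(s + w)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif, out$end), , drop = FALSE]
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Benjamini-Hochberg step-up by its definition: adjusted p_(i) =
# min_{j >= i} ( p_(j) * n / j ), capped at 1, mapped back to input order.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Conditional binomial (Poisson-limit) exact test: given group sums a and b
# with na and nb replicates at equal library sizes, the null conditional law
# of a given a + b is Binomial(a + b, na / (na + nb)); two-sided p sums the
# probabilities of all outcomes no more likely than the observed one.
binom_exact_oracle <- function(a, b, na, nb) {
  s <- a + b
  if (s == 0) return(1)
  f <- dbinom(0:s, s, na / (na + nb))
  min(1, sum(f[f <= f[a + 1] * (1 + 1e-7)]))
}

# Closed-form OLS slope: cov(x, y) / var(x).
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Small two-group count dataset wrapper for direct testing.
make_dataset <- function(counts, samples) {
  structure(list(counts = counts, samples = samples), class = "count_dataset")
}
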