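# Synthetic RiboTag IP/input count matrices with planted ribosome-loading
# shifts. Counts are negative binomial (Var = mu + phi * mu^2); planted
# effects act on the IP fraction of the treated condition at the late
# timepoint only, with input means identical across conditions.

#' Parameters for the RiboTag count simulator
#'
#' The default design mirrors a morpholino knockdown experiment: two
#' conditions (`CON`, `DAZL_MO`), two timepoints (`0h`, `6h`), paired
#' `input`/`IP` fractions, two biological replicates per cell.
#'
#' @param n_genes Number of genes.
#' @param library_size Expected total counts per sample.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2); 0 gives Poisson.
#' @param frac_up,frac_down Proportions of genes with planted increased /
#'   decreased IP loading in `DAZL_MO` at `6h`; must sum to < 1.
#' @param effect_fold Planted fold change (>= 1); up genes multiplied,
#'   down genes divided.
#' @param n_replicates Biological replicates per condition/timepoint cell.
#' @param seed RNG seed.
#' @return Object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes, library_size = 1e6, dispersion = 0.05,
                             frac_up = 0.05, frac_down = 0.05,
                             effect_fold = 4, n_replicates = 2L, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 1, effect_fold >= 1)
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  stop_if_not_scalar_prob(frac_up, "frac_up")
  stop_if_not_scalar_prob(frac_down, "frac_down")
  if (frac_up + frac_down >= 1) stop("frac_up + frac_down must be < 1", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), library_size = library_size,
                 dispersion = dispersion, frac_up = frac_up,
                 frac_down = frac_down, effect_fold = effect_fold,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "count_sim_params")
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate paired IP/input RiboTag count matrices
#'
#' Gene abundances are lognormal and shared by all samples; input-fraction
#' means are identical across conditions and timepoints, while IP means of
#' planted genes are multiplied (up) or divided (down) by `effect_fold` in
#' the treated condition at 6 h. Marginals are NB with the stated dispersion.
#'
#' @param params A [count_sim_params()].
#' @return List with `dataset` (a `count_dataset`: `$counts` gene x sample
#'   integer matrix, `$samples` metadata with columns `sample`, `fraction`,
#'   `condition`, `timepoint`, `replicate`) and `truth` (per gene: `class`
#'   in up/down/unchanged, `planted_fold`).
#' @export
simulate_ribo_counts <- function(params) {
  stopifnot(inherits(params, "count_sim_params"))
  p <- params
  with_seed(p$seed, {
    genes <- sprintf("gene%05d", seq_len(p$n_genes))
    rel <- stats::rlnorm(p$n_genes, meanlog = 0, sdlog = 1)
    rel <- rel / sum(rel)

    n_up <- round(p$frac_up * p$n_genes)
    n_down <- round(p$frac_down * p$n_genes)
    class <- rep("unchanged", p$n_genes)
    if (n_up + n_down > 0) {
      idx <- sample.int(p$n_genes, n_up + n_down)
      class[idx[seq_len(n_up)]] <- "up"
      if (n_down > 0) class[idx[n_up + seq_len(n_down)]] <- "down"
    }
    fold <- ifelse(class == "up", p$effect_fold,
                   ifelse(class == "down", 1 / p$effect_fold, 1))

    design <- expand.grid(replicate = seq_len(p$n_replicates),
                          timepoint = c("0h", "6h"),
                          condition = c("CON", "DAZL_MO"),
                          fraction = c("input", "IP"),
                          stringsAsFactors = FALSE)
    design$sample <- with(design, paste(fraction, condition, timepoint,
                                        paste0("r", replicate), sep = "_"))
    counts <- matrix(0L, nrow = p$n_genes, ncol = nrow(design),
                     dimnames = list(genes, design$sample))
    for (j in seq_len(nrow(design))) {
      eff <- if (design$fraction[j] == "IP" &&
                 design$condition[j] == "DAZL_MO" &&
                 design$timepoint[j] == "6h") fold else rep(1, p$n_genes)
      mu <- p$library_size * rel * eff
      counts[, j] <- as.integer(rnb(p$n_genes, mu, p$dispersion))
    }
    dataset <- structure(list(counts = counts,
                              samples = design[, c("sample", "fraction",
                                                   "condition", "timepoint",
                                                   "replicate")]),
                         class = "count_dataset")
    list(dataset = dataset,
         truth = data.frame(gene = genes, class = class, planted_fold = fold,
                            stringsAsFactors = FALSE))
  })
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(fraction = x$samples$fraction,
              cell = paste(x$samples$condition, x$samples$timepoint)))
  invisible(x)
}

#' Write / read a count dataset as TSV
#'
#' Counts go to `<prefix>_counts.tsv` (gene x sample, first column `gene`),
#' metadata to `<prefix>_samples.tsv`.
#'
#' @param dataset A `count_dataset`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_count_dataset <- function(dataset, prefix) {
  cts <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cts, paste0(prefix, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(prefix) {
  cts <- utils::read.delim(paste0(prefix, "_counts.tsv"), check.names = FALSE)
  samples <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                               stringsAsFactors = FALSE)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$gene
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_dataset")
}

#' Simulate a RIP (antibody vs IgG) replicate table
#'
#' Planted targets have antibody recovery centred `target_fold` above their
#' IgG background; non-targets are centred at fold 1. Replicate values are
#' lognormal around these means, emulating microarray/qPCR RIP quantification.
#'
#' @param genes Character vector of gene ids.
#' @param targets Logical vector, `TRUE` for planted binding targets.
#' @param target_fold Mean AB/IgG separation for targets (default 3).
#' @param n_replicates Replicates per antibody arm (default 3).
#' @param sdlog Lognormal replicate noise on the log scale (default 0.15).
#' @param seed RNG seed.
#' @return List with `ab` and `igg` (gene x replicate matrices) and `truth`
#'   (gene, target flag, planted fold).
#' @export
simulate_rip_table <- function(genes, targets, target_fold = 3,
                               n_replicates = 3L, sdlog = 0.15, seed = 1L) {
  stopifnot(length(genes) == length(targets), target_fold > 0,
            n_replicates >= 2)
  with_seed(seed, {
    n <- length(genes)
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.5)
    fold <- ifelse(targets, target_fold, 1)
    draw <- function(mu) matrix(stats::rlnorm(n * n_replicates,
                                              meanlog = log(mu) - sdlog^2 / 2,
                                              sdlog = sdlog),
                                nrow = n, dimnames = list(genes, NULL))
    list(ab = draw(base * fold), igg = draw(base),
         truth = data.frame(gene = genes, target = as.logical(targets),
                            planted_fold = fold, stringsAsFactors = FALSE))
  })
}
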