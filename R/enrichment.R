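# RIP-style fold enrichment (antibody vs IgG) and qPCR ddCt fold change.

#' RIP fold enrichment with Welch test
#'
#' Fold enrichment is `mean(AB) / mean(IgG)` per gene across paired
#' replicates; significance is a two-sided Welch t-test across replicate
#' values. A gene is called enriched when `fold >= fold_cutoff` and
#' `p < p_cutoff` (RIP-Chip style cutoffs: 1.5-fold, p < 0.05).
#'
#' @param ab,igg Gene x replicate matrices of antibody and IgG recovery
#'   values (row order must match; rownames are gene ids).
#' @param fold_cutoff Fold-enrichment cutoff (default 1.5).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @return Data frame: `gene`, `fold`, `p`, `enriched`, `undefined`
#'   (TRUE when the IgG mean is zero and the fold cannot be formed).
#' @export
fold_enrichment <- function(ab, igg, fold_cutoff = 1.5, p_cutoff = 0.05) {
  ab <- as.matrix(ab); igg <- as.matrix(igg)
  stopifnot(nrow(ab) == nrow(igg), ncol(ab) >= 2, ncol(igg) >= 2)
  genes <- rownames(ab)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(ab)))
  mu_igg <- rowMeans(igg)
  undefined <- mu_igg == 0
  fold <- ifelse(undefined, NA_real_, rowMeans(ab) / mu_igg)
  p <- vapply(seq_len(nrow(ab)), function(i) {
    welch_test(ab[i, ], igg[i, ])$p.value
  }, numeric(1))
  data.frame(gene = genes, fold = fold, p = p,
             enriched = !undefined & fold >= fold_cutoff & p < p_cutoff,
             undefined = undefined, stringsAsFactors = FALSE, row.names = NULL)
}

#' qPCR fold enrichment by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_ip - Ct_ref_ip) - (Ct_target_bg - Ct_ref_bg)` and the
#' fold enrichment is `2^-ddCt`; with the background arm as the IgG control
#' this sets the IgG fold to 1 by construction.
#'
#' @param ct_target_ip,ct_ref_ip Ct values of target and reference genes in
#'   the IP (antibody) arm.
#' @param ct_target_bg,ct_ref_bg Ct values in the background (IgG / input)
#'   arm.
#' @return Fold enrichment (vectorised over targets).
#' @export
ddct_fold <- function(ct_target_ip, ct_ref_ip, ct_target_bg, ct_ref_bg) {
  stopifnot(all(is.finite(ct_target_ip)), all(is.finite(ct_ref_ip)),
            all(is.finite(ct_target_bg)), all(is.finite(ct_ref_bg)))
  ddct <- (ct_target_ip - ct_ref_ip) - (ct_target_bg - ct_ref_bg)
  2^(-ddct)
}
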