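#!/usr/bin/env Rscript
# Stage 5 — integrate RIP enrichment, translation classes and UTR elements.
#
# Computes antibody/IgG fold enrichment from the stage-1 RIP replicates,
# joins it with the stage-3 differential-loading classes into target
# quadrants (binding x translation direction), runs the null-subset analysis
# (affected transcripts with no DAZL element), and writes a JSON summary.

suppressPackageStartupMessages(library(oomat))

out <- "results/integrate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- jsonlite::read_json("results/sim/config.json", simplifyVector = TRUE)

rip_reps <- read.delim("results/sim/rip_replicates.tsv")
ab <- as.matrix(rip_reps[, grep("^ab_", names(rip_reps))])
igg <- as.matrix(rip_reps[, grep("^igg_", names(rip_reps))])
rownames(ab) <- rownames(igg) <- rip_reps$gene
rip <- fold_enrichment(ab, igg, fold_cutoff = cfg$rip$fold_cutoff,
                       p_cutoff = cfg$rip$p_cutoff)
write.table(rip, file.path(out, "rip_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("RIP: %d of %d transcripts enriched (fold >= %g, p < %g)",
                sum(rip$enriched), nrow(rip), cfg$rip$fold_cutoff,
                cfg$rip$p_cutoff))

de <- read.delim("results/ribo/differential_loading.tsv")
quad <- classify_quadrants(rip, de)
write.table(quad, file.path(out, "quadrants.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("quadrants:")
print(table(quad$quadrant))

ann <- read.delim("results/scan/element_summary.tsv")
subsets <- null_element_subset(de, ann)
message(sprintf("null-subset: %d down / %d up transcripts carry no DAZL element",
                subsets$down$n_without, subsets$up$n_without))
coverage <- element_coverage_summary(
  ann, list(down = de$gene[de$class == "down"],
            up = de$gene[de$class == "up"],
            unchanged = de$gene[de$class == "unchanged"]))
write.table(coverage, file.path(out, "element_coverage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_rip <- read.delim("results/sim/truth_rip.tsv")
truth_genes <- read.delim("results/sim/truth_genes.tsv")
summary <- list(
  de = list(up = sum(de$class == "up"), down = sum(de$class == "down")),
  rip = list(enriched = sum(rip$enriched),
             planted_targets = sum(truth_rip$target)),
  quadrants = as.list(table(quad$quadrant)),
  null_subset = list(down_without = subsets$down$n_without,
                     up_without = subsets$up$n_without),
  recovery = list(
    de_sensitivity = sum(de$class == truth_genes$class &
                           truth_genes$class != "unchanged") /
      sum(truth_genes$class != "unchanged"),
    rip_sensitivity = sum(rip$enriched & truth_rip$target) /
      sum(truth_rip$target)))
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = 10, pretty = TRUE)
message("stage 5 complete: summary under ", out)
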