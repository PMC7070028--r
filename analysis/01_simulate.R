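#!/usr/bin/env Rscript
# Stage 1 — simulate the study's data with planted ground truth.
#
# Generates (a) a RiboTag IP/input count matrix for the morpholino-knockdown
# design (CON vs DAZL_MO, 0 h vs 6 h, paired input/IP, 2 replicates),
# (b) 3'UTR sequences whose DAZL-element carriage is tied to the planted
# translation classes, (c) a RIP antibody/IgG replicate table, and
# (d) oligo/poly reporter trajectories for the GV-arrest mutagenesis design.
# Everything downstream reads the files written here.

suppressPackageStartupMessages(library(oomat))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_pipeline_config(seed = 20260926 %% 100000)
jsonlite::write_json(cfg[c("seed", "de", "rip")], file.path(out, "config.json"),
                     auto_unbox = TRUE, pretty = TRUE)

message("simulating RiboTag counts: ", cfg$counts$n_genes, " genes, ",
        "effects ", cfg$counts$frac_up + cfg$counts$frac_down,
        " of genes at ", cfg$counts$effect_fold, "-fold")
sim <- simulate_ribo_counts(do.call(count_sim_params,
                                    c(cfg$counts, seed = cfg$seed + 1)))
write_count_dataset(sim$dataset, file.path(out, "ribotag"))
write.table(sim$truth, file.path(out, "truth_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  planted: ", sum(sim$truth$class == "up"), " up, ",
        sum(sim$truth$class == "down"), " down")

message("simulating 3'UTRs tied to gene classes")
affected <- sim$truth$class != "unchanged"
set.seed(cfg$seed + 2)
dazl_carrier <- ifelse(affected,
                       runif(nrow(sim$truth)) < cfg$utr$affected_dazl_fraction,
                       runif(nrow(sim$truth)) < cfg$utr$background_dazl_fraction)
utrs <- generate_utr_set(
  utr_spec(nrow(sim$truth), length_range = cfg$utr$length_range,
           gc_fraction = cfg$utr$gc_fraction,
           element_plan = list(DAZL = list(fraction = 0.5, copies = 1),
                               CPE = list(fraction = cfg$utr$cpe_fraction, copies = 1),
                               PAS = list(fraction = cfg$utr$pas_fraction, copies = 1)),
           seed = cfg$seed + 3),
  carriers = list(DAZL = dazl_carrier))
utrs$utrs$utr_id <- sim$truth$gene
utrs$truth$carriers$utr_id <- sim$truth$gene
write_utr_fasta(utrs$utrs, file.path(out, "utrs.fasta"))
write.table(utrs$truth$carriers, file.path(out, "truth_utrs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  ", sum(dazl_carrier), " UTRs carry a DAZL element")

message("simulating RIP table")
set.seed(cfg$seed + 4)
targets <- affected | runif(nrow(sim$truth)) < cfg$rip$extra_target_fraction
rip <- simulate_rip_table(sim$truth$gene, targets,
                          target_fold = cfg$rip$target_fold,
                          n_replicates = cfg$rip$n_replicates,
                          sdlog = cfg$rip$sdlog, seed = cfg$seed + 5)
write.table(data.frame(gene = sim$truth$gene, rip$ab, rip$igg,
                       check.names = FALSE),
            file.path(out, "rip_replicates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE,
            col.names = c("gene", paste0("ab_r", 1:cfg$rip$n_replicates),
                          paste0("igg_r", 1:cfg$rip$n_replicates)))
write.table(rip$truth, file.path(out, "truth_rip.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  ", sum(targets), " planted binding targets")

message("simulating reporter trajectories (GV-arrest mutagenesis design)")
traj <- simulate_trajectories(trajectory_sim_params(
  groups = cfg$kinetics$groups, n_oocytes = cfg$kinetics$n_oocytes,
  times = cfg$kinetics$times, gvbd_time = cfg$kinetics$gvbd_time,
  noise_cv = cfg$kinetics$noise_cv, seed = cfg$seed + 6))
write.csv(traj$trajectories, file.path(out, "trajectories.csv"),
          row.names = FALSE)
write.table(traj$truth, file.path(out, "truth_trajectories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  ", length(unique(traj$trajectories$oocyte_id)), " oocytes across ",
        nrow(cfg$kinetics$groups), " reporter constructs x oligo/poly")
message("stage 1 complete: tables under ", out)
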