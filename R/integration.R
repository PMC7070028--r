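# Integration of RIP enrichment, differential ribosome loading and UTR
# annotation into target quadrants, plus the end-to-end pipeline driver.

#' Classify genes into RIP x translation quadrants
#'
#' Joins a RIP enrichment table with differential-loading results on exact
#' gene ids and assigns each gene one of five mutually exclusive labels:
#' `target-activated` (enriched, translation up), `target-repressed`
#' (enriched, down), `target-unchanged` (enriched, unchanged),
#' `nontarget-changed` (not enriched, up or down) and
#' `nontarget-unchanged`.
#'
#' @param rip Data frame from [fold_enrichment()] (needs `gene`, `enriched`).
#' @param de Data frame from [differential_loading()] (needs `gene`, `class`).
#' @return Data frame: `gene`, `rip_enriched`, `translation_class`,
#'   `quadrant`. Counts of unmatched ids on each side are attached as the
#'   `"unmatched"` attribute; an empty intersection is an error.
#' @export
classify_quadrants <- function(rip, de) {
  shared <- intersect(rip$gene, de$gene)
  if (length(shared) == 0) stop("no shared genes between RIP and DE tables",
                                call. = FALSE)
  unmatched <- c(rip_only = length(setdiff(rip$gene, shared)),
                 de_only = length(setdiff(de$gene, shared)))
  if (any(unmatched > 0)) {
    warning(sprintf("unmatched ids: %d RIP-only, %d DE-only",
                    unmatched[1], unmatched[2]), call. = FALSE)
  }
  enriched <- rip$enriched[match(shared, rip$gene)]
  class <- de$class[match(shared, de$gene)]
  quadrant <- ifelse(enriched & class == "up", "target-activated",
              ifelse(enriched & class == "down", "target-repressed",
              ifelse(enriched, "target-unchanged",
              ifelse(class != "unchanged", "nontarget-changed",
                     "nontarget-unchanged"))))
  out <- data.frame(gene = shared, rip_enriched = enriched,
                    translation_class = class, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  out
}

#' Partition translationally affected genes by element presence
#'
#' The null-subset analysis: among genes whose translation is up- or
#' down-regulated, how many carry no binding element of the given class in
#' their 3'UTR? Genes without an annotated UTR are excluded from both lists
#' and counted separately.
#'
#' @param de Differential-loading results (`gene`, `class`).
#' @param annotations UTR annotation summary ([annotate_utrs()]`$summary`).
#' @param element Motif class to test for (default `"DAZL"`).
#' @return Named list per direction (`up`, `down`), each with `with_element`,
#'   `without_element` (gene id vectors), `n_with`, `n_without`, `n_no_utr`.
#' @export
null_element_subset <- function(de, annotations, element = "DAZL") {
  flag_col <- paste0("has_", tolower(element))
  if (!flag_col %in% names(annotations)) {
    stop(sprintf("annotations carry no '%s' flag", flag_col), call. = FALSE)
  }
  out <- list()
  for (dir in c("up", "down")) {
    genes <- de$gene[de$class == dir]
    known <- genes[genes %in% annotations$utr_id]
    has <- annotations[[flag_col]][match(known, annotations$utr_id)]
    out[[dir]] <- list(with_element = known[has],
                       without_element = known[!has],
                       n_with = sum(has), n_without = sum(!has),
                       n_no_utr = length(genes) - length(known))
  }
  out
}

#' Default pipeline configuration
#'
#' A compact demonstration configuration with strongly separated planted
#' effects, small enough to run end to end in well under five minutes on one
#' CPU.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return Nested config list (schema: `counts`, `utr`, `rip`, `kinetics`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    counts = list(n_genes = 1200L, library_size = 1e6, dispersion = 0.02,
                  frac_up = 0.1, frac_down = 0.1, effect_fold = 6,
                  n_replicates = 2L),
    de = list(fold = 2, alpha = 0.05, min_count = 10),
    utr = list(length_range = c(300L, 800L), gc_fraction = 0.45,
               affected_dazl_fraction = 0.9, background_dazl_fraction = 0.5,
               cpe_fraction = 0.5, pas_fraction = 0.95),
    rip = list(target_fold = 4, n_replicates = 3L, sdlog = 0.1,
               extra_target_fraction = 0.15,
               fold_cutoff = 1.5, p_cutoff = 0.05),
    kinetics = list(
      n_oocytes = 12L, times = seq(0, 10, by = 0.5), gvbd_time = Inf,
      noise_cv = 0.05, delta = 0.5,
      windows = list(early = c(0, 3), late = c(7, 10)),
      groups = data.frame(
        group = c("WT", "dCPE", "dDazl", "dCPE_dDazl"),
        rate_pre = c(0.15, 0.15, 0.15, 0.15),
        rate_post = c(0.15, 0.15, 0.15, 0.15),
        adenylation_rate = c(0, 4, 0, 8),
        stringsAsFactors = FALSE))
  )
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "counts", "de", "utr", "rip", "kinetics")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop(sprintf("pipeline config is missing blocks: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> scan -> ribosome loading -> reporter kinetics ->
#' integrate on one configuration, writing every stage table (TSV/FASTA/CSV),
#' a machine-readable JSON summary and a run log (seeds, sizes, package
#' version) into `out_dir`. Re-running with the same config is byte-identical.
#'
#' @param config Config list (see [default_pipeline_config()]) or a path to a
#'   YAML file with the same schema.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly. Key tables are also attached:
#'   `de`, `quadrants`, `truth`, `adenylation`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- simulate counts -------------------------------------------------
  sim <- run_stage("simulate_counts", {
    cp <- config$counts
    simulate_ribo_counts(count_sim_params(
      n_genes = cp$n_genes, library_size = cp$library_size,
      dispersion = cp$dispersion, frac_up = cp$frac_up,
      frac_down = cp$frac_down, effect_fold = cp$effect_fold,
      n_replicates = cp$n_replicates, seed = child_seed(seed, 1L)))
  })
  write_count_dataset(sim$dataset, file.path(out_dir, "ribotag"))
  utils::write.table(sim$truth, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- simulate UTRs tied to gene classes ------------------------------
  utr_set <- run_stage("simulate_utrs", {
    up <- config$utr
    affected <- sim$truth$class != "unchanged"
    with_seed(child_seed(seed, 2L), {
      dazl_carrier <- ifelse(affected,
                             stats::runif(nrow(sim$truth)) < up$affected_dazl_fraction,
                             stats::runif(nrow(sim$truth)) < up$background_dazl_fraction)
    })
    spec <- utr_spec(n_utrs = nrow(sim$truth), length_range = up$length_range,
                     gc_fraction = up$gc_fraction,
                     element_plan = list(
                       DAZL = list(fraction = 0.5, copies = 1),
                       CPE = list(fraction = up$cpe_fraction, copies = 1),
                       PAS = list(fraction = up$pas_fraction, copies = 1)),
                     seed = child_seed(seed, 3L))
    res <- generate_utr_set(spec, carriers = list(DAZL = dazl_carrier))
    res$utrs$utr_id <- sim$truth$gene
    res$truth$elements$utr_id <-
      sim$truth$gene[match(res$truth$elements$utr_id,
                           res$truth$carriers$utr_id)]
    res$truth$carriers$utr_id <- sim$truth$gene
    res
  })
  write_utr_fasta(utr_set$utrs, file.path(out_dir, "utrs.fasta"))
  utils::write.table(utr_set$truth$carriers,
                     file.path(out_dir, "truth_utrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- scan ------------------------------------------------------------
  ann <- run_stage("scan", annotate_utrs(utr_set$utrs))
  utils::write.table(ann$hits[, c("utr_id", "start", "end", "motif", "matched")],
                     file.path(out_dir, "element_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$summary, file.path(out_dir, "element_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- differential ribosome loading ----------------------------------
  de <- run_stage("ribo", differential_loading(
    sim$dataset, fold = config$de$fold, alpha = config$de$alpha,
    min_count = config$de$min_count))
  utils::write.table(de, file.path(out_dir, "differential_loading.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  te <- run_stage("te", compute_te(sim$dataset))
  utils::write.table(te, file.path(out_dir, "translational_efficiency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- RIP simulation + enrichment ------------------------------------
  rp <- config$rip
  rip_truth_targets <- run_stage("simulate_rip", {
    affected <- sim$truth$class != "unchanged"
    with_seed(child_seed(seed, 4L), {
      affected | stats::runif(nrow(sim$truth)) < rp$extra_target_fraction
    })
  })
  rip_sim <- simulate_rip_table(sim$truth$gene, rip_truth_targets,
                                target_fold = rp$target_fold,
                                n_replicates = rp$n_replicates,
                                sdlog = rp$sdlog,
                                seed = child_seed(seed, 5L))
  rip <- run_stage("fold_enrichment",
                   fold_enrichment(rip_sim$ab, rip_sim$igg,
                                   fold_cutoff = rp$fold_cutoff,
                                   p_cutoff = rp$p_cutoff))
  utils::write.table(rip, file.path(out_dir, "rip_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- reporter kinetics ----------------------------------------------
  kp <- config$kinetics
  traj_sim <- run_stage("simulate_trajectories", simulate_trajectories(
    trajectory_sim_params(groups = kp$groups, n_oocytes = kp$n_oocytes,
                          times = kp$times, gvbd_time = kp$gvbd_time,
                          noise_cv = kp$noise_cv,
                          seed = child_seed(seed, 6L))))
  utils::write.csv(traj_sim$trajectories,
                   file.path(out_dir, "trajectories.csv"), row.names = FALSE)
  kin <- run_stage("kinetics", {
    norm <- normalize_trajectory(traj_sim$trajectories, mode = "plateau")
    fits <- fit_all_rates(norm, kp$windows)
    calls <- lapply(unique(fits$group), function(g) {
      oligo <- fits[fits$group == g & fits$adenylation_state == "oligo", ]
      poly <- fits[fits$group == g & fits$adenylation_state == "poly", ]
      a <- infer_adenylation(oligo, if (nrow(poly) > 0) poly else NULL,
                             delta = kp$delta)
      data.frame(group = g, call = a$call,
                 mean_log2_ratio = a$mean_log2_ratio,
                 poly_mean_log2_ratio = if (is.null(a$poly_mean_log2_ratio))
                   NA_real_ else a$poly_mean_log2_ratio,
                 n = a$n, stringsAsFactors = FALSE)
    })
    list(fits = fits, calls = do.call(rbind, calls))
  })
  utils::write.table(kin$fits, file.path(out_dir, "window_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(kin$calls, file.path(out_dir, "adenylation_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- integrate -------------------------------------------------------
  quad <- run_stage("integrate", classify_quadrants(rip, de))
  utils::write.table(quad, file.path(out_dir, "quadrants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  subsets <- run_stage("null_subset", null_element_subset(de, ann$summary))

  truth_quadrant <- ifelse(rip_truth_targets & sim$truth$class == "up",
                           "target-activated",
                    ifelse(rip_truth_targets & sim$truth$class == "down",
                           "target-repressed",
                    ifelse(rip_truth_targets, "target-unchanged",
                    ifelse(sim$truth$class != "unchanged",
                           "nontarget-changed", "nontarget-unchanged"))))
  qcount <- function(x) {
    lv <- c("target-activated", "target-repressed", "target-unchanged",
            "nontarget-changed", "nontarget-unchanged")
    as.list(table(factor(x, levels = lv)))
  }
  summary <- list(
    seed = seed,
    n_genes = nrow(sim$truth),
    de = list(n_up = sum(de$class == "up"), n_down = sum(de$class == "down"),
              n_filtered = sum(de$filtered)),
    truth = list(n_up = sum(sim$truth$class == "up"),
                 n_down = sum(sim$truth$class == "down"),
                 n_rip_targets = sum(rip_truth_targets)),
    rip = list(n_enriched = sum(rip$enriched)),
    quadrants = qcount(quad$quadrant),
    quadrants_truth = qcount(truth_quadrant),
    null_subset = list(
      up = list(n_with = subsets$up$n_with, n_without = subsets$up$n_without,
                n_no_utr = subsets$up$n_no_utr),
      down = list(n_with = subsets$down$n_with,
                  n_without = subsets$down$n_without,
                  n_no_utr = subsets$down$n_no_utr)),
    adenylation = stats::setNames(as.list(kin$calls$call), kin$calls$group)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_lines <- c(
    sprintf("oomat pipeline, package version %s",
            as.character(utils::packageVersion("oomat"))),
    sprintf("master seed: %d", seed),
    sprintf("genes: %d, oocytes/group/state: %d", nrow(sim$truth),
            kp$n_oocytes),
    "stages: simulate, scan, ribo, kinetics, integrate: ok")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(c(summary, list(de = de, quadrants = quad, truth = sim$truth,
                            adenylation = kin$calls,
                            rip_targets = rip_truth_targets)))
}
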