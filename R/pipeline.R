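#' Default pipeline configuration
#'
#' One configuration drives the whole run: a top-level `seed`, a
#' `synthetic` section mirroring [synthetic_config()], and per-module
#' analysis sections (`trajectory`, `integration`, `survival`).  A user
#' config (YAML/JSON file or list) is merged over these defaults.
#'
#' @param config optional path to a YAML/JSON config file, or a list.
#' @return the merged configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    synthetic = list(),
    trajectory = list(fc_threshold = 1.5, p_threshold = 0.05,
                      early_transitions = c(1L, 2L), normalize = "none"),
    integration = list(q_threshold = 0.25, signature_fc = 1.5,
                       signature_p = 0.05, signature_from = NULL,
                       signature_to = NULL),
    survival = list(alpha = 0.05)
  )
  user <- if (is.null(config)) list()
    else if (is.character(config)) yaml::read_yaml(config)
    else if (is.list(config)) config
    else stop("config must be a file path or a list")
  merge_lists(defaults, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full progression-analysis pipeline
#'
#' Composes generation, normalization, trajectory classification and the
#' preneoplastic census, signature extraction, target-set enrichment with
#' the anticorrelation filter, survival stratification, methylation
#' summaries and the qPCR quantification into one seeded, reproducible
#' run.  Every stage writes its table under `out_dir` and the headline
#' numbers are collected into `report.json`.
#'
#' @param config optional config (path or list), see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @param quiet suppress per-stage progress messages.
#' @return the report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("psrun"),
                         seed = NULL, quiet = FALSE) {
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(name) file.path(out_dir, name)

  # -- generate ------------------------------------------------------------
  syn <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))
  gen <- gen_progression_expression(syn)
  predictions <- gen_target_predictions(gen$truth, syn)
  cohort <- gen_survival_cohort(syn)
  methyl <- gen_methylation_panel(syn)
  qpcr_effects <- stats::setNames(mimic_qpcr_table()$fold_change,
                                  mimic_qpcr_table()$gene_id)
  qpcr <- gen_qpcr_fixture(qpcr_effects, syn)
  paths$mirna_panel <- write_panel_tsv(gen$mirna, out("mirna_panel.tsv"))
  paths$mrna_panel <- write_panel_tsv(gen$mrna, out("mrna_panel.tsv"))
  paths$predictions <- write_tsv(predictions, out("predictions.tsv"))
  paths$survival_cohort <- write_tsv(cohort, out("survival_cohort.tsv"))
  paths$methylation <- write_tsv(methyl, out("methylation.tsv"))
  paths$qpcr <- write_tsv(qpcr, out("qpcr_ct.tsv"))
  truth_path <- out("truth.json")
  jsonlite::write_json(list(
    mirna_groups = as.list(gen$truth$mirna_groups),
    regulators = gen$truth$regulators,
    true_edges = gen$truth$true_edges), truth_path, auto_unbox = TRUE)
  paths$truth <- truth_path
  pipeline_log(quiet, "generate", "%d miRNAs, %d mRNAs, %d predicted edges",
               nrow(gen$mirna), nrow(gen$mrna), nrow(predictions))

  # -- trajectories --------------------------------------------------------
  # the generator emulates depth-normalized abundance panels, so the
  # normalization stage is pass-through unless requested
  tr <- cfg$trajectory
  if (identical(tr$normalize, "quantile")) {
    mirna_norm <- quantile_normalize(gen$mirna)
    mrna_norm <- quantile_normalize(gen$mrna)
  } else {
    mirna_norm <- gen$mirna
    mrna_norm <- gen$mrna
  }
  stats_mirna <- transition_stats(mirna_norm, tr$fc_threshold, tr$p_threshold)
  calls <- classify_trajectory(stats_mirna)
  census <- preneoplastic_census(calls, tr$early_transitions)
  g24 <- calls$feature_id[calls$group %in% c("G2", "G4")]
  paths$transition_stats <- write_tsv(stats_mirna, out("transition_stats_mirna.tsv"))
  paths$trajectory_calls <- write_tsv(calls, out("trajectory_calls_mirna.tsv"))
  pipeline_log(quiet, "trajectory",
               "%d/%d altered early (%.1f%%); %d miRNAs in G2/G4",
               census$n_early, census$n_altered, 100 * census$fraction,
               length(g24))

  # -- integration ---------------------------------------------------------
  it <- cfg$integration
  stages <- panel_stages(mrna_norm)
  from <- if (is.null(it$signature_from)) stages[1] else it$signature_from
  to <- if (is.null(it$signature_to)) stages[length(stages) - 1] else it$signature_to
  signature <- extract_signature(mrna_norm, from, to,
                                 it$signature_fc, it$signature_p, "up")
  universe <- rownames(mrna_norm)[rowSums(mrna_norm) > 0]
  enrich <- fisher_enrichment(signature, predictions, universe)
  top <- enrich$mirna_id[1]
  mir_means <- stage_means(mirna_norm)
  anticorr <- anticorrelation_filter(mir_means[top, ], mrna_norm,
                                     signature$gene_id, it$q_threshold)
  candidates <- candidate_targets(top, signature, predictions, anticorr,
                                  enrich, it$q_threshold)
  paths$signature <- write_tsv(as.data.frame(signature), out("signature.tsv"))
  paths$enrichment <- write_tsv(as.data.frame(enrich), out("enrichment.tsv"))
  paths$candidates <- write_tsv(candidates, out("candidate_targets.tsv"))
  pipeline_log(quiet, "integration",
               "signature %s->%s: %d genes; top miRNA %s (Q=%.3g), %d candidates",
               from, to, nrow(signature), top, enrich$q_value[1],
               nrow(candidates))

  # -- survival ------------------------------------------------------------
  surv <- survival_stratification(cohort, cfg$survival$alpha)
  km_df <- do.call(rbind, lapply(names(surv$km), function(g) {
    k <- surv$km[[g]]
    data.frame(group = g, time = k$time, n_risk = k$n_risk,
               n_event = k$n_event, n_censor = k$n_censor, surv = k$surv)
  }))
  paths$km_curves <- write_tsv(km_df, out("km_curves.tsv"))
  pipeline_log(quiet, "survival",
               "log-rank chisq=%.3g p=%.3g; medians low=%.4g high=%.4g months",
               surv$logrank$chisq, surv$logrank$p_value,
               surv$medians[["low"]], surv$medians[["high"]])

  # -- methylation ---------------------------------------------------------
  rm_ <- region_means(methyl)
  # correlate all-16 average methylation with the focal miRNA's stage means
  focal <- if (length(gen$truth$regulators)) gen$truth$regulators[1] else top
  meth_corr <- methylation_expression_correlation(rm_[, "CpG1-16"],
                                                  mir_means[focal, ])
  rm_df <- data.frame(stage = rownames(rm_), as.data.frame(rm_),
                      check.names = FALSE)
  paths$region_means <- write_tsv(rm_df, out("methylation_region_means.tsv"))
  pipeline_log(quiet, "methylation", "all-16 vs %s expression: r=%.3f (p=%.3g)",
               focal, meth_corr$r, meth_corr$p_value)

  # -- qPCR quantification -------------------------------------------------
  folds <- do.call(rbind, lapply(names(qpcr_effects), function(g)
    ddct_fold(qpcr, g, "RNU44", alpha = cfg$survival$alpha)))
  repressed <- count_repressed(folds)
  paths$fold_changes <- write_tsv(folds, out("fold_changes.tsv"))
  pipeline_log(quiet, "quantify", "%d of %d genes significantly repressed",
               repressed$count, nrow(folds))

  report <- list(
    config = cfg,
    paths = lapply(paths, normalizePath),
    trajectory = list(n_early = census$n_early, n_altered = census$n_altered,
                      fraction_early = census$fraction,
                      group2_4_mirnas = g24),
    integration = list(signature_size = nrow(signature),
                       top_mirna = top, top_q = enrich$q_value[1],
                       n_candidates = nrow(candidates),
                       candidate_genes = candidates$gene_id),
    survival = list(chisq = surv$logrank$chisq, p_value = surv$logrank$p_value,
                    median_low = surv$medians[["low"]],
                    median_high = surv$medians[["high"]],
                    significant = surv$significant),
    methylation = list(r = meth_corr$r, abs_r = meth_corr$abs_r,
                       p_value = meth_corr$p_value,
                       region_means = rm_df),
    quantification = list(n_repressed = repressed$count,
                          repressed_genes = repressed$genes)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  pipeline_log(quiet, "report", "written to %s", out("report.json"))
  invisible(report)
}
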