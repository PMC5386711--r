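#' Configuration for the synthetic progression-study generator
#'
#' Bundles every knob of the synthetic data that the pipeline's analyses
#' assume: a 5-stage ordered progression panel with replicates, planted
#' trajectory groups, planted miRNA-to-target repression, a TargetScan-style
#' prediction table with decoys, an exponential-hazard survival cohort tied
#' to expression, a 16-CpG promoter methylation panel with a stage trend,
#' and replicate qPCR Ct fixtures.
#'
#' Defaults describe the emulated study: stages P < NeoT < AT1 < DCIS < Ca1d
#' (normal-like, hyperplasia, atypical hyperplasia, carcinoma in situ,
#' invasive); 561 miRNAs of which 63 fall in the four trajectory groups and
#' 5 in the decreasing groups G2/G4; 2000 mRNAs; one focal regulator with 35
#' true targets; a survival cohort of n = 80 with baseline hazard log(2)/95
#' per month and hazard ratio 95/60 for the low-expression half; and a
#' two-region CpG methylation trend (sites 1-7: 15/26/26/56/30 percent
#' across stages; sites 8-16: 70/96/96/96/96).
#'
#' @param n_stages number of ordered stages (>= 2).
#' @param stage_labels stage names in progression order, length `n_stages`.
#' @param n_replicates_per_stage replicates per stage (>= 2 when
#'   `noise_cv > 0`, otherwise downstream t-tests are undefined).
#' @param n_mirnas,n_mrnas feature counts for the two panels.
#' @param group_fractions named fractions over `G1`, `G2`, `G3`, `G4`,
#'   `none`, summing to 1 (within 1e-9); applied to both panels.
#' @param effect_size linear fold change per "changing" stage transition
#'   (> 1).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   replicate noise (>= 0).
#' @param n_regulators how many Group-2 miRNAs carry planted true-target
#'   edges (the focal tumor-suppressor miRNAs).
#' @param n_true_edges_per_regulator true targets per regulator.
#' @param decoy_edge_rate probability in `[0, 1]` that any non-true
#'   (miRNA, gene) pair appears in the prediction table.
#' @param survival_n cohort size (>= 4).
#' @param survival_hazard_ratio hazard multiplier (> 0) applied to the
#'   below-median-expression half of the cohort.
#' @param survival_base_hazard exponential event rate per month for the
#'   high-expression half.
#' @param censor_time administrative censoring time in months (`Inf` for
#'   none, the default).
#' @param methyl_trend list of regions, each `list(cpgs = <indices>,
#'   means = <per-stage percent>)`; together the regions must cover CpG
#'   sites 1-16.
#' @param methyl_noise_sd additive noise (percentage points) on per-CpG
#'   values; results are clipped to `[0, 100]`.
#' @param methyl_passages replicate cell passages per stage.
#' @param ct_noise_sd additive noise (cycles) on simulated Ct values.
#' @param seed single integer; fans out to per-generator substreams so the
#'   components are independent yet jointly reproducible.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_stages = 5,
                             stage_labels = c("P", "NeoT", "AT1", "DCIS", "Ca1d"),
                             n_replicates_per_stage = 3,
                             n_mirnas = 561,
                             n_mrnas = 2000,
                             group_fractions = c(G1 = 30, G2 = 3, G3 = 28,
                                                 G4 = 2, none = 498) / 561,
                             effect_size = 2,
                             noise_cv = 0.1,
                             n_regulators = 1,
                             n_true_edges_per_regulator = 35,
                             decoy_edge_rate = 0.02,
                             survival_n = 80,
                             survival_hazard_ratio = 95 / 60,
                             survival_base_hazard = log(2) / 95,
                             censor_time = Inf,
                             methyl_trend = list(
                               list(cpgs = 1:7,
                                    means = c(15, 26, 26, 56, 30)),
                               list(cpgs = 8:16,
                                    means = c(70, 96, 96, 96, 96))),
                             methyl_noise_sd = 2,
                             methyl_passages = 2,
                             ct_noise_sd = 0.15,
                             seed = 1L) {
  cfg <- list(n_stages = as.integer(n_stages), stage_labels = stage_labels,
              n_replicates_per_stage = as.integer(n_replicates_per_stage),
              n_mirnas = as.integer(n_mirnas), n_mrnas = as.integer(n_mrnas),
              group_fractions = unlist(group_fractions),
              effect_size = effect_size,
              noise_cv = noise_cv, n_regulators = as.integer(n_regulators),
              n_true_edges_per_regulator = as.integer(n_true_edges_per_regulator),
              decoy_edge_rate = decoy_edge_rate, survival_n = as.integer(survival_n),
              survival_hazard_ratio = survival_hazard_ratio,
              survival_base_hazard = survival_base_hazard,
              censor_time = censor_time, methyl_trend = methyl_trend,
              methyl_noise_sd = methyl_noise_sd,
              methyl_passages = as.integer(methyl_passages),
              ct_noise_sd = ct_noise_sd, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_stages >= 2, length(cfg$stage_labels) == cfg$n_stages)
  gf <- cfg$group_fractions
  if (!setequal(names(gf), c("G1", "G2", "G3", "G4", "none")))
    stop("group_fractions must be named G1, G2, G3, G4, none")
  if (abs(sum(gf) - 1) > 1e-9) stop("group_fractions must sum to 1")
  if (any(gf < 0)) stop("group_fractions must be non-negative")
  if (cfg$effect_size <= 1) stop("effect_size must be > 1")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  if (cfg$noise_cv > 0 && cfg$n_replicates_per_stage < 2)
    stop("need >= 2 replicates per stage when noise_cv > 0 (t-tests undefined)")
  counts <- c(cfg$n_replicates_per_stage, cfg$n_mirnas, cfg$n_mrnas,
              cfg$n_regulators, cfg$n_true_edges_per_regulator,
              cfg$methyl_passages)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$decoy_edge_rate < 0 || cfg$decoy_edge_rate > 1)
    stop("decoy_edge_rate must lie in [0, 1]")
  if (cfg$survival_n < 4) stop("survival_n must be >= 4")
  if (cfg$survival_hazard_ratio <= 0) stop("survival_hazard_ratio must be > 0")
  if (cfg$survival_base_hazard <= 0) stop("survival_base_hazard must be > 0")
  cpgs <- sort(unlist(lapply(cfg$methyl_trend, `[[`, "cpgs")))
  if (!identical(cpgs, 1:16)) stop("methyl_trend regions must partition CpG sites 1-16")
  for (reg in cfg$methyl_trend)
    if (length(reg$means) != cfg$n_stages)
      stop("each methyl_trend region needs one mean per stage")
  invisible(cfg)
}

# Largest-remainder apportionment of n features over the group fractions.
group_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

# Per-stage multiplier pattern of a trajectory group.
# G1: up at every transition; G2: down at every transition;
# G3: up at the first transition only; G4: down at the first only.
group_pattern <- function(group, effect_size, n_stages) {
  k <- n_stages - 1
  switch(group,
    G1 = effect_size ^ (0:k),
    G2 = effect_size ^ -(0:k),
    G3 = c(1, rep(effect_size, k)),
    G4 = c(1, rep(1 / effect_size, k)),
    none = rep(1, n_stages),
    stop("unknown group: ", group))
}

mirror_group <- function(group) {
  c(G1 = "G2", G2 = "G1", G3 = "G4", G4 = "G3", none = "none")[[group]]
}

# Replicate noise: multiplicative lognormal with the requested CV, mean 1.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

build_panel <- function(prefix, n_features, groups, cfg) {
  ids <- sprintf("%s%04d", prefix, seq_len(n_features))
  baselines <- 2 ^ stats::runif(n_features, 4, 10)
  means <- t(vapply(seq_len(n_features), function(i) {
    baselines[i] * group_pattern(groups[i], cfg$effect_size, cfg$n_stages)
  }, numeric(cfg$n_stages)))
  rownames(means) <- ids
  colnames(means) <- cfg$stage_labels
  nrep <- cfg$n_replicates_per_stage
  values <- means[, rep(seq_len(cfg$n_stages), each = nrep), drop = FALSE]
  values <- values * matrix(lognormal_noise(length(values), cfg$noise_cv),
                            nrow = n_features)
  colnames(values) <- paste0(rep(cfg$stage_labels, each = nrep), "_rep",
                             rep(seq_len(nrep), cfg$n_stages))
  list(panel = expression_panel(values, rep(cfg$stage_labels, each = nrep),
                                cfg$stage_labels),
       means = means)
}

#' Generate the miRNA and mRNA progression panels with planted ground truth
#'
#' Each feature is assigned one trajectory group (or `none`); its stage
#' means follow the planted pattern (multiply or divide by `effect_size` at
#' every transition for G1/G2, at the first transition only for G3/G4) and
#' replicates are the stage mean times mean-one lognormal noise with the
#' configured CV.  The first `n_regulators` Group-2 miRNAs are designated
#' regulators: each receives `n_true_edges_per_regulator` true-target mRNAs
#' whose trajectory is forced to the mirror (anti-monotone) group.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `mirna` and `mrna` ([expression_panel()]s) and
#'   `truth`: a list holding `mirna_groups`, `mrna_groups` (named character),
#'   `regulators`, `true_edges` (data.frame `mirna_id`, `gene_id`),
#'   `mirna_stage_means`, `mrna_stage_means`.
#' @export
gen_progression_expression <- function(config) {
  validate_synthetic_config(config)
  with_substream(config$seed, 1L, {
    assign_groups <- function(n) {
      counts <- group_counts(config$group_fractions, n)
      sample(rep(names(counts), counts))
    }
    mirna_groups <- assign_groups(config$n_mirnas)
    mrna_groups <- assign_groups(config$n_mrnas)

    g2_idx <- which(mirna_groups == "G2")
    if (length(g2_idx) < config$n_regulators)
      stop("fewer Group-2 miRNAs than n_regulators; raise the G2 fraction")
    regulator_idx <- g2_idx[seq_len(config$n_regulators)]

    # plant anti-monotone true targets: regulators are G2 (continuous
    # decrease), so their targets are forced to G1 (continuous increase)
    n_targets <- config$n_regulators * config$n_true_edges_per_regulator
    if (n_targets > config$n_mrnas)
      stop("more planted targets than mRNAs")
    target_pool <- sample(config$n_mrnas, n_targets)
    edges <- data.frame(
      mirna_idx = rep(regulator_idx, each = config$n_true_edges_per_regulator),
      gene_idx = target_pool
    )
    mrna_groups[target_pool] <- vapply(
      mirna_groups[edges$mirna_idx], mirror_group, character(1))

    mir <- build_panel("mir", config$n_mirnas, mirna_groups, config)
    mrna <- build_panel("gene", config$n_mrnas, mrna_groups, config)

    mir_ids <- rownames(mir$means)
    gene_ids <- rownames(mrna$means)
    names(mirna_groups) <- mir_ids
    names(mrna_groups) <- gene_ids
    truth <- list(
      mirna_groups = mirna_groups,
      mrna_groups = mrna_groups,
      regulators = mir_ids[regulator_idx],
      true_edges = data.frame(mirna_id = mir_ids[edges$mirna_idx],
                              gene_id = gene_ids[edges$gene_idx],
                              stringsAsFactors = FALSE),
      mirna_stage_means = mir$means,
      mrna_stage_means = mrna$means
    )
    list(mirna = mir$panel, mrna = mrna$panel, truth = truth)
  })
}

#' Generate a TargetScan-style miRNA-to-gene prediction table
#'
#' Contains every planted true edge plus decoy edges: each non-true
#' (miRNA, gene) pair enters independently with probability
#' `decoy_edge_rate`.  Pairs are unique.
#'
#' @param truth the `truth` element of [gen_progression_expression()].
#' @param config the same [synthetic_config()].
#' @return data.frame with columns `mirna_id`, `gene_id`.
#' @export
gen_target_predictions <- function(truth, config) {
  validate_synthetic_config(config)
  with_substream(config$seed, 2L, {
    mirnas <- names(truth$mirna_groups)
    genes <- names(truth$mrna_groups)
    tab <- truth$true_edges
    if (config$decoy_edge_rate > 0) {
      keep <- stats::runif(length(mirnas) * length(genes)) < config$decoy_edge_rate
      decoys <- data.frame(
        mirna_id = rep(mirnas, each = length(genes))[keep],
        gene_id = rep(genes, times = length(mirnas))[keep],
        stringsAsFactors = FALSE)
      tab <- rbind(tab, decoys)
    }
    tab <- tab[!duplicated(paste(tab$mirna_id, tab$gene_id, sep = "\r")), ]
    rownames(tab) <- NULL
    tab
  })
}

#' Generate an expression-linked exponential survival cohort
#'
#' Expression is standard lognormal; the below-median-expression half has
#' its exponential event hazard multiplied by `survival_hazard_ratio`.
#' Administrative censoring at `censor_time` months if finite.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `sample_id`, `time_months`,
#'   `event` (1 = death observed, 0 = censored), `expression`.
#' @export
gen_survival_cohort <- function(config) {
  validate_synthetic_config(config)
  with_substream(config$seed, 3L, {
    n <- config$survival_n
    expression <- stats::rlnorm(n)
    low <- expression <= stats::median(expression)
    rate <- config$survival_base_hazard *
      ifelse(low, config$survival_hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    event <- as.integer(t_event <= config$censor_time)
    data.frame(sample_id = sprintf("s%03d", seq_len(n)),
               time_months = pmin(t_event, config$censor_time),
               event = event, expression = expression,
               stringsAsFactors = FALSE)
  })
}

#' Generate a 16-CpG promoter methylation panel across stages
#'
#' Per-CpG percent methylation follows the configured per-region stage
#' trend plus additive Gaussian noise; values outside `[0, 100]` are
#' clipped (with a message).  Replicate passages emulate repeated
#' pyrosequencing of independent cultures.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `stage` (ordered factor), `cpg_index`
#'   (1-16), `passage`, `percent`.
#' @export
gen_methylation_panel <- function(config) {
  validate_synthetic_config(config)
  with_substream(config$seed, 4L, {
    rows <- do.call(rbind, lapply(config$methyl_trend, function(reg) {
      expand.grid(stage = config$stage_labels, cpg_index = reg$cpgs,
                  passage = seq_len(config$methyl_passages),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    target <- numeric(nrow(rows))
    for (reg in config$methyl_trend) {
      sel <- rows$cpg_index %in% reg$cpgs
      target[sel] <- reg$means[match(rows$stage[sel], config$stage_labels)]
    }
    percent <- target + stats::rnorm(nrow(rows), 0, config$methyl_noise_sd)
    n_clip <- sum(percent < 0 | percent > 100)
    if (n_clip > 0)
      message(n_clip, " methylation value(s) outside [0, 100] clipped")
    percent <- pmin(pmax(percent, 0), 100)
    out <- data.frame(stage = factor(rows$stage, levels = config$stage_labels,
                                     ordered = TRUE),
                      cpg_index = rows$cpg_index, passage = rows$passage,
                      percent = percent)
    out[order(out$stage, out$cpg_index, out$passage), , drop = FALSE]
  })
}

#' Generate a replicate qPCR Ct fixture with known fold changes
#'
#' For each gene the treated-vs-control fold change of the
#' reference-normalized expression (2^-ddCt) equals the requested fold in
#' expectation; with `ct_noise_sd = 0` the recovery is exact.
#'
#' @param effects named numeric vector: gene ID to true linear fold change
#'   (> 0) of treated relative to control.
#' @param config a [synthetic_config()]; uses `n_replicates_per_stage`
#'   replicates per arm and `ct_noise_sd` cycles of Ct noise.
#' @param reference_gene reference small RNA / housekeeping gene ID.
#' @return data.frame with columns `sample_id`, `arm` (`treated` /
#'   `control`), `gene_id`, `ct`.
#' @export
gen_qpcr_fixture <- function(effects, config, reference_gene = "RNU44") {
  validate_synthetic_config(config)
  if (is.null(names(effects)) || any(effects <= 0))
    stop("effects must be a named vector of positive folds")
  with_substream(config$seed, 5L, {
    nrep <- config$n_replicates_per_stage
    arms <- c("control", "treated")
    recs <- expand.grid(rep = seq_len(nrep), arm = arms,
                        gene_id = c(reference_gene, names(effects)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base_ref <- 18
    base_target <- 24
    ct <- ifelse(recs$gene_id == reference_gene, base_ref,
                 base_target - ifelse(recs$arm == "treated",
                                      log2(effects[recs$gene_id]), 0))
    ct <- ct + stats::rnorm(nrow(recs), 0, config$ct_noise_sd)
    data.frame(sample_id = paste0(recs$arm, "_rep", recs$rep),
               arm = recs$arm, gene_id = recs$gene_id, ct = as.numeric(ct),
               stringsAsFactors = FALSE)
  })
}
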