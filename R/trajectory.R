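#' Quantile-normalize an expression panel
#'
#' Forces every sample to a common distribution: after normalization each
#' sample's sorted values equal the across-sample mean of sorted values,
#' while the rank order within each sample is preserved.  Ties receive the
#' mean of the tied quantiles.
#'
#' @param panel an [expression_panel()] with at least 2 samples.
#' @return the normalized [expression_panel()].
#' @export
quantile_normalize <- function(panel) {
  if (ncol(panel) < 2) stop("quantile normalization needs >= 2 samples")
  constant <- apply(panel, 2, function(x) length(unique(x)) == 1)
  if (any(constant))
    message("all-constant sample(s) ", paste(colnames(panel)[constant], collapse = ", "),
            ": mean-of-tied-ranks rule applied")
  norm <- limma::normalizeQuantiles(unclass(panel), ties = TRUE)
  d <- panel_design(panel)
  expression_panel(norm, as.character(d$stage), levels(d$stage))
}

# log2 transform with pseudocount substituted for zeros
log2_expr <- function(x, pseudocount = 1) {
  x[x == 0] <- pseudocount
  log2(x)
}

# Vectorized equal-variance two-sample t-test on the log2 scale, rowwise
# over two sample-column groups.  Degenerate conventions: zero pooled
# variance with equal means -> p = 1; with unequal means -> p = 0.
row_ttest_log2 <- function(panel, cols_a, cols_b, pseudocount = 1) {
  la <- log2_expr(panel[, cols_a, drop = FALSE], pseudocount)
  lb <- log2_expr(panel[, cols_b, drop = FALSE], pseudocount)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  fc <- mb - ma
  if (na < 2 || nb < 2) {
    return(data.frame(log2fc = fc, t = NA_real_, p_value = NA_real_))
  }
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- fc / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  degenerate <- se == 0
  if (any(degenerate)) {
    message(sum(degenerate), " feature(s) with zero within-stage variance: ",
            "p set to 0/1 by convention")
    p[degenerate] <- ifelse(fc[degenerate] == 0, 1, 0)
    tstat[degenerate] <- ifelse(fc[degenerate] == 0, 0,
                                sign(fc[degenerate]) * Inf)
  }
  data.frame(log2fc = fc, t = tstat, p_value = p)
}

direction_call <- function(log2fc, p, fc_threshold, p_threshold) {
  lt <- log2(fc_threshold)
  ifelse(log2fc >= lt & p < p_threshold, "up",
         ifelse(log2fc <= -lt & p < p_threshold, "down", "flat"))
}

#' Per-transition differential statistics across adjacent stages
#'
#' For every adjacent stage transition, computes the log2 fold change of
#' the later versus the earlier stage (difference of mean log2 replicate
#' values), a two-sided equal-variance Student t-test p-value on the log2
#' values, and a direction call: `up` when the fold change reaches
#' `fc_threshold` (linear) with `p < p_threshold`, `down` symmetrically,
#' otherwise `flat`.  No multiple-testing correction is applied at this
#' stage.
#'
#' @param panel an [expression_panel()]; p-values need >= 2 replicates per
#'   stage.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param p_threshold significance threshold (default 0.05).
#' @param pseudocount substituted for zero values before log2.
#' @return A `transition_stats` data.frame with columns `feature_id`,
#'   `transition` (1-based index), `from_stage`, `to_stage`, `log2fc`,
#'   `p_value`, `direction`; thresholds and the stage order are stored as
#'   attributes.
#' @export
transition_stats <- function(panel, fc_threshold = 1.5, p_threshold = 0.05,
                             pseudocount = 1) {
  d <- panel_design(panel)
  stages <- levels(d$stage)
  if (length(stages) < 2) stop("need >= 2 stages")
  out <- do.call(rbind, lapply(seq_len(length(stages) - 1), function(t) {
    cols_a <- d$sample_id[d$stage == stages[t]]
    cols_b <- d$sample_id[d$stage == stages[t + 1]]
    tt <- row_ttest_log2(panel, cols_a, cols_b, pseudocount)
    data.frame(feature_id = rownames(panel), transition = t,
               from_stage = stages[t], to_stage = stages[t + 1],
               log2fc = tt$log2fc, p_value = tt$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$direction <- direction_call(out$log2fc, out$p_value,
                                  fc_threshold, p_threshold)
  structure(out, fc_threshold = fc_threshold, p_threshold = p_threshold,
            stages = stages,
            class = c("transition_stats", "data.frame"))
}

#' Classify features into the four progression trajectory groups
#'
#' Group definitions over the per-transition direction calls:
#' `G1` early and continuous increase (every transition `up`);
#' `G2` early and continuous decrease (every transition `down`);
#' `G3` early increase then plateau (`up` at transition 1, `flat` after);
#' `G4` early decrease then plateau (`down` at transition 1, `flat` after);
#' anything else is `none`.  Also records the first altered transition
#' (smallest transition index with a non-flat call).
#'
#' @param stats a [transition_stats()] table covering all transitions.
#' @return A `trajectory_calls` data.frame with columns `feature_id`,
#'   `group`, `first_altered_transition` (NA when never altered).
#' @export
classify_trajectory <- function(stats) {
  n_trans <- length(attr(stats, "stages")) - 1
  split_dir <- split(stats[c("transition", "direction")], stats$feature_id)
  calls <- lapply(split_dir, function(df) {
    dir <- df$direction[order(df$transition)]
    if (length(dir) != n_trans || anyNA(dir))
      stop("transition stats incomplete for a feature")
    group <- if (all(dir == "up")) "G1"
      else if (all(dir == "down")) "G2"
      else if (dir[1] == "up" && all(dir[-1] == "flat")) "G3"
      else if (dir[1] == "down" && all(dir[-1] == "flat")) "G4"
      else "none"
    altered <- which(dir != "flat")
    data.frame(group = group,
               first_altered_transition =
                 if (length(altered)) min(altered) else NA_integer_)
  })
  out <- do.call(rbind, calls)
  out <- data.frame(feature_id = names(split_dir), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  # restore panel feature order
  out <- out[order(match(out$feature_id, unique(stats$feature_id))), ]
  rownames(out) <- NULL
  structure(out, stages = attr(stats, "stages"),
            class = c("trajectory_calls", "data.frame"))
}

#' Census of alterations arising in the preneoplastic window
#'
#' Counts how many altered features (first non-flat transition exists) were
#' first altered in the preneoplastic transitions — by default the
#' transitions into hyperplasia and atypia (transitions 1 and 2 of the
#' default panel).
#'
#' @param calls a [classify_trajectory()] result.
#' @param preneoplastic_transitions transition indices counted as early.
#' @return list with `n_early`, `n_altered`, `fraction`
#'   (`n_early / n_altered`, 0 when nothing is altered).
#' @export
preneoplastic_census <- function(calls, preneoplastic_transitions = 1:2) {
  first <- calls$first_altered_transition
  n_altered <- sum(!is.na(first))
  n_early <- sum(first %in% preneoplastic_transitions)
  list(n_early = n_early, n_altered = n_altered,
       fraction = if (n_altered > 0) n_early / n_altered else 0)
}
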