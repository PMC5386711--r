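#' Extract a differential gene signature between two stages
#'
#' Genes whose expression changes from `from_stage` to `to_stage` by at
#' least `fc_threshold` (linear) in the requested direction with
#' `p < p_threshold` under the equal-variance Student t-test on log2
#' replicate values.  The canonical use is the up-signature of the
#' normal-like to carcinoma-in-situ transition (P to DCIS) at thresholds
#' 1.5 and 0.05.
#'
#' @param panel mRNA [expression_panel()].
#' @param from_stage,to_stage distinct stage labels present in the design.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param p_threshold significance threshold (default 0.05).
#' @param direction `"up"` or `"down"` relative to `from_stage`.
#' @param pseudocount substituted for zero values before log2.
#' @return A `signature` data.frame with columns `gene_id`, `log2fc`,
#'   `p_value`; the stage pair, direction and thresholds are attributes.
#' @export
extract_signature <- function(panel, from_stage, to_stage,
                              fc_threshold = 1.5, p_threshold = 0.05,
                              direction = c("up", "down"), pseudocount = 1) {
  direction <- match.arg(direction)
  stages <- panel_stages(panel)
  if (!all(c(from_stage, to_stage) %in% stages))
    stop("stages not present in the panel design")
  if (identical(from_stage, to_stage)) stop("from_stage and to_stage must differ")
  d <- panel_design(panel)
  tt <- row_ttest_log2(panel,
                       d$sample_id[d$stage == from_stage],
                       d$sample_id[d$stage == to_stage], pseudocount)
  lt <- log2(fc_threshold)
  keep <- if (direction == "up") tt$log2fc >= lt else tt$log2fc <= -lt
  keep <- keep & !is.na(tt$p_value) & tt$p_value < p_threshold
  out <- data.frame(gene_id = rownames(panel)[keep], log2fc = tt$log2fc[keep],
                    p_value = tt$p_value[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, from_stage = from_stage, to_stage = to_stage,
            direction = direction, fc_threshold = fc_threshold,
            p_threshold = p_threshold,
            class = c("signature", "data.frame"))
}

#' Filter candidate genes by inverse correlation with a miRNA profile
#'
#' Pearson product-moment correlation between the miRNA's per-stage mean
#' expression and each candidate gene's per-stage means across the
#' progression.  Genes are retained when `r < 0` and the
#' Benjamini-Hochberg-adjusted two-sided correlation p-value is below
#' `q_threshold`.  Zero-variance profiles are skipped with a warning.
#'
#' @param mirna_profile numeric vector of the miRNA's per-stage means, in
#'   stage order.
#' @param mrna_panel mRNA [expression_panel()] (stage means are computed
#'   from it), or a precomputed gene-by-stage matrix.
#' @param candidates character vector of candidate gene IDs.
#' @param q_threshold FDR gate (default 0.25).
#' @return data.frame with columns `gene_id`, `r`, `p_value`, `q_value`,
#'   `retained`.
#' @export
anticorrelation_filter <- function(mirna_profile, mrna_panel, candidates,
                                   q_threshold = 0.25) {
  sm <- if (inherits(mrna_panel, "expression_panel")) stage_means(mrna_panel)
        else as.matrix(mrna_panel)
  if (length(mirna_profile) != ncol(sm))
    stop("miRNA profile length must match the number of stages")
  if (length(mirna_profile) < 3) stop("need >= 3 stages for correlation")
  missing <- setdiff(candidates, rownames(sm))
  if (length(missing))
    stop("candidate genes absent from the panel: ", paste(missing, collapse = ", "))
  if (stats::sd(mirna_profile) == 0) stop("miRNA profile has zero variance")
  res <- lapply(candidates, function(g) {
    y <- sm[g, ]
    if (stats::sd(y) == 0) {
      warning("zero-variance profile for gene ", g, "; skipped")
      return(data.frame(gene_id = g, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(mirna_profile, y, method = "pearson")
    data.frame(gene_id = g, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q_value <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out$retained <- !is.na(out$r) & out$r < 0 & out$q_value < q_threshold
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric probability P(X >= k) for X ~ Hyper(N, K, n):
# direct summation of the mass via log-gamma arithmetic, exact at small
# counts (no 2x2 chi-square approximation).
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0, K <= N, n <= N)
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  i <- k:hi
  i <- i[i >= max(0, n - (N - K))]
  if (!length(i)) return(0)
  logp <- lchoose_(K, i) + lchoose_(N - K, n - i) - lchoose_(N, n)
  min(1, sum(exp(logp)))
}

#' Per-miRNA hypergeometric enrichment of predicted targets in a signature
#'
#' The target-set enrichment statistic: for each miRNA in the prediction
#' table, the one-sided Fisher exact (upper-tail hypergeometric)
#' probability of observing at least `k` of its `K` in-universe predicted
#' targets inside the `n`-gene signature drawn from an `N`-gene universe,
#' with Benjamini-Hochberg Q-values across all miRNAs tested.  A miRNA
#' with no in-universe targets gets `p = 1` by convention.
#'
#' @param signature an [extract_signature()] result (or a character vector
#'   of gene IDs).
#' @param predictions prediction table: data.frame with columns `mirna_id`,
#'   `gene_id`.
#' @param universe character vector: all genes quantified (the signature
#'   must be a subset; target sets are intersected with it).
#' @return An `enrichment_result` data.frame, one row per miRNA, columns
#'   `mirna_id`, `k`, `K`, `n`, `N`, `p_value`, `q_value`, sorted by
#'   `q_value` then `p_value` then `mirna_id`.
#' @export
fisher_enrichment <- function(signature, predictions, universe) {
  sig_genes <- if (is.data.frame(signature)) signature$gene_id else signature
  if (length(universe) == 0) stop("empty gene universe")
  if (anyDuplicated(universe)) stop("universe contains duplicate gene IDs")
  if (!all(sig_genes %in% universe))
    stop("signature must be a subset of the universe")
  N <- length(universe)
  n <- length(sig_genes)
  in_sig <- universe %in% sig_genes
  names(in_sig) <- universe
  pred <- predictions[predictions$gene_id %in% universe, , drop = FALSE]
  targets <- split(pred$gene_id, pred$mirna_id)
  mirnas <- sort(unique(predictions$mirna_id))
  rows <- lapply(mirnas, function(m) {
    tg <- unique(targets[[m]])
    K <- length(tg)
    k <- if (K) sum(in_sig[tg]) else 0L
    p <- if (K == 0) 1 else hyper_upper_tail(k, K, n, N)
    data.frame(mirna_id = m, k = as.integer(k), K = as.integer(K),
               n = as.integer(n), N = as.integer(N), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$mirna_id), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up Q-values: `Q_(i) = min over j >= i of m * p_(j) / j`, returned
#' in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of Q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Ranked candidate target genes of an enriched miRNA
#'
#' For a miRNA passing the enrichment gate (`Q < q_threshold`), intersects
#' its predicted targets with the signature and the anticorrelation-
#' retained set, and ranks by the magnitude of the signature-transition
#' fold change (descending; ties broken lexicographically by gene ID).
#' A miRNA failing the gate yields an empty list; a miRNA absent from the
#' prediction table yields an empty list with a warning.
#'
#' @param mirna_id the miRNA to report.
#' @param signature an [extract_signature()] result.
#' @param predictions prediction table (`mirna_id`, `gene_id`).
#' @param anticorr an [anticorrelation_filter()] result (its retained
#'   genes are used), or a character vector of retained gene IDs.
#' @param enrichment a [fisher_enrichment()] result covering `mirna_id`.
#' @param q_threshold FDR gate (default 0.25).
#' @return data.frame of evidence rows: `gene_id`, `log2fc`, `p_value`
#'   (signature test), `r` (anticorrelation, when available), in rank
#'   order.
#' @export
candidate_targets <- function(mirna_id, signature, predictions, anticorr,
                              enrichment, q_threshold = 0.25) {
  empty <- data.frame(gene_id = character(0), log2fc = numeric(0),
                      p_value = numeric(0), r = numeric(0))
  if (!mirna_id %in% predictions$mirna_id) {
    warning("miRNA ", mirna_id, " absent from the prediction table")
    return(empty)
  }
  row <- enrichment[enrichment$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(row) == 0) stop("enrichment result does not cover ", mirna_id)
  if (row$q_value >= q_threshold) return(empty)
  kept <- if (is.data.frame(anticorr)) anticorr$gene_id[anticorr$retained]
          else anticorr
  tg <- unique(predictions$gene_id[predictions$mirna_id == mirna_id])
  hits <- signature[signature$gene_id %in% intersect(tg, kept), , drop = FALSE]
  hits <- hits[order(-abs(hits$log2fc), hits$gene_id), , drop = FALSE]
  if (is.data.frame(anticorr)) {
    hits$r <- anticorr$r[match(hits$gene_id, anticorr$gene_id)]
  } else hits$r <- NA_real_
  rownames(hits) <- NULL
  as.data.frame(hits)
}
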