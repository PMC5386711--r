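#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; the fold change of the
#' treated arm relative to control is `2^-ddCt` with
#' `ddCt = mean dCt(treated) - mean dCt(control)` (amplification
#' efficiency fixed at 2).  Significance is a two-sided equal-variance
#' t-test on the replicate dCt values; with fewer than 2 replicates per
#' arm the fold is still computed and the p-value is `NA` (flagged with a
#' warning).
#'
#' @param ct long data.frame with columns `sample_id`, `arm`
#'   (`treated` / `control`), `gene_id`, `ct` (cycles, > 0).
#' @param target_gene gene of interest.
#' @param reference_gene normalizer (e.g. a small nucleolar RNA control or
#'   a ribosomal housekeeping gene).
#' @param alpha significance level for the `significant` flag.
#' @return one-row data.frame: `gene_id`, `fold_change`, `p_value`,
#'   `significant`.
#' @export
ddct_fold <- function(ct, target_gene, reference_gene, alpha = 0.05) {
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  dct_arm <- function(arm) {
    sub <- ct[ct$arm == arm, ]
    tgt <- sub[sub$gene_id == target_gene, c("sample_id", "ct")]
    ref <- sub[sub$gene_id == reference_gene, c("sample_id", "ct")]
    if (nrow(tgt) == 0) stop("no Ct for target gene in arm ", arm)
    if (nrow(ref) == 0) stop("missing reference Ct in arm ", arm)
    m <- match(tgt$sample_id, ref$sample_id)
    if (anyNA(m)) stop("missing reference Ct for sample(s) in arm ", arm)
    tgt$ct - ref$ct[m]
  }
  dct_t <- dct_arm("treated")
  dct_c <- dct_arm("control")
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2 ^ (-ddct)
  if (length(dct_t) < 2 || length(dct_c) < 2) {
    warning("fewer than 2 replicates: fold computed, p-value undefined")
    p <- NA_real_
  } else if (stats::sd(c(dct_t - mean(dct_t), dct_c - mean(dct_c))) == 0) {
    p <- if (ddct == 0) 1 else 0
  } else {
    p <- stats::t.test(dct_t, dct_c, var.equal = TRUE)$p.value
  }
  data.frame(gene_id = target_gene, fold_change = fold, p_value = p,
             significant = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
}

#' Count significantly repressed genes among fold-change rows
#'
#' A gene counts as repressed when its treated fold change is below 1.0
#' and the significance flag is set.
#'
#' @param rows data.frame with columns `gene_id`, `fold_change`,
#'   `significant` (one row per gene, e.g. from [ddct_fold()]).
#' @return list with `count` and the lexicographically sorted `genes`.
#' @export
count_repressed <- function(rows) {
  hit <- rows$fold_change < 1.0 & rows$significant
  list(count = sum(hit), genes = sort(rows$gene_id[hit]))
}

#' Ki67 proliferation index
#'
#' Fraction of cells scored proliferative: those with at least
#' `positive_threshold` nuclear Ki67 foci (default 3, i.e. cells with 0-2
#' foci count as Ki67-negative).
#'
#' @param foci integer vector of per-cell focus counts (>= 0).
#' @param positive_threshold minimum focus count scored positive.
#' @return fraction of positive cells in `[0, 1]`.
#' @export
ki67_index <- function(foci, positive_threshold = 3) {
  if (length(foci) == 0) stop("no cells scored")
  if (any(foci < 0) || any(foci != round(foci))) stop("focus counts must be non-negative integers")
  mean(foci >= positive_threshold)
}

#' Count colonies above the minimum size
#'
#' A colony counts when it has strictly more than `min_cells` cells
#' (default 50).
#'
#' @param sizes integer vector of per-colony cell counts (>= 0).
#' @param min_cells size threshold; strictly exceeded to count.
#' @return number of qualifying colonies.
#' @export
colony_count <- function(sizes, min_cells = 50) {
  if (any(sizes < 0)) stop("colony sizes must be non-negative")
  sum(sizes > min_cells)
}

#' Normalized dual-luciferase reporter activity
#'
#' Firefly signal (the 3'UTR reporter) divided by renilla signal (the
#' transfection-efficiency control), rescaled so the reference condition
#' (scramble mimic) equals 1.0.  Replicate wells within a condition are
#' averaged after the ratio.
#'
#' @param firefly,renilla positive luminescence readings, one per well.
#' @param condition condition label per well.
#' @param reference the condition rescaled to 1.0.
#' @return named numeric vector of relative activities, one per condition.
#' @export
luciferase_activity <- function(firefly, renilla, condition,
                                reference = "scramble") {
  if (any(renilla <= 0)) stop("renilla signal must be positive")
  if (any(firefly <= 0)) stop("firefly signal must be positive")
  if (!reference %in% condition) stop("reference condition absent")
  ratio <- tapply(firefly / renilla, condition, mean)
  out <- ratio / ratio[[reference]]
  out[unique(as.character(condition))]
}

#' Published mimic-transfection qPCR fold changes (14-gene validation set)
#'
#' Reads the shipped plain-text table of the 14 candidate target genes
#' assayed by qPCR after tumor-suppressor miRNA mimic transfection:
#' the scramble-control fold (1.0 by definition), the mimic fold change,
#' and the published significance flag.
#'
#' @return data.frame with columns `gene_id`, `scramble_fold`,
#'   `fold_change`, `significant`.
#' @export
mimic_qpcr_table <- function() {
  path <- system.file("extdata", "mir29c_mimic_qpcr.tsv",
                      package = "progressionscope", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}
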