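#' Per-stage region means of a CpG methylation panel
#'
#' Averages replicate passages per (stage, CpG) first, then takes the
#' arithmetic mean over the CpG sites of each region, per stage.  The
#' default regions are the promoter's two blocks (CpG 1-7 and 8-16) plus
#' the full 16-site window.
#'
#' @param panel long data.frame with columns `stage`, `cpg_index`,
#'   `percent` and optionally `passage` (the shape returned by
#'   [gen_methylation_panel()]).
#' @param regions named list of CpG index vectors.
#' @return matrix of mean percent methylation, stages (in panel order) by
#'   regions.
#' @export
region_means <- function(panel,
                         regions = list("CpG1-7" = 1:7, "CpG8-16" = 8:16,
                                        "CpG1-16" = 1:16)) {
  if (any(lengths(regions) == 0)) stop("empty region")
  if (!all(unlist(regions) %in% panel$cpg_index))
    stop("region indexes CpG sites absent from the panel")
  if (any(panel$percent < 0 | panel$percent > 100))
    stop("percent methylation outside [0, 100]")
  # collapse passages to per-(stage, CpG) means
  per_site <- stats::aggregate(percent ~ stage + cpg_index, data = panel,
                               FUN = mean)
  stages <- if (is.factor(panel$stage)) levels(panel$stage)
            else unique(as.character(panel$stage))
  out <- sapply(regions, function(idx) {
    sub <- per_site[per_site$cpg_index %in% idx, ]
    m <- tapply(sub$percent, as.character(sub$stage), mean)
    m[stages]
  })
  rownames(out) <- stages
  out
}

#' Correlation between average promoter methylation and miRNA expression
#'
#' Pearson product-moment correlation computed across the progression
#' stages (one point per stage, matched order).  Both the signed `r` and
#' `|r|` are reported, with the two-sided p-value.
#'
#' @param methylation per-stage average percent methylation, in stage
#'   order.
#' @param expression per-stage miRNA expression level, same order.
#' @return list with `r`, `abs_r`, `p_value`, `n_stages`.
#' @export
methylation_expression_correlation <- function(methylation, expression) {
  if (length(methylation) != length(expression))
    stop("stage vectors must have equal length")
  if (length(methylation) < 3) stop("need >= 3 stages")
  if (stats::sd(methylation) == 0 || stats::sd(expression) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(methylation, expression, method = "pearson")
  list(r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
       p_value = ct$p.value, n_stages = length(methylation))
}

#' Percent change of expression after demethylating treatment
#'
#' `100 * (treated - vehicle) / vehicle`, the percent response of a
#' normalized miRNA level to a demethylating agent relative to vehicle.
#'
#' @param vehicle normalized level under vehicle control (> 0).
#' @param treated normalized level under treatment.
#' @return percent change (positive = induction).
#' @export
demethylation_response <- function(vehicle, treated) {
  if (any(vehicle <= 0)) stop("vehicle level must be positive")
  100 * (treated - vehicle) / vehicle
}
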