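#' Construct an expression panel with an ordered stage design
#'
#' An `expression_panel` is the central container for the progression
#' analyses: a non-negative feature-by-sample matrix (linear scale) together
#' with an ordered stage design.  Sample IDs encode the design as
#' `"<stage>_rep<k>"`.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   non-negative, linear scale.  Must have unique rownames (feature IDs)
#'   and colnames (sample IDs).
#' @param stages character or factor of length `ncol(values)`: the stage of
#'   each sample.
#' @param stage_levels character: the stage labels in progression order.
#'   Defaults to the unique values of `stages` in order of appearance.
#' @return An `expression_panel`: the matrix with a `design` attribute
#'   (data.frame of `sample_id`, `stage` ordered factor, `replicate`).
#' @export
expression_panel <- function(values, stages,
                             stage_levels = unique(as.character(stages))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("feature IDs (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample IDs (colnames) must be present and unique")
  if (any(values < 0)) stop("expression values must be non-negative")
  stages <- as.character(stages)
  if (length(stages) != ncol(values))
    stop("one stage per sample required")
  if (!all(stages %in% stage_levels))
    stop("stage labels outside the declared stage order")
  stage <- factor(stages, levels = stage_levels, ordered = TRUE)
  design <- data.frame(
    sample_id = colnames(values),
    stage = stage,
    replicate = stats::ave(seq_along(stage), stage, FUN = seq_along),
    stringsAsFactors = FALSE
  )
  structure(values, design = design, class = c("expression_panel", "matrix", "array"))
}

#' @export
print.expression_panel <- function(x, ...) {
  d <- panel_design(x)
  cat(sprintf("expression_panel: %d features x %d samples\n", nrow(x), ncol(x)))
  cat("stages:", paste(levels(d$stage), collapse = " < "), "\n")
  cat("replicates per stage:", paste(table(d$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Stage design of a panel
#'
#' @param panel an [expression_panel()].
#' @return data.frame with columns `sample_id`, `stage` (ordered factor),
#'   `replicate`.
#' @export
panel_design <- function(panel) {
  d <- attr(panel, "design")
  if (is.null(d)) stop("not an expression_panel: no stage design attached")
  d
}

#' Stage labels of a panel, in progression order
#' @param panel an [expression_panel()].
#' @return character vector of stage labels.
#' @export
panel_stages <- function(panel) levels(panel_design(panel)$stage)

#' Per-stage mean expression
#'
#' Arithmetic mean over replicates within each stage, per feature.
#'
#' @param panel an [expression_panel()].
#' @return numeric matrix, features x stages (in progression order).
#' @export
stage_means <- function(panel) {
  d <- panel_design(panel)
  sapply(levels(d$stage), function(s) {
    cols <- d$sample_id[d$stage == s]
    rowMeans(panel[, cols, drop = FALSE])
  })
}

#' Read / write an expression panel as TSV
#'
#' The TSV dialect has a header row, first column `feature_id`, and sample
#' columns named `"<stage>_rep<k>"` from which the stage design is recovered.
#'
#' @param panel an [expression_panel()].
#' @param path file path.
#' @param stage_levels optional explicit stage order for reading; by default
#'   stages are ordered by first appearance in the columns.
#' @return `read_panel_tsv` returns an [expression_panel()];
#'   `write_panel_tsv` returns `path` invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- data.frame(feature_id = rownames(panel), as.data.frame(unclass(panel)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path, stage_levels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stages <- sub("_rep[0-9]+$", "", colnames(m))
  if (is.null(stage_levels)) stage_levels <- unique(stages)
  expression_panel(m, stages, stage_levels)
}

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.  Generators derive per-component substreams so
# that one global seed yields independent, reproducible components.
with_substream <- function(seed, offset, code) {
  sub <- (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
  sub <- sub %% 2147483647L
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(sub)
  force(code)
}
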