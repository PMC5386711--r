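# Shared fixtures and independent oracles for the test suite.

# Build a small expression panel from a plain matrix of linear values.
make_panel <- function(values, stages, stage_levels = unique(stages)) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(stages, "_rep",
                               stats::ave(seq_along(stages), stages, FUN = seq_along))
  expression_panel(values, stages, stage_levels)
}

# Two-stage panel with given log2 replicate values per stage (one feature).
two_stage_panel <- function(log2_a, log2_b) {
  vals <- matrix(2 ^ c(log2_a, log2_b), nrow = 1)
  make_panel(vals, rep(c("A", "B"), c(length(log2_a), length(log2_b))))
}

# Brute-force upper-tail hypergeometric oracle: enumerate every n-subset of
# an N-gene universe with K marked targets and count subsets overlapping the
# target set in at least k genes.  Independent of the analytical route.
hyper_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Hand product-limit estimator for uncensored data: S after each distinct
# event time.
km_oracle_uncensored <- function(times) {
  times <- sort(times)
  n <- length(times)
  distinct <- unique(times)
  surv <- numeric(length(distinct))
  s <- 1
  for (i in seq_along(distinct)) {
    d <- sum(times == distinct[i])
    at_risk <- sum(times >= distinct[i])
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = distinct, surv = surv)
}

# Default-shaped config scaled down for fast unit tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_mirnas = 60, n_mrnas = 300,
                   group_fractions = c(G1 = 0.1, G2 = 0.05, G3 = 0.1,
                                       G4 = 0.05, none = 0.7),
                   n_true_edges_per_regulator = 10, seed = 11L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}
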