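test_that("signature extraction applies the fold and significance gates", {
  # 5 genes, exactly 2 exceed 1.5-fold with p < 0.05 between P and DCIS
  set.seed(3)
  log2_means <- c(2.0, 0.1, 1.2, -0.3, 0.0)  # planted P -> DCIS shifts
  base <- matrix(rep(c(5, 6, 7, 8, 9), 6), nrow = 5)
  shift <- outer(log2_means, c(0, 0, 0, 1, 1, 1))
  vals <- 2 ^ (base + shift + matrix(rnorm(30, 0, 0.05), 5))
  p <- make_panel(vals, rep(c("P", "DCIS"), each = 3))
  sig <- extract_signature(p, "P", "DCIS")
  expect_setequal(sig$gene_id, c("f001", "f003"))
  expect_identical(attr(sig, "fc_threshold"), 1.5)
  expect_identical(attr(sig, "p_threshold"), 0.05)
  expect_error(extract_signature(p, "P", "P"), "differ")

  down <- extract_signature(p, "DCIS", "P", direction = "up")
  expect_length(down$gene_id, 0)  # no up-genes in the reversed contrast
})

test_that("anticorrelation filter keeps inverse profiles and drops parallel ones", {
  mir <- c(5, 4, 3, 2, 1)
  genes <- rbind(inv = 11 - 2 * mir,      # exact inverse (affine)
                 par = 3 * mir + 1,       # parallel
                 toy = c(1, 2, 2, 4, 5))  # the worked toy profile
  colnames(genes) <- c("P", "NeoT", "AT1", "DCIS", "Ca1d")
  res <- anticorrelation_filter(mir, genes, rownames(genes), q_threshold = 0.25)
  expect_equal(res$r[res$gene_id == "inv"], -1, tolerance = 1e-12)
  expect_true(res$retained[res$gene_id == "inv"])
  expect_equal(res$r[res$gene_id == "par"], 1, tolerance = 1e-12)
  expect_false(res$retained[res$gene_id == "par"])
  # product-moment arithmetic on the toy vectors: r = -10 / sqrt(10 * 10.8)
  expect_equal(res$r[res$gene_id == "toy"], -10 / sqrt(108), tolerance = 1e-12)
  expect_equal(res$q_value[res$gene_id == "toy"],
               p.adjust(res$p_value, "BH")[res$gene_id == "toy"])
})

test_that("zero-variance gene profiles are skipped with a warning", {
  genes <- rbind(flat = rep(4, 5), ok = 5:1)
  expect_warning(res <- anticorrelation_filter(1:5, genes, rownames(genes)),
                 "zero-variance")
  expect_true(is.na(res$r[res$gene_id == "flat"]))
  expect_false(res$retained[res$gene_id == "flat"])
})

test_that("hypergeometric upper tail matches enumeration and phyper", {
  hyper <- progressionscope:::hyper_upper_tail
  # worked example: N=10, K=3, n=4, k=2 -> (63 + 7) / 210 = 1/3
  expect_equal(hyper(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hyper(0, 3, 4, 10), 1)
  # random spot-checks against the reference distribution function
  set.seed(9)
  for (i in 1:50) {
    N <- sample(5:200, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyper(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("enrichment table respects its count identities and conventions", {
  universe <- sprintf("g%02d", 1:20)
  sig <- universe[1:8]
  pred <- data.frame(
    mirna_id = rep(c("mirA", "mirB", "mirC"), times = c(6, 5, 2)),
    gene_id = c(universe[c(1:5, 9)],       # mirA: 5 of 6 targets in signature
                universe[c(10, 12, 14, 16, 18)],  # mirB: none in signature
                c("offuniverse1", "offuniverse2")))  # mirC: no in-universe targets
  res <- fisher_enrichment(sig, pred, universe)
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$n == 8 & res$N == 20))
  a <- res[res$mirna_id == "mirA", ]
  expect_identical(c(a$k, a$K), c(5L, 6L))
  expect_equal(res$p_value[res$mirna_id == "mirC"], 1)  # K = 0 convention
  expect_true(all(res$q_value >= res$p_value))
  expect_lt(a$q_value, res$q_value[res$mirna_id == "mirB"])
  # signature = universe makes every p exactly 1
  res_all <- fisher_enrichment(universe, pred, universe)
  expect_true(all(res_all$p_value == 1))
  expect_error(fisher_enrichment(sig, pred, character(0)), "empty")
  expect_error(fisher_enrichment(c(sig, "nope"), pred, universe), "subset")
})

test_that("enrichment is invariant under gene relabeling", {
  cfg <- small_config(seed = 31L)
  gen <- gen_progression_expression(cfg)
  pred <- gen_target_predictions(gen$truth, cfg)
  universe <- rownames(gen$mrna)
  sig <- universe[seq(1, 300, by = 3)]
  res <- fisher_enrichment(sig, pred, universe)
  relabel <- setNames(sprintf("X%03d", sample(seq_along(universe))), universe)
  pred2 <- transform(pred, gene_id = relabel[gene_id])
  res2 <- fisher_enrichment(unname(relabel[sig]), pred2, unname(relabel))
  expect_equal(res2[c("k", "K", "n", "N", "p_value", "q_value")],
               res[c("k", "K", "n", "N", "p_value", "q_value")])
})

test_that("BH adjustment reproduces step-up arithmetic and its properties", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
  }
})

test_that("candidate targets recover the planted regulator's genes", {
  cfg <- small_config(decoy_edge_rate = 0, noise_cv = 0.05,
                      n_true_edges_per_regulator = 12, seed = 17L)
  gen <- gen_progression_expression(cfg)
  pred <- gen_target_predictions(gen$truth, cfg)
  reg <- gen$truth$regulators[1]
  stages <- panel_stages(gen$mrna)
  sig <- extract_signature(gen$mrna, stages[1], stages[4])
  universe <- rownames(gen$mrna)
  enr <- fisher_enrichment(sig, pred, universe)
  anti <- anticorrelation_filter(stage_means(gen$mirna)[reg, ], gen$mrna,
                                 sig$gene_id)
  cand <- candidate_targets(reg, sig, pred, anti, enr)
  planted <- intersect(gen$truth$true_edges$gene_id, sig$gene_id)
  expect_setequal(cand$gene_id, planted)
  # ranked by descending fold-change magnitude
  expect_true(all(diff(abs(cand$log2fc)) <= 1e-12))

  # gate contract: a miRNA failing Q < q_threshold yields an empty list
  pred2 <- rbind(pred, data.frame(mirna_id = "mir-null",
                                  gene_id = setdiff(universe, sig$gene_id)[1]))
  enr2 <- fisher_enrichment(sig, pred2, universe)
  expect_gte(enr2$q_value[enr2$mirna_id == "mir-null"], 0.25)
  expect_identical(nrow(candidate_targets("mir-null", sig, pred2, anti, enr2)),
                   0L)
  expect_warning(
    none <- candidate_targets("mir-absent", sig, pred, anti, enr),
    "absent")
  expect_identical(nrow(none), 0L)
})
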