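test_that("quantile normalization equalizes sample distributions", {
  # identical value multisets are left unchanged
  m <- cbind(a = c(3, 1, 2), b = c(1, 2, 3))
  p <- make_panel(m, c("A", "B"))
  out <- quantile_normalize(p)
  expect_equal(unclass(out), unclass(p), ignore_attr = TRUE)

  # rank-mean arithmetic on the worked pair
  p2 <- make_panel(cbind(a = 1:3, b = 4:6), c("A", "B"))
  out2 <- quantile_normalize(p2)
  expect_equal(unname(out2[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out2[, 2]), c(2.5, 3.5, 4.5))

  # column means equal after normalization, rank order preserved
  set.seed(1)
  m3 <- matrix(rlnorm(200), ncol = 4)
  p3 <- make_panel(m3, c("A", "A", "B", "B"))
  out3 <- quantile_normalize(p3)
  expect_equal(diff(range(colMeans(out3))), 0, tolerance = 1e-12)
  for (j in 1:4) expect_equal(order(out3[, j]), order(m3[, j]))
})

test_that("transition t-statistics match the pooled-variance formula", {
  # earlier log2 {1,2,3}, later {4,5,6}: FC = 3, t = 3.674 (df 4), p ~ 0.021
  p <- two_stage_panel(c(1, 2, 3), c(4, 5, 6))
  st <- transition_stats(p)
  expect_equal(st$log2fc, 3)
  expect_equal(st$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(st$p_value, 0.02131164, tolerance = 1e-6)
  expect_identical(st$direction, "up")

  # symmetric null: identical replicate values -> FC 0, p 1, flat
  p0 <- two_stage_panel(c(1, 2, 3), c(1, 2, 3))
  st0 <- transition_stats(p0)
  expect_equal(st0$log2fc, 0)
  expect_equal(st0$p_value, 1)
  expect_identical(st0$direction, "flat")

  # a 1.6-fold change with p < 0.05 is called up at the (1.5, 0.05) gates
  dc <- progressionscope:::direction_call
  expect_identical(dc(log2(1.6), 0.03, 1.5, 0.05), "up")
  expect_identical(dc(log2(1.4), 0.03, 1.5, 0.05), "flat")
  expect_identical(dc(-log2(1.6), 0.03, 1.5, 0.05), "down")
})

test_that("p-values agree with the reference t-test on random small cases", {
  set.seed(42)
  for (i in 1:100) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = runif(1, -2, 2))
    p <- two_stage_panel(a, b)
    st <- transition_stats(p)
    ref <- t.test(b, a, var.equal = TRUE)  # log2 values are a and b by design
    expect_equal(st$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(st$log2fc, mean(b) - mean(a), tolerance = 1e-9)
  }
})

test_that("zero-variance conventions apply and are logged", {
  p <- two_stage_panel(c(2, 2, 2), c(2, 2, 2))
  expect_message(st <- transition_stats(p), "zero within-stage variance")
  expect_equal(st$p_value, 1)
  p2 <- two_stage_panel(c(2, 2, 2), c(4, 4, 4))
  st2 <- suppressMessages(transition_stats(p2))
  expect_equal(st2$p_value, 0)
  expect_identical(st2$direction, "up")
})

test_that("trajectory groups follow their definitions", {
  dirsets <- list(
    list(d = c("down", "down", "down", "down"), g = "G2", first = 1L),
    list(d = c("up", "up", "up", "up"), g = "G1", first = 1L),
    list(d = c("down", "flat", "flat", "flat"), g = "G4", first = 1L),
    list(d = c("up", "flat", "flat", "flat"), g = "G3", first = 1L),
    list(d = c("flat", "flat", "flat", "flat"), g = "none", first = NA_integer_),
    list(d = c("up", "flat", "down", "flat"), g = "none", first = 1L),
    list(d = c("flat", "flat", "down", "flat"), g = "none", first = 3L),
    list(d = c("up", "up", "up", "flat"), g = "none", first = 1L))
  stats <- do.call(rbind, lapply(seq_along(dirsets), function(i)
    data.frame(feature_id = sprintf("f%02d", i), transition = 1:4,
               from_stage = c("P", "NeoT", "AT1", "DCIS"),
               to_stage = c("NeoT", "AT1", "DCIS", "Ca1d"),
               log2fc = 0, p_value = 1, direction = dirsets[[i]]$d)))
  attr(stats, "stages") <- c("P", "NeoT", "AT1", "DCIS", "Ca1d")
  class(stats) <- c("transition_stats", "data.frame")
  calls <- classify_trajectory(stats)
  expect_identical(calls$group, vapply(dirsets, `[[`, "", "g"))
  expect_identical(calls$first_altered_transition,
                   vapply(dirsets, `[[`, NA_integer_, "first"))
  # partition: exactly one label per feature
  expect_identical(nrow(calls), length(dirsets))
})

test_that("stats and calls are invariant to scaling and replicate order", {
  cfg <- small_config(seed = 21L)
  gen <- gen_progression_expression(cfg)
  st <- transition_stats(gen$mirna)
  calls <- classify_trajectory(st)

  scaled <- expression_panel(unclass(gen$mirna) * 7.3,
                             as.character(panel_design(gen$mirna)$stage),
                             panel_stages(gen$mirna))
  st_s <- transition_stats(scaled)
  expect_equal(st_s$log2fc, st$log2fc, tolerance = 1e-9)
  expect_equal(st_s$p_value, st$p_value, tolerance = 1e-9)
  expect_identical(classify_trajectory(st_s)$group, calls$group)

  d <- panel_design(gen$mirna)
  perm <- unlist(lapply(split(d$sample_id, d$stage), sample))
  shuf <- expression_panel(unclass(gen$mirna)[, perm],
                           sub("_rep[0-9]+$", "", perm),
                           panel_stages(gen$mirna))
  st_p <- transition_stats(shuf)
  expect_equal(st_p$log2fc, st$log2fc, tolerance = 1e-12)
  expect_equal(st_p$p_value, st$p_value, tolerance = 1e-12)
})

test_that("preneoplastic census counts first alterations in the early window", {
  calls <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                      group = c("G2", "G4", "none", "none", "none"),
                      first_altered_transition = c(1L, 1L, 1L, 3L, NA_integer_))
  cen <- preneoplastic_census(calls, 1:2)
  expect_identical(cen$n_early, 3L)
  expect_identical(cen$n_altered, 4L)
  expect_equal(cen$fraction, 0.75)
  empty <- preneoplastic_census(calls[0, ], 1:2)
  expect_equal(unlist(empty), c(n_early = 0, n_altered = 0, fraction = 0))
  none <- preneoplastic_census(
    data.frame(feature_id = "a", group = "none",
               first_altered_transition = NA_integer_))
  expect_equal(none$fraction, 0)
})

test_that("census fraction tracks a planted early/late mixture", {
  # plant 60 features stepping down at transition 1 and 40 at transition 3
  set.seed(7)
  n_early <- 60; n_late <- 40
  base <- 2 ^ runif(n_early + n_late, 5, 9)
  means <- rbind(
    t(sapply(base[1:n_early], function(b) b * c(1, .25, .25, .25, .25))),
    t(sapply(base[-(1:n_early)], function(b) b * c(1, 1, 1, .25, .25))))
  vals <- means[, rep(1:5, each = 3)] *
    matrix(exp(rnorm(100 * 15, 0, 0.1)), 100)
  p <- make_panel(vals, rep(c("P", "NeoT", "AT1", "DCIS", "Ca1d"), each = 3))
  cen <- preneoplastic_census(classify_trajectory(transition_stats(p)), 1:2)
  expect_equal(cen$fraction, 0.6, tolerance = 0.1)
})
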