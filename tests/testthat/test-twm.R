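test_that("pairwise aggregation sums adjacent contrasts", {
  expect_equal(aggregate_logfc(c(0.5, 0.7, -0.2)), c(1.2, 0.5))
  expect_equal(aggregate_logfc(c(0, 0, 0, 0)), c(0, 0, 0))
  expect_equal(aggregate_or(c(1, 3, 2)), c(4, 5))
  expect_equal(aggregate_or(rep(1, 4)), rep(2, 3))
  set.seed(1)
  x <- rnorm(6)
  expect_equal(aggregate_logfc(x), x[-6] + x[-1])
  expect_error(aggregate_logfc(1))
})

test_that("the contrast odds ratio matches the 2x2 closed form", {
  u <- paste0("g", 1:100)
  de <- setNames(rep(0, 100), u)
  de[c(paste0("g", 1:8), paste0("g", 11:30))] <- 1  # a=8, c=20
  targets <- paste0("g", c(1:8, 99, 100))           # b=2, d=70
  expect_equal(contrast_odds_ratio(targets, de), 14)
})

test_that("a zero cell triggers the continuity correction, keeping OR finite", {
  u <- paste0("g", 1:100)
  de <- setNames(rep(0, 100), u)
  de[paste0("g", 11:30)] <- 1               # a = 0 among targets g1..g10
  or <- contrast_odds_ratio(paste0("g", 1:10), de)
  expect_true(is.finite(or) && or > 0)
  expect_equal(or, (0.5 * 70.5) / (10.5 * 20.5))
})

test_that("odds ratio is ~1 when DE is independent of targets", {
  set.seed(33)
  u <- paste0("g", 1:500)
  ors <- replicate(1000, {
    de <- setNames(rbinom(500, 1, 0.3), u)
    contrast_odds_ratio(sample(u, 50), de)
  })
  expect_true(median(ors) > 0.8 && median(ors) < 1.25)
})

test_that("gene coherence is the strict positivity of the four-sign product", {
  expect_equal(gene_coherence(c(1, 1), c(1, 1)), 1)
  expect_equal(gene_coherence(c(-1, -1), c(1, 1)), 1)
  expect_equal(gene_coherence(c(1, -1), c(1, 1)), 0)
  expect_equal(gene_coherence(c(1, 0), c(1, 1)), 0)
  expect_equal(gene_coherence(c(1, 1), c(0, 1)), 0)
})

# A hand-built instance with known per-contrast odds ratios (1, 3, 2),
# TF fold changes (0.5, 0.7, -0.2) and pair coherences (0.75, 1):
#   aggregated logFC (1.2, 0.5), aggregated OR (4, 5),
#   comb = 1.2*4 + 0.5*5 = 7.3, coh = 0.75, twm = 5.475.
hand_instance <- function() {
  genes <- c(sprintf("g%03d", 1:99), "TF")
  lf <- matrix(0.1, 100, 3, dimnames = list(genes, NULL))
  lf["TF", ] <- c(0.5, 0.7, -0.2)
  # target signs over the 3 contrasts (only eligibility + signs matter)
  lf["g001", ] <- c(1, 1, -1)
  lf["g002", ] <- c(-1, -1, 1)
  lf["g003", ] <- c(1, -1, 1)
  lf["g004", ] <- c(-1, -1, 1)
  lf["g005", ] <- c(0.1, 1, -1)
  de <- matrix(0, 100, 3, dimnames = dimnames(lf))
  de[sprintf("g%03d", 1:4), 1] <- 1        # a1 = 4
  de[sprintf("g%03d", 11:46), 1] <- 1      # c1 = 36 -> OR1 = 1
  de[sprintf("g%03d", 1:6), 2] <- 1        # a2 = 6
  de[sprintf("g%03d", 11:40), 2] <- 1      # c2 = 30 -> OR2 = 3
  de[sprintf("g%03d", 1:5), 3] <- 1        # a3 = 5
  de[sprintf("g%03d", 11:40), 3] <- 1      # c3 = 30 -> OR3 = 2
  targets <- sprintf("g%03d", 1:10)
  list(lf = lf, de = de, targets = targets, genes = genes)
}

fit_hand <- function(...) {
  h <- hand_instance()
  vals <- cbind(5, 5 + h$lf %*% (outer(1:3, 1:3, "<=") * 1))
  rownames(vals) <- h$genes
  expr <- expression_ts(vals, sample_time = c(0, 6, 12, 24),
                        check_scale = FALSE)
  graph <- binding_graph(data.frame(tf = "TF", gene = h$targets))
  twm(expr, graph, de = h$de, ...)
}

test_that("the score decomposes as hand-computed on a known instance", {
  fit <- fit_hand()
  expect_equal(unname(fit$pair_logfc[1, ]), c(1.2, 0.5))
  expect_equal(unname(fit$pair_or[1, ]), c(4, 5))
  expect_equal(unname(fit$pair_coh[1, ]), c(0.75, 1))
  expect_equal(unname(fit$n_eligible[1, ]), c(4L, 5L))
  expect_equal(fit$results$comb, 7.3)
  expect_equal(fit$results$coh, 0.75)
  expect_equal(fit$results$twm, 5.475)
})

test_that("twm = comb * coh and collapses to zero with an incoherent pair", {
  fit <- fit_hand()
  expect_equal(fit$results$twm, fit$results$comb * fit$results$coh,
               tolerance = 1e-12)
  # zero out every eligible target's coherence in pair 1
  h <- hand_instance()
  h$lf[sprintf("g%03d", c(1, 2, 4)), 1:2] <- rep(c(1, -1), each = 3)
  vals <- cbind(5, 5 + h$lf %*% (outer(1:3, 1:3, "<=") * 1))
  rownames(vals) <- h$genes
  expr <- expression_ts(vals, c(0, 6, 12, 24), check_scale = FALSE)
  graph <- binding_graph(data.frame(tf = "TF", gene = h$targets))
  fit0 <- twm(expr, graph, de = h$de)
  expect_equal(unname(fit0$pair_coh[1, 1]), 0)
  expect_equal(fit0$results$twm, 0)
})

test_that("pair_coherence averages eligible targets and flags undefined", {
  h <- hand_instance()
  vals <- cbind(5, 5 + h$lf %*% (outer(1:3, 1:3, "<=") * 1))
  rownames(vals) <- h$genes
  expr <- expression_ts(vals, c(0, 6, 12, 24), check_scale = FALSE)
  cs <- set_de(compute_contrasts(expr), h$de)
  graph <- binding_graph(data.frame(tf = "TF", gene = h$targets))
  expect_equal(pair_coherence("TF", 1, graph, cs), 0.75)
  # no target DE in both contrasts of the pair -> undefined
  cs0 <- set_de(cs, matrix(0, 100, 3, dimnames = dimnames(h$de)))
  expect_true(is.na(pair_coherence("TF", 1, graph, cs0)))
})

test_that("a perfectly coherent planted driver saturates coherence", {
  sim <- simulate_bulk(sim_config(n_genes = 200, n_tfs = 2,
                                  targets_per_tf = 30, p_coh = 1,
                                  noise_sd = 1e-9, seed = 21))
  fit <- twm(sim$expr, sim$graph, de = sim$truth$de)
  drv <- fit$results[fit$results$tf == "TF01", ]
  expect_equal(drv$coh, 1)
  expect_equal(drv$twm, drv$comb)
})

test_that("ranking is deterministic: ties by coherence then id, order-invariant", {
  res <- data.frame(tf = c("B", "A", "C", "D"),
                    coh = c(0.5, 0.9, 1.0, 0.5),
                    twm = c(2.0, 2.0, 1.0, 2.0))
  r <- rank_tfs(res)
  expect_equal(r$tf, c("A", "B", "D", "C"))
  r2 <- rank_tfs(res[c(3, 1, 4, 2), ])
  expect_equal(r2$tf, r$tf)
  expect_equal(rank_tfs(res[2, , drop = FALSE])$tf, "A")
})

test_that("modular pipeline equals the literal one-function oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    cs <- contrast_series(inst$logfc, de = inst$de)
    graph <- instance_graph(inst)
    fit_s <- twm(cs, graph, signed = TRUE)
    fit_a <- twm(cs, graph)
    for (tf in inst$tfs) {
      oracle <- oracle_twm_one(tf, inst$logfc, inst$de, inst$targets[[tf]],
                               signed = TRUE)
      oracle_abs <- oracle_twm_one(tf, inst$logfc, inst$de,
                                   inst$targets[[tf]], signed = FALSE)
      expect_lt(abs(fit_s$results$twm[fit_s$results$tf == tf] - oracle$twm),
                1e-12)
      expect_lt(abs(fit_a$results$twm[fit_a$results$tf == tf] -
                      oracle_abs$twm), 1e-12)
    }
  }
})

test_that("permutation null is seeded and reproducible", {
  sim <- simulate_bulk(sim_config(n_genes = 300, n_tfs = 3,
                                  targets_per_tf = 30, seed = 5))
  fit <- twm(sim$expr, sim$graph, de = sim$truth$de)
  a <- twm_null(fit, "TF01", n_perm = 100, seed = 42)
  b <- twm_null(fit, "TF01", n_perm = 100, seed = 42)
  expect_identical(a$null, b$null)
  expect_identical(a$percentile, b$percentile)
  expect_gte(a$percentile, 0.95)  # planted driver
})

test_that("monotonicity: inflating the TF fold change never lowers the score", {
  h <- hand_instance()
  base <- fit_hand()
  h$lf["TF", ] <- h$lf["TF", ] * 3  # same signs, larger |aggregated logFC|
  vals <- cbind(5, 5 + h$lf %*% (outer(1:3, 1:3, "<=") * 1))
  rownames(vals) <- h$genes
  expr <- expression_ts(vals, c(0, 6, 12, 24), check_scale = FALSE)
  graph <- binding_graph(data.frame(tf = "TF", gene = h$targets))
  up <- twm(expr, graph, de = h$de)
  expect_gte(up$results$twm, base$results$twm)
})

test_that("fit methods expose coefficients, summary and plot", {
  fit <- fit_hand()
  expect_equal(unname(coef(fit)), fit$results$twm)
  expect_s3_class(summary(fit), "summary.twm")
  expect_output(print(fit), "Transition weight")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_identical(as.data.frame(fit), fit$results)
})
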