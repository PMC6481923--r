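test_that("tertile grouping splits 1..9 into 3/3/3 after the zero filter", {
  g <- quantile_group(1:9)
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_equal(as.character(g[c(1, 5, 9)]), c("low", "mid", "high"))
})

test_that("an all-zero gene is an error", {
  expect_error(quantile_group(rep(0, 20)), "positive")
})

test_that("zeros are excluded, not grouped", {
  g <- quantile_group(c(0, 0, 1:9))
  expect_true(all(is.na(g[1:2])))
  expect_equal(sum(!is.na(g)), 9)
})

test_that("tied values at a cut are assigned deterministically, matching ranks", {
  v <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  g <- quantile_group(v)
  # rank-based oracle: equal values must share a group
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_true(all(tapply(as.integer(g), v, function(x) length(unique(x))) == 1))
  # repeated evaluation is identical
  expect_identical(g, quantile_group(v))
})

test_that("a gene identical to the TF is strongly associated", {
  set.seed(1)
  tfv <- rexp(90) + 0.1
  grp <- quantile_group(tfv)
  out <- gene_association(grp, tfv)
  expect_true(out$significant)
  # simulated p floors at 1/(B+1): demand the floor-level significance
  expect_lt(out$p_value, 1e-4)
})

test_that("the 2x2 collapsed variant reproduces the hypergeometric Fisher p", {
  set.seed(2)
  tfv <- rexp(60) + 0.1
  gv <- rexp(60) + 0.1
  pooled <- pooled_variants(quantile_group(tfv))
  out <- gene_association(pooled$low_mid, gv)
  # closed-form oracle on the same table
  expect_equal(out$p_value, fisher.test(out$table)$p.value, tolerance = 1e-12)
  expect_equal(out$method, "exact")
})

test_that("a degenerate margin gives p = 1 with a warning", {
  grp <- factor(rep("low", 30), levels = c("low", "mid", "high"))
  expect_warning(out <- gene_association(grp, rexp(30) + 0.1), "degenerate")
  expect_equal(out$p_value, 1)
})

test_that("simulated p-values are used above the exact size bound and are seeded", {
  set.seed(3)
  tfv <- rexp(300) + 0.1
  gv <- rexp(300) + 0.1
  grp <- quantile_group(tfv)
  a <- gene_association(grp, gv, B = 2000, seed = 7)
  b <- gene_association(grp, gv, B = 2000, seed = 7)
  expect_equal(a$method, "simulated")
  expect_identical(a$p_value, b$p_value)
})

test_that("pooled variants relabel a 9-cell toy correctly", {
  g <- quantile_group(1:9)
  pv <- pooled_variants(g)
  expect_equal(as.vector(table(pv$low_mid)), c(6, 3))
  expect_equal(as.vector(table(pv$mid_high)), c(3, 6))
  expect_true(all((pv$low_mid == "high") == (g == "high")))
  expect_true(all((pv$mid_high == "low") == (g == "low")))
})

test_that("target enrichment matches the 2x2 closed form and flags degeneracy", {
  u <- paste0("g", 1:100)
  sig <- u[1:20]                       # a=10, c=10
  targets <- u[c(1:10, 21:30)]         # b=10, d=70
  out <- target_enrichment(sig, targets, u)
  expect_equal(out$or, 7)
  expect_false(out$corrected)
  # targets identical to significant set: zero cells -> corrected, finite
  out2 <- target_enrichment(sig, sig, u)
  expect_true(out2$corrected && is.finite(out2$or) && out2$or > 1)
  expect_error(target_enrichment(sig, character(), u), "empty")
})

test_that("random significant sets give odds ratios near 1", {
  set.seed(4)
  u <- paste0("g", 1:400)
  targets <- u[1:60]
  ors <- replicate(500, target_enrichment(sample(u, 80), targets, u)$or)
  expect_true(median(ors) > 0.8 && median(ors) < 1.25)
})

test_that("variance partition recovers pure time and pure TF dependence", {
  set.seed(5)
  time <- rep(1:6, each = 10)
  lev <- factor(sample(paste0("q", 1:6), 60, TRUE))
  y_time <- 2 + 0.5 * time + 0.1  # deterministic in time
  out <- suppressWarnings(variance_partition(y_time, time, lev))
  expect_equal(out$r2_time, 1, tolerance = 1e-12)
  expect_lt(out$increment, 1e-12)
  y_lev <- 1 + as.integer(lev) * 0.7
  out2 <- suppressWarnings(variance_partition(y_lev, time, lev))
  expect_equal(out2$r2_tf, 1, tolerance = 1e-12)
})

test_that("r2 values match a brute-force sum-of-squares decomposition", {
  set.seed(6)
  time <- rep(1:6, each = 12)
  lev <- factor(sample(paste0("q", 1:6), 72, TRUE))
  y <- 1 + 0.3 * time + 0.5 * as.integer(lev) + rnorm(72, 0, 0.5) + 3
  out <- variance_partition(y, time, lev)
  # oracle: projection onto the factor design via group means / explicit lsfit
  keep <- y > 0
  r2_oracle <- function(X, yy) {
    fit <- qr.fitted(qr(X), yy)
    1 - sum((yy - fit)^2) / sum((yy - mean(yy))^2)
  }
  Xt <- model.matrix(~ factor(time[keep]))
  Xl <- model.matrix(~ lev[keep])
  Xj <- model.matrix(~ factor(time[keep]) + lev[keep])
  expect_lt(abs(out$r2_time - r2_oracle(Xt, y[keep])), 1e-10)
  expect_lt(abs(out$r2_tf - r2_oracle(Xl, y[keep])), 1e-10)
  expect_lt(abs(out$r2_joint - r2_oracle(Xj, y[keep])), 1e-10)
  expect_gte(out$r2_joint, max(out$r2_time, out$r2_tf) - 1e-12)
  expect_true(all(unlist(out[c("r2_time", "r2_tf", "r2_joint")]) >= 0 &
                    unlist(out[c("r2_time", "r2_tf", "r2_joint")]) <= 1))
})

test_that("association p-values are invariant to permuting cell order", {
  set.seed(7)
  tfv <- rexp(90) + 0.1
  gv <- rexp(90) + 0.1
  p1 <- gene_association(quantile_group(tfv), gv, B = 2000, seed = 3)$p_value
  o <- sample(90)
  p2 <- gene_association(quantile_group(tfv[o]), gv[o], B = 2000, seed = 3)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the full single-cell workflow flags planted targets as enriched", {
  sim <- simulate_cells(sim_config(n_genes = 60, targets_per_tf = 20,
                                   cells_per_time = 30, sc_effect = 2,
                                   dropout = 0.2, seed = 13))
  res <- sc_coherence(cbind(sim$sc), "TF01", sim$targets, B = 2000)
  expect_true(res$enrichment$or > 1)
  expect_lt(res$enrichment$p, 0.05)
})
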