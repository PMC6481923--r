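make_expr <- function(means, n_rep = 2, noise = 0, seed = 1) {
  # means: genes x time points matrix of population means
  set.seed(seed)
  A <- ncol(means)
  v <- means[, rep(seq_len(A), each = n_rep), drop = FALSE] +
    rnorm(nrow(means) * A * n_rep, 0, noise)
  rownames(v) <- rownames(means)
  expression_ts(v, sample_time = rep(seq_len(A), each = n_rep),
                check_scale = FALSE)
}

test_that("contrasts are differences of replicate means at adjacent times", {
  m <- rbind(g1 = c(2, 3, 3.5), g2 = c(1, 1, 1))
  cs <- compute_contrasts(make_expr(m))
  expect_equal(unname(cs$logfc["g1", ]), c(1.0, 0.5))
  expect_equal(unname(cs$logfc["g2", ]), c(0, 0))
  expect_equal(length(cs$pairs), 1)
})

test_that("contrasts are invariant to adding a constant to all values", {
  m <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  cs1 <- compute_contrasts(make_expr(m))
  cs2 <- compute_contrasts(make_expr(m + 7))
  expect_equal(cs1$logfc, cs2$logfc)
})

test_that("estimated contrasts stay within 3 SEM of truth for >=99% of genes", {
  set.seed(5)
  n <- 2000
  truth <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("g", 1:n), NULL))
  sd <- 0.5; n_rep <- 6
  cs <- compute_contrasts(make_expr(truth, n_rep = n_rep, noise = sd, seed = 6))
  sem <- sd * sqrt(2 / n_rep)
  err <- abs(cs$logfc - (truth[, -1] - truth[, -4]))
  expect_gte(mean(err <= 3 * sem), 0.99)
})

test_that("identical replicate groups give p = 1 and de = 0", {
  m <- rbind(g1 = c(4, 4, 4))
  v <- m[, rep(1:3, each = 3), drop = FALSE]
  rownames(v) <- "g1"
  expr <- expression_ts(v, rep(1:3, each = 3), check_scale = FALSE)
  cs <- fallback_de_test(expr)
  expect_equal(unname(cs$p["g1", ]), c(1, 1))
  expect_equal(unname(cs$de["g1", ]), c(0, 0))
})

test_that("a single replicate is an error pointing to external statistics", {
  m <- matrix(1:3, 1, 3, dimnames = list("g1", NULL))
  expr <- expression_ts(m, 1:3, check_scale = FALSE)
  expect_error(fallback_de_test(expr), "external")
})

test_that("a planted 2-logFC shift at n=4, sd=0.25 is detected for >=95% of genes", {
  set.seed(7)
  n <- 400
  truth <- cbind(rep(0, n), rep(2, n), rep(2, n))
  rownames(truth) <- paste0("g", 1:n)
  cs <- fallback_de_test(make_expr(truth, n_rep = 4, noise = 0.25, seed = 8),
                         alpha = 0.05)
  expect_gte(mean(cs$de[, 1] == 1), 0.95)
})

test_that("the consensus rule reproduces its three clauses on a threshold grid", {
  fdr_grid <- c(0, 0.0005, 0.001, 0.0015, 0.005, 0.01, 0.02, 0.5, 1)
  r2_grid <- c(0, 0.3, 0.60, 0.61, 0.75, 0.90, 0.91, 1, NA)
  g <- expand.grid(fdr = fdr_grid, r2 = r2_grid)
  got <- consensus_de(g$fdr, g$r2)
  want <- with(g, (fdr < 0.001) |
                 (!is.na(r2) & r2 > 0.90) |
                 (fdr < 0.01 & !is.na(r2) & r2 > 0.60))
  expect_identical(got, want)
  # the printed examples
  expect_true(consensus_de(0.0005, 0.1))
  expect_true(consensus_de(0.005, 0.65))
  expect_false(consensus_de(0.005, 0.50))
})

test_that("consensus rule rejects out-of-range inputs", {
  expect_error(consensus_de(-0.1, 0.5))
  expect_error(consensus_de(0.5, 1.2))
})

test_that("trend labels follow the sign-change rule", {
  expect_equal(trend_label(c(2, 0.1)), "up")
  expect_equal(trend_label(c(-2, -0.1)), "down")
  expect_equal(trend_label(c(1, -1.2)), "up-down")
  expect_equal(trend_label(c(-1, 1.2)), "down-up")
  expect_equal(trend_label(c(1, -1, 1)), "complex")
  expect_equal(trend_label(c(0, 0)), "flat")
  # dead zone suppresses a small wobble
  expect_equal(trend_label(c(1, -0.05, 1), epsilon = 0.1), "up")
})

test_that("candidate selection applies threshold, in-vivo and trend rescue", {
  m <- rbind(tfA = c(0, 2.0, 2.1),    # logfc (+2.0, +0.1): threshold
             tfB = c(0, 1.0, -0.2),   # (+1.0, -1.2): nonmonotonic rescue
             tfC = c(0, 0.2, 0.4),    # (+0.2, +0.2): nothing
             tfD = c(0, 0.3, 0.6))    # rescued in vivo
  cs <- compute_contrasts(make_expr(m))
  iv <- data.frame(gene = "tfD", logfc = 2, adj_p = 1e-5)
  out <- select_candidate_tfs(cs, rownames(m), in_vivo = iv)
  expect_equal(out$candidate, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$trend[1:2], c("up", "up-down"))
  expect_match(out$criteria[4], "in_vivo")
})
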