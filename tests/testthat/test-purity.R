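test_that("the cosine purity transform evaluates, decreases, and flags the boundary", {
  expect_equal(estimate_purity(0), cos(0.6049872018), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(estimate_purity(0) - 0.8225), 1e-4)

  scores <- seq(-2000, 6000, by = 500)
  p <- as.numeric(estimate_purity(scores))
  expect_true(all(diff(p) < 0))

  # drive the argument to pi/2: purity clamps to eps and the sample is flagged
  big <- (pi / 2 - 0.6049872018) / 0.0001467884 + 100
  expect_warning(pb <- estimate_purity(big), "outside")
  expect_true(attr(pb, "flagged"))
  expect_gt(as.numeric(pb), 0)
})

test_that("ESTIMATE scores are the enrichment statistic on the two sets, summed", {
  co <- cohort500()
  sub <- co$expr[, 1:25]
  attr(sub, "scale_tag") <- "linear"
  est <- estimate_scores(sub, co$gene_sets$ESTIMATE_STROMAL,
                         co$gene_sets$ESTIMATE_IMMUNE)
  expect_lt(max(abs(est$estimate_score - (est$stromal_score + est$immune_score))),
            1e-12)
  es <- enrich_all(sub, gene_set_collection(
    list(stromal = co$gene_sets$ESTIMATE_STROMAL,
         immune = co$gene_sets$ESTIMATE_IMMUNE)))
  for (j in colnames(sub)[1:5]) {
    expect_equal(est$stromal_score[est$sample_id == j],
                 es$es[es$set_name == "stromal" & es$sample_id == j])
  }

  # two identical samples give identical score triples
  dup <- cbind(sub[, 1, drop = FALSE], sub[, 1, drop = FALSE])
  colnames(dup) <- c("c1", "c2")
  dup <- expression_matrix(dup, "linear")
  est2 <- estimate_scores(dup, co$gene_sets$ESTIMATE_STROMAL,
                          co$gene_sets$ESTIMATE_IMMUNE)
  expect_equal(est2[1, -1], est2[2, -1], ignore_attr = TRUE)
})

test_that("stromal and immune scores recover the true compartment fractions", {
  co <- cohort500()
  est <- estimate_scores(co$expr, co$gene_sets$ESTIMATE_STROMAL,
                         co$gene_sets$ESTIMATE_IMMUNE)
  rho_s <- stats::cor(est$stromal_score, co$truth$stromal_fraction,
                      method = "spearman")
  rho_i <- stats::cor(est$immune_score, co$truth$immune_fraction,
                      method = "spearman")
  expect_gt(rho_s, 0.7)
  expect_gt(rho_i, 0.7)
  # purity estimate tracks true purity
  p_est <- as.numeric(estimate_purity(est$estimate_score))
  expect_gt(stats::cor(p_est, co$truth$purity, method = "spearman"), 0.7)
})

test_that("purity residualization reproduces the exact-fit, orthogonal and closed-form cases", {
  set.seed(9)
  n <- 50
  purity <- stats::runif(n, 0.3, 0.95)
  x <- log(1 - purity)

  exact <- 1.5 + 0.8 * x
  adj <- adjust_for_purity(exact, purity)
  expect_lt(max(abs(adj$score_adjusted)), 1e-10)
  reg <- attr(adj, "regression")
  expect_equal(unname(reg["intercept"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(reg["slope"]), 0.8, tolerance = 1e-9)

  # a score exactly orthogonal to the regressor: slope 0, residual = centered score
  orth <- stats::residuals(stats::lm(stats::rnorm(n) ~ x)) + 5
  adj2 <- adjust_for_purity(orth, purity)
  expect_lt(abs(attr(adj2, "regression")["slope"]), 1e-10)
  expect_lt(max(abs(adj2$score_adjusted - (orth - mean(orth)))), 1e-8)

  y <- 2 + 0.5 * x + stats::rnorm(n, 0, 0.2)
  adj3 <- adjust_for_purity(y, purity)
  cf <- ols_closed_form(y, x)
  reg3 <- attr(adj3, "regression")
  expect_equal(unname(reg3["intercept"]), unname(cf["intercept"]), tolerance = 1e-10)
  expect_equal(unname(reg3["slope"]), unname(cf["slope"]), tolerance = 1e-10)
  expect_lt(max(abs(adj3$score_adjusted - (y - cf["intercept"] - cf["slope"] * x))),
            1e-10)
})

test_that("residuals are orthogonal to the regressor, sum to zero, and adjustment is idempotent", {
  sc <- scores500()
  co <- cohort500()
  for (adj in list(sc$ita_adj, sc$emt_adj)) {
    expect_lt(abs(sum(adj$score_adjusted)), 1e-9 * nrow(adj))
    x <- log(1 - co$truth$purity)
    expect_lt(abs(stats::cor(adj$score_adjusted, x)), 1e-10)

    again <- adjust_for_purity(adj$score_adjusted, co$truth$purity)
    expect_lt(max(abs(again$score_adjusted - adj$score_adjusted)), 1e-9)
  }
})

test_that("purity-1 samples are excluded from the fit but retained flagged; constant purity errors", {
  set.seed(11)
  n <- 20
  purity <- c(stats::runif(n - 2, 0.4, 0.9), 1, 1)
  y <- stats::rnorm(n)
  expect_warning(adj <- adjust_for_purity(y, purity), "purity = 1")
  expect_equal(sum(adj$excluded_from_fit), 2)
  reg <- attr(adj, "regression")
  expect_equal(adj$score_adjusted[n], y[n] - unname(reg["intercept"]))

  expect_error(adjust_for_purity(y, rep(0.5, n)), "degenerate")
})

test_that("score-purity correlations report the built-in negative dependence and OLS orthogonality", {
  sc <- scores500()
  co <- cohort500()
  raw <- score_purity_correlation(sc$ita, co$truth$purity)
  expect_lt(raw$r, 0)
  expect_lt(raw$p, 0.05)
  raw_emt <- score_purity_correlation(sc$emt, co$truth$purity)
  expect_lt(raw_emt$r, 0)

  adj <- score_purity_correlation(sc$ita_adj, co$truth$purity, on = "log1m_purity")
  expect_lt(abs(adj$r), 1e-10)

  # affine invariance of r
  shifted <- sc$ita
  shifted$score <- 3 * shifted$score - 7
  expect_equal(score_purity_correlation(shifted, co$truth$purity)$r, raw$r,
               tolerance = 1e-12)

  flat <- rep(2, nrow(co$truth))
  expect_true(score_purity_correlation(flat, co$truth$purity)$degenerate)
})

test_that("adjustment raises the EMT-ITA correlation under the built-in negative confounding", {
  s <- summarize_truth(cohort500())
  expect_lt(s$cor_emt_ita_raw, s$cor_emt_ita_adjusted)
})
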