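test_that("the Cox coefficient matches a score-equation bisection on a small instance", {
  # 6 subjects, binary covariate, no ties
  d <- tibble::tibble(
    sample_id = paste0("P", 1:6),
    os_time = c(3, 5, 7, 11, 13, 17),
    os_event = c(1L, 1L, 0L, 1L, 1L, 1L),
    x = c(1, 0, 1, 1, 0, 0))
  fit <- fit_cox(d, "x")
  beta_oracle <- cox_bisection_beta(d$os_time, d$os_event, d$x)
  expect_lt(abs(tidy(fit)$beta - beta_oracle), 1e-6)
})

test_that("Breslow fits are invariant to subject replication and covariate translation", {
  set.seed(19)
  d <- tiny_clin(40, seed = 19)
  d$x <- stats::rnorm(40)
  fit <- fit_cox(d, "x")
  b <- tidy(fit)$beta

  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, sample_id = paste0(sample_id, "b")))
  fit2 <- fit_cox(d2, "x")
  expect_lt(abs(tidy(fit2)$beta - b), 1e-6)

  d3 <- dplyr::mutate(d, x = x + 100)
  fit3 <- fit_cox(d3, "x")
  expect_lt(abs(tidy(fit3)$beta - b), 1e-8)
  expect_lt(abs(tidy(fit3)$se - tidy(fit)$se), 1e-8)
})

test_that("the Wald test is calibrated under the null", {
  set.seed(23)
  reps <- 500
  n <- 200
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    t_ev <- stats::rexp(n, 0.01)
    cens <- stats::runif(n, 0, 150)
    d <- tibble::tibble(sample_id = as.character(1:n),
                        os_time = pmin(t_ev, cens),
                        os_event = as.integer(t_ev <= cens),
                        x = stats::rnorm(n))
    rej[i] <- tidy(fit_cox(d, "x"))$wald_p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("degenerate survival inputs are rejected", {
  d <- tiny_clin(20)
  d$x <- stats::rnorm(20)
  d0 <- dplyr::mutate(d, os_event = 0L)
  expect_error(fit_cox(d0, "x"), "no events")
  dflat <- dplyr::mutate(d, x = 1)
  expect_error(fit_cox(dflat, "x"), "zero variance")
  expect_error(fit_cox(d, "missing_col"), "lacks")
})

test_that("IQR-scaled hazard ratios follow the stated arithmetic", {
  set.seed(31)
  d <- tiny_clin(60, seed = 31)
  d$x <- stats::rnorm(60)
  fit <- fit_cox(d, "x")
  beta <- stats::coef(fit$fit)[[1]]
  se <- sqrt(stats::vcov(fit$fit)[1, 1])
  hr <- hr_iqr(fit)
  delta <- unname(diff(stats::quantile(d$x, c(0.25, 0.75))))
  expect_equal(hr$hr, exp(beta * delta), tolerance = 1e-12)
  expect_equal(sort(c(hr$ci_low, hr$ci_high)),
               sort(exp((beta + c(-1, 1) * 1.959963985 * se) * delta)),
               tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$hr_iqr, hr$hr)
  expect_true(td$ci_low <= td$hr_iqr && td$hr_iqr <= td$ci_high)

  # beta = 0 gives hr 1; beta = ln 2 with unit IQR gives hr 2
  expect_equal(exp(0 * delta), 1)
  expect_equal(hr_iqr(fit, values = c(rep(0, 2), rep(1, 2)))$hr,
               exp(beta * 1), tolerance = 1e-12)
  expect_error(hr_iqr(fit, values = rep(1, 10)), "IQR is zero")
})

test_that("hr_iqr is invariant to affine rescaling of the score", {
  set.seed(37)
  d <- tiny_clin(80, seed = 37)
  d$x <- stats::rnorm(80)
  h1 <- hr_iqr(fit_cox(d, "x"))
  d$x <- 5 * d$x + 3
  h2 <- hr_iqr(fit_cox(d, "x"))
  expect_equal(h1$hr, h2$hr, tolerance = 1e-6)
  expect_equal(h1$ci_low, h2$ci_low, tolerance = 1e-6)
})

test_that("median splits put ties low and record the cutpoint", {
  s1 <- median_split(stats::setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5)))
  expect_identical(as.character(s1$group), c("low", "low", "low", "high", "high"))
  expect_equal(attr(s1, "cutpoint"), 3)

  s2 <- median_split(stats::setNames(c(1, 1, 2, 2), paste0("s", 1:4)))
  expect_equal(table(s2$group)[["low"]], 2)
  expect_equal(table(s2$group)[["high"]], 2)

  expect_error(median_split(rep(2, 5)), "identical")
})

test_that("median-split group sizes differ by at most the number of median ties", {
  set.seed(41)
  for (rep in 1:20) {
    vals <- sample(1:8, 30, replace = TRUE)  # heavy ties
    if (length(unique(vals)) < 2) next
    sp <- median_split(vals)
    med <- stats::median(vals)
    n_ties <- sum(vals == med)
    sizes <- table(sp$group)
    # ties all land low, so the imbalance is bounded by twice the tie count
    expect_lte(abs(sizes[["low"]] - sizes[["high"]]), 2 * n_ties + 1)
    # brute-force counting check
    expect_equal(sizes[["high"]], sum(vals > med))
    expect_equal(sizes[["low"]], sum(vals <= med))
  }
})

test_that("four_group crosses the two median splits with fixed levels", {
  set.seed(43)
  n <- 400
  ids <- sprintf("S%03d", 1:n)
  mk <- function(v) {
    s <- tibble::tibble(sample_id = ids, score = v)
    class(s) <- c("itaemt_score", class(tibble::tibble()))
    s
  }
  emt <- mk(stats::runif(n)); ita <- mk(stats::runif(n))
  g4 <- four_group(emt, ita)
  expect_identical(levels(g4$group),
                   c("lowEMT-lowITA", "lowEMT-highITA", "highEMT-lowITA",
                     "highEMT-highITA"))
  counts <- table(g4$group)
  expect_true(all(counts >= 70 & counts <= 130))

  # compositional identity with the two marginal splits
  se <- median_split(emt); si <- median_split(ita)
  rebuilt <- paste0(ifelse(se$group == "high", "highEMT", "lowEMT"), "-",
                    ifelse(si$group == "high", "highITA", "lowITA"))
  expect_identical(as.character(g4$group), rebuilt)

  # comonotone scores leave the discordant cells empty
  g4c <- four_group(emt, mk(emt$score * 2 + 1))
  expect_equal(as.vector(table(g4c$group)[c("lowEMT-highITA", "highEMT-lowITA")]),
               c(0L, 0L))
})

test_that("identical groups give a null log-rank and curves start at 1 non-increasing", {
  clin <- tiny_clin(40, seed = 47)
  # two groups that are exact copies of the same survival data
  clin2 <- dplyr::mutate(clin, sample_id = paste0(sample_id, "x"))
  both <- dplyr::bind_rows(clin, clin2)
  groups <- tibble::tibble(sample_id = both$sample_id,
                           group = factor(rep(c("a", "b"), each = 40)))
  km <- km_logrank(groups, both)
  expect_lt(km$chi2, 1e-10)
  expect_equal(km$p, 1, tolerance = 1e-8)
  for (g in c("a", "b")) {
    cv <- km$curves[km$curves$group == g, ]
    expect_equal(cv$surv[1], 1)
    expect_true(all(diff(cv$surv) <= 1e-12))
  }
})

test_that("the product-limit curve matches brute-force risk sets at n <= 50", {
  for (seed in c(51, 52)) {
    clin <- tiny_clin(50, seed = seed)
    groups <- tibble::tibble(sample_id = clin$sample_id,
                             group = factor(rep(c("g1", "g2"), 25)))
    km <- km_logrank(groups, clin)
    for (g in c("g1", "g2")) {
      sub <- clin[groups$group == g, ]
      oracle <- km_brute_force(sub$os_time, sub$os_event)
      got <- km$curves[km$curves$group == g & km$curves$n_event > 0, ]
      expect_equal(got$time, oracle$time)
      expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
    }
  }
})

test_that("the two-group log-rank statistic equals the Cox score test at beta 0", {
  for (seed in c(57, 58, 59)) {
    set.seed(seed)
    n <- 60
    t_ev <- stats::rexp(n, 0.01)        # continuous: no ties
    cens <- stats::runif(n, 0, 200)
    clin <- tibble::tibble(sample_id = as.character(1:n),
                           os_time = pmin(t_ev, cens),
                           os_event = as.integer(t_ev <= cens),
                           cohort = "x")
    grp <- factor(rep(c("a", "b"), n / 2))
    km <- km_logrank(tibble::tibble(sample_id = clin$sample_id, group = grp), clin)
    oracle <- cox_score_test_stat(clin$os_time, clin$os_event, grp)
    expect_lt(abs(km$chi2 - oracle), 1e-8)
  }
})

test_that("empty declared group levels are dropped with a warning", {
  clin <- tiny_clin(20, seed = 61)
  groups <- tibble::tibble(
    sample_id = clin$sample_id,
    group = factor(rep(c("a", "b"), 10), levels = c("a", "b", "ghost")))
  expect_warning(km <- km_logrank(groups, clin), "ghost")
  expect_equal(km$df, 1)
})

test_that("the per-gene screen finds planted effects, reports direction, and sorts by p", {
  set.seed(67)
  n <- 600
  n_genes <- 200
  ids <- sprintf("S%03d", 1:n)
  expr <- matrix(stats::rlnorm(n_genes * n, log(50), 1), n_genes,
                 dimnames = list(sprintf("G%03d", 1:n_genes), ids))
  causal <- rownames(expr)[1:5]
  z <- scale(t(log2(expr[causal, ] + 1)))
  lp <- 0.6 * rowSums(z) / sqrt(5)
  # gene 5 made protective to pin the direction rule
  lp <- lp - 2 * 0.6 * z[, 5] / sqrt(5)
  t_ev <- stats::rexp(n, 0.002 * exp(lp))
  cens <- stats::runif(n, 0, 1500)
  clin <- tibble::tibble(sample_id = ids, os_time = pmin(t_ev, cens),
                         os_event = as.integer(t_ev <= cens), cohort = "sim")
  ita <- mean_log_score(
    expression_matrix(matrix(stats::rlnorm(n, log(30), 0.5), 1, n,
                             dimnames = list("M1", ids)), "linear"), "M1")
  rk <- rank_emt_genes(expression_matrix(expr, "linear"), rownames(expr),
                       ita, clin)
  expect_identical(rk$wald_p, sort(rk$wald_p))
  expect_identical(rk$selected, rk$wald_p < 0.05)
  expect_identical(rk$direction, ifelse(rk$beta > 0, "risk", "favorable"))
  expect_gte(sum(rk$selected & rk$gene %in% causal), 4)
  expect_identical(rk$direction[rk$gene == "G005"], "favorable")
  null_rate <- mean(rk$selected[!rk$gene %in% causal])
  expect_lte(null_rate, 0.09)

  # zero-variance genes are skipped with a warning
  expr2 <- expr
  expr2["G010", ] <- 3
  expect_warning(
    rk2 <- rank_emt_genes(expression_matrix(expr2, "linear"),
                          c("G010", "G011"), ita, clin),
    "zero-variance")
  expect_identical(rk2$gene, "G011")
})

test_that("validation reports untestable genes and replicates planted effects", {
  expect_equal(nrow(validate_genes(character(0), tiny_expr(), tiny_clin(),
                                   NULL)), 0)

  set.seed(71)
  n <- 400
  ids <- sprintf("V%03d", 1:n)
  expr <- matrix(stats::rlnorm(3 * n, log(40), 1), 3,
                 dimnames = list(c("GA", "GB", "GC"), ids))
  zA <- as.numeric(scale(log2(expr["GA", ] + 1)))
  t_ev <- stats::rexp(n, 0.002 * exp(0.8 * zA))
  cens <- stats::runif(n, 0, 1500)
  clin <- tibble::tibble(sample_id = ids, os_time = pmin(t_ev, cens),
                         os_event = as.integer(t_ev <= cens), cohort = "v")
  ita <- mean_log_score(
    expression_matrix(matrix(stats::rlnorm(n, log(30), 0.5), 1, n,
                             dimnames = list("M1", ids)), "linear"), "M1")
  v <- validate_genes(c("GA", "GB", "ABSENT"), expression_matrix(expr, "linear"),
                      clin, ita)
  expect_identical(v$gene, c("GA", "GB", "ABSENT"))
  expect_true(v$validated[v$gene == "GA"])
  expect_identical(v$direction[v$gene == "GA"], "risk")
  expect_false(v$testable[v$gene == "ABSENT"])
  expect_false(v$validated[v$gene == "ABSENT"])
})
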