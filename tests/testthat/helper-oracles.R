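# independent oracles: deliberately naive implementations used only to
# cross-check the package's code paths

# ssGSEA running sum as an explicit element-by-element loop
ssgsea_loop_oracle <- function(expr_values, gene_set, alpha = 0.25) {
  n <- length(expr_values)
  r <- rank(expr_values, ties.method = "average")
  ord <- order(-expr_values, names(expr_values), method = "radix")
  in_set <- names(expr_values)[ord] %in% gene_set
  n_hit <- sum(in_set)
  w_sum <- 0
  for (i in seq_len(n)) if (in_set[i]) w_sum <- w_sum + r[ord][i]^alpha
  running <- 0
  total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      running <- running + r[ord][i]^alpha / w_sum
    } else {
      running <- running - 1 / (n - n_hit)
    }
    total <- total + running
  }
  unname(total)
}

# two-parameter OLS by the closed-form normal equations (sum formulas)
ols_closed_form <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Cox partial-likelihood score for a single covariate, Breslow ties
cox_score_fn <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    w <- exp(beta * x[at_risk])
    s <- s + x[i] - sum(w * x[at_risk]) / sum(w)
  }
  s
}

# solve the score equation by bisection
cox_bisection_beta <- function(time, event, x, lower = -20, upper = 20,
                               tol = 1e-9) {
  stats::uniroot(cox_score_fn, c(lower, upper), time = time, event = event,
                 x = x, tol = tol)$root
}

# product-limit estimator from explicit risk sets
km_brute_force <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t_k <- times[k]
    n_risk <- sum(time >= t_k)
    d_k <- sum(time == t_k & event == 1)
    s <- s * (1 - d_k / n_risk)
    surv[k] <- s
  }
  tibble::tibble(time = times, surv = surv)
}

# two-group Cox score test statistic at beta = 0 (no ties assumed):
# U^2 / I with U, I accumulated over risk sets for the group indicator
cox_score_test_stat <- function(time, event, grp) {
  x <- as.numeric(grp == levels(factor(grp))[2])
  u <- 0; info <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    p <- mean(x[at_risk])
    u <- u + x[i] - p
    info <- info + p * (1 - p)
  }
  u^2 / info
}

# brute-force marker selection: explicit row scan
select_markers_oracle <- function(sig, t_cell_labels, threshold = 2) {
  out <- character(0)
  for (g in rownames(sig)) {
    row <- sig[g, ]
    if (mean(row) == 0) next
    norm <- row / mean(row)
    if (mean(norm[t_cell_labels]) > threshold) out <- c(out, g)
  }
  out
}

# mean log2 score as an explicit double loop
mean_log_score_oracle <- function(expr, genes, pseudocount = 1) {
  genes <- intersect(genes, rownames(expr))
  out <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    acc <- 0
    for (g in genes) acc <- acc + log2(expr[g, j] + pseudocount)
    out[j] <- acc / length(genes)
  }
  stats::setNames(out, colnames(expr))
}

# Pearson r and t-test p from raw sum formulas
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}
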