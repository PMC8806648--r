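#' ESTIMATE-style stromal and immune scores
#'
#' Single-sample enrichment (the package's ssGSEA statistic) of a stromal
#' and an immune gene set per sample; the ESTIMATE score is their sum and
#' feeds the cosine purity transform ([estimate_purity()]).
#'
#' @param expr Genes x samples expression matrix.
#' @param stromal_set,immune_set Character vectors of gene ids (shipped as
#'   GMT inputs, not hard-coded).
#' @param alpha Rank-weight exponent passed to the enrichment engine.
#' @return Tibble with columns `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  es <- enrich_all(expr,
                   gene_set_collection(list(stromal = stromal_set,
                                            immune = immune_set),
                                       source_tag = "estimate"),
                   alpha = alpha)
  wide <- tidyr::pivot_wider(tibble::as_tibble(es), names_from = "set_name",
                             values_from = "es")
  tibble::tibble(
    sample_id = wide$sample_id,
    stromal_score = wide$stromal,
    immune_score = wide$immune,
    estimate_score = wide$stromal + wide$immune
  )
}

#' Tumor purity from an ESTIMATE score
#'
#' The published closed form `purity = cos(0.6049872018 + 0.0001467884 *
#' estimate_score)`, clamped into `(eps, 1]`; samples whose pre-clamp value
#' is not positive are flagged via the `flagged` attribute.
#'
#' @param estimate_score Numeric vector of ESTIMATE scores.
#' @param intercept,slope Constants of the affine argument
#'   (config-overridable).
#' @param eps Lower clamp bound.
#' @return Numeric purity vector in `(eps, 1]` with logical attribute
#'   `flagged` marking clamped samples.
#' @export
estimate_purity <- function(estimate_score,
                            intercept = 0.6049872018,
                            slope = 0.0001467884,
                            eps = 1e-6) {
  raw <- cos(intercept + slope * estimate_score)
  flagged <- !is.finite(raw) | raw <= 0 | raw > 1
  if (any(flagged)) {
    rlang::warn(sprintf("estimate_purity: %d sample(s) outside (0, 1] before clamping",
                        sum(flagged)))
  }
  out <- pmin(pmax(raw, eps), 1)
  attr(out, "flagged") <- flagged
  out
}

#' Add ESTIMATE purity to an expression cohort
#'
#' Convenience composition of [estimate_scores()] and [estimate_purity()].
#'
#' @inheritParams estimate_scores
#' @inheritParams estimate_purity
#' @return The [estimate_scores()] tibble with `purity` and `purity_flagged`
#'   columns appended.
#' @export
purity_from_expression <- function(expr, stromal_set, immune_set, alpha = 0.25,
                                   intercept = 0.6049872018,
                                   slope = 0.0001467884) {
  out <- estimate_scores(expr, stromal_set, immune_set, alpha = alpha)
  p <- estimate_purity(out$estimate_score, intercept = intercept, slope = slope)
  out$purity <- as.numeric(p)
  out$purity_flagged <- attr(p, "flagged")
  out
}

#' Residualize a biomarker score on log(1 - purity)
#'
#' Ordinary least squares of the score on `intercept + log(1 - purity)`; the
#' adjusted score is the residual, which is exactly orthogonal to the
#' regressor and sums to zero. Samples with purity 1 (undefined regressor)
#' are excluded from the fit but retained with adjusted value
#' `score - intercept`, flagged in the output.
#'
#' @param score An `itaemt_score` tibble (`sample_id`, `score`) or numeric
#'   vector aligned with `purity`.
#' @param purity Per-sample purity fractions in (0, 1].
#' @return A tibble (class `adjusted_score`) with columns `sample_id`,
#'   `score`, `score_adjusted`, `excluded_from_fit`; attributes `regression`
#'   (intercept, slope, r_squared), `regressor_tag = "log(1-purity)"`, and
#'   the score-name/adjusted attributes of `itaemt_score`.
#' @export
adjust_for_purity <- function(score, purity) {
  if (is.numeric(score)) {
    score <- new_score(tibble::tibble(sample_id = paste0("s", seq_along(score)),
                                      score = score),
                       name = "score", adjusted = FALSE)
  }
  if (nrow(score) != length(purity)) {
    abort_itaemt("`purity` must have one value per score row")
  }
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    abort_itaemt("purity values must lie in (0, 1]")
  }
  if (nrow(score) < 3) abort_itaemt("need at least 3 samples to adjust")
  at_one <- purity >= 1
  if (any(at_one)) {
    rlang::warn(sprintf("adjust_for_purity: %d sample(s) with purity = 1 excluded from the fit",
                        sum(at_one)))
  }
  x <- log(1 - purity[!at_one])
  if (stats::sd(x) == 0) {
    abort_itaemt("degenerate regression: all purities equal, log(1-purity) is constant")
  }
  y <- score$score[!at_one]
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  adjusted <- numeric(nrow(score))
  adjusted[!at_one] <- stats::residuals(fit)
  adjusted[at_one] <- score$score[at_one] - coefs[[1]]
  out <- tibble::tibble(
    sample_id = score$sample_id,
    score = score$score,
    score_adjusted = adjusted,
    excluded_from_fit = at_one
  )
  sst <- sum((y - mean(y))^2)
  r_squared <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(out,
            regression = c(intercept = unname(coefs[[1]]),
                           slope = unname(coefs[[2]]),
                           r_squared = r_squared),
            regressor_tag = "log(1-purity)",
            score_name = attr(score, "score_name") %||% "score",
            adjusted = TRUE,
            class = c("adjusted_score", class(tibble::tibble())))
}

#' Correlation between a biomarker score and tumor purity
#'
#' Pearson r and the two-sided t-test p-value between the score and purity
#' (or `log(1 - purity)` when `on = "log1m_purity"`). Degenerate
#' (zero-variance) inputs give a flagged `NA` row.
#'
#' @param score `itaemt_score`/`adjusted_score` tibble or numeric vector.
#' @param purity Per-sample purity fractions.
#' @param on `"purity"` or `"log1m_purity"`.
#' @param use_adjusted For `adjusted_score` input, correlate the adjusted
#'   values (default) rather than the raw ones.
#' @return One-row tibble (`r`, `p`, `n`, `on`, `degenerate`).
#' @export
score_purity_correlation <- function(score, purity,
                                     on = c("purity", "log1m_purity"),
                                     use_adjusted = TRUE) {
  on <- match.arg(on)
  vals <- if (is.numeric(score)) {
    score
  } else if (inherits(score, "adjusted_score") && use_adjusted) {
    score$score_adjusted
  } else {
    score$score
  }
  x <- if (on == "purity") purity else log(1 - pmin(purity, 1 - 1e-12))
  if (stats::sd(vals) == 0 || stats::sd(x) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(vals),
                          on = on, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(vals, x))
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(vals),
                 on = on, degenerate = FALSE)
}
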