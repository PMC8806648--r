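#' Fit a Cox proportional-hazards model on biomarker covariates
#'
#' Wraps `survival::coxph()` (Breslow tie handling by default, Efron behind
#' the `ties` flag; convergence tolerance 1e-9, at most 100 iterations) and
#' stores the covariate data so hazard ratios can be reported on the
#' IQR-compared scale. Use [generics::tidy()] / [generics::glance()] (or
#' [hr_iqr()]) on the result.
#'
#' @param data Tibble with one row per sample, containing the covariate
#'   columns and the survival columns.
#' @param covariates Character vector of covariate column names.
#' @param time,event Names of the survival time (days) and event (1 = death)
#'   columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_fit`.
#' @export
fit_cox <- function(data, covariates, time = "os_time", event = "os_event",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  missing_cols <- setdiff(c(covariates, time, event), colnames(data))
  if (length(missing_cols) > 0) {
    abort_itaemt(sprintf("data lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (length(covariates) == 0) abort_itaemt("need at least one covariate")
  if (sum(data[[event]]) == 0) abort_itaemt("no events: Cox model undefined")
  for (cv in covariates) {
    if (stats::sd(data[[cv]]) == 0) {
      abort_itaemt(sprintf("covariate '%s' has zero variance", cv))
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    fit = fit,
    covariates = covariates,
    covariate_data = data[, covariates, drop = FALSE],
    ties = ties,
    n = fit$n,
    n_events = fit$nevent,
    converged = converged,
    iterations = fit$iter
  ), class = "cox_fit")
}

z975 <- 1.959963985

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d sample(s), %d event(s), ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit: coefficients with IQR-scaled hazard ratios
#'
#' One row per covariate: log-hazard `beta`, standard error from the inverse
#' observed information, two-sided Wald `p`, and the IQR-scaled hazard ratio
#' `exp(beta * (q75 - q25))` with its two-sided 95% Wald interval — the
#' hazard comparing a 75th- to a 25th-percentile sample of that covariate.
#'
#' @param x A [fit_cox()] result.
#' @param ... Unused.
#' @return Tibble (`term`, `beta`, `se`, `wald_p`, `iqr`, `hr_iqr`,
#'   `ci_low`, `ci_high`).
#' @export
tidy.cox_fit <- function(x, ...) {
  beta <- stats::coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  purrr::map_dfr(seq_along(beta), function(i) {
    term <- x$covariates[i]
    delta <- unname(diff(stats::quantile(x$covariate_data[[term]], c(0.25, 0.75))))
    b <- unname(beta[i]); s <- unname(se[i])
    hr <- if (delta > 0) exp(b * delta) else NA_real_
    ci <- if (delta > 0) sort(exp((b + c(-1, 1) * z975 * s) * delta)) else c(NA_real_, NA_real_)
    tibble::tibble(
      term = term,
      beta = b,
      se = s,
      wald_p = 2 * stats::pnorm(-abs(b / s)),
      iqr = delta,
      hr_iqr = hr,
      ci_low = ci[1],
      ci_high = ci[2]
    )
  })
}

#' Model-level summary of a Cox fit
#'
#' @param x A [fit_cox()] result.
#' @param ... Unused.
#' @return One-row tibble (`n`, `n_events`, `converged`, `iterations`,
#'   `logLik`).
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, converged = x$converged,
                 iterations = x$iterations,
                 logLik = as.numeric(stats::logLik(x$fit)))
}

#' IQR-scaled hazard ratio for one covariate of a Cox fit
#'
#' `delta = q75 - q25` of the covariate; `hr = exp(beta * delta)`;
#' `ci95 = exp((beta +/- 1.959963985 * se) * delta)`.
#'
#' @param fit A [fit_cox()] result.
#' @param term Covariate name (default: the first covariate).
#' @param values Optional numeric vector whose quartiles define `delta`
#'   (defaults to the fitted covariate data).
#' @return One-row tibble (`term`, `hr`, `ci_low`, `ci_high`, `iqr`).
#' @export
hr_iqr <- function(fit, term = NULL, values = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  term <- term %||% fit$covariates[1]
  if (!term %in% fit$covariates) abort_itaemt(sprintf("unknown covariate '%s'", term))
  values <- values %||% fit$covariate_data[[term]]
  delta <- unname(diff(stats::quantile(values, c(0.25, 0.75))))
  if (delta == 0) abort_itaemt("degenerate score: IQR is zero")
  i <- match(term, fit$covariates)
  beta <- stats::coef(fit$fit)[i]
  se <- sqrt(diag(stats::vcov(fit$fit)))[i]
  ci <- sort(exp((beta + c(-1, 1) * z975 * se) * delta))
  tibble::tibble(term = term, hr = unname(exp(beta * delta)),
                 ci_low = ci[1], ci_high = ci[2], iqr = delta)
}

#' Median dichotomization of a biomarker score
#'
#' Samples strictly above the within-cohort median are labeled `high`;
#' values equal to the median go to `low`. The cutpoint is recorded in the
#' `cutpoint` attribute.
#'
#' @param score `itaemt_score`/`adjusted_score` tibble or numeric vector.
#' @param use_adjusted For adjusted scores, split on the adjusted values.
#' @return Tibble (`sample_id`, `group` factor with levels low/high) with
#'   attribute `cutpoint`.
#' @export
median_split <- function(score, use_adjusted = TRUE) {
  if (is.numeric(score)) {
    ids <- names(score) %||% paste0("s", seq_along(score))
    vals <- unname(score)
  } else {
    ids <- score$sample_id
    vals <- if (inherits(score, "adjusted_score") && use_adjusted) {
      score$score_adjusted
    } else {
      score$score
    }
  }
  if (length(unique(vals)) < 2) abort_itaemt("all score values identical: no split possible")
  med <- stats::median(vals)
  grp <- factor(ifelse(vals > med, "high", "low"), levels = c("low", "high"))
  structure(tibble::tibble(sample_id = ids, group = grp),
            cutpoint = med, class = c("group_split", class(tibble::tibble())))
}

#' Cross the EMT and ITA median splits into four prognostic groups
#'
#' @param emt,ita Score tibbles (raw or adjusted) sharing sample ids.
#' @param use_adjusted Split on adjusted values where available.
#' @return Tibble (`sample_id`, `group` factor with levels
#'   `lowEMT-lowITA`, `lowEMT-highITA`, `highEMT-lowITA`, `highEMT-highITA`)
#'   with attribute `cutpoints` (the two medians).
#' @export
four_group <- function(emt, ita, use_adjusted = TRUE) {
  se <- median_split(emt, use_adjusted = use_adjusted)
  si <- median_split(ita, use_adjusted = use_adjusted)
  merged <- dplyr::inner_join(
    dplyr::rename(se, emt_group = "group"),
    dplyr::rename(si, ita_group = "group"), by = "sample_id")
  if (nrow(merged) < 4) abort_itaemt("need at least 4 shared samples")
  lv <- c("lowEMT-lowITA", "lowEMT-highITA", "highEMT-lowITA", "highEMT-highITA")
  grp <- factor(paste0(ifelse(merged$emt_group == "high", "highEMT", "lowEMT"), "-",
                       ifelse(merged$ita_group == "high", "highITA", "lowITA")),
                levels = lv)
  structure(tibble::tibble(sample_id = merged$sample_id, group = grp),
            cutpoints = c(emt = attr(se, "cutpoint"), ita = attr(si, "cutpoint")),
            class = c("group_split", class(tibble::tibble())))
}

#' Kaplan-Meier curves per group with a log-rank test
#'
#' Product-limit curves per group (`survival::survfit`) and the log-rank
#' statistic (`survival::survdiff`) with `df = #groups - 1`. Declared group
#' levels with zero samples are dropped with a warning and the degrees of
#' freedom adjusted.
#'
#' @param groups A [median_split()]/[four_group()] tibble (`sample_id`,
#'   `group`).
#' @param clin Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @return List of class `km_result`: `curves` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`, including a time-0 row at survival 1),
#'   `chi2`, `df`, `p`, `n`, `n_events`.
#' @export
km_logrank <- function(groups, clin) {
  df <- dplyr::inner_join(tibble::as_tibble(groups), tibble::as_tibble(clin),
                          by = "sample_id")
  if (nrow(df) == 0) abort_itaemt("no samples shared between groups and clinical table")
  present <- table(df$group)
  if (any(present == 0)) {
    rlang::warn(sprintf("dropping empty group level(s): %s",
                        paste(names(present)[present == 0], collapse = ", ")))
    df$group <- droplevels(df$group)
  }
  if (nlevels(df$group) < 2) abort_itaemt("need at least 2 non-empty groups")
  if (sum(df$os_event) == 0) abort_itaemt("no events observed")
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  strata_names <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble::tibble(group = strata_names, time = sf$time,
                           n_risk = sf$n.risk, n_event = sf$n.event,
                           surv = sf$surv)
  zero <- curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0,
                  n_risk = as.vector(table(df$group)[.data$group]),
                  n_event = 0, surv = 1)
  curves <- dplyr::bind_rows(zero, curves) |>
    dplyr::arrange(.data$group, .data$time)
  sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df)
  dfree <- nlevels(df$group) - 1
  structure(list(curves = curves,
                 chi2 = unname(sd_$chisq),
                 df = dfree,
                 p = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE),
                 n = nrow(df), n_events = sum(df$os_event)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d group(s), n = %d, events = %d; log-rank chi2 = %.3f (df = %d), p = %.4g\n",
              length(unique(x$curves$group)), x$n, x$n_events, x$chi2, x$df, x$p))
  invisible(x)
}

#' Restricted mean survival time per group from Kaplan-Meier curves
#'
#' Area under each group's step curve up to `horizon` (days).
#'
#' @param km A [km_logrank()] result.
#' @param horizon Upper integration limit; defaults to the largest observed
#'   time.
#' @return Tibble (`group`, `rmst`).
#' @export
km_rmst <- function(km, horizon = NULL) {
  stopifnot(inherits(km, "km_result"))
  horizon <- horizon %||% max(km$curves$time)
  km$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(rmst = {
      t <- pmin(.data$time, horizon)
      s <- .data$surv
      keep <- !duplicated(t, fromLast = TRUE)
      t <- t[keep]; s <- s[keep]
      sum(c(s[-length(s)], s[length(s)]) * diff(c(t, horizon)))
    }, .groups = "drop")
}

#' Per-gene Cox screening of an EMT set controlling for ITA
#'
#' For each gene, fits `Surv ~ log2(x + 1) + ITA` and records the gene's
#' coefficient and two-sided Wald p-value; direction is `risk` for positive
#' coefficients and `favorable` for negative ones. Genes are sorted by
#' p-value ascending and selected at the uncorrected `p < p_cutoff`
#' (matching the screening convention); a Benjamini-Hochberg column `p_bh`
#' is additionally reported as a labeled extension. Genes absent from the
#' matrix or with zero variance are skipped with a warning.
#'
#' @param expr Linear-scale expression matrix.
#' @param emt_set Character vector of gene ids to screen.
#' @param ita ITA score tibble (raw or adjusted; adjusted values used when
#'   available).
#' @param clin Clinical tibble.
#' @param p_cutoff Selection cutoff (default 0.05).
#' @param use_adjusted Use adjusted ITA values where available.
#' @return Tibble (`gene`, `beta`, `se`, `wald_p`, `p_bh`, `direction`,
#'   `selected`), sorted by `wald_p`.
#' @export
rank_emt_genes <- function(expr, emt_set, ita, clin, p_cutoff = 0.05,
                           use_adjusted = TRUE) {
  ita_vals <- if (inherits(ita, "adjusted_score") && use_adjusted) {
    ita$score_adjusted
  } else {
    ita$score
  }
  ita_tbl <- tibble::tibble(sample_id = ita$sample_id, .ita = ita_vals)
  base <- dplyr::inner_join(ita_tbl, tibble::as_tibble(clin), by = "sample_id")
  genes <- intersect(emt_set, rownames(expr))
  if (length(genes) == 0) abort_itaemt("no screened gene present in the expression matrix")
  skipped <- character(0)
  rows <- purrr::map_dfr(genes, function(g) {
    x <- log2(expr[g, base$sample_id] + 1)
    if (stats::sd(x) == 0) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    dat <- base
    dat$.gene <- unname(x)
    fit <- fit_cox(dat, covariates = c(".gene", ".ita"))
    td <- tidy(fit)
    tibble::tibble(gene = g, beta = td$beta[1], se = td$se[1],
                   wald_p = td$wald_p[1])
  })
  if (length(skipped) > 0) {
    rlang::warn(sprintf("skipped %d zero-variance gene(s): %s", length(skipped),
                        paste(utils::head(skipped, 5), collapse = ", ")))
  }
  rows |>
    dplyr::mutate(p_bh = stats::p.adjust(.data$wald_p, method = "BH"),
                  direction = ifelse(.data$beta > 0, "risk", "favorable"),
                  selected = .data$wald_p < p_cutoff) |>
    dplyr::arrange(.data$wald_p)
}

#' Validate screened genes in a second cohort
#'
#' Refits the per-gene Cox model (gene + ITA, with ITA recomputed on the
#' validation cohort) for each candidate gene; a gene validates iff its
#' Wald p-value is below `p_cutoff`, with the direction reported. Genes
#' absent from the validation matrix (or with zero variance there) are
#' reported as untestable, not failed.
#'
#' @param genes Character vector of candidate genes (e.g. the selected rows
#'   of [rank_emt_genes()]).
#' @param expr2 Validation-cohort expression matrix.
#' @param clin2 Validation-cohort clinical tibble.
#' @param ita2 ITA score tibble computed on the validation cohort.
#' @param p_cutoff Validation cutoff (default 0.05).
#' @param use_adjusted Use adjusted ITA values where available.
#' @return Tibble (`gene`, `testable`, `beta`, `se`, `wald_p`, `direction`,
#'   `validated`).
#' @export
validate_genes <- function(genes, expr2, clin2, ita2, p_cutoff = 0.05,
                           use_adjusted = TRUE) {
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(0), testable = logical(0),
                          beta = numeric(0), se = numeric(0),
                          wald_p = numeric(0), direction = character(0),
                          validated = logical(0)))
  }
  testable <- genes %in% rownames(expr2)
  res <- if (any(testable)) {
    suppressWarnings(
      rank_emt_genes(expr2, genes[testable], ita2, clin2,
                     p_cutoff = p_cutoff, use_adjusted = use_adjusted))
  } else {
    NULL
  }
  purrr::map_dfr(genes, function(g) {
    row <- if (!is.null(res)) res[res$gene == g, ] else NULL
    if (is.null(row) || nrow(row) == 0) {
      tibble::tibble(gene = g, testable = FALSE, beta = NA_real_,
                     se = NA_real_, wald_p = NA_real_,
                     direction = NA_character_, validated = FALSE)
    } else {
      tibble::tibble(gene = g, testable = TRUE, beta = row$beta, se = row$se,
                     wald_p = row$wald_p, direction = row$direction,
                     validated = row$wald_p < p_cutoff)
    }
  })
}
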