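#' Build a 2x2 contingency table for disproportionality analysis
#'
#' Cell layout: `a` AKI reports in the index exposure group, `b` other-ADE
#' reports in the index group, `c` AKI reports in the reference group, `d`
#' other-ADE reports in the reference group.
#'
#' @param a,b,c,d Non-negative integer counts; the total must be positive.
#' @return An object of class `tw_2x2`.
#' @export
#' @examples
#' contingency_2x2(275, 2727, 10949, 391559)
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("2x2 cells must be non-negative integers.",
          class = "twaki_validation_error")
  }
  if (sum(cells) <= 0) {
    abort("2x2 table must have a positive total.",
          class = "twaki_validation_error")
  }
  structure(as.list(cells), class = "tw_2x2")
}

#' Crude reporting odds ratio from a 2x2 table
#'
#' ROR = (a/b) / (c/d): the odds of the target event among index-exposure
#' reports divided by the same odds among reference reports. The confidence
#' interval is a Wald interval on the log scale,
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A signal is declared
#' when the CI lower bound exceeds 1.
#'
#' @param table A [contingency_2x2()] object.
#' @param alpha Two-sided significance level (default 0.05).
#' @param zero_policy `"error"` (default) fails on any zero cell;
#'   `"haldane"` adds 0.5 to every cell when any cell is zero
#'   (Haldane-Anscombe correction) and flags `correction_applied`.
#' @return An object of class `ror_result` with elements `ror`, `ci_low`,
#'   `ci_high`, `alpha`, `signal`, `correction_applied`, `table`.
#' @export
#' @examples
#' crude_ror(contingency_2x2(275, 2727, 10949, 391559))
crude_ror <- function(table, alpha = 0.05,
                      zero_policy = c("error", "haldane")) {
  stopifnot(inherits(table, "tw_2x2"))
  zero_policy <- match.arg(zero_policy)
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (zero_policy == "error") {
      abort("Degenerate 2x2 table: zero cell (use zero_policy = 'haldane').",
            class = "twaki_degenerate_table")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  ror <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  ci <- exp(log(ror) + c(-1, 1) * z * se)
  structure(
    list(ror = ror, ci_low = ci[1], ci_high = ci[2], alpha = alpha,
         signal = ci[1] > 1, correction_applied = corrected, table = table),
    class = "ror_result"
  )
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.3f [%.0f%% CI %.3f-%.3f]%s%s\n",
              x$ror, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$signal) " signal" else "",
              if (x$correction_applied) " (Haldane +0.5)" else ""))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Wraps `stats::chisq.test` without continuity correction by default
#' (Yates correction available via `correct = TRUE`).
#'
#' @param table A [contingency_2x2()] object.
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "tw_2x2"))
  m <- matrix(c(table$a, table$c, table$b, table$d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Chi-square test undefined: zero row or column margin.",
          class = "twaki_degenerate_table")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}

#' Covariate-adjusted reporting odds ratios via logistic regression
#'
#' Fits a binomial logistic regression of the AKI indicator on combination
#' pattern indicators (reference: no Triple Whammy drug) plus the AKI risk
#' covariates — male sex, elderly (>= 70 years), any AKI-risk drug, and
#' reporting year. The maximum-likelihood fit is computed by iteratively
#' reweighted least squares (`stats::glm`); the adjusted ROR for each
#' pattern is `exp` of its coefficient with a Wald CI, reported only when
#' the fit converged with a small analytic gradient norm and no sign of
#' complete separation.
#'
#' @param annotations Tibble from [annotate_cohort()] (needs `is_aki`,
#'   `pattern`, `sex_male`, `elderly_70`, `uses_aki_risk`, `report_year`).
#' @param reference Reference pattern level, default `"NONE"`.
#' @param alpha Two-sided level for Wald CIs.
#' @param year_coding `"continuous"` (default; centered integer year) or
#'   `"categorical"` (one indicator per year).
#' @param pattern_grouping `"pattern"` (default: one indicator per observed
#'   combination pattern) or `"count"` (pooled single/double/triple groups).
#' @param covariates Character vector of covariate column names to adjust
#'   for; set to `character()` for an unadjusted (pattern-only) model.
#' @return An object of class `logistic_fit`: a list with `coefficients`
#'   (term-level tibble), `adjusted` (per-pattern tibble with `ror`,
#'   `ci_low`, `ci_high`, `signal`), `iterations`, `gradient_norm`,
#'   `converged`, `reference`.
#' @export
adjusted_ror <- function(annotations, reference = "NONE", alpha = 0.05,
                         year_coding = c("continuous", "categorical"),
                         pattern_grouping = c("pattern", "count"),
                         covariates = c("sex_male", "elderly_70",
                                        "uses_aki_risk", "report_year")) {
  year_coding <- match.arg(year_coding)
  pattern_grouping <- match.arg(pattern_grouping)
  dat <- as.data.frame(annotations)
  if (length(unique(dat$is_aki)) < 2) {
    abort("Outcome is constant; logistic model is degenerate.",
          class = "twaki_degenerate_model")
  }
  if (pattern_grouping == "count") {
    grp <- c(NONE = "none", R = "single", D = "single", N = "single",
             RD = "double", RN = "double", DN = "double", RDN = "triple")
    dat$pattern <- grp[as.character(dat$pattern)]
    reference <- "none"
  }
  dat$pattern <- droplevels(factor(as.character(dat$pattern)))
  if (!reference %in% levels(dat$pattern)) {
    abort(paste0("Reference pattern '", reference, "' not present."),
          class = "twaki_validation_error")
  }
  dat$pattern <- stats::relevel(dat$pattern, ref = reference)
  terms <- "pattern"
  if ("report_year" %in% covariates) {
    if (year_coding == "continuous") {
      dat$report_year <- dat$report_year - mean(dat$report_year, na.rm = TRUE)
    } else {
      dat$report_year <- factor(dat$report_year)
    }
  }
  terms <- c(terms, covariates)
  form <- stats::as.formula(paste("is_aki ~", paste(terms, collapse = " + ")))
  X_check <- stats::model.matrix(form, dat)
  if (qr(X_check)$rank < ncol(X_check)) {
    abort("Design matrix is rank deficient.", class = "twaki_validation_error")
  }
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  beta <- stats::coef(fit)
  if (any(abs(beta) > 10)) {
    abort("Apparent complete separation: diverging coefficient.",
          class = "twaki_separation_error")
  }
  if (!fit$converged) {
    abort("Logistic regression did not converge.",
          class = "twaki_convergence_error")
  }
  X <- stats::model.matrix(fit)
  mu <- stats::fitted(fit)
  grad <- drop(crossprod(X, fit$y - mu))
  se <- sqrt(diag(stats::vcov(fit)))
  z <- qnorm(1 - alpha / 2)
  coefs <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z_value = unname(beta / se),
    p_value = 2 * pnorm(-abs(unname(beta / se)))
  )
  pat_terms <- grepl("^pattern", names(beta))
  adjusted <- tibble::tibble(
    pattern = sub("^pattern", "", names(beta)[pat_terms]),
    ror = exp(unname(beta[pat_terms])),
    ci_low = exp(unname(beta[pat_terms]) - z * unname(se[pat_terms])),
    ci_high = exp(unname(beta[pat_terms]) + z * unname(se[pat_terms]))
  )
  adjusted$signal <- adjusted$ci_low > 1
  structure(
    list(coefficients = coefs, adjusted = adjusted,
         iterations = fit$iter, gradient_norm = sqrt(sum(grad^2)),
         converged = fit$converged, reference = reference, alpha = alpha,
         log_likelihood = as.numeric(stats::logLik(fit))),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> reference:", x$reference,
      "| iterations:", x$iterations,
      "| gradient norm:", format(x$gradient_norm, digits = 3), "\n")
  print(x$adjusted)
  invisible(x)
}

#' Disproportionality summary table by combination pattern
#'
#' One row per combination pattern (and pooled single/double/triple
#' groups): AKI and other-ADE counts with percentages, crude ROR with CI
#' and signal flag, and adjusted ROR from the logistic model.
#'
#' @param annotations Tibble from [annotate_cohort()].
#' @param alpha Two-sided level.
#' @param zero_policy Passed to [crude_ror()].
#' @inheritParams adjusted_ror
#' @return Tibble with columns `group`, `pattern`, `n_aki`, `pct_aki`,
#'   `n_other`, `pct_other`, `crude_ror`, `crude_low`, `crude_high`,
#'   `crude_signal`, `adj_ror`, `adj_low`, `adj_high`, `adj_signal`.
#' @export
ror_table <- function(annotations, alpha = 0.05, zero_policy = "haldane",
                      year_coding = "continuous",
                      covariates = c("sex_male", "elderly_70",
                                     "uses_aki_risk", "report_year")) {
  ann <- annotations
  n_aki_tot <- sum(ann$is_aki)
  n_oth_tot <- sum(!ann$is_aki)
  ctrl <- ann$pattern == "NONE"
  c_cell <- sum(ctrl & ann$is_aki)
  d_cell <- sum(ctrl & !ann$is_aki)
  # a sparse pattern with no events makes its coefficient non-estimable
  # (separation); degrade to crude-only rows rather than failing the table
  try_fit <- function(...) {
    tryCatch(adjusted_ror(ann, alpha = alpha, year_coding = year_coding,
                          covariates = covariates, ...),
             twaki_separation_error = function(e) NULL,
             twaki_convergence_error = function(e) NULL,
             twaki_degenerate_model = function(e) NULL)
  }
  fit_pat <- try_fit()
  fit_cnt <- try_fit(pattern_grouping = "count")
  row_for <- function(group, label, idx, adj) {
    a <- sum(idx & ann$is_aki)
    b <- sum(idx & !ann$is_aki)
    cr <- crude_ror(contingency_2x2(a, b, c_cell, d_cell), alpha = alpha,
                    zero_policy = zero_policy)
    tibble::tibble(
      group = group, pattern = label,
      n_aki = a, pct_aki = 100 * a / n_aki_tot,
      n_other = b, pct_other = 100 * b / n_oth_tot,
      crude_ror = cr$ror, crude_low = cr$ci_low, crude_high = cr$ci_high,
      crude_signal = cr$signal,
      adj_ror = adj$ror %||% NA_real_, adj_low = adj$ci_low %||% NA_real_,
      adj_high = adj$ci_high %||% NA_real_,
      adj_signal = adj$signal %||% NA
    )
  }
  pick <- function(fit, label) {
    if (is.null(fit)) return(list())
    row <- fit$adjusted[fit$adjusted$pattern == label, , drop = FALSE]
    if (nrow(row)) as.list(row) else list()
  }
  pats <- list(
    list("single", "R"), list("single", "D"), list("single", "N"),
    list("double", "RD"), list("double", "RN"), list("double", "DN"),
    list("triple", "RDN")
  )
  rows <- purrr::map(pats, function(p) {
    row_for(p[[1]], p[[2]], ann$pattern == p[[2]], pick(fit_pat, p[[2]]))
  })
  n_tw_class <- nchar(as.character(ann$pattern)) *
    (as.character(ann$pattern) != "NONE")
  totals <- purrr::map2(
    list(1L, 2L, 3L), c("single", "double", "triple"),
    function(k, lab) {
      row_for(lab, paste0(lab, "_total"), n_tw_class == k, pick(fit_cnt, lab))
    }
  )
  dplyr::bind_rows(c(rows, totals))
}
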