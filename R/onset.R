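#' Time from last combination-drug start to event onset
#'
#' Day-0 convention (default): the duration is the calendar-day difference,
#' so an event on the day the last drug was started scores 0 days. Day-1
#' convention: the start day itself counts as day 1, i.e. the day-0 value
#' plus one.
#'
#' @param last_start,onset `Date` vectors (recycled to common length).
#' @param convention `"day0"` (default) or `"day1"`.
#' @return Numeric vector of durations in days.
#' @export
#' @examples
#' compute_duration(as.Date("2020-05-01"), as.Date("2020-05-08"))
compute_duration <- function(last_start, onset,
                             convention = c("day0", "day1")) {
  convention <- match.arg(convention)
  d <- as.numeric(onset - last_start)
  if (any(!is.na(d) & d < 0)) {
    abort("Implausible sequence: onset precedes the last drug start.",
          class = "twaki_implausible_sequence")
  }
  if (convention == "day1") d <- d + 1
  d
}

#' Order drug classes by start date within a case
#'
#' Ranks the Triple Whammy classes involved in a multi-drug case by their
#' start dates (earliest administration per class). Any tie among the
#' class start dates marks the case `simultaneous`; such cases are
#' excluded from order-stratified analyses but retained in pattern-level
#' totals. The last class is defined only when a unique latest start
#' exists.
#'
#' @param starts Named `Date` vector, one element per involved class
#'   (names from `R`, `D`, `N`).
#' @return List with `order` (named integer ranks, or `NULL` when
#'   simultaneous), `last_class` (`NA` if no unique latest start),
#'   `simultaneous` (logical).
#' @export
#' @examples
#' order_strata(c(R = as.Date("2020-01-01"), N = as.Date("2020-01-10")))
order_strata <- function(starts) {
  if (length(starts) < 2) {
    abort("order_strata needs at least two involved classes.",
          class = "twaki_validation_error")
  }
  if (any(is.na(starts))) {
    abort("order_strata requires complete start dates.",
          class = "twaki_validation_error")
  }
  tie <- anyDuplicated(starts) > 0
  last_unique <- sum(starts == max(starts)) == 1
  list(
    order = if (tie) NULL else
      stats::setNames(rank(as.numeric(starts)), names(starts)),
    last_class = if (last_unique) names(starts)[which.max(as.numeric(starts))]
                 else NA_character_,
    simultaneous = tie
  )
}

#' Build time-to-onset records for AKI cases on Triple Whammy drugs
#'
#' For each AKI case in a Triple Whammy pattern, takes the earliest
#' complete start date per involved class, requires an AKI reaction with a
#' complete onset date, and computes the duration from the last-started
#' class. Cases missing any required date, and cases where onset precedes
#' the last start, are excluded and logged. Simultaneous starts are kept
#' (flagged) for pattern-level analyses.
#'
#' @param cases A `jader_cases` object.
#' @param annotations Tibble from [annotate_cohort()].
#' @param lists A [drug_lists()] object.
#' @param pt_list AKI Preferred Term list.
#' @param convention Duration convention, see [compute_duration()].
#' @return List with `records` — tibble(`case_id`, `pattern`, `n_tw`,
#'   `last_class`, `first_class`, `simultaneous`, `duration_days`) — and
#'   `exclusions` — tibble(`case_id`, `reason`).
#' @export
build_onset_records <- function(cases, annotations,
                                lists = default_drug_lists(),
                                pt_list = default_aki_pts(),
                                convention = c("day0", "day1")) {
  convention <- match.arg(convention)
  ann <- annotations[annotations$is_aki & annotations$pattern != "NONE", ,
                     drop = FALSE]
  drugs <- cases$drugs
  name <- normalize_term(drugs$drug_name)
  drugs$tw_class <- dplyr::case_when(
    name %in% lists$rasi ~ "R",
    name %in% lists$diuretic ~ "D",
    name %in% lists$nsaid & drugs$route != "topical" ~ "N",
    TRUE ~ NA_character_
  )
  class_starts <- drugs |>
    dplyr::filter(!is.na(.data$tw_class), !is.na(.data$start_date)) |>
    dplyr::group_by(.data$case_id, .data$tw_class) |>
    dplyr::summarise(start = min(.data$start_date), .groups = "drop")
  aki_pts <- normalize_term(pt_list)
  onsets <- cases$reactions |>
    dplyr::filter(normalize_term(.data$pt) %in% aki_pts,
                  !is.na(.data$onset_date)) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(onset = min(.data$onset_date), .groups = "drop")
  # wide per-case matrix of earliest class starts (numeric days)
  cls <- c("R", "D", "N")
  S <- matrix(NA_real_, nrow = nrow(ann), ncol = 3,
              dimnames = list(NULL, cls))
  for (k in cls) {
    sub <- class_starts[class_starts$tw_class == k, , drop = FALSE]
    S[, k] <- as.numeric(sub$start)[match(ann$case_id, sub$case_id)]
  }
  pat <- as.character(ann$pattern)
  M <- cbind(R = grepl("R", pat), D = grepl("D", pat), N = grepl("N", pat))
  n_tw <- rowSums(M)
  have_all <- rowSums(!is.na(S) & M) == n_tw
  onset_num <- as.numeric(onsets$onset)[match(ann$case_id, onsets$case_id)]

  Sm <- S
  Sm[!M] <- NA_real_
  last_start <- suppressWarnings(
    do.call(pmax, c(as.data.frame(Sm), na.rm = TRUE)))
  reason <- rep(NA_character_, nrow(ann))
  reason[!have_all] <- "missing_start_date"
  reason[have_all & is.na(onset_num)] <- "missing_onset_date"
  keep0 <- is.na(reason)
  reason[keep0 & onset_num < last_start] <- "implausible_sequence"
  keep <- is.na(reason)

  # ties among involved class starts => simultaneous; last/first class
  # defined only when the extreme start is unique
  n_at_max <- rowSums(Sm == last_start, na.rm = TRUE)
  first_start <- suppressWarnings(
    do.call(pmin, c(as.data.frame(Sm), na.rm = TRUE)))
  n_at_min <- rowSums(Sm == first_start, na.rm = TRUE)
  tie <-(!is.na(Sm[, "R"]) & !is.na(Sm[, "D"]) & Sm[, "R"] == Sm[, "D"]) |
    (!is.na(Sm[, "R"]) & !is.na(Sm[, "N"]) & Sm[, "R"] == Sm[, "N"]) |
    (!is.na(Sm[, "D"]) & !is.na(Sm[, "N"]) & Sm[, "D"] == Sm[, "N"])
  simultaneous <- n_tw >= 2 & tie
  class_at <- function(target, n_at) {
    hit <- Sm == target
    hit[is.na(hit)] <- FALSE
    out <- rep(NA_character_, nrow(hit))
    unique_hit <- n_at == 1
    idx <- max.col(hit, ties.method = "first")
    out[unique_hit] <- cls[idx[unique_hit]]
    out
  }
  last_class <- class_at(last_start, n_at_max)
  first_class <- class_at(first_start, n_at_min)

  dur <- onset_num - last_start
  if (convention == "day1") dur <- dur + 1

  records <- tibble::tibble(
    case_id = ann$case_id[keep], pattern = pat[keep],
    n_tw = as.integer(n_tw[keep]),
    last_class = last_class[keep], first_class = first_class[keep],
    simultaneous = simultaneous[keep],
    duration_days = dur[keep]
  )
  list(
    records = records,
    exclusions = tibble::tibble(case_id = ann$case_id[!keep],
                                reason = reason[!keep])
  )
}

#' Two-parameter Weibull maximum-likelihood fit for onset durations
#'
#' Fits shape (beta) and scale by maximum likelihood. The shape is found by
#' a one-dimensional root solve of the profile score equation
#' `1/k + mean(log t) - sum(t^k log t)/sum(t^k) = 0`; the scale is then
#' closed-form, `(mean(t^k))^(1/k)`. The shape CI is a Wald interval on the
#' log-parameter scale from the observed information. A shape below 1
#' indicates early failure (decreasing hazard), 1 random failure, above 1
#' wear-out failure; see [classify_failure()].
#'
#' @param durations Numeric vector of durations in days (zeros allowed,
#'   handled per `zero_policy`).
#' @param zero_policy How to handle zero durations before fitting (Weibull
#'   support is strictly positive): `"offset_half"` (default) replaces 0
#'   with 0.5 days, `"exclude"` drops zeros, `"shift_all_plus1"` adds one
#'   day to every duration.
#' @param alpha Two-sided level for the shape CI.
#' @return An object of class `weibull_fit`: `shape`, `scale`, `ci_low`,
#'   `ci_high`, `n`, `n_zero`, `log_likelihood`, `failure_type`, `alpha`,
#'   `zero_policy`.
#' @export
#' @examples
#' fit_weibull(rweibull(500, shape = 0.5, scale = 30))
fit_weibull <- function(durations,
                        zero_policy = c("offset_half", "exclude",
                                        "shift_all_plus1"),
                        alpha = 0.05) {
  zero_policy <- match.arg(zero_policy)
  t <- durations[!is.na(durations)]
  if (any(t < 0)) {
    abort("Durations must be non-negative.", class = "twaki_validation_error")
  }
  n_zero <- sum(t == 0)
  t <- switch(zero_policy,
    offset_half = { t[t == 0] <- 0.5; t },
    exclude = t[t > 0],
    shift_all_plus1 = t + 1
  )
  if (length(t) < 3) {
    abort("Weibull fit needs at least 3 positive durations.",
          class = "twaki_fit_error")
  }
  if (length(unique(t)) == 1) {
    abort("Degenerate sample: all durations equal.",
          class = "twaki_fit_error")
  }
  lt <- log(t)
  mean_lt <- mean(lt)
  # profile score in the shape; weights computed in log space for stability
  score <- function(k) {
    w <- exp(k * lt - max(k * lt))
    1 / k + mean_lt - sum(w * lt) / sum(w)
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) > 0 && hi < 1e3) hi <- hi * 2
  if (score(lo) <= 0 || score(hi) > 0) {
    abort(paste0("Weibull shape root not bracketed in [", lo, ", ", hi, "]."),
          class = "twaki_convergence_error")
  }
  root <- stats::uniroot(score, c(lo, hi), tol = 1e-10)
  shape <- root$root
  # closed-form scale (mean(t^k))^(1/k), evaluated in log space
  m <- max(shape * lt)
  scale <- exp((log(mean(exp(shape * lt - m))) + m) / shape)
  loglik <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2])
    sum(stats::dweibull(t, shape = k, scale = lam, log = TRUE))
  }
  H <- stats::optimHess(c(log(shape), log(scale)), loglik)
  info <- -H
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || cov[1, 1] <= 0) {
    abort("Observed information is singular at the optimum.",
          class = "twaki_convergence_error")
  }
  se_logk <- sqrt(cov[1, 1])
  z <- qnorm(1 - alpha / 2)
  ci <- exp(log(shape) + c(-1, 1) * z * se_logk)
  fit <- structure(
    list(shape = shape, scale = scale, ci_low = ci[1], ci_high = ci[2],
         n = length(t), n_zero = n_zero,
         log_likelihood = loglik(c(log(shape), log(scale))),
         alpha = alpha, zero_policy = zero_policy),
    class = "weibull_fit"
  )
  fit$failure_type <- classify_failure(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit: shape %.3f [%.3f-%.3f], scale %.2f days, n = %d (%s)\n",
              x$shape, x$ci_low, x$ci_high, x$scale, x$n, x$failure_type))
  invisible(x)
}

#' Classify the hazard trend from a Weibull shape estimate
#'
#' In CI mode (default) the classification is conservative: `"early"` only
#' when the whole CI lies below 1, `"wear_out"` only when it lies above 1,
#' otherwise `"random"` (constant hazard not excluded). In strict mode the
#' point estimate alone is compared with 1.
#'
#' @param fit A `weibull_fit` object.
#' @param mode `"ci"` (default) or `"strict"`.
#' @return One of `"early"`, `"random"`, `"wear_out"`.
#' @export
classify_failure <- function(fit, mode = c("ci", "strict")) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    if (fit$shape < 1) "early"
    else if (fit$shape > 1) "wear_out"
    else "random"
  } else {
    if (fit$ci_high < 1) "early"
    else if (fit$ci_low > 1) "wear_out"
    else "random"
  }
}

#' Cumulative incidence curve of onset durations
#'
#' With every record an observed event (no censoring exists in this
#' design), the Kaplan-Meier estimator reduces to the empirical cumulative
#' distribution of the durations: one step per distinct event time, final
#' value 1.
#'
#' @param durations Non-empty numeric vector of durations.
#' @return An object of class `incidence_curve`: tibble-backed list with
#'   `time` (sorted distinct times), `incidence`, `n`.
#' @export
#' @examples
#' incidence_curve(c(6, 6, 6, 10, 12))
incidence_curve <- function(durations) {
  t <- durations[!is.na(durations)]
  if (!length(t)) {
    abort("incidence_curve needs at least one duration.",
          class = "twaki_validation_error")
  }
  tab <- table(t)
  times <- as.numeric(names(tab))
  structure(
    list(time = times, incidence = cumsum(as.numeric(tab)) / length(t),
         n = length(t)),
    class = "incidence_curve"
  )
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat("<incidence_curve> n =", x$n, "| median =", median_onset(x), "days\n")
  invisible(x)
}

#' Median onset time from a cumulative incidence curve
#'
#' The smallest event time at which the cumulative incidence reaches 50%.
#'
#' @param x An `incidence_curve` or a numeric vector of durations.
#' @return Median onset in days.
#' @export
median_onset <- function(x) {
  if (is.numeric(x)) x <- incidence_curve(x)
  stopifnot(inherits(x, "incidence_curve"))
  x$time[which(x$incidence >= 0.5)[1L]]
}

gehan_scores <- function(pool) {
  # U_i = #(pool < t_i) - #(pool > t_i), computed via ranks to stay O(n log n)
  r_min <- rank(pool, ties.method = "min")
  r_max <- rank(pool, ties.method = "max")
  (r_min - 1) - (length(pool) - r_max)
}

#' Gehan generalized Wilcoxon two-sample test
#'
#' The Gehan-Breslow statistic scores every cross-pair: +1 when the second
#' group's value is larger, -1 when smaller, 0 on ties;
#' `W = sum over pairs sign(b_j - a_i)`. The default p-value uses the
#' normal approximation with the permutation variance of `W` conditional
#' on the pooled sample and a continuity correction (as in base R's
#' `wilcox.test`); `"exact_permutation"` enumerates all group assignments
#' (intended for total n up to ~14).
#'
#' @param a,b Non-empty numeric duration vectors.
#' @param method `"normal_approx"` (default) or `"exact_permutation"`.
#' @param correct Apply the continuity correction in the normal
#'   approximation? Default `TRUE`.
#' @return An object of class `gehan_result`: `statistic`, `variance`,
#'   `z`, `p_value`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' gehan_wilcoxon(c(1, 2, 3), c(10, 11, 12))
gehan_wilcoxon <- function(a, b,
                           method = c("normal_approx", "exact_permutation"),
                           correct = TRUE) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    abort("Both groups must be non-empty.", class = "twaki_validation_error")
  }
  pool <- c(a, b)
  N <- length(pool); n1 <- length(a); n2 <- length(b)
  U <- gehan_scores(pool)
  W <- sum(U[(n1 + 1):N])
  V <- as.numeric(n1) * as.numeric(n2) / (as.numeric(N) * (N - 1)) * sum(U^2)
  if (method == "normal_approx") {
    if (V == 0) {
      z <- 0; p <- 1
    } else {
      eff <- if (correct) max(abs(W) - 1, 0) else abs(W)
      z <- sign(W) * eff / sqrt(V)
      p <- min(2 * pnorm(-eff / sqrt(V)), 1)
    }
  } else {
    if (N > 22) {
      abort("Exact permutation is limited to total n <= 22.",
            class = "twaki_validation_error")
    }
    combs <- combn(N, n2)
    Wp <- apply(combs, 2, function(ix) sum(U[ix]))
    p <- mean(abs(Wp) >= abs(W) - 1e-9)
    z <- if (V > 0) W / sqrt(V) else 0
  }
  structure(
    list(statistic = W, variance = V, z = z, p_value = p, method = method,
         n1 = n1, n2 = n2),
    class = "gehan_result"
  )
}

#' @export
print.gehan_result <- function(x, ...) {
  cat(sprintf("Gehan W = %d, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Pairwise Gehan comparisons between labeled duration groups
#'
#' Tests every unordered pair of groups; significance at `alpha` (0.05 by
#' default), optionally Holm-adjusted.
#'
#' @param groups Named list of numeric duration vectors (>= 2 groups).
#' @param adjust `"none"` (default) or `"holm"`.
#' @param alpha Significance level.
#' @param method Passed to [gehan_wilcoxon()].
#' @return Tibble with `group1`, `group2`, `statistic`, `p_value`, `p_adj`,
#'   `significant`.
#' @export
pairwise_onset_comparison <- function(groups, adjust = c("none", "holm"),
                                      alpha = 0.05,
                                      method = "normal_approx") {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) {
    abort("Need at least two groups.", class = "twaki_validation_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("Groups must be named.", class = "twaki_validation_error")
  }
  pairs <- combn(names(groups), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    r <- gehan_wilcoxon(groups[[g1]], groups[[g2]], method = method)
    tibble::tibble(group1 = g1, group2 = g2, statistic = r$statistic,
                   p_value = r$p_value)
  }) |> dplyr::bind_rows()
  res$p_adj <- if (adjust == "holm") stats::p.adjust(res$p_value, "holm")
               else res$p_value
  res$significant <- res$p_adj < alpha
  res
}

#' Weibull shape table by pattern and start order
#'
#' Builds the stratified shape-parameter table: per-pattern fits (which
#' include simultaneous-start cases), pooled totals by number of
#' combination drugs, start-order strata within double combinations, and
#' last-started-class strata within the triple combination (order strata
#' exclude simultaneous starts).
#'
#' @param records Onset records from [build_onset_records()] (or
#'   [read_onset_dataset()] output with a `n_tw` column added).
#' @param zero_policy,alpha Passed to [fit_weibull()].
#' @param min_n Strata smaller than this are reported with `NA` fits
#'   (default 3, the fitting minimum).
#' @return Tibble with `group`, `stratum`, `n`, `shape`, `ci_low`,
#'   `ci_high`, `failure_type`.
#' @export
weibull_table <- function(records, zero_policy = "offset_half", alpha = 0.05,
                          min_n = 3) {
  fit_row <- function(group, stratum, d) {
    if (length(d) < min_n || length(unique(d)) < 2) {
      return(tibble::tibble(group = group, stratum = stratum, n = length(d),
                            shape = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, failure_type = NA_character_))
    }
    f <- fit_weibull(d, zero_policy = zero_policy, alpha = alpha)
    tibble::tibble(group = group, stratum = stratum, n = length(d),
                   shape = f$shape, ci_low = f$ci_low, ci_high = f$ci_high,
                   failure_type = f$failure_type)
  }
  rows <- list()
  singles <- c("R", "D", "N")
  for (p in singles) {
    rows[[length(rows) + 1L]] <-
      fit_row("single", p, records$duration_days[records$pattern == p])
  }
  rows[[length(rows) + 1L]] <- fit_row(
    "single", "total", records$duration_days[records$n_tw == 1])
  doubles <- c("RD", "RN", "DN")
  for (p in doubles) {
    sub <- records[records$pattern == p, , drop = FALSE]
    rows[[length(rows) + 1L]] <- fit_row("double", p, sub$duration_days)
    classes <- strsplit(p, "")[[1]]
    ordered_sub <- sub[!sub$simultaneous & !is.na(sub$last_class), ,
                       drop = FALSE]
    for (last in classes) {
      first <- setdiff(classes, last)
      rows[[length(rows) + 1L]] <- fit_row(
        "double", paste0(p, ":", first, "_then_", last),
        ordered_sub$duration_days[ordered_sub$last_class == last])
    }
  }
  tri <- records[records$pattern == "RDN", , drop = FALSE]
  tri_ord <- tri[!tri$simultaneous & !is.na(tri$last_class), , drop = FALSE]
  for (last in c("R", "D", "N")) {
    rows[[length(rows) + 1L]] <- fit_row(
      "triple", paste0("last_", last),
      tri_ord$duration_days[tri_ord$last_class == last])
  }
  rows[[length(rows) + 1L]] <- fit_row("triple", "total", tri$duration_days)
  dplyr::bind_rows(rows)
}

#' Median onset table by combination group
#'
#' Kaplan-Meier medians (first time cumulative incidence reaches 50%) for
#' the groups the onset figures report: by number of combination drugs, by
#' single drug class, by start order within doubles, and by last-started
#' class within the triple. Order-dependent groups exclude simultaneous
#' starts.
#'
#' @param records Onset records from [build_onset_records()].
#' @return Tibble with `group`, `stratum`, `n`, `median_days`.
#' @export
median_table <- function(records) {
  med_row <- function(group, stratum, d) {
    tibble::tibble(group = group, stratum = stratum, n = length(d),
                   median_days = if (length(d)) median_onset(d) else NA_real_)
  }
  rows <- list(
    med_row("count", "single", records$duration_days[records$n_tw == 1]),
    med_row("count", "double",
            records$duration_days[records$n_tw == 2 & !records$simultaneous]),
    med_row("count", "triple",
            records$duration_days[records$n_tw == 3 & !records$simultaneous])
  )
  for (p in c("R", "D", "N")) {
    rows[[length(rows) + 1L]] <-
      med_row("single", p, records$duration_days[records$pattern == p])
  }
  for (p in c("RD", "RN", "DN")) {
    sub <- records[records$pattern == p & !records$simultaneous &
                     !is.na(records$last_class), , drop = FALSE]
    classes <- strsplit(p, "")[[1]]
    for (last in classes) {
      first <- setdiff(classes, last)
      rows[[length(rows) + 1L]] <- med_row(
        "double", paste0(first, "_then_", last),
        sub$duration_days[sub$last_class == last])
    }
  }
  tri <- records[records$pattern == "RDN" & !records$simultaneous &
                   !is.na(records$last_class), , drop = FALSE]
  for (last in c("R", "D", "N")) {
    rows[[length(rows) + 1L]] <- med_row(
      "triple", paste0("last_", last),
      tri$duration_days[tri$last_class == last])
  }
  dplyr::bind_rows(rows)
}
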