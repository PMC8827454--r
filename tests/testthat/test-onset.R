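test_that("duration conventions give day-0 and day-1 values", {
  d0 <- compute_duration(as.Date("2020-05-01"), as.Date("2020-05-01"))
  expect_equal(d0, 0)
  expect_equal(compute_duration(as.Date("2020-05-01"), as.Date("2020-05-08")), 7)
  expect_equal(compute_duration(as.Date("2020-05-01"), as.Date("2020-05-01"),
                                convention = "day1"), 1)
  expect_error(compute_duration(as.Date("2020-05-02"), as.Date("2020-05-01")),
               class = "twaki_implausible_sequence")
})

test_that("start-order strata rank classes and flag simultaneous starts", {
  os <- order_strata(c(R = as.Date("2020-01-01"), N = as.Date("2020-01-10")))
  expect_equal(os$order, c(R = 1, N = 2))
  expect_equal(os$last_class, "N")
  expect_false(os$simultaneous)

  tie <- order_strata(c(R = as.Date("2020-01-01"), D = as.Date("2020-01-01")))
  expect_true(tie$simultaneous)
  expect_null(tie$order)
  expect_true(is.na(tie$last_class))

  tri <- order_strata(c(R = as.Date("2020-01-01"), D = as.Date("2020-01-05"),
                        N = as.Date("2020-02-01")))
  expect_equal(tri$last_class, "N")
  expect_equal(unname(tri$order), c(1, 2, 3))
})

test_that("weibull fit recovers generating parameters", {
  set.seed(101)
  f <- fit_weibull(rweibull(5000, shape = 0.5, scale = 30))
  expect_gt(f$shape, 0.47)
  expect_lt(f$shape, 0.53)
  expect_equal(f$scale, 30, tolerance = 0.08)
  expect_equal(f$failure_type, "early")

  # exponential sample: shape 1, scale equals the sample mean
  x <- rexp(5000, rate = 1 / 20)
  fe <- fit_weibull(x)
  expect_equal(fe$shape, 1, tolerance = 0.05)
  expect_equal(fe$scale, mean(x), tolerance = 0.05 * mean(x))
})

test_that("weibull fit is a stationary point and a local maximum", {
  set.seed(102)
  t <- rweibull(800, shape = 0.7, scale = 15)
  f <- fit_weibull(t)
  # analytic profile score at the fitted shape
  score <- 1 / f$shape + mean(log(t)) -
    sum(t^f$shape * log(t)) / sum(t^f$shape)
  expect_lt(abs(score), 1e-6)
  ll <- function(k, lam) sum(dweibull(t, k, lam, log = TRUE))
  at_fit <- ll(f$shape, f$scale)
  grid <- expand.grid(k = f$shape * seq(0.8, 1.2, length.out = 7),
                      lam = f$scale * seq(0.8, 1.2, length.out = 7))
  expect_true(all(mapply(ll, grid$k, grid$lam) <= at_fit + 1e-8))
})

test_that("weibull fit agrees with an independent MLE implementation", {
  skip_if_not_installed("fitdistrplus")
  set.seed(103)
  t <- rweibull(1000, shape = 0.6, scale = 40)
  f <- fit_weibull(t)
  ref <- fitdistrplus::fitdist(t, "weibull")
  expect_equal(f$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("zero-duration policies and degenerate samples behave as declared", {
  d <- c(0, 0, 3, 8, 20)
  f_off <- fit_weibull(d, zero_policy = "offset_half")
  expect_equal(f_off$n, 5)
  expect_equal(f_off$n_zero, 2)
  f_ex <- fit_weibull(d, zero_policy = "exclude")
  expect_equal(f_ex$n, 3)
  f_sh <- fit_weibull(d, zero_policy = "shift_all_plus1")
  expect_equal(f_sh$n, 5)
  expect_error(fit_weibull(c(5, 5, 5, 5)), class = "twaki_fit_error")
  expect_error(fit_weibull(c(1, 2)), class = "twaki_fit_error")
})

test_that("recovery sweep: median bias within 5% and CI coverage >= 17/20", {
  for (beta_true in c(0.5, 1, 2)) {
    est <- numeric(20); covered <- logical(20)
    for (s in 1:20) {
      set.seed(4000 + s)
      f <- fit_weibull(rweibull(2000, shape = beta_true, scale = 30))
      est[s] <- f$shape
      covered[s] <- f$ci_low <= beta_true && beta_true <= f$ci_high
    }
    expect_lt(abs(median(est) - beta_true) / beta_true, 0.05)
    expect_gte(sum(covered), 17)
  }
})

test_that("failure classification follows the CI and strict rules", {
  fit <- structure(list(shape = 0.47, ci_low = 0.46, ci_high = 0.49),
                   class = "weibull_fit")
  expect_equal(classify_failure(fit), "early")
  wide <- structure(list(shape = 1.74, ci_low = 0.63, ci_high = 3.67),
                    class = "weibull_fit")
  expect_equal(classify_failure(wide), "random")
  expect_equal(classify_failure(wide, mode = "strict"), "wear_out")
  unit <- structure(list(shape = 1, ci_low = 0.9, ci_high = 1.1),
                    class = "weibull_fit")
  expect_equal(classify_failure(unit, mode = "strict"), "random")
})

test_that("incidence curve equals the empirical CDF with merged ties", {
  cv <- incidence_curve(c(6, 6, 6, 10, 12))
  expect_equal(cv$time, c(6, 10, 12))
  expect_equal(cv$incidence, c(0.6, 0.8, 1.0))
  single <- incidence_curve(7)
  expect_equal(single$time, 7)
  expect_equal(single$incidence, 1)
  expect_error(incidence_curve(numeric()), class = "twaki_validation_error")
})

test_that("incidence curve matches survfit with no censoring", {
  skip_if_not_installed("survival")
  set.seed(7)
  d <- floor(rweibull(300, 0.6, 20))
  cv <- incidence_curve(d)
  sf <- survival::survfit(survival::Surv(d, rep(1, length(d))) ~ 1)
  expect_equal(cv$time, sf$time)
  expect_equal(cv$incidence, 1 - sf$surv, tolerance = 1e-12)
})

test_that("median onset is the first time incidence reaches one half", {
  expect_equal(median_onset(c(6, 6, 6, 10, 12)), 6)
  expect_equal(median_onset(c(1, 2, 3, 4)), 2)
  expect_equal(median_onset(7), 7)
  # invariance under duplication of the whole sample
  set.seed(8)
  for (i in 1:20) {
    d <- sample.int(50, sample(3:30, 1), replace = TRUE)
    expect_equal(median_onset(rep(d, 2)), median_onset(d))
  }
})

test_that("gehan statistic matches the cross-pair oracle and is antisymmetric", {
  expect_equal(gehan_wilcoxon(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(gehan_wilcoxon(c(1, 2, 3), c(10, 11, 12))$statistic, 9)
  set.seed(9)
  for (i in 1:30) {
    a <- floor(rweibull(sample(3:20, 1), 0.7, 10))
    b <- floor(rweibull(sample(3:20, 1), 0.7, 15))
    g <- gehan_wilcoxon(a, b)
    expect_equal(g$statistic, gehan_oracle_W(a, b))
    expect_equal(gehan_wilcoxon(b, a)$statistic, -g$statistic)
  }
})

test_that("exact permutation p equals the exhaustive oracle", {
  set.seed(10)
  for (i in 1:15) {
    a <- rweibull(sample(3:5, 1), 0.7, 10)
    b <- rweibull(sample(3:5, 1), 0.7, 30)
    g <- gehan_wilcoxon(a, b, method = "exact_permutation")
    expect_equal(g$p_value, gehan_oracle_p(a, b))
  }
})

test_that("pairwise comparisons cover all pairs and detect separation", {
  set.seed(12)
  groups <- list(fast = rweibull(200, 0.6, 5),
                 slow = rweibull(200, 0.6, 100),
                 mid = rweibull(200, 0.6, 30))
  res <- pairwise_onset_comparison(groups)
  expect_equal(nrow(res), 3)
  fs <- res[res$group1 == "fast" & res$group2 == "slow", ]
  expect_true(fs$significant)
  # a group against itself: statistic 0, p approximately 1
  self <- gehan_wilcoxon(groups$fast, groups$fast)
  expect_equal(self$statistic, 0)
  expect_gt(self$p_value, 0.99)
  # Holm adjustment never decreases p-values
  resh <- pairwise_onset_comparison(groups, adjust = "holm")
  expect_true(all(resh$p_adj >= resh$p_value - 1e-12))
})

test_that("onset records handle missing dates, order, and implausible cases", {
  lists <- tiny_lists()
  demo <- tibble::tibble(
    case_id = c("ok", "sim", "nostart", "early"),
    sex = "male", age_band = "70s", report_year = 2020L
  )
  drug <- tibble::tibble(
    case_id = c("ok", "ok", "sim", "sim", "nostart", "nostart",
                "early", "early"),
    drug_name = c("enalapril", "diclofenac", "enalapril", "furosemide",
                  "enalapril", "diclofenac", "enalapril", "diclofenac"),
    involvement = "suspect",
    route = "systemic",
    start_date = as.Date(c("2020-01-01", "2020-01-10", "2020-02-01",
                           "2020-02-01", "2020-01-01", NA,
                           "2020-03-01", "2020-03-10")),
    start_date_raw = "", date_incomplete = FALSE
  )
  reac <- tibble::tibble(
    case_id = c("ok", "sim", "nostart", "early"),
    pt = "Acute kidney injury",
    onset_date = as.Date(c("2020-01-17", "2020-02-06", "2020-02-01",
                           "2020-03-05")),
    onset_date_raw = "", date_incomplete = FALSE,
    outcome = "Recovered"
  )
  cases <- join_cases(demo, drug, reac)
  ann <- annotate_cohort(cases, lists, tiny_pts())
  out <- build_onset_records(cases, ann, lists, tiny_pts())
  rec <- out$records
  expect_setequal(rec$case_id, c("ok", "sim"))
  ok <- rec[rec$case_id == "ok", ]
  expect_equal(ok$pattern, "RN")
  expect_equal(ok$last_class, "N")
  expect_equal(ok$first_class, "R")
  expect_equal(ok$duration_days, 7)
  expect_true(rec$simultaneous[rec$case_id == "sim"])
  expect_setequal(out$exclusions$reason,
                  c("missing_start_date", "implausible_sequence"))
})

test_that("weibull and median tables stratify by pattern and order", {
  set.seed(13)
  n <- 900
  rec <- tibble::tibble(
    case_id = as.character(1:n),
    pattern = sample(c("R", "D", "N", "RD", "RN", "DN", "RDN"), n,
                     replace = TRUE),
    simultaneous = runif(n) < 0.1,
    duration_days = floor(rweibull(n, 0.5, 20))
  )
  rec$n_tw <- nchar(rec$pattern)
  rec$last_class <- ifelse(rec$simultaneous, NA_character_,
                           substr(rec$pattern, rec$n_tw, rec$n_tw))
  wt <- weibull_table(rec)
  expect_true(all(c("single", "double", "triple") %in% wt$group))
  # pattern-level totals include simultaneous cases, ordered rows exclude them
  rd_total <- wt[wt$group == "double" & wt$stratum == "RD", ]
  rd_ordered <- wt[grepl("^RD:", wt$stratum), ]
  expect_equal(rd_total$n, sum(rec$pattern == "RD"))
  expect_equal(sum(rd_ordered$n),
               sum(rec$pattern == "RD" & !rec$simultaneous))
  mt <- median_table(rec)
  expect_true(all(mt$median_days[mt$n > 0] >= 0))
  expect_equal(mt$n[mt$group == "count" & mt$stratum == "single"],
               sum(rec$n_tw == 1))
})
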