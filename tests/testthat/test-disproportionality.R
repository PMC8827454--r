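test_that("crude ROR matches hand arithmetic and the signal rule", {
  # triple-combination vs no-TW-drug aggregate counts: ROR = (a*d)/(b*c)
  oracle <- (275 * 391559) / (2727 * 10949)
  r <- crude_ror(contingency_2x2(275, 2727, 10949, 391559))
  expect_equal(r$ror, oracle, tolerance = 1e-12)
  expect_equal(round(r$ror, 3), 3.606)
  expect_true(r$signal)
  # Wald CI on the log scale, recomputed independently
  se <- sqrt(1 / 275 + 1 / 2727 + 1 / 10949 + 1 / 391559)
  expect_equal(r$ci_low, exp(log(oracle) - qnorm(0.975) * se))

  eq <- crude_ror(contingency_2x2(10, 10, 10, 10))
  expect_equal(eq$ror, 1)
  expect_false(eq$signal)
})

test_that("zero cells error by default and Haldane-correct on request", {
  tab <- contingency_2x2(0, 5, 5, 5)
  expect_error(crude_ror(tab), class = "twaki_degenerate_table")
  r <- crude_ror(tab, zero_policy = "haldane")
  expect_true(r$correction_applied)
  expect_equal(r$ror, (0.5 / 5.5) / (5.5 / 5.5))
})

test_that("ROR invariances: scaling of non-case columns and group inversion", {
  set.seed(3)
  for (i in 1:25) {
    cells <- rpois(4, lambda = c(20, 200, 50, 500)) + 1
    r <- crude_ror(do.call(contingency_2x2, as.list(cells)))
    # scaling b and d by the same factor leaves the point estimate unchanged
    k <- sample(2:7, 1)
    r_scaled <- crude_ror(contingency_2x2(cells[1], k * cells[2],
                                          cells[3], k * cells[4]))
    expect_equal(r_scaled$ror, r$ror, tolerance = 1e-12)
    # swapping index and reference inverts the estimate and flips the CI
    r_inv <- crude_ror(contingency_2x2(cells[3], cells[4],
                                       cells[1], cells[2]))
    expect_equal(r_inv$ror, 1 / r$ror, tolerance = 1e-12)
    expect_equal(r_inv$ci_low, 1 / r$ci_high, tolerance = 1e-12)
    expect_equal(r_inv$ci_high, 1 / r$ci_low, tolerance = 1e-12)
    # signal rule equivalence against direct recomputation
    expect_identical(r$signal, unname(r$ci_low > 1))
  }
})

test_that("chi-square matches the brute-force expected-count formula", {
  brute <- function(a, b, c, d) {
    O <- matrix(c(a, c, b, d), nrow = 2)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  res <- chi_square_2x2(contingency_2x2(275, 2727, 10949, 391559))
  expect_equal(res$statistic, brute(275, 2727, 10949, 391559),
               tolerance = 1e-10)
  expect_equal(res$p_value,
               pchisq(res$statistic, df = 1, lower.tail = FALSE))
  # independence and transposition symmetry
  expect_equal(chi_square_2x2(contingency_2x2(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi_square_2x2(contingency_2x2(10, 10, 10, 10))$p_value, 1)
  # transposing the table (swapping b and c) leaves the statistic unchanged
  expect_equal(chi_square_2x2(contingency_2x2(20, 10, 5, 40))$statistic,
               chi_square_2x2(contingency_2x2(20, 5, 10, 40))$statistic)
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 5, 5)),
               class = "twaki_degenerate_table")
})

test_that("adjusted ROR equals crude ROR when covariates are pure noise", {
  set.seed(21)
  n <- 20000
  pattern <- sample(c("NONE", "RDN"), n, replace = TRUE, prob = c(0.7, 0.3))
  p <- ifelse(pattern == "RDN", 0.15, 0.10)  # small effect, noise covariates
  ann <- make_annotations(n, pattern, rbinom(n, 1, p) == 1, seed = 22)
  fit <- adjusted_ror(ann)
  a <- sum(ann$is_aki & pattern == "RDN"); b <- sum(!ann$is_aki & pattern == "RDN")
  c_ <- sum(ann$is_aki & pattern == "NONE"); d <- sum(!ann$is_aki & pattern == "NONE")
  crude <- crude_ror(contingency_2x2(a, b, c_, d))
  adj <- fit$adjusted$ror[fit$adjusted$pattern == "RDN"]
  expect_lt(abs(adj - crude$ror) / crude$ror, 0.05)
})

test_that("logistic fit converges with a small analytic gradient norm", {
  set.seed(33)
  n <- 5000
  pattern <- sample(c("NONE", "N", "RD"), n, replace = TRUE)
  lp <- -2 + 0.5 * (pattern == "RD") + 0.2 * (pattern == "N")
  ann <- make_annotations(n, pattern, rbinom(n, 1, plogis(lp)) == 1, seed = 34)
  fit <- adjusted_ror(ann)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-4)
  # Wald CI is exp of a symmetric log-scale interval
  adj <- fit$adjusted
  expect_equal(adj$ror^2, adj$ci_low * adj$ci_high, tolerance = 1e-8)
})

test_that("degenerate logistic inputs raise structured errors", {
  ann <- make_annotations(100, sample(c("NONE", "N"), 100, replace = TRUE),
                          rep(FALSE, 100))
  expect_error(adjusted_ror(ann), class = "twaki_degenerate_model")
  # complete separation: outcome determined by pattern
  pattern <- rep(c("NONE", "N"), each = 200)
  ann2 <- make_annotations(400, pattern, pattern == "N")
  expect_error(
    suppressWarnings(adjusted_ror(ann2, covariates = character())),
    class = "twaki_separation_error"
  )
})

test_that("ror_table produces per-pattern and pooled rows with both RORs", {
  set.seed(55)
  n <- 8000
  pats <- c("NONE", "R", "D", "N", "RD", "RN", "DN", "RDN")
  pattern <- sample(pats, n, replace = TRUE,
                    prob = c(0.5, rep(0.5 / 7, 7)))
  lp <- -2.5 + 0.6 * (pattern != "NONE")
  ann <- make_annotations(n, pattern, rbinom(n, 1, plogis(lp)) == 1)
  tab <- ror_table(ann)
  expect_equal(nrow(tab), 10)  # 7 patterns + 3 pooled totals
  expect_setequal(tab$pattern[1:7], setdiff(pats, "NONE"))
  expect_true(all(is.finite(tab$crude_ror)))
  expect_true(all(is.finite(tab$adj_ror)))
  # pooled single row aggregates the three single-drug patterns
  single <- tab[tab$pattern == "single_total", ]
  expect_equal(single$n_aki,
               sum(ann$is_aki & as.character(ann$pattern) %in% c("R", "D", "N")))
})
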