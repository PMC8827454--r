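test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_cases = 500)
  s1 <- simulate_reports(cfg, seed = 99)
  s2 <- simulate_reports(cfg, seed = 99)
  expect_identical(s1$demo, s2$demo)
  expect_identical(s1$drug, s2$drug)
  expect_identical(s1$reac, s2$reac)
  s3 <- simulate_reports(cfg, seed = 100)
  expect_false(identical(s1$demo, s3$demo))
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(simulation_config(baseline_aki_prob = 1.5),
               "probabilities", class = "twaki_config_error")
  expect_error(
    simulation_config(pattern_prevalence = c(NONE = 0.5, R = 0.1, D = 0.1,
                                             N = 0.1, RD = 0.1, RN = 0.05,
                                             DN = 0.05, RDN = 0.5)),
    "sum to 1", class = "twaki_config_error"
  )
  expect_error(
    simulation_config(onset_params = tibble::tibble(
      pattern = "R", last_class = "any", shape = 0.5, median_days = 10
    )),
    "'any' row", class = "twaki_config_error"
  )
})

test_that("without missingness every TW AKI case yields an onset record", {
  cfg <- simulation_config(
    n_cases = 3000, date_missing_prob = 0, partial_date_prob = 0,
    onset_missing_prob = 0, sex_unknown_prob = 0, age_unknown_prob = 0,
    age_band_probs = c("30s" = 0.5, "70s" = 0.5)
  )
  sim <- simulate_reports(cfg, seed = 17)
  cases <- join_cases(sim$demo, sim$drug, sim$reac)
  ann <- annotate_cohort(cases)
  out <- build_onset_records(cases, ann)
  expect_equal(nrow(out$exclusions), 0)
  expect_equal(nrow(out$records),
               sum(sim$cases$is_aki & sim$cases$pattern != "NONE"))
  # classification recovers the generator's pattern assignment exactly
  merged <- dplyr::inner_join(
    tibble::tibble(case_id = sim$cases$case_id, truth = sim$cases$pattern),
    tibble::tibble(case_id = ann$case_id,
                   obs = as.character(ann$pattern)),
    by = "case_id"
  )
  expect_true(all(merged$truth == merged$obs))
})

test_that("crude ROR recovers the configured odds multiplier", {
  cfg <- simulation_config(
    n_cases = 200000,
    pattern_prevalence = c(NONE = 0.7, R = 0, D = 0, N = 0, RD = 0,
                           RN = 0, DN = 0, RDN = 0.3),
    pattern_or = c(R = 1, D = 1, N = 1, RD = 1, RN = 1, DN = 1, RDN = 2.5),
    beta_male = 0, beta_elderly = 0, beta_risk = 0, beta_year = 0,
    baseline_aki_prob = 0.03
  )
  sim <- simulate_reports(cfg, seed = 31)
  ct <- sim$cases
  a <- sum(ct$is_aki & ct$pattern == "RDN")
  b <- sum(!ct$is_aki & ct$pattern == "RDN")
  c_ <- sum(ct$is_aki & ct$pattern == "NONE")
  d <- sum(!ct$is_aki & ct$pattern == "NONE")
  r <- crude_ror(contingency_2x2(a, b, c_, d))
  expect_gt(r$ror, 2.3)
  expect_lt(r$ror, 2.7)
})

test_that("simulated onset medians converge to the configured day medians", {
  cfg <- simulation_config(
    n_cases = 10000,
    pattern_prevalence = c(NONE = 0, R = 0.5, D = 0, N = 0.5, RD = 0,
                           RN = 0, DN = 0, RDN = 0),
    baseline_aki_prob = 0.999, date_missing_prob = 0,
    onset_missing_prob = 0
  )
  sim <- simulate_reports(cfg, seed = 41)
  ct <- sim$cases
  truth <- ground_truth(cfg)
  for (p in c("R", "N")) {
    d <- ct$duration_days[ct$pattern == p & ct$is_aki]
    want <- truth$analytic_median[truth$pattern == p &
                                    truth$last_class == "any"]
    expect_lte(abs(median_onset(d) - want), 1)
  }
})

test_that("fixtures round-trip through the I/O layer", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_cases = 400)
  paths <- emit_fixture(cfg, dir, seed = 5)
  expect_true(all(file.exists(paths)))
  demo <- read_jader_table(paths[["demo"]], "demo")
  drug <- read_jader_table(paths[["drug"]], "drug")
  reac <- read_jader_table(paths[["reac"]], "reac")
  expect_equal(nrow(demo), 400)
  expect_equal(nrow(reac), 400)
  sim <- simulate_reports(cfg, seed = 5)
  expect_equal(demo, sim$demo)
  expect_equal(drug, sim$drug)
  expect_equal(reac, sim$reac)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$n_cases, 400)
})

test_that("all-early-shape fixture classifies every pattern fit as early", {
  op <- default_onset_params()
  op$shape <- 0.5
  cfg <- simulation_config(
    n_cases = 6000,
    pattern_prevalence = c(NONE = 0, R = 0.25, D = 0.25, N = 0.25, RD = 0.125,
                           RN = 0.125, DN = 0, RDN = 0),
    baseline_aki_prob = 0.999, date_missing_prob = 0, onset_missing_prob = 0,
    onset_params = op
  )
  sim <- simulate_reports(cfg, seed = 53)
  ct <- sim$cases[sim$cases$is_aki, ]
  for (p in c("R", "D", "N", "RD", "RN")) {
    d <- ct$duration_days[ct$pattern == p]
    f <- fit_weibull(d)
    expect_equal(f$failure_type, "early", info = p)
  }
})
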