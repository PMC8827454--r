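#' Configuration for the synthetic report-database generator
#'
#' Defines a complete generative model for a JADER-shaped spontaneous
#' report database: demographics, combination-pattern prevalences, a
#' logistic model for the AKI outcome, and per-group Weibull onset-time
#' distributions. The defaults mimic the published study conditions for
#' Triple Whammy nephrotoxicity: pattern prevalences follow the observed
#' other-ADE distribution, the baseline AKI probability matches the
#' no-TW-drug stratum (~2.7%), pattern odds multipliers follow the
#' published adjusted RORs, and onset distributions are keyed by pattern
#' and last-started class with shapes around 0.5 (early failure) and
#' scales back-solved from the published Kaplan-Meier medians
#' (`scale = median / log(2)^(1/shape)`). The generated database is
#' synthetic throughout — it emulates the statistical structure, not real
#' reports.
#'
#' @param n_cases Number of cases.
#' @param prop_male Proportion of male cases among known-sex cases.
#' @param sex_unknown_prob,age_unknown_prob Probability of missing sex /
#'   age band (exercises the population filter).
#' @param age_band_probs Named probability vector over decade bands
#'   (lower bounds 10-90).
#' @param year_range Inclusive reporting-year range.
#' @param pattern_prevalence Named probability vector over the eight
#'   combination patterns (must sum to 1).
#' @param baseline_aki_prob AKI probability in the reference stratum
#'   (pattern NONE, female, non-elderly, no risk drug, mid-window year).
#' @param pattern_or Named odds multipliers versus NONE for the seven
#'   exposure patterns.
#' @param beta_male,beta_elderly,beta_risk,beta_year Covariate log-odds
#'   (year is per-year on the centered reporting year).
#' @param risk_drug_prob Probability a case uses an AKI-risk drug.
#' @param onset_params Data frame with columns `pattern`, `last_class`
#'   (a class letter or `"any"`), `shape`, `median_days`; scales are
#'   derived internally. Every non-NONE pattern needs an `"any"` row.
#' @param start_window Character vector of two dates bounding drug start
#'   dates.
#' @param date_missing_prob Probability a drug start date is missing.
#' @param partial_date_prob Probability a recorded start date is partial
#'   (year-month only).
#' @param onset_missing_prob Probability a reaction onset date is missing.
#' @param simultaneous_prob Probability all combination drugs of a
#'   multi-drug case start on the same day.
#' @param aspirin_prob Probability of an added aspirin exposure (never
#'   counts as NSAID).
#' @param topical_nsaid_prob Probability of an added topical-route NSAID
#'   row in cases whose pattern excludes NSAIDs (must not flip the
#'   pattern).
#' @param mean_start_gap_days Mean gap in days between successive
#'   combination-drug starts.
#' @param lists A [drug_lists()] object supplying names to draw from.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cases = 20000,
    prop_male = 0.55,
    sex_unknown_prob = 0.03,
    age_unknown_prob = 0.03,
    age_band_probs = c("10s" = 0.05, "20s" = 0.07, "30s" = 0.09,
                       "40s" = 0.12, "50s" = 0.15, "60s" = 0.20,
                       "70s" = 0.19, "80s" = 0.10, "90s" = 0.03),
    year_range = c(2004L, 2020L),
    pattern_prevalence = c(NONE = 0.740, R = 0.071, D = 0.037, N = 0.095,
                           RD = 0.031, RN = 0.014, DN = 0.007, RDN = 0.005),
    baseline_aki_prob = 0.027,
    pattern_or = c(R = 1.43, D = 1.76, N = 1.18, RD = 2.41, RN = 1.55,
                   DN = 1.70, RDN = 2.44),
    beta_male = 0.25,
    beta_elderly = 0.6,
    beta_risk = 0.7,
    beta_year = 0.01,
    risk_drug_prob = 0.2,
    onset_params = default_onset_params(),
    start_window = c("2004-04-01", "2020-06-30"),
    date_missing_prob = 0.30,
    partial_date_prob = 0.02,
    onset_missing_prob = 0.15,
    simultaneous_prob = 0.08,
    aspirin_prob = 0.05,
    topical_nsaid_prob = 0.03,
    mean_start_gap_days = 60,
    lists = default_drug_lists()) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Default per-group onset-time parameters
#'
#' Weibull shapes and target medians keyed by pattern and last-started
#' class. Order-specific rows express the strong order dependence of onset
#' within mixed patterns (NSAID-last cases have short onsets; RASI-last
#' onsets are long); `"any"` rows cover single-drug patterns, simultaneous
#' starts, and patterns without order-specific rows.
#'
#' @return Tibble with `pattern`, `last_class`, `shape`, `median_days`.
#' @export
default_onset_params <- function() {
  tibble::tribble(
    ~pattern, ~last_class, ~shape, ~median_days,
    "R",   "any", 0.57,  66,
    "D",   "any", 0.49,  60,
    "N",   "any", 0.49,   9,
    "RD",  "any", 0.62, 120,
    "RN",  "any", 0.49,  10,
    "RN",  "N",   0.48,   7,
    "RN",  "R",   0.58, 119,
    "DN",  "any", 0.48,   8,
    "DN",  "N",   0.44,   9,
    "DN",  "D",   0.65,   6,
    "RDN", "any", 0.51,   8
  )
}

validate_simulation_config <- function(cfg) {
  problems <- character()
  chk <- function(cond, msg) {
    if (!cond) problems <<- c(problems, msg)
  }
  chk(cfg$n_cases >= 1, "n_cases must be >= 1")
  probs <- c(cfg$prop_male, cfg$sex_unknown_prob, cfg$age_unknown_prob,
             cfg$baseline_aki_prob, cfg$risk_drug_prob,
             cfg$date_missing_prob, cfg$partial_date_prob,
             cfg$onset_missing_prob, cfg$simultaneous_prob,
             cfg$aspirin_prob, cfg$topical_nsaid_prob)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  chk(abs(sum(cfg$pattern_prevalence) - 1) < 1e-8,
      "pattern_prevalence must sum to 1")
  chk(all(names(cfg$pattern_prevalence) %in% .tw_patterns) &&
        length(cfg$pattern_prevalence) == 8,
      "pattern_prevalence must cover the 8 patterns")
  chk(all(cfg$pattern_or > 0), "pattern_or must be positive")
  chk(all(cfg$onset_params$shape > 0) && all(cfg$onset_params$median_days > 0),
      "onset shapes and medians must be positive")
  need_any <- setdiff(.tw_patterns, "NONE")
  have_any <- cfg$onset_params$pattern[cfg$onset_params$last_class == "any"]
  chk(all(need_any %in% have_any),
      "onset_params needs an 'any' row for every non-NONE pattern")
  if (length(problems)) {
    abort(paste0("Invalid simulation config:\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "twaki_config_error")
  }
  invisible(cfg)
}

#' Ground truth implied by a simulation configuration
#'
#' @param config A [simulation_config()].
#' @return Tibble with one row per (pattern, last_class) onset group:
#'   the true odds ratio versus NONE, Weibull `shape` and `scale`, the
#'   analytic continuous median `scale * log(2)^(1/shape)` (half a day
#'   above `day_median` because continuous onset times sit at day
#'   midpoints), and the day-resolution `day_median`.
#' @export
ground_truth <- function(config) {
  op <- config$onset_params
  # continuous onset times sit at day midpoints so that flooring to whole
  # days leaves the day-resolution median at the configured integer
  scale <- (op$median_days + 0.5) / log(2)^(1 / op$shape)
  tibble::tibble(
    pattern = op$pattern, last_class = op$last_class,
    odds_ratio = unname(config$pattern_or[op$pattern]),
    shape = op$shape, scale = scale,
    analytic_median = scale * log(2)^(1 / op$shape),
    day_median = op$median_days
  )
}

draw_names <- function(pool, n) {
  # preserve original case/width variety a little: occasionally upper-case
  x <- sample(pool, n, replace = TRUE)
  up <- runif(n) < 0.1
  x[up] <- toupper(x[up])
  x
}

#' Simulate a JADER-shaped report database
#'
#' Generates DEMO/DRUG/REAC tables from a [simulation_config()]. The AKI
#' outcome is drawn from the configured logistic model; AKI cases in a
#' combination pattern receive an onset date equal to the last
#' combination-drug start plus a Weibull-distributed duration rounded down
#' to whole days; non-AKI cases receive decoy Preferred Terms. Missing and
#' partial dates and simultaneous starts are injected at the configured
#' rates. Fully reproducible for a given seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `demo`, `drug`, `reac` tibbles (in the normalized
#'   schema of [read_jader_table()]), `truth` (from [ground_truth()]),
#'   `cases` (internal per-case truth table), and `config`.
#' @export
simulate_reports <- function(config, seed = 1L) {
  validate_simulation_config(config)
  set.seed(as.integer(seed))
  n <- config$n_cases
  lists <- config$lists
  case_id <- sprintf("C%07d", seq_len(n))

  sex <- ifelse(runif(n) < config$sex_unknown_prob, "unknown",
                ifelse(runif(n) < config$prop_male, "male", "female"))
  bands <- names(config$age_band_probs)
  age_band <- ifelse(runif(n) < config$age_unknown_prob, "unknown",
                     sample(bands, n, replace = TRUE,
                            prob = config$age_band_probs))
  report_year <- sample(seq(config$year_range[1], config$year_range[2]),
                        n, replace = TRUE)
  pattern <- sample(names(config$pattern_prevalence), n, replace = TRUE,
                    prob = config$pattern_prevalence)
  uses_risk <- runif(n) < config$risk_drug_prob
  elderly <- !is.na(parse_age_band(age_band)) & parse_age_band(age_band) >= 70
  male <- sex == "male"

  or_vec <- c(NONE = 1, config$pattern_or)
  lp <- stats::qlogis(config$baseline_aki_prob) +
    log(or_vec[pattern]) +
    config$beta_male * male +
    config$beta_elderly * elderly +
    config$beta_risk * uses_risk +
    config$beta_year * (report_year - mean(config$year_range))
  is_aki <- runif(n) < stats::plogis(lp)

  window <- as.Date(config$start_window)
  window_days <- as.integer(diff(window))
  anchor <- window[1] + sample.int(window_days, n, replace = TRUE) - 1L

  # per-case combination drug starts
  tw <- ifelse(pattern == "NONE", "", pattern)
  class_mat <- cbind(
    R = grepl("R", tw), D = grepl("D", tw), N = grepl("N", tw)
  )
  n_tw <- rowSums(class_mat)
  simultaneous <- n_tw >= 2 & runif(n) < config$simultaneous_prob

  op <- config$onset_params
  op$scale <- (op$median_days + 0.5) / log(2)^(1 / op$shape)
  onset_key <- paste(op$pattern, op$last_class, sep = ":")

  name_pool <- list(R = lists$rasi, D = lists$diuretic, N = lists$nsaid)
  outcomes <- c("Recovered", "Remission", "Unrecovered", "Death",
                "With sequelae", "unknown")
  aki_pt_pool <- default_aki_pts()
  decoy_pt_pool <- default_decoy_pts()

  # per-(case, class) combination-drug rows, vectorized
  sel <- as.vector(class_mat)
  tw_rows <- tibble::tibble(
    i = rep(seq_len(n), times = 3L)[sel],
    class = rep(c("R", "D", "N"), each = n)[sel]
  )
  # random start order within each case, then day offsets from the anchor:
  # first class starts at the anchor, later classes after exponential gaps
  tw_rows$rank <- stats::ave(runif(nrow(tw_rows)), tw_rows$i, FUN = rank)
  tw_rows <- tw_rows[order(tw_rows$i, tw_rows$rank), , drop = FALSE]
  gap <- round(stats::rexp(nrow(tw_rows),
                           rate = 1 / config$mean_start_gap_days)) + 1
  gap[!duplicated(tw_rows$i)] <- 0
  gap[simultaneous[tw_rows$i]] <- 0
  tw_rows$offset <- stats::ave(gap, tw_rows$i, FUN = cumsum)
  tw_rows$start <- anchor[tw_rows$i] + tw_rows$offset

  case_last_start <- rep(as.Date(NA), n)
  case_last_class <- rep(NA_character_, n)
  duration_days <- rep(NA_real_, n)
  last_row <- !duplicated(tw_rows$i, fromLast = TRUE)
  case_last_start[tw_rows$i[last_row]] <- tw_rows$start[last_row]
  case_last_class[tw_rows$i[last_row]] <- tw_rows$class[last_row]
  case_last_class[simultaneous & n_tw > 1] <- NA_character_

  # onset duration for AKI cases on combination drugs, keyed by
  # (pattern, last class) with fallback to the pattern's "any" row
  aki_tw <- which(is_aki & n_tw > 0)
  if (length(aki_tw)) {
    key <- paste(pattern[aki_tw],
                 ifelse(is.na(case_last_class[aki_tw]), "any",
                        case_last_class[aki_tw]), sep = ":")
    j <- match(key, onset_key)
    j_any <- match(paste(pattern[aki_tw], "any", sep = ":"), onset_key)
    j[is.na(j)] <- j_any[is.na(j)]
    duration_days[aki_tw] <- floor(rweibull(length(aki_tw),
                                            shape = op$shape[j],
                                            scale = op$scale[j]))
  }

  # assemble drug rows: combination drugs, risk drugs, aspirin, and
  # topical NSAIDs (the latter only where they cannot flip the pattern)
  tw_names <- character(nrow(tw_rows))
  for (cl in c("R", "D", "N")) {
    pick <- tw_rows$class == cl
    tw_names[pick] <- draw_names(name_pool[[cl]], sum(pick))
  }
  risk_i <- which(uses_risk)
  asp_i <- which(runif(n) < config$aspirin_prob)
  top_i <- which(!class_mat[, "N"] & runif(n) < config$topical_nsaid_prob)
  extra_start <- function(idx) anchor[idx] + sample.int(90L, length(idx),
                                                        replace = TRUE) - 1L
  drug_tbl <- dplyr::bind_rows(
    tibble::tibble(i = tw_rows$i, drug_name = tw_names, route_raw = "oral",
                   start = tw_rows$start),
    tibble::tibble(i = risk_i,
                   drug_name = draw_names(lists$aki_risk, length(risk_i)),
                   route_raw = "oral", start = extra_start(risk_i)),
    tibble::tibble(i = asp_i,
                   drug_name = sample(c("Aspirin", "aspirin"),
                                      length(asp_i), replace = TRUE),
                   route_raw = "oral", start = extra_start(asp_i)),
    tibble::tibble(i = top_i,
                   drug_name = draw_names(lists$nsaid, length(top_i)),
                   route_raw = "topical patch", start = extra_start(top_i))
  )
  drug_tbl <- drug_tbl[order(drug_tbl$i), , drop = FALSE]

  demo <- tibble::tibble(case_id = case_id, sex = sex, age_band = age_band,
                         report_year = as.integer(report_year))

  involvement_raw <- sample(c("suspect drug", "concomitant drug",
                              "interaction"),
                            nrow(drug_tbl), replace = TRUE,
                            prob = c(0.6, 0.35, 0.05))
  miss <- runif(nrow(drug_tbl)) < config$date_missing_prob
  partial <- !miss & runif(nrow(drug_tbl)) < config$partial_date_prob
  start_raw <- format(drug_tbl$start, "%Y-%m-%d")
  start_raw[miss] <- ""
  start_raw[partial] <- format(drug_tbl$start[partial], "%Y-%m")
  drug <- tibble::tibble(
    case_id = case_id[drug_tbl$i],
    drug_name = drug_tbl$drug_name,
    involvement = map_enum(involvement_raw, .involvement_levels),
    route = classify_route(drug_tbl$route_raw),
    start_date = dplyr::if_else(miss | partial, as.Date(NA), drug_tbl$start),
    start_date_raw = start_raw,
    date_incomplete = partial
  )

  pt <- character(n)
  pt[is_aki] <- sample(aki_pt_pool, sum(is_aki), replace = TRUE)
  pt[!is_aki] <- sample(decoy_pt_pool, sum(!is_aki), replace = TRUE)
  onset_dates <- anchor + sample.int(180L, n, replace = TRUE) - 1L
  has_tw_onset <- is_aki & n_tw > 0 & !is.na(duration_days)
  onset_dates[has_tw_onset] <- case_last_start[has_tw_onset] +
    duration_days[has_tw_onset]
  onset_miss <- runif(n) < config$onset_missing_prob
  onset_raw <- format(onset_dates, "%Y-%m-%d")
  onset_raw[onset_miss] <- ""
  reac <- tibble::tibble(
    case_id = case_id,
    pt = pt,
    onset_date = dplyr::if_else(onset_miss, as.Date(NA), onset_dates),
    onset_date_raw = onset_raw,
    date_incomplete = FALSE,
    outcome = sample(outcomes, n, replace = TRUE)
  )

  cases_truth <- tibble::tibble(
    case_id = case_id, pattern = pattern, is_aki = is_aki,
    sex_male = male, elderly_70 = elderly, uses_aki_risk = uses_risk,
    report_year = as.integer(report_year), n_tw = n_tw,
    simultaneous = simultaneous, last_class = case_last_class,
    last_start = case_last_start, duration_days = duration_days
  )

  list(demo = demo, drug = drug, reac = reac,
       truth = ground_truth(config), cases = cases_truth, config = config)
}

#' Write a synthetic fixture to disk
#'
#' Emits the simulated demo/drug/reac tables as CSV (readable by
#' [read_jader_table()] with the default dialect) plus a ground-truth YAML.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param seed RNG seed passed to [simulate_reports()].
#' @return Named character vector of the four file paths, invisibly.
#' @export
emit_fixture <- function(config, dir, seed = 1L) {
  sim <- simulate_reports(config, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    demo = file.path(dir, "demo.csv"),
    drug = file.path(dir, "drug.csv"),
    reac = file.path(dir, "reac.csv"),
    truth = file.path(dir, "ground_truth.yaml")
  )
  write_jader_table(sim$demo, paths[["demo"]], "demo")
  write_jader_table(sim$drug, paths[["drug"]], "drug")
  write_jader_table(sim$reac, paths[["reac"]], "reac")
  yaml::write_yaml(
    list(seed = as.integer(seed), n_cases = config$n_cases,
         truth = lapply(seq_len(nrow(sim$truth)), function(i)
           as.list(sim$truth[i, ]))),
    paths[["truth"]]
  )
  invisible(paths)
}
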