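#' Parse a decade age band to its lower bound
#'
#' JADER reports age only as decade bands ("20s", "70s", ...). Returns the
#' band's lower bound in years, or `NA` for unknown/garbled labels.
#'
#' @param label Character vector of age band labels.
#' @return Integer vector of lower bounds (NA where unknown).
#' @export
#' @examples
#' parse_age_band(c("20s", "70s", "", "adult"))
parse_age_band <- function(label) {
  norm <- normalize_term(label)
  m <- stringi::stri_match_first_regex(norm, "^([0-9]{1,3})\\s*s$")
  as.integer(m[, 2L])
}

.tw_patterns <- c("NONE", "R", "D", "N", "RD", "RN", "DN", "RDN")

pattern_label <- function(uses_rasi, uses_diuretic, uses_nsaid) {
  lab <- paste0(ifelse(uses_rasi, "R", ""),
                ifelse(uses_diuretic, "D", ""),
                ifelse(uses_nsaid, "N", ""))
  ifelse(nzchar(lab), lab, "NONE")
}

#' Apply the population inclusion filter
#'
#' Excludes cases with incomplete sex or age information, then cases whose
#' age band lower bound is below 20 years (NSAIDs are generally not given
#' to children in Japan, so pediatric reports are out of scope).
#'
#' @param demo Demo tibble from [read_jader_table()] (or the `demo` element
#'   of a `jader_cases` object).
#' @return A list with `demo` (kept rows) and `flow`, a tibble of stage
#'   counts (`stage`, `n`).
#' @export
filter_population <- function(demo) {
  if (inherits(demo, "jader_cases")) demo <- demo$demo
  n_total <- nrow(demo)
  age_lower <- parse_age_band(demo$age_band)
  known <- demo$sex %in% c("male", "female") & !is.na(age_lower)
  demo1 <- demo[known, , drop = FALSE]
  adult <- parse_age_band(demo1$age_band) >= 20L
  demo2 <- demo1[adult, , drop = FALSE]
  flow <- tibble::tibble(
    stage = c("total", "known_sex_age", "age_20_plus"),
    n = c(n_total, nrow(demo1), nrow(demo2))
  )
  list(demo = demo2, flow = flow)
}

#' Flag AKI cases from reaction Preferred Terms
#'
#' A case is an AKI case iff any of its reaction PTs matches the supplied
#' PT list (exact match after normalization).
#'
#' @param reactions Reaction tibble (`case_id`, `pt`).
#' @param pt_list Character vector of AKI Preferred Terms; must be
#'   non-empty.
#' @return Character vector of AKI case ids.
#' @export
flag_aki <- function(reactions, pt_list = default_aki_pts()) {
  if (!length(pt_list)) {
    abort("AKI PT list is empty; supply at least one Preferred Term.",
          class = "twaki_config_error")
  }
  hits <- normalize_term(reactions$pt) %in% normalize_term(pt_list)
  unique(reactions$case_id[hits])
}

#' Classify Triple Whammy and AKI-risk drug exposures
#'
#' Computes per-case exposure flags from the drug table. All involvement
#' categories (suspect, concomitant, interaction) count as exposure.
#' Aspirin never counts as an NSAID; an NSAID exposure counts only if at
#' least one NSAID row has a systemic (or unknown) route — cases with only
#' topical NSAID use are NSAID-naive.
#'
#' @param drugs Drug tibble (`case_id`, `drug_name`, `route`).
#' @param lists A [drug_lists()] object.
#' @return Tibble with one row per case id present in `drugs`:
#'   `case_id`, `uses_rasi`, `uses_diuretic`, `uses_nsaid`,
#'   `uses_aki_risk`, `pattern`.
#' @export
classify_exposures <- function(drugs, lists = default_drug_lists()) {
  name <- normalize_term(drugs$drug_name)
  is_rasi <- name %in% lists$rasi
  is_diur <- name %in% lists$diuretic
  is_nsaid <- name %in% lists$nsaid & drugs$route != "topical"
  is_risk <- name %in% lists$aki_risk
  flags <- tibble::tibble(
    case_id = drugs$case_id,
    rasi = is_rasi, diuretic = is_diur, nsaid = is_nsaid, risk = is_risk
  ) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      uses_rasi = any(.data$rasi), uses_diuretic = any(.data$diuretic),
      uses_nsaid = any(.data$nsaid), uses_aki_risk = any(.data$risk),
      .groups = "drop"
    )
  flags$pattern <- pattern_label(flags$uses_rasi, flags$uses_diuretic,
                                 flags$uses_nsaid)
  flags
}

#' Annotate a filtered cohort
#'
#' Joins demographics, exposure classification, and the AKI flag into the
#' case-level annotation table used by the disproportionality and onset
#' stages.
#'
#' @param cases A `jader_cases` object (ideally after
#'   [filter_population()] has been applied to its demo table) or a list
#'   with `demo`, `drugs`, `reactions`.
#' @param lists A [drug_lists()] object.
#' @param pt_list AKI Preferred Term list.
#' @return Tibble with columns `case_id`, `is_aki`, `uses_rasi`,
#'   `uses_diuretic`, `uses_nsaid`, `uses_aki_risk`, `pattern`,
#'   `sex_male`, `elderly_70`, `report_year`.
#' @export
annotate_cohort <- function(cases, lists = default_drug_lists(),
                            pt_list = default_aki_pts()) {
  demo <- cases$demo
  drugs <- cases$drugs[cases$drugs$case_id %in% demo$case_id, , drop = FALSE]
  reac <- cases$reactions[cases$reactions$case_id %in% demo$case_id, ,
                          drop = FALSE]
  aki_ids <- flag_aki(reac, pt_list)
  expo <- classify_exposures(drugs, lists)
  ann <- tibble::tibble(
    case_id = demo$case_id,
    is_aki = demo$case_id %in% aki_ids,
    sex_male = demo$sex == "male",
    elderly_70 = !is.na(parse_age_band(demo$age_band)) &
      parse_age_band(demo$age_band) >= 70L,
    report_year = demo$report_year
  ) |>
    dplyr::left_join(expo, by = "case_id")
  for (col in c("uses_rasi", "uses_diuretic", "uses_nsaid", "uses_aki_risk")) {
    ann[[col]] <- !is.na(ann[[col]]) & ann[[col]]
  }
  ann$pattern <- ifelse(is.na(ann$pattern), "NONE", ann$pattern)
  ann$pattern <- factor(ann$pattern, levels = .tw_patterns)
  ann$n_tw <- nchar(as.character(ann$pattern)) *
    (as.character(ann$pattern) != "NONE")
  ann
}

#' Summarize a cohort annotation table
#'
#' Cross-tabulations in the style of a target-case characteristics table:
#' counts and percentages by sex, elderly status, each Triple Whammy drug
#' class, AKI-risk drug use, and combination pattern; optionally AKI
#' outcome categories by pattern.
#'
#' @param annotations Tibble from [annotate_cohort()].
#' @param reactions Optional reaction tibble; when given, outcomes of AKI
#'   reactions are tabulated by pattern.
#' @param pt_list AKI Preferred Term list used for the outcome tabulation.
#' @return A list of tibbles: `characteristics`, `patterns`, and (when
#'   `reactions` is supplied) `outcomes_by_pattern`. Formatted columns
#'   show `"n (pct)"` with blank percentages for an empty cohort.
#' @export
summarize_cohort <- function(annotations, reactions = NULL,
                             pt_list = default_aki_pts()) {
  n <- nrow(annotations)
  fmt <- function(k) {
    if (n == 0) sprintf("%d", k)
    else sprintf("%d (%.1f)", k, 100 * k / n)
  }
  count_row <- function(label, flag) {
    k <- sum(flag)
    tibble::tibble(variable = label, n = k,
                   pct = if (n == 0) NA_real_ else 100 * k / n,
                   formatted = fmt(k))
  }
  characteristics <- dplyr::bind_rows(
    count_row("male", annotations$sex_male),
    count_row("elderly_70", annotations$elderly_70),
    count_row("uses_rasi", annotations$uses_rasi),
    count_row("uses_diuretic", annotations$uses_diuretic),
    count_row("uses_nsaid", annotations$uses_nsaid),
    count_row("any_tw", annotations$pattern != "NONE"),
    count_row("uses_aki_risk", annotations$uses_aki_risk),
    count_row("aki", annotations$is_aki)
  )
  patterns <- dplyr::count(annotations, .data$pattern, .drop = FALSE)
  patterns$pct <- if (n == 0) NA_real_ else 100 * patterns$n / n
  out <- list(characteristics = characteristics, patterns = patterns)
  if (!is.null(reactions)) {
    aki_reac <- reactions[normalize_term(reactions$pt) %in%
                            normalize_term(pt_list), , drop = FALSE]
    out$outcomes_by_pattern <- annotations |>
      dplyr::inner_join(
        dplyr::distinct(aki_reac, .data$case_id, .data$outcome),
        by = "case_id"
      ) |>
      dplyr::count(.data$pattern, .data$outcome, .drop = FALSE)
  }
  out
}
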