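#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either paths to
#' demo/drug/reac tables or a [simulation_config()], the classification
#' lists, analysis options, an output directory, and a seed.
#'
#' @param input Either `NULL` (when `simulation` is given) or a named list
#'   with elements `demo`, `drug`, `reac` (file paths) and optionally
#'   `dialect` (a [jader_dialect()]).
#' @param simulation Optional [simulation_config()]; used when `input` is
#'   `NULL`.
#' @param lists A [drug_lists()] object.
#' @param pt_list AKI Preferred Term list.
#' @param convention Duration convention (`"day0"`/`"day1"`).
#' @param zero_policy Zero-duration policy for Weibull fits.
#' @param alpha Significance level in (0, 1).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed controlling all randomness of the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       lists = default_drug_lists(),
                       pt_list = default_aki_pts(),
                       convention = c("day0", "day1"),
                       zero_policy = "offset_half",
                       alpha = 0.05, out_dir = tempfile("twaki_run_"),
                       seed = 1L) {
  convention <- match.arg(convention)
  if (is.null(input) && is.null(simulation)) {
    abort("run_config needs either input paths or a simulation config.",
          class = "twaki_config_error")
  }
  if (!is.null(input)) {
    for (key in c("demo", "drug", "reac")) {
      if (is.null(input[[key]]) || !file.exists(input[[key]])) {
        abort(paste0("Input file for '", key, "' missing or not found."),
              class = "twaki_config_error")
      }
    }
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("alpha must lie in (0, 1).", class = "twaki_config_error")
  }
  structure(
    list(input = input, simulation = simulation, lists = lists,
         pt_list = pt_list, convention = convention,
         zero_policy = zero_policy, alpha = alpha, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "twaki_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation), population filtering, cohort
#' annotation, disproportionality analysis, and time-to-onset analysis,
#' writing a diffable report bundle: flow report, disproportionality
#' table, cohort summary, Weibull shape table, median onset table,
#' pairwise Gehan test tables, cumulative-incidence step coordinates, and
#' a machine-readable run manifest. Identical config and seed produce
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return The report bundle as a named list (also written under
#'   `config$out_dir`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- stage("ingest", {
    if (!is.null(config$input)) {
      dialect <- config$input$dialect %||% jader_dialect()
      list(
        demo = read_jader_table(config$input$demo, "demo", dialect),
        drug = read_jader_table(config$input$drug, "drug", dialect),
        reac = read_jader_table(config$input$reac, "reac", dialect)
      )
    } else {
      sim <- simulate_reports(config$simulation, seed = config$seed)
      sim[c("demo", "drug", "reac")]
    }
  })

  cases <- stage("join", join_cases(tables$demo, tables$drug, tables$reac))
  filt <- stage("filter", filter_population(cases$demo))
  kept <- list(demo = filt$demo,
               drugs = cases$drugs[cases$drugs$case_id %in%
                                     filt$demo$case_id, , drop = FALSE],
               reactions = cases$reactions[cases$reactions$case_id %in%
                                             filt$demo$case_id, ,
                                           drop = FALSE])
  ann <- stage("annotate",
               annotate_cohort(kept, config$lists, config$pt_list))
  onset <- stage("onset_records",
                 build_onset_records(kept, ann, config$lists,
                                     config$pt_list, config$convention))
  flow <- dplyr::bind_rows(
    filt$flow,
    tibble::tibble(stage = "aki_cases", n = sum(ann$is_aki)),
    tibble::tibble(stage = "tw_cases", n = sum(ann$pattern != "NONE")),
    tibble::tibble(stage = "aki_tw_cases",
                   n = sum(ann$is_aki & ann$pattern != "NONE")),
    tibble::tibble(stage = "target_cases_with_dates",
                   n = nrow(onset$records))
  )

  rors <- stage("disproportionality",
                ror_table(ann, alpha = config$alpha))
  summary_tabs <- stage("summary", summarize_cohort(ann, kept$reactions,
                                                    config$pt_list))
  wtab <- stage("weibull", weibull_table(onset$records,
                                         zero_policy = config$zero_policy,
                                         alpha = config$alpha))
  mtab <- stage("medians", median_table(onset$records))

  rec <- onset$records
  ordered <- rec[!rec$simultaneous, , drop = FALSE]
  count_groups <- split(ordered$duration_days,
                        c("single", "double", "triple")[ordered$n_tw])
  pw_count <- if (length(count_groups) >= 2) {
    pairwise_onset_comparison(count_groups, alpha = config$alpha)
  } else NULL
  single_groups <- split(rec$duration_days[rec$n_tw == 1],
                         rec$pattern[rec$n_tw == 1])
  single_groups <- single_groups[lengths(single_groups) > 0]
  pw_single <- if (length(single_groups) >= 2) {
    pairwise_onset_comparison(single_groups, alpha = config$alpha)
  } else NULL

  curves <- purrr::imap(
    count_groups[lengths(count_groups) > 0],
    function(d, g) {
      cv <- incidence_curve(d)
      tibble::tibble(group = g, time = cv$time, incidence = cv$incidence)
    }
  ) |> dplyr::bind_rows()

  manifest <- list(
    package = "twaki",
    version = as.character(utils::packageVersion("twaki")),
    seed = config$seed,
    convention = config$convention,
    zero_policy = config$zero_policy,
    alpha = config$alpha,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_cases_input = nrow(tables$demo),
    n_orphans = nrow(cases$orphans)
  )

  out <- function(name) file.path(config$out_dir, name)
  readr::write_csv(flow, out("flow_report.csv"))
  readr::write_csv(format_ror_table(rors), out("ror_table.csv"))
  readr::write_csv(summary_tabs$characteristics, out("cohort_summary.csv"))
  readr::write_csv(summary_tabs$patterns, out("pattern_counts.csv"))
  readr::write_csv(format_weibull_table(wtab), out("weibull_table.csv"))
  readr::write_csv(mtab, out("median_table.csv"))
  if (!is.null(pw_count)) readr::write_csv(pw_count, out("pairwise_count.csv"))
  if (!is.null(pw_single)) {
    readr::write_csv(pw_single, out("pairwise_single.csv"))
  }
  readr::write_csv(curves, out("incidence_curves.csv"))
  readr::write_csv(onset$exclusions, out("onset_exclusions.csv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    flow = flow, ror_table = rors, summary = summary_tabs,
    weibull_table = wtab, median_table = mtab,
    pairwise_count = pw_count, pairwise_single = pw_single,
    curves = curves, onset = onset, annotations = ann,
    manifest = manifest, out_dir = config$out_dir
  ))
}

# Fixed decimal formatting for the diffable CSVs: ratios and shapes to two
# decimals alongside the full-precision columns.
format_ror_table <- function(rors) {
  rors$crude_fmt <- sprintf("%.2f [%.2f-%.2f]", rors$crude_ror,
                            rors$crude_low, rors$crude_high)
  rors$adj_fmt <- ifelse(
    is.na(rors$adj_ror), "",
    sprintf("%.2f [%.2f-%.2f]", rors$adj_ror, rors$adj_low, rors$adj_high)
  )
  rors
}

format_weibull_table <- function(wtab) {
  wtab$shape_fmt <- ifelse(
    is.na(wtab$shape), "",
    sprintf("%.2f [%.2f-%.2f]", wtab$shape, wtab$ci_low, wtab$ci_high)
  )
  wtab
}
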