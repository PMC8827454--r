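#' Table dialect for JADER-style delimited files
#'
#' A dialect bundles everything needed to read one release format: the field
#' delimiter, the text encoding (real JADER releases are Shift-JIS, not
#' UTF-8), and a header mapping that binds source column names to the
#' package's schema fields. Columns not named in the mapping are ignored.
#'
#' @param delim Field delimiter, default `","`.
#' @param encoding Text encoding name passed to the reader, default `"UTF-8"`.
#' @param col_map Named list of character vectors, one element per schema
#'   (`demo`, `drug`, `reac`), each mapping schema field name -> source
#'   column name. Fields omitted fall back to the defaults.
#' @return An object of class `jader_dialect`.
#' @export
#' @examples
#' d <- jader_dialect(delim = "\t", encoding = "UTF-8")
#' d$col_map$demo
jader_dialect <- function(delim = ",", encoding = "UTF-8", col_map = NULL) {
  default_map <- list(
    demo = c(case_id = "case_id", sex = "sex", age_band = "age",
             report_year = "report_year"),
    drug = c(case_id = "case_id", drug_name = "drug_name",
             involvement = "involvement", route = "route",
             start_date = "start_date"),
    reac = c(case_id = "case_id", pt = "pt", onset_date = "onset_date",
             outcome = "outcome")
  )
  if (!is.null(col_map)) {
    for (schema in names(col_map)) {
      m <- col_map[[schema]]
      default_map[[schema]][names(m)] <- unname(m)
    }
  }
  structure(list(delim = delim, encoding = encoding, col_map = default_map),
            class = "jader_dialect")
}

# Enum label dictionaries. Anything not listed maps to "unknown".
.sex_levels <- c(
  "m" = "male", "male" = "male", "男性" = "male",
  "f" = "female", "female" = "female", "女性" = "female"
)
.involvement_levels <- c(
  "suspect" = "suspect", "suspect drug" = "suspect",
  "被疑薬" = "suspect",
  "concomitant" = "concomitant", "concomitant drug" = "concomitant",
  "併用薬" = "concomitant",
  "interaction" = "interaction", "相互作用" = "interaction"
)
.outcome_levels <- c(
  "recovered" = "Recovered", "remission" = "Remission",
  "unrecovered" = "Unrecovered", "death" = "Death",
  "with sequelae" = "With sequelae"
)

# Dosage-form keywords that mark a topical route; everything else with a
# non-blank route string is treated as systemic.
default_topical_keywords <- function() {
  c("topical", "ointment", "cream", "gel", "patch", "tape", "plaster",
    "cutaneous", "transdermal", "eye", "ophthalmic", "dermal")
}

map_enum <- function(x, dict) {
  out <- unname(dict[normalize_term(x)])
  out[is.na(out)] <- "unknown"
  out[is.na(x) | !nzchar(trimws(as.character(x)))] <- "unknown"
  out
}

classify_route <- function(x, topical_keywords = default_topical_keywords()) {
  norm <- normalize_term(x)
  blank <- is.na(x) | !nzchar(norm)
  pat <- paste(topical_keywords, collapse = "|")
  topical <- !blank & stringi::stri_detect_regex(norm, pat)
  out <- rep("systemic", length(norm))
  out[topical] <- "topical"
  out[blank] <- "unknown"
  out
}

# Parse dates that may be complete ("2020-05-01", "2020/05/01", "20200501"),
# partial year-month ("2020-05", "202005"), or missing. Returns a list with
# a Date vector (NA unless complete) and an incomplete flag (TRUE only for
# partial year-month values).
parse_report_date <- function(x) {
  x <- as.character(x)
  raw <- ifelse(is.na(x), "", trimws(x))
  compact <- stringi::stri_replace_all_regex(raw, "[-/]", "")
  complete <- stringi::stri_detect_regex(compact, "^\\d{8}$")
  partial <- stringi::stri_detect_regex(compact, "^\\d{6}$")
  date <- rep(as.Date(NA), length(raw))
  if (any(complete)) {
    parsed <- as.Date(compact[complete], format = "%Y%m%d")
    date[complete] <- parsed
  }
  # a complete-looking string that is not a real calendar date stays NA
  list(date = date, incomplete = partial & !complete)
}

format_report_date <- function(date, raw) {
  out <- ifelse(is.na(raw) | !nzchar(raw), "", raw)
  has_date <- !is.na(date)
  out[has_date] <- format(date[has_date], "%Y-%m-%d")
  out
}

#' Read one JADER-style table
#'
#' Reads a delimited DEMO, DRUG, or REAC table using a [jader_dialect()] and
#' returns a normalized tibble. Parsing is header-keyed: column order in the
#' file is irrelevant. Enum values that cannot be mapped become `"unknown"`;
#' dates are parsed to `Date` where complete, and year-month partial dates
#' are retained as raw strings with an `date_incomplete` flag (downstream
#' duration calculations treat them as unknown).
#'
#' @param path Path to the delimited text file.
#' @param schema One of `"demo"`, `"drug"`, `"reac"`.
#' @param dialect A [jader_dialect()].
#' @return A tibble with one row per input row:
#'   * demo: `case_id`, `sex`, `age_band`, `report_year`
#'   * drug: `case_id`, `drug_name`, `involvement`, `route`, `start_date`,
#'     `start_date_raw`, `date_incomplete`
#'   * reac: `case_id`, `pt`, `onset_date`, `onset_date_raw`,
#'     `date_incomplete`, `outcome`
#' @export
read_jader_table <- function(path, schema = c("demo", "drug", "reac"),
                             dialect = jader_dialect()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "twaki_io_error")
  }
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_types = readr::cols(.default = "c"),
    locale = readr::locale(encoding = dialect$encoding),
    progress = FALSE, show_col_types = FALSE
  )
  cmap <- dialect$col_map[[schema]]
  missing_cols <- cmap[!cmap %in% names(raw)]
  if (length(missing_cols)) {
    abort(
      paste0("Missing mandatory column(s) in ", schema, " table: ",
             paste0(missing_cols, " (field '", names(missing_cols), "')",
                    collapse = ", ")),
      class = "twaki_schema_error"
    )
  }
  get <- function(field) raw[[cmap[[field]]]]
  blank_to_unknown <- function(x, unknown = "unknown") {
    x <- as.character(x)
    ifelse(is.na(x) | !nzchar(trimws(x)), unknown, trimws(x))
  }
  switch(schema,
    demo = tibble::tibble(
      case_id = blank_to_unknown(get("case_id"), unknown = ""),
      sex = map_enum(get("sex"), .sex_levels),
      age_band = blank_to_unknown(get("age_band")),
      report_year = suppressWarnings(as.integer(get("report_year")))
    ),
    drug = {
      d <- parse_report_date(get("start_date"))
      tibble::tibble(
        case_id = blank_to_unknown(get("case_id"), unknown = ""),
        drug_name = blank_to_unknown(get("drug_name"), unknown = ""),
        involvement = map_enum(get("involvement"), .involvement_levels),
        route = classify_route(get("route")),
        start_date = d$date,
        start_date_raw = ifelse(is.na(get("start_date")), "",
                                trimws(get("start_date"))),
        date_incomplete = d$incomplete
      )
    },
    reac = {
      d <- parse_report_date(get("onset_date"))
      tibble::tibble(
        case_id = blank_to_unknown(get("case_id"), unknown = ""),
        pt = blank_to_unknown(get("pt"), unknown = ""),
        onset_date = d$date,
        onset_date_raw = ifelse(is.na(get("onset_date")), "",
                                trimws(get("onset_date"))),
        date_incomplete = d$incomplete,
        outcome = map_enum(get("outcome"), .outcome_levels)
      )
    }
  )
}

#' Write a normalized table back to disk
#'
#' Emits a table read by [read_jader_table()] using the same dialect, so
#' that re-reading yields identical records (round-trip property).
#'
#' @param records Tibble produced by [read_jader_table()].
#' @param path Output path.
#' @param schema One of `"demo"`, `"drug"`, `"reac"`.
#' @param dialect A [jader_dialect()].
#' @return `path`, invisibly.
#' @export
write_jader_table <- function(records, path, schema = c("demo", "drug", "reac"),
                              dialect = jader_dialect()) {
  schema <- match.arg(schema)
  cmap <- dialect$col_map[[schema]]
  out <- switch(schema,
    demo = tibble::tibble(
      case_id = records$case_id, sex = records$sex,
      age_band = records$age_band, report_year = records$report_year
    ),
    drug = tibble::tibble(
      case_id = records$case_id, drug_name = records$drug_name,
      involvement = records$involvement, route = records$route,
      start_date = records$start_date_raw
    ),
    reac = tibble::tibble(
      case_id = records$case_id, pt = records$pt,
      onset_date = records$onset_date_raw, outcome = records$outcome
    )
  )
  names(out) <- unname(cmap[names(out)])
  readr::write_delim(out, path, delim = dialect$delim, na = "")
  invisible(path)
}

#' Join DEMO, DRUG, and REAC tables into a case collection
#'
#' Produces one case per distinct DEMO `case_id`. Drug or reaction rows
#' whose `case_id` does not appear in DEMO are collected into an orphan
#' report rather than silently dropped.
#'
#' @param demo,drug,reac Tibbles from [read_jader_table()]. `drug` and
#'   `reac` may be `NULL` or empty.
#' @return An object of class `jader_cases`: a list with elements `demo`,
#'   `drugs`, `reactions` (orphans removed), and `orphans` (a tibble with
#'   columns `table`, `case_id`).
#' @export
join_cases <- function(demo, drug = NULL, reac = NULL) {
  drug <- drug %||% tibble::tibble(case_id = character())
  reac <- reac %||% tibble::tibble(case_id = character())
  dup <- unique(demo$case_id[duplicated(demo$case_id)])
  if (length(dup)) {
    abort(
      paste0("Duplicate case_id in demo table: ",
             paste(head(dup, 10L), collapse = ", "),
             if (length(dup) > 10L) " ..."),
      class = "twaki_validation_error"
    )
  }
  known <- demo$case_id
  orphans <- dplyr::bind_rows(
    tibble::tibble(table = "drug",
                   case_id = drug$case_id[!drug$case_id %in% known]),
    tibble::tibble(table = "reac",
                   case_id = reac$case_id[!reac$case_id %in% known])
  )
  structure(
    list(
      demo = demo,
      drugs = drug[drug$case_id %in% known, , drop = FALSE],
      reactions = reac[reac$case_id %in% known, , drop = FALSE],
      orphans = orphans
    ),
    class = "jader_cases"
  )
}

#' @export
print.jader_cases <- function(x, ...) {
  cat("<jader_cases> ", nrow(x$demo), " cases, ", nrow(x$drugs),
      " drug rows, ", nrow(x$reactions), " reaction rows, ",
      nrow(x$orphans), " orphan rows\n", sep = "")
  invisible(x)
}

#' Read a deposited time-to-onset dataset
#'
#' Reads a per-case duration dataset of the layout used for deposited
#' time-until-AKI-onset data (one row per target case: case id, Triple
#' Whammy combination pattern, start-order or last-started class, duration
#' in days). Accepts CSV/TSV, or XLSX when the `readxl` package is
#' installed. Column matching is tolerant of header wording.
#'
#' @param path Path to the dataset.
#' @return A tibble with columns `case_id`, `pattern` (one of R, D, N, RD,
#'   RN, DN, RDN), `last_class` (R/D/N or NA), `duration_days`.
#' @export
read_onset_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Onset dataset not found: ", path), class = "twaki_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading XLSX requires the 'readxl' package.",
            class = "twaki_io_error")
    }
    readxl::read_excel(path)
  } else {
    delim <- if (ext == "tsv") "\t" else ","
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE)
  }
  nm <- normalize_term(names(raw))
  find_col <- function(pattern, required = TRUE) {
    hit <- which(stringi::stri_detect_regex(nm, pattern))
    if (!length(hit)) {
      if (required) {
        abort(paste0("Could not locate a column matching /", pattern,
                     "/ in ", path), class = "twaki_schema_error")
      }
      return(NA_integer_)
    }
    hit[[1L]]
  }
  id_col <- find_col("case|id", required = FALSE)
  pat_col <- find_col("pattern|combination|group")
  dur_col <- find_col("duration|day|time")
  last_col <- find_col("order|last|added", required = FALSE)
  canon_pattern <- function(x) {
    x <- toupper(normalize_term(x))
    x <- stringi::stri_replace_all_regex(x, "[^A-Z]", "")
    # accept either letter codes (RDN) or spelled-out class words
    spelled <- stringi::stri_replace_all_fixed(x, "RASIS", "R")
    spelled <- stringi::stri_replace_all_fixed(spelled, "RASI", "R")
    spelled <- stringi::stri_replace_all_fixed(spelled, "DIURETICS", "D")
    spelled <- stringi::stri_replace_all_fixed(spelled, "DIURETIC", "D")
    spelled <- stringi::stri_replace_all_fixed(spelled, "NSAIDS", "N")
    spelled <- stringi::stri_replace_all_fixed(spelled, "NSAID", "N")
    sorted <- vapply(stringi::stri_split_boundaries(spelled, type = "character"),
                     function(ch) {
                       ch <- intersect(c("R", "D", "N"), ch)
                       paste(ch, collapse = "")
                     }, character(1))
    sorted
  }
  tibble::tibble(
    case_id = if (is.na(id_col)) as.character(seq_len(nrow(raw)))
              else as.character(raw[[id_col]]),
    pattern = canon_pattern(raw[[pat_col]]),
    last_class = if (is.na(last_col)) NA_character_
                 else canon_pattern(raw[[last_col]]),
    duration_days = suppressWarnings(as.numeric(raw[[dur_col]]))
  )
}
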