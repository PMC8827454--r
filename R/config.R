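#' Drug definition lists for Triple Whammy classification
#'
#' Bundles the name sets that drive exposure classification: RASIs
#' (ACE inhibitors, ARBs, renin inhibitors), diuretics, NSAIDs, AKI-risk
#' drugs used as a confounding covariate, and aspirin names. Matching is
#' exact after normalization (trim, case-fold, width-unification) — brand
#' name coverage is the responsibility of the supplied lists. Aspirin is
#' never counted as an NSAID (it is typically given in low antiplatelet
#' doses), so any aspirin name present in `nsaid` is removed at
#' construction.
#'
#' @param rasi,diuretic,nsaid,aki_risk Character vectors of drug names.
#' @param aspirin_names Names to exclude from the NSAID class.
#' @return An object of class `drug_lists` with normalized name sets.
#' @seealso [default_drug_lists()] for the shipped defaults.
#' @export
drug_lists <- function(rasi, diuretic, nsaid, aki_risk = character(),
                       aspirin_names = c("aspirin", "acetylsalicylic acid")) {
  norm_set <- function(x) unique(normalize_term(x[nzchar(trimws(x))]))
  aspirin <- norm_set(aspirin_names)
  nsaid <- setdiff(norm_set(nsaid), aspirin)
  structure(
    list(
      rasi = norm_set(rasi),
      diuretic = norm_set(diuretic),
      nsaid = nsaid,
      aki_risk = norm_set(aki_risk),
      aspirin_names = aspirin
    ),
    class = "drug_lists"
  )
}

#' @export
print.drug_lists <- function(x, ...) {
  cat("<drug_lists> RASI:", length(x$rasi), "| diuretic:", length(x$diuretic),
      "| NSAID:", length(x$nsaid), "| AKI-risk:", length(x$aki_risk), "\n")
  invisible(x)
}

#' Load drug lists from a YAML or JSON config file
#'
#' The file must contain top-level keys `rasi`, `diuretic`, `nsaid`, and
#' optionally `aki_risk` and `aspirin_names`, each a list of names.
#'
#' @param path Path to the YAML/JSON file.
#' @return A [drug_lists()] object.
#' @export
read_drug_lists <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("rasi", "diuretic", "nsaid")) {
    if (is.null(cfg[[key]])) {
      abort(paste0("Drug list config is missing key '", key, "'"),
            class = "twaki_config_error")
    }
  }
  drug_lists(
    rasi = unlist(cfg$rasi), diuretic = unlist(cfg$diuretic),
    nsaid = unlist(cfg$nsaid), aki_risk = unlist(cfg$aki_risk %||% character()),
    aspirin_names = unlist(cfg$aspirin_names %||%
                             c("aspirin", "acetylsalicylic acid"))
  )
}

#' Default Triple Whammy drug lists
#'
#' Editable defaults loaded from the package's bundled YAML config: generic
#' names for common RASIs (ACE inhibitors, ARBs, a renin inhibitor),
#' diuretics (loop, thiazide and related, potassium-sparing, vasopressin
#' V2 antagonist), systemically used NSAIDs including COX-2 inhibitors,
#' and the AKI-risk covariate drugs (antivirals, vancomycin, piperacillin-
#' tazobactam, famotidine, levofloxacin, proton pump inhibitors,
#' aminoglycosides, eldecalcitol, edaravone).
#'
#' @return A [drug_lists()] object.
#' @export
default_drug_lists <- function() {
  read_drug_lists(system.file("extdata", "tw_drug_lists.yaml",
                              package = "twaki", mustWork = TRUE))
}

#' Default MedDRA Preferred Term list for AKI identification
#'
#' A configurable Preferred Term list in the style of the standardized
#' query for acute renal failure. It is a plain-text default shipped with
#' the package, intended to be replaced by the user's licensed MedDRA SMQ
#' export for production analyses.
#'
#' @return Character vector of Preferred Terms.
#' @export
default_aki_pts <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "aki_pt_list.yaml",
                                     package = "twaki", mustWork = TRUE))
  unlist(cfg$aki_pts)
}

# Decoy (non-AKI) Preferred Terms used by the synthetic generator.
default_decoy_pts <- function() {
  c("Nausea", "Rash", "Headache", "Interstitial lung disease",
    "Hepatic function abnormal", "Diarrhoea", "Pyrexia", "Dizziness",
    "Thrombocytopenia", "Stevens-Johnson syndrome")
}
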