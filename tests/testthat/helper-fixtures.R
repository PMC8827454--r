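# Small in-code fixtures shared across test files.

tiny_lists <- function() {
  drug_lists(
    rasi = c("enalapril", "losartan"),
    diuretic = c("furosemide", "spironolactone"),
    nsaid = c("loxoprofen", "diclofenac", "ibuprofen", "aspirin"),
    aki_risk = c("vancomycin", "famotidine")
  )
}

tiny_pts <- function() c("Acute kidney injury", "Renal failure")

# Write a demo/drug/reac CSV trio to a temp dir; returns the paths.
write_tiny_db <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  demo <- data.frame(
    case_id = c("A", "B", "C"),
    sex = c("M", "F", ""),
    age = c("20s", "70s", "10s"),
    report_year = c(2015L, 2018L, 2020L)
  )
  drug <- data.frame(
    case_id = c("A", "A", "B", "Z"),
    drug_name = c("Enalapril", "loxoprofen", "furosemide", "ibuprofen"),
    involvement = c("suspect drug", "concomitant drug", "interaction", "suspect drug"),
    route = c("oral", "oral", "injection", "topical gel"),
    start_date = c("2020-01-01", "2020-01-10", "2020-02", "")
  )
  reac <- data.frame(
    case_id = c("A", "B", "C", "Q"),
    pt = c("Acute kidney injury", "Nausea", "Renal failure", "Rash"),
    onset_date = c("2020-01-15", "2020-03-01", "", "2020-04-01"),
    outcome = c("Recovered", "Death", "", "Remission")
  )
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"))
  utils::write.csv(demo, paths$demo, row.names = FALSE, na = "")
  utils::write.csv(drug, paths$drug, row.names = FALSE, na = "")
  utils::write.csv(reac, paths$reac, row.names = FALSE, na = "")
  paths
}

# Minimal annotation tibble for disproportionality tests.
make_annotations <- function(n, pattern, is_aki, seed = 1) {
  set.seed(seed)
  pat <- factor(pattern, levels = c("NONE", "R", "D", "N", "RD",
                                    "RN", "DN", "RDN"))
  tibble::tibble(
    case_id = sprintf("S%06d", seq_len(n)),
    is_aki = is_aki,
    pattern = pat,
    uses_rasi = grepl("R", as.character(pat)) & pat != "NONE",
    uses_diuretic = grepl("D", as.character(pat)) & pat != "NONE",
    uses_nsaid = grepl("N", as.character(pat)) & pat != "NONE",
    sex_male = sample(c(TRUE, FALSE), n, replace = TRUE),
    elderly_70 = sample(c(TRUE, FALSE), n, replace = TRUE),
    uses_aki_risk = sample(c(TRUE, FALSE), n, replace = TRUE),
    report_year = sample(2004:2020, n, replace = TRUE)
  )
}

# Independent Gehan oracles: brute-force cross-pair statistic, and an
# exhaustive permutation p-value (only feasible for small pooled samples).
gehan_oracle_W <- function(a, b) {
  W <- 0
  for (x in a) for (y in b) W <- W + sign(y - x)
  W
}

gehan_oracle_p <- function(a, b) {
  pool <- c(a, b)
  N <- length(pool)
  stopifnot(N <= 14)
  W <- gehan_oracle_W(a, b)
  combs <- utils::combn(N, length(b))
  Wp <- apply(combs, 2, function(ix) gehan_oracle_W(pool[-ix], pool[ix]))
  mean(abs(Wp) >= abs(W) - 1e-9)
}
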