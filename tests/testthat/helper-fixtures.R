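# Shared fixtures: everything is built in code at test time.

# A small four-condition rule set covering the three threshold tiers and an
# exception-based reassignment, written through the real reader so its
# validation runs too.
tiny_rules <- function() {
  txt <- paste(
    "condition,atc_pattern,min_rx_per_year,exception_codes,flag",
    "diabetes,A10,2,,",
    "psychosis,N05A,2,N05AN01,",
    "bipolar,N05AN01,1,,",
    "ppi,A02B,3,,nonspecific",
    sep = "\n"
  )
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(txt, f)
  read_condition_rules(f)
}

make_claims <- function(patient_id, atc_code, dispense_date,
                        n_packages = 1L) {
  data.frame(patient_id = patient_id, atc_code = atc_code,
             dispense_date = as.Date(dispense_date),
             n_packages = n_packages, stringsAsFactors = FALSE)
}

make_cohort <- function(ids, index_date = "2018-01-01", age = 70,
                        sex = "female") {
  data.frame(patient_id = ids, age_at_index = age,
             sex = factor(rep_len(sex, length(ids)),
                          levels = c("female", "male")),
             index_date = as.Date(index_date), stringsAsFactors = FALSE)
}

write_temp_csv <- function(df, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  write_mcds_table(df, f)
  f
}

# Zero-padded profile over the full published condition list, with the
# named conditions switched on.
profile_with <- function(conditions_on, patient_id = "P1") {
  all_cond <- mcds_weights()$condition
  prof <- as.data.frame(as.list(stats::setNames(
    as.integer(all_cond %in% conditions_on), all_cond
  )), check.names = FALSE)
  cbind(data.frame(patient_id = patient_id, stringsAsFactors = FALSE),
        prof)
}

# Brute-force tie-aware AUC over all case-control pairs (the oracle the
# fast implementations are checked against).
auc_brute <- function(score, outcome) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  tot <- 0
  for (x in cases) {
    for (y in controls) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(cases) * length(controls))
}
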