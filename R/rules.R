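# Condition-mapping rule table: ATC patterns -> named chronic conditions,
# with per-rule minimum-prescription thresholds and drug-level exceptions.

#' Read a condition-mapping rule table
#'
#' The mapping file has one row per ATC pattern with columns `condition`,
#' `atc_pattern`, `min_rx_per_year`, `exception_codes` (semicolon-separated
#' full 7-character codes excluded from the rule because they belong to
#' another condition) and `flag` (blank, `nonspecific`, `wrong` or
#' `not_refunded`). Rows flagged `wrong` (drug-condition associations known
#' to be wrong, e.g. antitussives under cancer) are dropped from the active
#' rule set unless `include_flagged = TRUE`.
#'
#' Validation: thresholds outside 1-3 are allowed but warned about (the
#' shipped table uses 2 in general, 1 for disease-specific drugs and 3 for
#' drugs frequent in minor conditions); an ATC pattern claimed by two active
#' conditions must be disambiguated through `exception_codes`, otherwise the
#' read aborts.
#'
#' @param path path to the mapping file; defaults to the table shipped with
#'   the package (a best-effort reconstruction of the published condition
#'   list -- override it with your own file for production use).
#' @param sep field separator.
#' @param include_flagged keep rows flagged `wrong`?
#' @return a `data.frame` of class `mcds_rules`: one row per active pattern,
#'   with `exception_codes` parsed into a list column.
#' @export
read_condition_rules <- function(path = NULL, sep = ",",
                                 include_flagged = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "condition_rules.csv", package = "mcds",
                        mustWork = TRUE)
  }
  dt <- .read_delim(path, sep)
  .require_cols(dt, c("condition", "atc_pattern", "min_rx_per_year"),
                "mapping")
  rules <- data.frame(
    condition = dt$condition,
    atc_pattern = toupper(dt$atc_pattern),
    min_rx_per_year = as.integer(dt$min_rx_per_year),
    flag = if ("flag" %in% names(dt)) {
      ifelse(is.na(dt$flag), "", dt$flag)
    } else "",
    stringsAsFactors = FALSE
  )
  exc <- if ("exception_codes" %in% names(dt)) dt$exception_codes
         else rep(NA_character_, nrow(dt))
  rules$exception_codes <- lapply(exc, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else toupper(strsplit(x, ";", fixed = TRUE)[[1]])
  })
  if (any(is.na(rules$min_rx_per_year) | rules$min_rx_per_year < 1L)) {
    stop("min_rx_per_year must be a positive integer", call. = FALSE)
  }
  if (any(rules$min_rx_per_year > 3L)) {
    warning("min_rx_per_year above 3 is unusual; the published thresholds ",
            "are 1, 2 or 3", call. = FALSE)
  }
  if (!include_flagged) rules <- rules[rules$flag != "wrong", , drop = FALSE]
  bad <- !atc_valid(rules$atc_pattern) &
    !atc_valid(atc_complete(rules$atc_pattern))
  if (any(bad)) {
    warning("ATC pattern(s) not at a standard hierarchy level: ",
            paste(unique(rules$atc_pattern[bad]), collapse = ", "),
            call. = FALSE)
  }
  .check_rule_overlap(rules)
  rownames(rules) <- NULL
  class(rules) <- c("mcds_rules", "data.frame")
  rules
}

# A pattern claimed by two conditions (one pattern a prefix of the other, or
# identical) is only legal when the finer overlap is listed among the
# coarser rule's exception codes.
.check_rule_overlap <- function(rules) {
  n <- nrow(rules)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (rules$condition[i] == rules$condition[j]) next
      pi <- rules$atc_pattern[i]
      pj <- rules$atc_pattern[j]
      if (!(startsWith(pi, pj) || startsWith(pj, pi))) next
      finer <- if (nchar(pi) >= nchar(pj)) pi else pj
      coarser_exc <- if (nchar(pi) >= nchar(pj)) {
        rules$exception_codes[[j]]
      } else {
        rules$exception_codes[[i]]
      }
      if (!any(startsWith(finer, coarser_exc) |
                 vapply(coarser_exc, startsWith, logical(1), x = finer))) {
        stop("ATC pattern overlap between conditions '", rules$condition[i],
             "' (", pi, ") and '", rules$condition[j], "' (", pj,
             ") without a disambiguating exception code", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Condition metadata for the default M-CDS condition list
#'
#' Returns the candidate chronic conditions the score considers, with a
#' human-readable label, the reference prevalence in the development
#' population (residents aged 50+ of a large Italian healthcare authority),
#' and the reference Cox log-hazard coefficient (0 for conditions not
#' selected into the published weight table). The prevalences and
#' coefficients parameterise the synthetic-cohort simulator.
#'
#' @return a `data.frame` with columns `condition`, `label`, `prevalence`,
#'   `coefficient`.
#' @export
mcds_conditions <- function() {
  x <- read.csv(text = 'condition,label,prevalence
cardio_cerebrovascular,"Cardiovascular and cerebrovascular disease",0.571
respiratory_illness,"Respiratory illness",0.131
exocrine_pancreas_failure,"Exocrine pancreas failure",0.003
cystic_fibrosis,"Cystic fibrosis",0.0000026
tuberculosis,"Tuberculosis",0.001
cancer,"Cancer",0.036
acid_disorders_peptic_ulcer,"Acid related disorders/peptic ulcer",0.248
irritable_colon,"Irritable colon",0.004
liver_disease,"Liver diseases",0.022
chronic_hepatitis,"Chronic hepatitis",0.002
diabetes,"Diabetes",0.098
glaucoma,"Glaucoma",0.067
chronic_renal_disease,"Chronic renal disease",0.001
anaemias,"Anaemias",0.039
bone_diseases,"Bone diseases",0.069
ibd_rheumatologic,"Inflammatory bowel + rheumatologic disease",0.008
pain_inflammation,"Pain and inflammation",0.212
hyperuricemia_gout,"Hyperuricemia/gout",0.067
dermatological_severe,"Dermatological severe",0.019
transplantation,"Transplantation",0.001
hyperlipidaemia,"Hyperlipidaemia",0.25
hiv,"HIV",0.002
hypothyroidism,"Hypothyroidism",0.093
epilepsy,"Epilepsy",0.013
dementia,"Dementia",0.008
parkinson,"Parkinson\'s disease",0.013
depression_anxiety_ocd,"Depression, anxiety, OCD",0.148
bipolar_disorders,"Bipolar disorders",0.002
psychosis,"Psychosis",0.024
multiple_sclerosis,"Multiple sclerosis",0.0004
haemorrhagic_diathesis,"Haemorrhagic diathesis",0.004
allergic_disorders,"Allergic disorders",0.036
addictive_disorders,"Addictive disorders",0.0000026
', stringsAsFactors = FALSE)
  w <- mcds_weights()
  x$coefficient <- w$coefficient[match(x$condition, w$condition)]
  x$coefficient[is.na(x$coefficient)] <- 0
  x
}
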