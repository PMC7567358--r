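# Condition mapper: two years of prescription records -> per-patient binary
# chronic-condition flags, via ATC-prefix matching with per-rule
# minimum-prescription thresholds and drug-level exceptions.

.rule_thresholds <- function(rules) {
  thr <- tapply(rules$min_rx_per_year, rules$condition, function(v) {
    u <- unique(v)
    if (length(u) > 1L) {
      warning("condition with mixed thresholds; using the smallest",
              call. = FALSE)
    }
    min(u)
  })
  # plain named vector (tapply's dim attribute trips up matrix arithmetic),
  # in rule-table condition order
  thr <- thr[unique(rules$condition)]
  stats::setNames(as.vector(thr, mode = "integer"), names(thr))
}

#' Count condition-attributable prescriptions per patient and calendar year
#'
#' A prescription record contributes to a condition when its ATC code starts
#' with one of the condition's patterns and is not listed among the
#' condition's exception codes (full codes reassigned to another condition,
#' e.g. midazolam counted under epilepsy rather than with the other
#' benzodiazepine hypnotics). Records outside the lookback window are
#' ignored. The window must span whole calendar years because thresholds
#' apply per calendar year.
#'
#' @param claims a claims `data.frame` as returned by [read_prescriptions()].
#' @param rules a rule table from [read_condition_rules()].
#' @param window_start,window_end lookback window, half-open
#'   `[start, end)`; both must be January 1st.
#' @return a `data.frame` with columns `patient_id`, `condition`, `year`,
#'   `n_rx` (one row per nonzero count).
#' @export
count_condition_rx <- function(claims, rules,
                               window_start = "2016-01-01",
                               window_end = "2018-01-01") {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (format(window_start, "%m-%d") != "01-01" ||
      format(window_end, "%m-%d") != "01-01") {
    stop("lookback window must span whole calendar years ",
         "(both endpoints on January 1st)", call. = FALSE)
  }
  dt <- data.table::as.data.table(claims)
  dt <- dt[dt$dispense_date >= window_start &
             dt$dispense_date < window_end, ]
  atc <- toupper(dt$atc_code)
  yr <- as.integer(format(dt$dispense_date, "%Y"))
  exc_by_cond <- tapply(rules$exception_codes, rules$condition,
                        function(l) unique(unlist(l)))
  pieces <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    cond <- rules$condition[i]
    hit <- startsWith(atc, rules$atc_pattern[i])
    exc <- exc_by_cond[[cond]]
    if (length(exc)) hit <- hit & !(atc %in% exc)
    if (!any(hit)) next
    pieces[[i]] <- data.table::data.table(
      patient_id = dt$patient_id[hit], condition = cond, year = yr[hit]
    )
  }
  hits <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  if (nrow(hits) == 0L) {
    return(data.frame(patient_id = character(0), condition = character(0),
                      year = integer(0), n_rx = integer(0)))
  }
  counts <- hits[, list(n_rx = .N),
                 by = c("patient_id", "condition", "year")]
  data.table::setDF(counts)
  counts[order(counts$patient_id, counts$condition, counts$year), ,
         drop = FALSE]
}

#' Flag chronic conditions from per-year prescription counts
#'
#' A condition is flagged (`1`) for a patient when the prescription count
#' reaches the rule's `min_rx_per_year` in at least one observation year
#' (the default reading of the per-year thresholds), or -- with
#' `pooled = TRUE` -- when the counts summed over the window reach it.
#' Patients with no qualifying prescriptions get an all-zero profile and
#' stay in the cohort.
#'
#' @param counts output of [count_condition_rx()].
#' @param rules the rule table the counts were produced with.
#' @param patients character vector of all cohort patient ids (defines the
#'   rows of the result; patients absent from `counts` get zeros).
#' @param pooled pool counts across the observation years instead of
#'   requiring the threshold within a single year?
#' @return a `data.frame` of class `mcds_profiles`: `patient_id` plus one
#'   0/1 integer column per condition, in rule-table order.
#' @export
flag_conditions <- function(counts, rules, patients, pooled = FALSE) {
  thr <- .rule_thresholds(rules)
  conditions <- names(thr)
  prof <- matrix(0L, nrow = length(patients), ncol = length(conditions),
                 dimnames = list(NULL, conditions))
  if (nrow(counts)) {
    dt <- data.table::as.data.table(counts)
    agg <- if (pooled) {
      dt[, list(n = sum(n_rx)), by = c("patient_id", "condition")]
    } else {
      dt[, list(n = max(n_rx)), by = c("patient_id", "condition")]
    }
    agg <- agg[agg$n >= thr[agg$condition], ]
    ri <- match(agg$patient_id, patients)
    ci <- match(agg$condition, conditions)
    keep <- !is.na(ri) & !is.na(ci)
    prof[cbind(ri[keep], ci[keep])] <- 1L
  }
  out <- data.frame(patient_id = patients, prof, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "conditions") <- conditions
  class(out) <- c("mcds_profiles", "data.frame")
  out
}

#' Build condition profiles from claims in one step
#'
#' Convenience wrapper: [count_condition_rx()] then [flag_conditions()].
#'
#' @inheritParams count_condition_rx
#' @inheritParams flag_conditions
#' @return see [flag_conditions()].
#' @export
mcds_profile <- function(claims, rules = read_condition_rules(), patients,
                         window_start = "2016-01-01",
                         window_end = "2018-01-01", pooled = FALSE) {
  counts <- count_condition_rx(claims, rules, window_start, window_end)
  flag_conditions(counts, rules, patients, pooled = pooled)
}

#' Drop conditions below a prevalence floor
#'
#' Conditions flagged in fewer than `min_cases` patients are removed from
#' the active condition list before model derivation (mirroring the
#' exclusion of conditions that are virtually absent in a population, which
#' would otherwise enter the penalised model with no information).
#'
#' @param profiles an `mcds_profiles` data frame.
#' @param min_cases minimum number of flagged patients for a condition to
#'   stay active (default 2).
#' @return a list with `profiles` (reduced), `active` (kept condition
#'   names) and `dropped` (removed condition names).
#' @export
apply_prevalence_floor <- function(profiles, min_cases = 2L) {
  stopifnot(min_cases >= 0)
  conditions <- setdiff(names(profiles), "patient_id")
  n_cases <- vapply(profiles[conditions], function(x) sum(x > 0), integer(1))
  dropped <- conditions[n_cases < min_cases]
  active <- setdiff(conditions, dropped)
  if (!length(active)) {
    stop("prevalence floor removed every condition; check the inputs",
         call. = FALSE)
  }
  if (length(dropped)) {
    message("prevalence floor (min_cases = ", min_cases, ") dropped: ",
            paste(dropped, collapse = ", "))
  }
  out <- profiles[c("patient_id", active)]
  attr(out, "conditions") <- active
  class(out) <- c("mcds_profiles", "data.frame")
  list(profiles = out, active = active, dropped = dropped)
}
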