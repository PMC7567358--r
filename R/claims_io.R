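# Reading, validating and writing the tabular interfaces: pharmacy claims,
# cohort, outcomes, condition-mapping and weight tables. All files are
# delimited text with a header row; dates are ISO-8601 (YYYY-MM-DD) only.

.read_delim <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                    na.strings = c("", "NA"), data.table = TRUE,
                    encoding = "UTF-8")
}

.require_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(what, " file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.apply_schema <- function(dt, schema) {
  if (is.null(schema)) return(dt)
  stopifnot(is.character(schema), !is.null(names(schema)))
  for (std in names(schema)) {
    if (schema[[std]] %in% names(dt)) {
      data.table::setnames(dt, schema[[std]], std)
    }
  }
  dt
}

# Strict ISO-8601 parse: returns NA for anything that is not YYYY-MM-DD.
.parse_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

.report_rejects <- function(dt, bad, reason, strict, what) {
  if (!any(bad)) return(dt)
  lines <- which(bad) + 1L  # header is line 1
  msg <- sprintf("%s: rejected %d row(s) (%s), file lines: %s", what,
                 sum(bad), reason,
                 paste(utils::head(lines, 10L), collapse = ", "))
  if (strict) stop(msg, call. = FALSE)
  warning(msg, call. = FALSE)
  dt[!bad]
}

#' Read a pharmacy-claims file
#'
#' Expects one row per dispensed prescription with columns `patient_id`,
#' `atc_code`, `dispense_date` and optionally `n_packages` (defaulting to 1
#' when the column is absent, since condition flagging counts prescriptions,
#' not packages). Rows with a structurally invalid ATC code or an unparsable
#' date are rejected with a warning naming the file lines (or abort the read
#' in strict mode). No lookback-window filtering happens at read time; that
#' belongs to the condition mapper.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(patient_id = "ID", atc_code = "ATC")`.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @param strict abort on any rejected row instead of warning?
#' @return a `data.frame` with columns `patient_id` (character), `atc_code`
#'   (character, uppercase), `dispense_date` (`Date`), `n_packages`
#'   (integer).
#' @export
read_prescriptions <- function(path, schema = NULL, sep = ",",
                               strict = FALSE) {
  dt <- .apply_schema(.read_delim(path, sep), schema)
  .require_cols(dt, c("patient_id", "atc_code", "dispense_date"), "claims")
  dt[, "atc_code" := toupper(atc_code)]
  bad_atc <- !atc_valid(dt$atc_code)
  dt2 <- .report_rejects(dt, bad_atc, "ATC code does not match the ATC
    structural pattern at its level", strict, "claims")
  date <- .parse_date(dt2$dispense_date)
  dt2 <- .report_rejects(dt2[, "dispense_date" := NULL][, "d" := date],
                         is.na(date), "invalid ISO-8601 dispense_date",
                         strict, "claims")
  n_pack <- if ("n_packages" %in% names(dt2)) {
    suppressWarnings(as.integer(dt2$n_packages))
  } else {
    rep(1L, nrow(dt2))
  }
  n_pack[is.na(n_pack)] <- 1L
  if (any(n_pack < 1L)) stop("n_packages must be positive", call. = FALSE)
  out <- data.frame(patient_id = dt2$patient_id, atc_code = dt2$atc_code,
                    dispense_date = dt2$d, n_packages = n_pack,
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- nrow(dt) - nrow(out)
  out
}

#' Read a cohort file
#'
#' Expects columns `patient_id`, `sex` (`female`/`male`, `f`/`m` accepted),
#' `index_date`, and either `age_at_index` or `birth_year` (age is then
#' computed as index year minus birth year). Patient identifiers must be
#' unique.
#'
#' @inheritParams read_prescriptions
#' @param min_age optional eligibility filter: drop patients younger than
#'   this at index (the score was developed on an age >= 50 population);
#'   `NULL` (default) keeps everyone.
#' @return a `data.frame` with columns `patient_id`, `age_at_index`
#'   (integer), `sex` (factor `female`/`male`), `index_date` (`Date`).
#' @export
read_cohort <- function(path, schema = NULL, sep = ",", min_age = NULL) {
  dt <- .apply_schema(.read_delim(path, sep), schema)
  .require_cols(dt, c("patient_id", "sex", "index_date"), "cohort")
  if (anyDuplicated(dt$patient_id)) {
    stop("cohort file contains duplicated patient_id values", call. = FALSE)
  }
  index_date <- .parse_date(dt$index_date)
  if (anyNA(index_date)) stop("invalid ISO-8601 index_date", call. = FALSE)
  if ("age_at_index" %in% names(dt)) {
    age <- as.integer(dt$age_at_index)
  } else if ("birth_year" %in% names(dt)) {
    age <- as.integer(format(index_date, "%Y")) - as.integer(dt$birth_year)
  } else {
    stop("cohort file needs either age_at_index or birth_year",
         call. = FALSE)
  }
  sex <- tolower(dt$sex)
  sex[sex == "f"] <- "female"
  sex[sex == "m"] <- "male"
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be one of female/male (or f/m)", call. = FALSE)
  }
  out <- data.frame(patient_id = dt$patient_id, age_at_index = age,
                    sex = factor(sex, levels = c("female", "male")),
                    index_date = index_date, stringsAsFactors = FALSE)
  if (!is.null(min_age)) out <- out[out$age_at_index >= min_age, ,
                                    drop = FALSE]
  out
}

#' Read an outcomes file
#'
#' Expects `patient_id` plus optional `death_date` and
#' `hospitalization_date` columns; blank cells mean the event did not occur
#' within follow-up.
#'
#' @inheritParams read_prescriptions
#' @return a `data.frame` with `patient_id`, `death_date`,
#'   `hospitalization_date` (both `Date`, `NA` when absent).
#' @export
read_outcomes <- function(path, schema = NULL, sep = ",") {
  dt <- .apply_schema(.read_delim(path, sep), schema)
  .require_cols(dt, "patient_id", "outcomes")
  grab <- function(col) {
    if (col %in% names(dt)) .parse_date(dt[[col]])
    else as.Date(rep(NA_character_, nrow(dt)))
  }
  data.frame(patient_id = dt$patient_id,
             death_date = grab("death_date"),
             hospitalization_date = grab("hospitalization_date"),
             stringsAsFactors = FALSE)
}

#' Build survival records from cohort and outcomes
#'
#' Converts calendar outcome dates into (time, event) pairs for the one-year
#' mortality analysis. A death strictly after the index date and within
#' `follow_up_days` days yields `event = 1` with `time` the day count from
#' index to death; everyone else is administratively censored at
#' `follow_up_days`. A death on or before the index date is invalid input:
#' the cohort is alive at index by construction.
#'
#' @param cohort a cohort `data.frame` as returned by [read_cohort()].
#' @param outcomes an outcomes `data.frame` as returned by
#'   [read_outcomes()]; every `patient_id` must appear in `cohort`.
#' @param follow_up_days length of follow-up in days (default 365).
#' @param outcome which outcome date to use: `"death"` (default) or
#'   `"hospitalization"` (the secondary outcome reuses identical machinery).
#' @return a `data.frame` with `patient_id`, `time` (integer days), `event`
#'   (0/1), in cohort order.
#' @export
build_survival <- function(cohort, outcomes, follow_up_days = 365L,
                           outcome = c("death", "hospitalization")) {
  outcome <- match.arg(outcome)
  stopifnot(follow_up_days > 0)
  unknown <- setdiff(outcomes$patient_id, cohort$patient_id)
  if (length(unknown)) {
    stop("outcomes reference patient_id(s) absent from the cohort: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  col <- if (outcome == "death") "death_date" else "hospitalization_date"
  idx <- match(cohort$patient_id, outcomes$patient_id)
  edate <- outcomes[[col]][idx]
  days <- as.integer(edate - cohort$index_date)
  if (any(!is.na(days) & days <= 0L)) {
    stop(outcome, " date on or before index_date: subjects must be ",
         "alive and event-free at index", call. = FALSE)
  }
  event <- as.integer(!is.na(days) & days <= follow_up_days)
  time <- ifelse(event == 1L, days, as.integer(follow_up_days))
  data.frame(patient_id = cohort$patient_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Write a claims, cohort, outcomes or scores table
#'
#' Writes comma-delimited UTF-8 with a header row and ISO-8601 dates, the
#' same dialect the readers accept, so write-then-read round-trips exactly.
#'
#' @param x a `data.frame`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_mcds_table <- function(x, path, sep = ",") {
  data.table::fwrite(as.data.frame(x), path, sep = sep, quote = FALSE,
                     dateTimeAs = "ISO", na = "")
  invisible(path)
}
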