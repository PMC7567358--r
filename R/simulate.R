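# Synthetic pharmacy-claims cohort with the statistical structure the score
# assumes: independent condition flags at reference prevalences,
# prescription counts above/below the flagging thresholds, exponential
# proportional-hazards mortality calibrated to a target 1-year rate, and
# administrative censoring at one year.

#' Simulation parameters
#'
#' Defaults emulate the development population: the reference condition
#' prevalences and log-hazard coefficients of [mcds_conditions()], ~2.4%
#' marginal 1-year mortality, age normal (mean 67.5, SD 11.8) truncated at
#' 50, 56.1% female. `occasional_user_fraction` is the probability that a
#' patient *without* a condition still receives sub-threshold prescriptions
#' for it (occasional drug users the thresholds exist to exclude).
#'
#' @param n_patients cohort size.
#' @param conditions `data.frame` with `condition`, `prevalence`,
#'   `coefficient` (default [mcds_conditions()]).
#' @param rules rule table used to emit ATC codes and per-year counts.
#' @param baseline_1yr_mortality target marginal 1-year death probability.
#' @param age_mean,age_sd,age_min age distribution (truncated normal).
#' @param female_fraction probability of female sex.
#' @param occasional_user_fraction see description (default 0.05).
#' @param correlation exchangeable Gaussian-copula correlation between
#'   condition flags (default 0 = independent conditions; real
#'   comorbidities cluster, so positive values are more realistic but
#'   depart from the reference marginal structure).
#' @param follow_up_days administrative censoring horizon.
#' @param index_date follow-up start (ISO date).
#' @param seed integer RNG seed; fixing it fixes every output.
#' @return a list of class `mcds_sim_params`.
#' @export
mcds_sim_params <- function(n_patients = 10000L,
                            conditions = mcds_conditions(),
                            rules = read_condition_rules(),
                            baseline_1yr_mortality = 0.024,
                            age_mean = 67.5, age_sd = 11.8, age_min = 50,
                            female_fraction = 0.561,
                            occasional_user_fraction = 0.05,
                            correlation = 0,
                            follow_up_days = 365L,
                            index_date = "2018-01-01", seed = 1L) {
  stopifnot(n_patients > 0,
            all(conditions$prevalence >= 0, conditions$prevalence <= 1),
            baseline_1yr_mortality > 0, baseline_1yr_mortality < 1,
            female_fraction >= 0, female_fraction <= 1,
            occasional_user_fraction >= 0, occasional_user_fraction <= 1,
            correlation >= 0, correlation < 1)
  missing <- setdiff(conditions$condition, unique(rules$condition))
  if (length(missing)) {
    stop("conditions without mapping rules: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 conditions = conditions, rules = rules,
                 baseline_1yr_mortality = baseline_1yr_mortality,
                 age_mean = age_mean, age_sd = age_sd, age_min = age_min,
                 female_fraction = female_fraction,
                 occasional_user_fraction = occasional_user_fraction,
                 correlation = correlation,
                 follow_up_days = as.integer(follow_up_days),
                 index_date = as.Date(index_date), seed = as.integer(seed)),
            class = "mcds_sim_params")
}

#' Calibrate the baseline hazard to a target 1-year mortality
#'
#' Solves `mean(1 - exp(-h0 * exp(lp) * follow_up_days)) = target` for the
#' constant daily baseline hazard `h0` by monotone root-finding over the
#' simulated linear predictors `lp`. With all-zero linear predictors this
#' reduces to the closed form `-log(1 - target) / follow_up_days`.
#'
#' @param lp numeric vector of linear predictors `beta' x`.
#' @param target target marginal event probability over the horizon.
#' @param follow_up_days horizon in days.
#' @return the baseline hazard per day.
#' @export
calibrate_baseline <- function(lp, target, follow_up_days = 365L) {
  stopifnot(target > 0, target < 1)
  f <- function(h0) mean(1 - exp(-h0 * exp(lp) * follow_up_days)) - target
  lo <- 1e-12
  hi <- 1
  if (f(lo) > 0 || f(hi) < 0) {
    stop("baseline-hazard calibration failed: target mortality ",
         "unreachable for these linear predictors", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Simulate a synthetic pharmacy-claims cohort
#'
#' Draws condition flags independently per condition at the parameterised
#' prevalences; patients with a flag receive, in each of the two lookback
#' years, at least the rule's threshold number of prescriptions (threshold
#' plus a Poisson(1) excess) with ATC codes drawn from the condition's own
#' rule patterns; occasional users (flag off) receive strictly sub-threshold
#' counts in one random year. Survival times are exponential with hazard
#' `h0 * exp(beta' x)`, `h0` calibrated by [calibrate_baseline()], and
#' administratively censored at `follow_up_days`.
#'
#' @param params an [mcds_sim_params()] object.
#' @return a list of class `mcds_sim` with `data.frame`s `claims`,
#'   `cohort`, `outcomes`, `truth` (per-patient flags, linear predictor,
#'   true score, time, event) and the calibrated baseline hazard `h0`.
#' @export
simulate_mcds_cohort <- function(params = mcds_sim_params()) {
  stopifnot(inherits(params, "mcds_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  cond <- params$conditions
  K <- nrow(cond)
  ids <- sprintf("P%07d", seq_len(n))

  flags <- if (params$correlation > 0) {
    # exchangeable Gaussian copula: one shared frailty factor per patient,
    # marginal prevalences preserved exactly
    z <- sqrt(params$correlation) * stats::rnorm(n) +
      sqrt(1 - params$correlation) * matrix(stats::rnorm(n * K), n, K)
    m <- matrix(as.integer(z < rep(stats::qnorm(cond$prevalence),
                                   each = n)),
                nrow = n)
    dimnames(m) <- list(NULL, cond$condition)
    m
  } else {
    matrix(stats::rbinom(n * K, 1L, rep(cond$prevalence, each = n)),
           nrow = n, ncol = K,
           dimnames = list(NULL, cond$condition))
  }

  u <- stats::runif(n, stats::pnorm(params$age_min, params$age_mean,
                                    params$age_sd), 1)
  age <- as.integer(round(stats::qnorm(u, params$age_mean, params$age_sd)))
  sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")

  lp <- drop(flags %*% cond$coefficient)
  h0 <- calibrate_baseline(lp, params$baseline_1yr_mortality,
                           params$follow_up_days)
  t_raw <- stats::rexp(n, rate = h0 * exp(lp))
  day <- pmax(1L, as.integer(ceiling(t_raw)))
  event <- as.integer(day <= params$follow_up_days)
  time <- ifelse(event == 1L, day, params$follow_up_days)

  claims <- .simulate_claims(flags, params)

  cohort <- data.frame(patient_id = ids, age_at_index = age, sex = sex,
                       index_date = params$index_date,
                       stringsAsFactors = FALSE)
  outcomes <- data.frame(
    patient_id = ids,
    death_date = as.Date(ifelse(event == 1L,
                                as.character(params$index_date + time),
                                NA_character_)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(patient_id = ids, flags, lp = lp,
                      true_score = as.integer(
                        flags %*% coefficient_to_weight(cond$coefficient)),
                      time = as.integer(time), event = event,
                      stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(claims = claims, cohort = cohort, outcomes = outcomes,
                 truth = truth, h0 = h0, params = params),
            class = "mcds_sim")
}

# Emit claim rows for flagged patients (threshold-reaching counts in both
# lookback years) and occasional users (sub-threshold count in one year).
.simulate_claims <- function(flags, params) {
  n <- nrow(flags)
  rules <- params$rules
  thr <- .rule_thresholds(rules)[colnames(flags)]
  pat_by_cond <- split(rules$atc_pattern, rules$condition)
  years <- c(2016L, 2017L)

  pieces <- list()
  flagged <- which(flags == 1L, arr.ind = TRUE)
  if (nrow(flagged)) {
    i <- rep(flagged[, 1], times = 2L)
    j <- rep(flagged[, 2], times = 2L)
    yr <- rep(years, each = nrow(flagged))
    cnt <- thr[j] + stats::rpois(length(i), 1)
    pieces$flagged <- data.frame(i = i, j = j, year = yr, count = cnt)
  }
  if (params$occasional_user_fraction > 0) {
    occ_thr <- thr[col(flags)]
    occ <- which(flags == 0L &
                   matrix(stats::runif(length(flags)) <
                            params$occasional_user_fraction,
                          nrow = n) &
                   occ_thr > 1L, arr.ind = TRUE)
    if (nrow(occ)) {
      tj <- thr[occ[, 2]]
      cnt <- 1L + as.integer(floor(stats::runif(nrow(occ)) * (tj - 1L)))
      pieces$occ <- data.frame(i = occ[, 1], j = occ[, 2],
                               year = sample(years, nrow(occ),
                                             replace = TRUE),
                               count = cnt)
    }
  }
  if (!length(pieces)) {
    return(data.frame(patient_id = character(0), atc_code = character(0),
                      dispense_date = as.Date(character(0)),
                      n_packages = integer(0)))
  }
  grp <- do.call(rbind, pieces)
  condname <- colnames(flags)[grp$j]
  np <- lengths(pat_by_cond)
  offset <- cumsum(c(0L, np))[match(condname, names(pat_by_cond))]
  pick <- offset + 1L + as.integer(floor(stats::runif(nrow(grp)) *
                                           np[condname]))
  pats <- unlist(pat_by_cond, use.names = FALSE)[pick]
  codes <- atc_complete(unique(pats))[match(pats, unique(pats))]
  rows <- rep(seq_len(nrow(grp)), times = grp$count)
  year <- grp$year[rows]
  date <- as.Date(paste0(year, "-01-01")) +
    as.integer(floor(stats::runif(length(rows)) * 365))
  out <- data.frame(
    patient_id = sprintf("P%07d", grp$i[rows]),
    atc_code = codes[rows],
    dispense_date = date,
    n_packages = 1L,
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$dispense_date, out$atc_code), ,
      drop = FALSE]
}

#' @export
print.mcds_sim <- function(x, ...) {
  cat("Synthetic claims cohort:", nrow(x$cohort), "patients,",
      nrow(x$claims), "claims,", sum(x$truth$event), "deaths (",
      sprintf("%.2f%%", 100 * mean(x$truth$event)), ")\n")
  cat(sprintf("  calibrated baseline hazard: %.3g/day\n", x$h0))
  invisible(x)
}
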