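# Discriminative-performance validation: tie-aware Mann-Whitney AUC,
# DeLong variance for confidence intervals and paired AUC comparison,
# Kaplan-Meier curves per risk class and the k-sample log-rank test.

# Placement values (DeLong's structural components). For every case, the
# fraction of controls it outranks (ties count half), and vice versa.
# Computed via sorted lookups in O((m + n) log(m + n)).
.placements <- function(cases, controls) {
  sc <- sort(controls)
  less <- findInterval(cases, sc, left.open = TRUE)
  leq <- findInterval(cases, sc)
  v10 <- (less + 0.5 * (leq - less)) / length(controls)
  sx <- sort(cases)
  gt <- length(cases) - findInterval(controls, sx)
  geq <- length(cases) - findInterval(controls, sx, left.open = TRUE)
  v01 <- (gt + 0.5 * (geq - gt)) / length(cases)
  list(v10 = v10, v01 = v01)
}

.split_by_outcome <- function(score, outcome) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  list(cases = score[outcome == 1L], controls = score[outcome == 0L])
}

#' Area under the ROC curve (c-statistic)
#'
#' The tie-aware Mann-Whitney form: the probability that a randomly chosen
#' case outranks a randomly chosen control, ties counting one half,
#' averaged over all case-control pairs. Equals the trapezoidal integral of
#' the empirical ROC curve.
#'
#' @param score numeric prognostic score (higher = higher risk).
#' @param outcome binary outcome (1 = event).
#' @return the AUC, a number in \[0, 1\].
#' @examples
#' mcds_auc(c(3, 2, 1, 2), c(1, 1, 0, 0))  # 0.625
#' @export
mcds_auc <- function(score, outcome) {
  s <- .split_by_outcome(score, outcome)
  p <- .placements(s$cases, s$controls)
  mean(p$v10)
}

#' AUC with a DeLong confidence interval
#'
#' Nonparametric (DeLong) variance of the AUC from the placement values,
#' with a normal-approximation confidence interval truncated to \[0, 1\].
#' With a degenerate variance of 0 at an AUC of exactly 0 or 1 the interval
#' collapses to the point estimate, with a warning.
#'
#' @inheritParams mcds_auc
#' @param level confidence level (default 0.95).
#' @return a list of class `mcds_roc`: `auc`, `ci_low`, `ci_high`, `var`,
#'   `n_pos`, `n_neg`, `level`.
#' @export
auc_ci_delong <- function(score, outcome, level = 0.95) {
  s <- .split_by_outcome(score, outcome)
  m <- length(s$cases)
  n <- length(s$controls)
  if (m < 2L || n < 2L) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  p <- .placements(s$cases, s$controls)
  auc <- mean(p$v10)
  v <- stats::var(p$v10) / m + stats::var(p$v01) / n
  if (v == 0 && auc %in% c(0, 1)) {
    warning("degenerate AUC variance: confidence interval collapses to ",
            "the point estimate", call. = FALSE)
    lo <- hi <- auc
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * sqrt(v))
    hi <- min(1, auc + z * sqrt(v))
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi, var = v,
                 n_pos = m, n_neg = n, level = level),
            class = "mcds_roc")
}

#' @export
print.mcds_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f; %d%% CI [%.3f-%.3f] (%d cases, %d controls)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares two prognostic scores measured on the same patients against the
#' same outcome. The statistic is the squared standardised AUC difference
#' (DeLong's z squared), referred to a chi-square distribution with 1
#' degree of freedom. Scores that are monotone transforms of one another
#' have identical ROC curves and give a statistic of exactly 0.
#'
#' @param score_a,score_b the two scores, aligned to the same patients.
#' @inheritParams mcds_auc
#' @return a list: `auc_a`, `auc_b`, `chi_square`, `df`, `p`.
#' @export
compare_auc_paired <- function(score_a, score_b, outcome) {
  stopifnot(length(score_a) == length(score_b))
  sa <- .split_by_outcome(score_a, outcome)
  sb <- .split_by_outcome(score_b, outcome)
  m <- length(sa$cases)
  n <- length(sa$controls)
  if (m < 2L || n < 2L) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  pa <- .placements(sa$cases, sa$controls)
  pb <- .placements(sb$cases, sb$controls)
  d <- mean(pa$v10) - mean(pb$v10)
  v <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n
  if (v <= .Machine$double.eps) {
    chi <- 0
    p <- 1
  } else {
    chi <- d^2 / v
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  list(auc_a = mean(pa$v10), auc_b = mean(pb$v10), chi_square = chi,
       df = 1L, p = p)
}

#' Kaplan-Meier curves per risk class
#'
#' Product-limit survival estimates within each risk class.
#'
#' @param survival a `data.frame` with `time` and `event`.
#' @param classes per-patient class labels (each class nonempty).
#' @return a `data.frame` with `class`, `time`, `n_risk`, `n_event`,
#'   `surv`; the underlying `survfit` object is attached as attribute
#'   `"survfit"`.
#' @export
km_by_class <- function(survival, classes) {
  stopifnot(nrow(survival) == length(classes))
  cl <- factor(classes)
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ cl
  )
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) {
    # single stratum, or no event rows at all (all-censored data)
    rep(levels(cl)[1], length(sm$time))
  } else {
    sub("^cl=", "", as.character(sm$strata))
  }
  out <- data.frame(class = as.character(strata),
                    time = as.numeric(sm$time),
                    n_risk = as.numeric(sm$n.risk),
                    n_event = as.numeric(sm$n.event),
                    surv = as.numeric(sm$surv),
                    stringsAsFactors = FALSE)
  attr(out, "survfit") <- fit
  out
}

#' Survival probability at a time point, per class
#'
#' @inheritParams km_by_class
#' @param t time point (default 365 days).
#' @return named numeric vector of Kaplan-Meier estimates at `t` (1 when a
#'   class has no event up to `t`).
#' @export
km_survival_at <- function(survival, classes, t = 365) {
  tab <- km_by_class(survival, classes)
  cls <- sort(unique(as.character(classes)))
  out <- vapply(cls, function(k) {
    rows <- tab[tab$class == k & tab$time <= t & tab$n_event > 0, ]
    if (nrow(rows) == 0L) 1 else min(rows$surv)
  }, numeric(1))
  out
}

#' K-sample log-rank test across risk classes
#'
#' @inheritParams km_by_class
#' @return a list: `chi_square`, `df` (k - 1), `p`.
#' @export
logrank <- function(survival, classes) {
  cl <- factor(classes)
  if (nlevels(cl) < 2L) stop("need at least 2 classes", call. = FALSE)
  fit <- survival::survdiff(
    survival::Surv(survival$time, survival$event) ~ cl
  )
  df <- nlevels(cl) - 1L
  list(chi_square = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Validate a prognostic score against 1-year survival
#'
#' One-stop report: AUC with DeLong CI for the score, Kaplan-Meier
#' survival and the log-rank test across risk classes, and paired DeLong
#' comparisons against any competing scores (e.g. a diagnosis-based
#' comorbidity index supplied as a pre-computed numeric column).
#'
#' @param score numeric score vector.
#' @param survival a `data.frame` with `time` and `event`, aligned to
#'   `score`.
#' @param scheme an [mcds_scheme()] used to form risk classes (set to
#'   `NULL` to skip the class-based analyses).
#' @param compare optional named list of competing score vectors.
#' @param level confidence level.
#' @return a list of class `mcds_validation`: `roc`, `km` (survival at the
#'   last follow-up day per class), `logrank`, `comparisons`.
#' @export
mcds_validate <- function(score, survival, scheme = mcds_scheme(),
                          compare = NULL, level = 0.95) {
  out <- list(roc = auc_ci_delong(score, survival$event, level = level))
  if (!is.null(scheme)) {
    classes <- assign_class(score, scheme)
    out$km <- km_survival_at(survival, classes, t = max(survival$time))
    if (length(unique(classes)) >= 2L) {
      out$logrank <- logrank(survival, classes)
    }
  }
  if (!is.null(compare)) {
    out$comparisons <- lapply(compare, function(other) {
      cmp <- compare_auc_paired(score, other, survival$event)
      cmp$roc_other <- auc_ci_delong(other, survival$event, level = level)
      cmp
    })
  }
  class(out) <- "mcds_validation"
  out
}

#' @export
print.mcds_validation <- function(x, ...) {
  cat("M-CDS validation\n  ")
  print(x$roc)
  if (!is.null(x$km)) {
    cat("  KM survival at end of follow-up by class:\n")
    cat("   ", paste(sprintf("%s: %.3f", names(x$km), x$km),
                     collapse = "  "), "\n")
  }
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank chi-square = %.1f (df = %d), p %s\n",
                x$logrank$chi_square, x$logrank$df,
                format.pval(x$logrank$p, digits = 3)))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  vs %s: AUC %.3f vs %.3f, chi-square = %.2f, p %s\n",
                nm, cmp$auc_a, cmp$auc_b, cmp$chi_square,
                format.pval(cmp$p, digits = 3)))
  }
  invisible(x)
}
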