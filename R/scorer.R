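# Scoring: published integer weights, the coefficient-to-weight transform,
# the 6-class stratification scheme, and the `mcds` scorer object.

#' Transform Cox coefficients to integer score weights
#'
#' The score weight of a condition is its Cox log-hazard coefficient
#' multiplied by 10 and rounded to the nearest integer, halves away from
#' zero (so 0.25 -> 3, not the banker's 2). Negative coefficients transform
#' fine but are flagged with a warning: the published table has none, and a
#' protective "comorbidity" deserves a second look.
#'
#' @param beta numeric vector of Cox coefficients (finite).
#' @return integer vector of weights.
#' @examples
#' coefficient_to_weight(c(1.039, 0.689, 0.082))
#' @export
coefficient_to_weight <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop("beta must be finite numeric", call. = FALSE)
  }
  if (any(beta < 0)) {
    warning("negative coefficient(s): the resulting weights are negative",
            call. = FALSE)
  }
  as.integer(sign(beta) * floor(abs(10 * beta) + 0.5))
}

#' The published M-CDS weight table
#'
#' Reads a weight table (columns `condition`, `coefficient`, `weight`);
#' by default the 18-condition table shipped with the package. Weights are
#' recomputed from the coefficients on load and cross-checked against the
#' `weight` column; a mismatch aborts.
#'
#' @param path optional path to an alternative weight file.
#' @param sep field separator.
#' @return a `data.frame` with `condition`, `coefficient`, `weight`.
#' @export
mcds_weights <- function(path = NULL, sep = ",") {
  if (is.null(path)) {
    path <- system.file("extdata", "mcds_weights.csv", package = "mcds",
                        mustWork = TRUE)
  }
  dt <- .read_delim(path, sep)
  .require_cols(dt, c("condition", "coefficient"), "weights")
  w <- data.frame(condition = dt$condition,
                  coefficient = as.numeric(dt$coefficient),
                  stringsAsFactors = FALSE)
  w$weight <- coefficient_to_weight(w$coefficient)
  if ("weight" %in% names(dt)) {
    stated <- as.integer(dt$weight)
    if (!identical(stated, w$weight)) {
      stop("weight column disagrees with round(10 * coefficient) for: ",
           paste(w$condition[stated != w$weight], collapse = ", "),
           call. = FALSE)
    }
  }
  w
}

#' Integer score stratification scheme
#'
#' An ordered, exhaustive, non-overlapping partition of the nonnegative
#' integers into risk classes, represented by the lower bound of each
#' class. The default is the published 6-class scheme:
#' <=1, 2, 3-4, 5-6, 7-9, >=10.
#'
#' @param lowers increasing integer vector of class lower bounds; the first
#'   must be 0.
#' @return an object of class `mcds_scheme`.
#' @export
mcds_scheme <- function(lowers = c(0L, 2L, 3L, 5L, 7L, 10L)) {
  lowers <- as.integer(lowers)
  stopifnot(length(lowers) >= 1L, lowers[1] == 0L,
            !is.unsorted(lowers, strictly = TRUE))
  uppers <- c(lowers[-1] - 1L, Inf)
  labels <- ifelse(is.infinite(uppers), paste0(">=", lowers),
                   ifelse(lowers == uppers, as.character(lowers),
                          paste0(lowers, "-", uppers)))
  labels[1] <- if (is.finite(uppers[1])) paste0("<=", uppers[1]) else "all"
  structure(list(lowers = lowers, uppers = uppers, labels = labels),
            class = "mcds_scheme")
}

#' @export
print.mcds_scheme <- function(x, ...) {
  cat("M-CDS stratification scheme:", length(x$lowers), "classes\n")
  cat(" ", paste(seq_along(x$labels), x$labels, sep = ": ",
                 collapse = "  "), "\n")
  invisible(x)
}

#' Assign risk classes to integer scores
#'
#' @param score nonnegative integer score vector.
#' @param scheme an [mcds_scheme()].
#' @return 1-based class index vector (increasing risk).
#' @examples
#' assign_class(c(0, 2, 9, 45))
#' @export
assign_class <- function(score, scheme = mcds_scheme()) {
  stopifnot(inherits(scheme, "mcds_scheme"))
  if (any(score < 0)) stop("scores must be nonnegative", call. = FALSE)
  findInterval(score, scheme$lowers)
}

#' Compute the M-CDS total score
#'
#' The total score is the sum of the weights of the flagged conditions,
#' `S = sum_j w_j x_j`. Conditions present in the profile but absent from
#' the weight table contribute 0 (they were dropped during variable
#' selection); a weighted condition missing from the profile is an error.
#'
#' @param profiles an `mcds_profiles` data frame (or any data frame with
#'   `patient_id` and one 0/1 column per condition).
#' @param weights a weight table from [mcds_weights()].
#' @return integer vector of scores, one per profile row.
#' @export
mcds_score <- function(profiles, weights = mcds_weights()) {
  missing <- setdiff(weights$condition, names(profiles))
  if (length(missing)) {
    stop("weighted condition(s) absent from the profiles: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(profiles[weights$condition])
  if (!all(m %in% c(0, 1))) {
    stop("condition flags must be 0/1", call. = FALSE)
  }
  as.integer(m %*% weights$weight)
}

#' Construct an M-CDS scorer
#'
#' Bundles a weight table and a stratification scheme into a scorer object;
#' `predict()` then maps condition profiles to scores and risk classes.
#' With the defaults this is the published score.
#'
#' @param weights a weight table ([mcds_weights()]).
#' @param scheme an [mcds_scheme()].
#' @return an object of class `mcds`.
#' @examples
#' m <- mcds()
#' prof <- data.frame(patient_id = "P1", cancer = 1L, diabetes = 1L)
#' prof[setdiff(mcds_weights()$condition, names(prof))] <- 0L
#' predict(m, prof)  # score 13, class 6
#' @export
mcds <- function(weights = mcds_weights(), scheme = mcds_scheme()) {
  stopifnot(is.data.frame(weights),
            all(c("condition", "weight") %in% names(weights)),
            inherits(scheme, "mcds_scheme"))
  structure(list(weights = weights, scheme = scheme), class = "mcds")
}

#' @export
print.mcds <- function(x, ...) {
  cat("M-CDS scorer:", nrow(x$weights), "weighted conditions,",
      length(x$scheme$lowers), "risk classes\n")
  cat("  score range: 0 -", sum(pmax(x$weights$weight, 0)), "\n")
  invisible(x)
}

#' @export
summary.mcds <- function(object, ...) {
  print(object)
  w <- object$weights[order(-object$weights$weight), ]
  cat("\nWeights:\n")
  print(data.frame(condition = w$condition, coefficient = w$coefficient,
                   weight = w$weight, row.names = NULL))
  print(object$scheme)
  invisible(object)
}

#' @export
coef.mcds <- function(object, ...) {
  stats::setNames(object$weights$coefficient, object$weights$condition)
}

#' Score condition profiles with an M-CDS scorer
#'
#' @param object an [mcds()] scorer.
#' @param profiles an `mcds_profiles` data frame.
#' @param ... unused.
#' @return a `data.frame` with `patient_id`, `score`, `risk_class`.
#' @export
predict.mcds <- function(object, profiles, ...) {
  score <- mcds_score(profiles, object$weights)
  data.frame(patient_id = profiles$patient_id, score = score,
             risk_class = assign_class(score, object$scheme),
             stringsAsFactors = FALSE)
}
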