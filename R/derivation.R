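# Weight derivation: L1-penalised Cox partial likelihood over age, sex and
# condition flags; 10-fold cross-validation with the one-standard-error
# rule; unpenalised refit on the selected set; coefficient-to-weight
# transform.

#' Split a cohort into training and test sets
#'
#' Disjoint, exhaustive, reproducible from the seed; the training size is
#' `round(fraction * n)`.
#'
#' @param ids character vector of patient ids.
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer RNG seed.
#' @return a list with `train` and `test` id vectors.
#' @export
split_train_test <- function(ids, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n_train <- round(fraction * length(ids))
  set.seed(seed)
  train <- sample(ids, n_train)
  list(train = train, test = setdiff(ids, train))
}

#' Fit an L1-penalised Cox model with cross-validated penalty selection
#'
#' Maximises the Breslow-ties Cox partial log-likelihood minus
#' `lambda * sum(|beta|)` along a decreasing penalty grid (100 values from
#' the smallest all-zero penalty down to 1/1000 of it), and selects the
#' penalty by 10-fold cross-validated partial-likelihood deviance. Besides
#' the deviance-minimising `lambda_min`, the one-standard-error penalty
#' `lambda_1se` (the most parsimonious model within one SE of the minimum)
#' is recorded; the latter drives variable selection. Folds are stratified
#' by event status so every fold contains events, and are reproducible from
#' the seed.
#'
#' @param X numeric covariate matrix (columns: condition flags, optionally
#'   `age` and `sex`); constant columns are dropped with a warning.
#' @param survival a `data.frame` with `time` and `event` columns, rows
#'   aligned with `X`.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param nlambda,lambda_min_ratio penalty-grid resolution and lower end
#'   relative to the all-zero penalty.
#' @return an object of class `mcds_lasso`: the penalty grid, coefficient
#'   path, CV curve (mean and SE), `lambda_min`, `lambda_1se` and the
#'   selected covariate set at `lambda_1se`.
#' @export
fit_lasso_cox <- function(X, survival, n_folds = 10L, seed = 1L,
                          nlambda = 100L, lambda_min_ratio = 0.001) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(survival))
  event <- as.integer(survival$event)
  if (sum(event) == 0L) stop("no events in the data", call. = FALSE)
  keep <- apply(X, 2, function(x) stats::var(x) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  y <- survival::Surv(survival$time, event)
  set.seed(seed)
  foldid <- integer(nrow(X))
  for (grp in list(which(event == 1L), which(event == 0L))) {
    foldid[grp] <- sample(rep_len(seq_len(n_folds), length(grp)))
  }
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox",
                             type.measure = "deviance", foldid = foldid,
                             nlambda = nlambda,
                             lambda.min.ratio = lambda_min_ratio)
  beta_1se <- as.matrix(stats::coef(cvfit, s = "lambda.1se"))[, 1]
  structure(list(
    lambda_grid = cvfit$lambda,
    coefficient_path = as.matrix(cvfit$glmnet.fit$beta),
    cv_error = cvfit$cvm,
    cv_se = cvfit$cvsd,
    lambda_min = cvfit$lambda.min,
    lambda_1se = cvfit$lambda.1se,
    selected_set = names(beta_1se)[beta_1se != 0],
    beta_1se = beta_1se,
    n = nrow(X), n_events = sum(event),
    cvfit = cvfit
  ), class = "mcds_lasso")
}

#' @export
print.mcds_lasso <- function(x, ...) {
  cat("Penalised Cox fit:", x$n, "subjects,", x$n_events, "events\n")
  cat(sprintf("  lambda_min = %.5f, lambda_1se = %.5f\n",
              x$lambda_min, x$lambda_1se))
  cat("  selected at lambda_1se (", length(x$selected_set), "): ",
      paste(x$selected_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a weight table from a penalised Cox fit
#'
#' By default the covariates selected at `lambda_1se` are refit with an
#' unpenalised Cox model and those (unshrunken) coefficients are
#' transformed into integer weights; with `refit = FALSE` the penalised
#' coefficients at `lambda_1se` are transformed instead. Age and sex may
#' compete for selection but never receive weights: the score is a pure
#' comorbidity count, so their coefficients are only reported as an
#' attribute.
#'
#' @param fit an `mcds_lasso` object.
#' @param survival,X the data the fit was produced from.
#' @param refit refit the selected set without penalty (default `TRUE`)?
#' @param exclude covariates excluded from the weight table (default
#'   `c("age", "sex")`).
#' @param ties tie handling for the refit: `"breslow"` (default, matching
#'   the penalised path) or `"efron"`.
#' @return a weight table `data.frame` (`condition`, `coefficient`,
#'   `weight`), with attributes `adjustment` (age/sex coefficients) and
#'   `refit` (the `coxph` object, when refit).
#' @export
extract_weights <- function(fit, survival, X, refit = TRUE,
                            exclude = c("age", "sex"),
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(fit, "mcds_lasso"))
  sel <- fit$selected_set
  if (!length(sel)) {
    stop("the one-SE model is empty: no covariates selected", call. = FALSE)
  }
  X <- as.matrix(X)
  if (refit) {
    Xs <- X[, sel, drop = FALSE]
    cox <- tryCatch(
      withCallingHandlers(
        survival::coxph(
          survival::Surv(survival$time, survival$event) ~ Xs,
          ties = ties, control = survival::coxph.control(iter.max = 50)
        ),
        warning = function(w) {
          if (grepl("iterations|converge", conditionMessage(w))) {
            stop("unpenalised refit did not converge: ",
                 conditionMessage(w), call. = FALSE)
          }
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) stop("refit failed: ", conditionMessage(e),
                               call. = FALSE)
    )
    beta <- stats::setNames(stats::coef(cox), sel)
  } else {
    cox <- NULL
    beta <- fit$beta_1se[sel]
  }
  cond <- setdiff(sel, exclude)
  out <- data.frame(condition = cond, coefficient = unname(beta[cond]),
                    weight = coefficient_to_weight(unname(beta[cond])),
                    stringsAsFactors = FALSE)
  attr(out, "adjustment") <- beta[intersect(sel, exclude)]
  attr(out, "refit") <- cox
  out
}

# Assemble the covariate matrix for derivation: condition flags plus
# optional age (years) and sex (1 = male indicator).
.build_X <- function(profiles, age = NULL, sex = NULL) {
  conditions <- setdiff(names(profiles), "patient_id")
  X <- as.matrix(profiles[conditions])
  storage.mode(X) <- "double"
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (!is.null(sex)) {
    male <- if (is.numeric(sex)) as.numeric(sex)
            else as.numeric(tolower(as.character(sex)) %in% c("male", "m"))
    X <- cbind(X, sex = male)
  }
  X
}

#' Derive M-CDS weights on a cohort
#'
#' The full derivation pipeline: penalised Cox over gender, age and the
#' condition flags, 10-fold cross-validation, one-standard-error penalty
#' choice, unpenalised refit of the selected conditions, and the
#' multiply-by-10-and-round weight transform. Optionally grows a CHAID tree
#' on the derived scores to find risk-class boundaries; otherwise the
#' published 6-class scheme is attached.
#'
#' @param profiles an `mcds_profiles` data frame (apply
#'   [apply_prevalence_floor()] first if rare conditions should be
#'   excluded).
#' @param survival a survival `data.frame` from [build_survival()], matched
#'   to `profiles` by `patient_id`.
#' @param age,sex optional per-patient covariates entering the selection
#'   model as penalised candidates (never weighted).
#' @param stratify grow a CHAID tree on the derived scores to obtain the
#'   stratification scheme (default `FALSE`, which attaches the published
#'   scheme)?
#' @param chaid_params parameters for the tree, see [chaid_params()].
#' @inheritParams fit_lasso_cox
#' @inheritParams extract_weights
#' @return an object of class `c("mcds_fit", "mcds")`; usable with
#'   [predict.mcds()], and carrying the penalised fit (`$lasso`), the refit
#'   weight table (`$weights`) and the scheme (`$scheme`).
#' @export
mcds_derive <- function(profiles, survival, age = NULL, sex = NULL,
                        n_folds = 10L, seed = 1L, refit = TRUE,
                        ties = c("breslow", "efron"), stratify = FALSE,
                        chaid_params = NULL) {
  ties <- match.arg(ties)
  ord <- match(profiles$patient_id, survival$patient_id)
  if (anyNA(ord)) {
    stop("profiles contain patient_id(s) absent from survival",
         call. = FALSE)
  }
  survival <- survival[ord, , drop = FALSE]
  X <- .build_X(profiles, age, sex)
  fit <- fit_lasso_cox(X, survival, n_folds = n_folds, seed = seed)
  weights <- extract_weights(fit, survival, X, refit = refit, ties = ties)
  obj <- structure(list(weights = weights, scheme = mcds_scheme(),
                        lasso = fit, n = nrow(X),
                        n_events = sum(survival$event)),
                   class = c("mcds_fit", "mcds"))
  if (stratify) {
    score <- mcds_score(profiles, weights)
    tree <- mcds_chaid(score, survival$event,
                       params = chaid_params %||% chaid_params())
    obj$tree <- tree
    obj$scheme <- extract_boundaries(tree)
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mcds_fit <- function(x, ...) {
  cat("Derived M-CDS model:", x$n, "subjects,", x$n_events, "events\n")
  cat("  conditions weighted:", nrow(x$weights), "\n")
  adj <- attr(x$weights, "adjustment")
  if (length(adj)) {
    cat("  adjustment (unweighted):",
        paste(sprintf("%s=%.3f", names(adj), adj), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mcds_fit <- function(object, ...) {
  print(object)
  print(object$lasso)
  w <- object$weights[order(-object$weights$weight), ]
  rownames(w) <- NULL
  cat("\nDerived weights:\n")
  print(w)
  print(object$scheme)
  invisible(object)
}

#' @export
coef.mcds_fit <- function(object, ...) {
  c(stats::setNames(object$weights$coefficient, object$weights$condition),
    attr(object$weights, "adjustment"))
}

#' Plot the cross-validation curve of a derived model
#'
#' @param x an `mcds_fit` object.
#' @param ... passed to `plot.cv.glmnet`.
#' @export
plot.mcds_fit <- function(x, ...) {
  plot(x$lasso$cvfit, ...)
  invisible(x)
}
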