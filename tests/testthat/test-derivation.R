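test_that("train/test split is reproducible, disjoint and exhaustive", {
  ids <- sprintf("P%03d", 1:10)
  sp <- split_train_test(ids, 0.8, seed = 5)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(split_train_test(ids, 0.8, seed = 5), sp)
  # at the development cohort's size the 80% training share is 304,679
  expect_equal(round(0.8 * 380849), 304679)
})

# A small two-covariate cohort with one true log-hazard of 0.7 and one null
# covariate, shared by the penalised-path tests.
sim_two_cov <- function(n = 2000, seed = 3) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.3)
  x2 <- rbinom(n, 1, 0.5)
  t_raw <- rexp(n, rate = 0.0005 * exp(0.7 * x1))
  day <- pmax(1, ceiling(t_raw))
  list(X = cbind(risk = x1, null = x2),
       surv = data.frame(time = pmin(day, 365),
                         event = as.integer(day <= 365)))
}

test_that("the penalised path shrinks to the null model and to the oracle", {
  d <- sim_two_cov()
  fit <- fit_lasso_cox(d$X, d$surv, n_folds = 5, seed = 1,
                       lambda_min_ratio = 1e-5)
  # above the largest grid value every coefficient is exactly zero
  expect_true(all(fit$coefficient_path[, 1] == 0))
  # nonzero count is non-increasing as lambda grows along the path
  nz <- colSums(fit$coefficient_path != 0)
  expect_true(all(diff(nz[order(fit$lambda_grid)]) <= 0))
  # the bottom of the path approaches the unpenalised Newton-Raphson fit
  # (the remaining penalty at the smallest grid value leaves a small bias)
  oracle <- survival::coxph(
    survival::Surv(d$surv$time, d$surv$event) ~ d$X, ties = "breslow"
  )
  expect_lt(max(abs(fit$coefficient_path[, ncol(fit$coefficient_path)] -
                      coef(oracle))), 0.02)
})

test_that("the one-SE rule picks a sparser model within one SE of the best", {
  d <- sim_two_cov(n = 1500, seed = 9)
  fit <- fit_lasso_cox(d$X, d$surv, n_folds = 5, seed = 2)
  expect_gte(fit$lambda_1se, fit$lambda_min)
  i_min <- which.min(abs(fit$lambda_grid - fit$lambda_min))
  i_1se <- which.min(abs(fit$lambda_grid - fit$lambda_1se))
  expect_lte(fit$cv_error[i_1se],
             fit$cv_error[i_min] + fit$cv_se[i_min] + 1e-10)
  nz <- colSums(fit$coefficient_path != 0)
  expect_lte(nz[i_1se], nz[i_min])
})

test_that("degenerate inputs are refused", {
  d <- sim_two_cov()
  no_events <- d$surv
  no_events$event <- 0L
  expect_error(fit_lasso_cox(d$X, no_events), "events")
  const <- cbind(d$X, flat = 1)
  expect_warning(fit_lasso_cox(const, d$surv, n_folds = 5), "constant")
  fit <- fit_lasso_cox(d$X, d$surv, n_folds = 5)
  fit$selected_set <- character(0)
  expect_error(extract_weights(fit, d$surv, d$X), "empty")
})

test_that("weight extraction separates conditions from age/sex adjustment", {
  set.seed(21)
  n <- 3000
  flags <- cbind(cancer = rbinom(n, 1, 0.2), benign = rbinom(n, 1, 0.3))
  age <- round(rnorm(n, 68, 10))
  lp <- 1.0 * flags[, "cancer"] + 0.04 * (age - 68)
  day <- pmax(1, ceiling(rexp(n, rate = 0.0004 * exp(lp))))
  surv <- data.frame(time = pmin(day, 365),
                     event = as.integer(day <= 365))
  X <- cbind(flags, age = age)
  fit <- fit_lasso_cox(X, surv, n_folds = 5, seed = 4)
  w <- extract_weights(fit, surv, X)
  expect_false("age" %in% w$condition)
  expect_true("age" %in% names(attr(w, "adjustment")))
  expect_identical(w$weight, coefficient_to_weight(w$coefficient))
  # refit coefficients are unshrunken relative to the penalised ones
  wp <- extract_weights(fit, surv, X, refit = FALSE)
  shared <- intersect(w$condition, wp$condition)
  expect_true(mean(abs(w$coefficient[match(shared, w$condition)]) >=
                     abs(wp$coefficient[match(shared, wp$condition)]))
              >= 0.8)
})

test_that("the full pipeline recovers strong signals on a synthetic cohort", {
  sim <- simulate_mcds_cohort(mcds_sim_params(n_patients = 50000,
                                              seed = 1))
  prof <- mcds_profile(sim$claims, patients = sim$cohort$patient_id)
  fl <- suppressMessages(apply_prevalence_floor(prof))
  surv <- build_survival(sim$cohort, sim$outcomes)
  fit <- mcds_derive(fl$profiles, surv, age = sim$cohort$age_at_index,
                     sex = sim$cohort$sex, seed = 1)
  # the dominant signals (weight >= 7) survive the one-SE selection;
  # weight-4 conditions are not reliably retained at ~1,200 events
  expect_true(all(c("cancer", "psychosis") %in% fit$lasso$selected_set))
  # the refit's partial likelihood dominates the penalised coefficients
  # restricted to the same covariates
  sel <- fit$lasso$selected_set
  X <- mcds:::.build_X(fl$profiles, sim$cohort$age_at_index,
                       sim$cohort$sex)[, sel, drop = FALSE]
  pen <- fit$lasso$beta_1se[sel]
  at_pen <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ X, ties = "breslow",
    init = pen, control = survival::coxph.control(iter.max = 0)
  )
  refit <- attr(fit$weights, "refit")
  expect_gte(refit$loglik[2], at_pen$loglik[2])
  # derived weights for selected strong conditions are near the truth
  truth <- mcds_conditions()
  for (cond in intersect(fit$weights$condition, truth$condition)) {
    tw <- coefficient_to_weight(
      truth$coefficient[truth$condition == cond]
    )
    dw <- fit$weights$weight[fit$weights$condition == cond]
    expect_lte(abs(dw - tw), 2)
  }
})
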