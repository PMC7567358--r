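test_that("the c-statistic equals tie-aware pair counting", {
  expect_equal(mcds_auc(c(5, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(mcds_auc(rep(3, 10), rep(0:1, 5)), 0.5)
  expect_equal(mcds_auc(c(3, 2, 1, 2), c(1, 1, 0, 0)), 0.875)
  expect_error(mcds_auc(1:5, rep(1, 5)), "both outcome classes")
  # invariant under strictly monotone transforms
  set.seed(1)
  s <- rnorm(200)
  y <- rbinom(200, 1, plogis(s))
  expect_equal(mcds_auc(exp(s), y), mcds_auc(s, y))
})

test_that("fast AUC matches brute force and the trapezoidal ROC integral", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(10:120, 1)
    score <- if (i %% 2) rnorm(n) else sample(0:8, n, replace = TRUE)
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    a <- mcds_auc(score, outcome)
    expect_equal(a, auc_brute(score, outcome), tolerance = 1e-12)
    trap <- as.numeric(pROC::auc(pROC::roc(outcome, score, quiet = TRUE,
                                           direction = "<")))
    expect_equal(a, trap, tolerance = 1e-12)
  }
})

test_that("DeLong variance and CI agree with the reference implementation", {
  set.seed(9)
  for (i in 1:10) {
    n <- 150
    score <- rnorm(n) + 0.8 * (y <- rbinom(n, 1, 0.35))
    r <- auc_ci_delong(score, y)
    proc_roc <- pROC::roc(y, score, quiet = TRUE, direction = "<")
    expect_equal(r$var, as.numeric(pROC::var(proc_roc, method = "delong")),
                 tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(proc_roc, method = "delong"))
    expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("degenerate and duplicated data behave as the variance dictates", {
  # perfect separation: upper bound truncates at 1
  expect_warning(r <- auc_ci_delong(c(4, 3, 1, 0), c(1, 1, 0, 0)),
                 "degenerate")
  expect_equal(r$auc, 1)
  expect_equal(r$ci_high, 1)
  expect_equal(r$ci_low, 1)
  # doubling every record keeps the point estimate, shrinks the CI
  set.seed(2)
  s <- rnorm(80)
  y <- rbinom(80, 1, 0.4)
  one <- auc_ci_delong(s, y)
  two <- auc_ci_delong(c(s, s), c(y, y))
  expect_equal(two$auc, one$auc)
  expect_lt(two$ci_high - two$ci_low, one$ci_high - one$ci_low)
})

test_that("the paired DeLong test is null for rank-equivalent scores", {
  set.seed(5)
  s <- rnorm(100)
  y <- rbinom(100, 1, 0.4)
  self <- compare_auc_paired(s, s, y)
  expect_equal(self$chi_square, 0)
  expect_equal(self$p, 1)
  doubled <- compare_auc_paired(s, 2 * s, y)
  expect_equal(doubled$chi_square, 0)
})

test_that("the paired statistic is symmetric and matches pROC", {
  set.seed(14)
  for (i in 1:5) {
    n <- 300
    y <- rbinom(n, 1, 0.3)
    a <- rnorm(n) + 0.7 * y
    b <- rnorm(n) + 0.4 * y
    ab <- compare_auc_paired(a, b, y)
    ba <- compare_auc_paired(b, a, y)
    expect_equal(ab$chi_square, ba$chi_square)
    expect_equal(ab$p, ba$p)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                          pROC::roc(y, b, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(ab$chi_square, unname(ref$statistic)^2,
                 tolerance = 1e-9)
    expect_equal(ab$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the paired test holds its type-I error on independent nulls", {
  set.seed(31)
  reps <- 200
  p <- replicate(reps, {
    y <- rbinom(500, 1, 0.1)
    compare_auc_paired(rnorm(500), rnorm(500), y)$p
  })
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.10)
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  # no events: survival stays at 1
  s0 <- data.frame(time = rep(365L, 8), event = 0L)
  expect_equal(unname(km_survival_at(s0, rep(1, 8))), 1)
  # no censoring: empirical survival fraction
  s1 <- data.frame(time = c(50, 100, 200, 365, 365, 365),
                   event = c(1, 1, 1, 1, 1, 1))
  expect_equal(unname(km_survival_at(s1, rep(1, 6), t = 150)), 4 / 6)
  # 10 patients, 1 death at day 100, rest censored at 365
  s2 <- data.frame(time = c(100, rep(365, 9)), event = c(1, rep(0, 9)))
  expect_equal(unname(km_survival_at(s2, rep(1, 10))), 0.9)
  # staggered censoring: hand-computed product of (1 - d_i / n_i)
  s3 <- data.frame(time = c(30, 60, 60, 90, 120, 365, 365, 365),
                   event = c(1, 0, 1, 1, 0, 0, 0, 0))
  # deaths at 30 (n=8), 60 (n=7), 90 (n=5)
  expect_equal(unname(km_survival_at(s3, rep(1, 8))),
               (7 / 8) * (6 / 7) * (4 / 5))
  # the estimator never increases
  tab <- km_by_class(s3, rep(1, 8))
  expect_true(all(diff(tab$surv) <= 0))
})

test_that("the log-rank test separates what should be separated", {
  # two identical groups: statistic ~ 0
  s <- data.frame(time = rep(c(100, 250, 365), 20),
                  event = rep(c(1, 1, 0), 20))
  same <- logrank(rbind(s, s), rep(1:2, each = nrow(s)))
  expect_lt(same$chi_square, 1e-8)
  expect_equal(same$df, 1L)
  # k classes give k - 1 degrees of freedom
  set.seed(3)
  sk <- data.frame(time = sample(1:365, 300, TRUE),
                   event = rbinom(300, 1, 0.3))
  expect_equal(logrank(sk, sample(1:4, 300, TRUE))$df, 3L)
  # hazard ratio 5, n = 1000 per group: overwhelming rejection
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    t1 <- pmax(1, ceiling(rexp(1000, 0.0002)))
    t2 <- pmax(1, ceiling(rexp(1000, 0.001)))
    sv <- data.frame(time = pmin(c(t1, t2), 365),
                     event = as.integer(c(t1, t2) <= 365))
    lr <- logrank(sv, rep(1:2, each = 1000))
    expect_lt(lr$p, 0.001)
  }
})

test_that("the validation report assembles all components", {
  set.seed(6)
  n <- 400
  score <- rnbinom(n, size = 0.9, mu = 3.4)
  day <- pmax(1, ceiling(rexp(n, 0.0001 * exp(0.15 * score))))
  surv <- data.frame(time = pmin(day, 365),
                     event = as.integer(day <= 365))
  val <- mcds_validate(score, surv,
                       compare = list(noise = rnorm(n)))
  expect_s3_class(val, "mcds_validation")
  expect_true(val$roc$ci_low <= val$roc$auc &
                val$roc$auc <= val$roc$ci_high)
  expect_named(val$comparisons, "noise")
  expect_output(print(val), "log-rank")
})
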