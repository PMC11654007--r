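test_that("Youden dichotomization finds the separating cut", {
  r <- youden_dichotomize(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$cut, 2.5)
  expect_equal(r$youden_j, 1)
  expect_equal(r$direction, ">=")
  # constant feature degenerates with a warning
  expect_warning(rc <- youden_dichotomize(rep(2, 6), c(0, 1, 0, 1, 0, 1)),
                 "constant")
  expect_equal(rc$cut, 2)
  expect_equal(rc$youden_j, 0)
  expect_error(youden_dichotomize(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Youden maximization matches the exhaustive oracle", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    vals <- sample(round(rnorm(n, sd = 3), 1))
    labs <- rbinom(n, 1, 0.5)
    if (length(unique(labs)) < 2) labs[1:2] <- c(0L, 1L)
    r <- youden_dichotomize(vals, labs)
    expect_equal(r$youden_j, oracle_max_youden(vals, labs), tolerance = 1e-12)
    # the reported sens/spec are consistent with the rule itself
    pos <- apply_rule(r, vals)
    expect_equal(r$sensitivity, mean(pos[labs == 1]))
    expect_equal(r$specificity, mean(1 - pos[labs == 0]))
  }
})

test_that("2x2 diagnostics reproduce the printed platelet and albumin rows", {
  # platelet count >= 178e9/L against high grade
  p <- contingency_diagnostics(tp = 60, fp = 21, fn = 9, tn = 15)
  expect_equal(round(100 * p$estimates[["sensitivity"]], 1), 87.0)
  expect_equal(round(100 * p$estimates[["specificity"]], 1), 41.7)
  expect_equal(round(100 * p$estimates[["ppv"]], 1), 74.1)
  expect_equal(round(100 * p$estimates[["npv"]], 1), 62.5)
  expect_equal(p$auc, (60 / 69 + 15 / 36) / 2)
  # serum albumin < 42.6 g/L against high grade
  a <- contingency_diagnostics(tp = 58, fp = 19, fn = 11, tn = 17)
  expect_equal(round(100 * a$estimates[["sensitivity"]], 1), 84.1)
  expect_equal(round(100 * a$estimates[["specificity"]], 1), 47.2)
  expect_equal(round(100 * a$estimates[["ppv"]], 1), 75.3)
  expect_equal(round(100 * a$estimates[["npv"]], 1), 60.7)
})

test_that("diagnostics respect symmetry and reject empty margins", {
  # balanced table: sens = spec = 50%
  d <- contingency_diagnostics(tp = 10, fp = 10, fn = 10, tn = 10)
  expect_equal(d$estimates[["sensitivity"]], 0.5)
  expect_equal(d$estimates[["specificity"]], 0.5)
  # swapping the positive/negative labeling swaps sens<->spec and ppv<->npv
  d1 <- contingency_diagnostics(tp = 60, fp = 21, fn = 9, tn = 15)
  d2 <- contingency_diagnostics(tp = 15, fp = 9, fn = 21, tn = 60)
  expect_equal(d2$estimates[["sensitivity"]], d1$estimates[["specificity"]])
  expect_equal(d2$estimates[["ppv"]], d1$estimates[["npv"]])
  expect_error(contingency_diagnostics(0, 5, 0, 5), "sensitivity")
  # Clopper-Pearson interval contains the estimate
  td <- tidy(d1)
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
})

test_that("group comparisons reproduce the printed contingency p-values", {
  # platelet 2x2: low 15/21, high 9/60 below/above threshold
  vals <- rep(c(0, 1, 0, 1), c(15, 21, 9, 60))
  grp <- rep(c("low", "high"), c(36, 69))
  out <- compare_groups(vals, grp)
  expect_equal(out$method, "chi-squared")
  expect_equal(round(out$p_value, 3), 0.001)
  # hemoglobin 2x2: low 9/27, high 42/27
  vals2 <- rep(c(0, 1, 0, 1), c(9, 27, 42, 27))
  out2 <- compare_groups(vals2, grp)
  expect_lt(out2$p_value, 0.001)
  # identical distributions: statistic 0, p = 1
  v3 <- rep(c(0, 1), 20); g3 <- rep(c("a", "b"), each = 20)
  out3 <- compare_groups(v3, g3)
  expect_equal(out3$statistic, 0)
  expect_equal(out3$p_value, 1)
  # continuous path chooses a test and returns a two-sided p
  set.seed(8)
  out4 <- compare_groups(c(rnorm(20), rnorm(20, 2)), rep(c("a", "b"), each = 20),
                         kind = "continuous")
  expect_true(out4$method %in% c("t", "mann-whitney"))
  expect_lt(out4$p_value, 0.01)
})

test_that("univariate logistic regression matches the closed-form odds ratio", {
  x <- rep(c(1, 0, 1, 0), c(60, 9, 21, 15))
  y <- rep(c(1, 0), c(69, 36))
  fit <- univariate_logistic(x, y)
  expect_equal(fit$odds_ratio, (60 * 15) / (9 * 21), tolerance = 1e-6)
  expect_false(fit$separated)
  # a balanced null feature has a (near) zero coefficient
  xn <- rep(c(0, 1), 50); yn <- rep(c(0, 1, 1, 0), 25)
  expect_lt(abs(univariate_logistic(xn, yn)$estimate), 1e-6)
  # perfect separation is flagged
  xs <- rep(c(0, 1), each = 20); ys <- xs
  expect_true(univariate_logistic(xs, ys)$separated)
})

test_that("median imputation fills gaps and counts them", {
  d <- tibble::tibble(a = c(1, NA, 3), b = c(1, 2, NA, 100)[1:3])
  expect_message(out <- impute_median(d), "imputed")
  expect_equal(out$a, c(1, 2, 3))
  d2 <- tibble::tibble(a = c(1, 2, NA, 100))
  out2 <- suppressMessages(impute_median(d2))
  expect_equal(out2$a[3], 2)  # median of the observed values
  expect_equal(attr(out2, "imputed_counts")[["a"]], 1L)
  # no missing values: identity
  d3 <- tibble::tibble(a = 1:3)
  expect_equal(impute_median(d3)$a, 1:3)
  expect_error(impute_median(tibble::tibble(a = c(NA_real_, NA_real_))),
               "entirely missing")
})
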