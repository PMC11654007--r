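test_that("the published equation scores all indicator combinations exactly", {
  m <- printed_grade_model()
  X <- as.matrix(expand.grid(rep(list(0:1), 5)))
  colnames(X) <- names(m$coefficients)
  got <- score_printed_model(X, m)
  manual <- 0.936 - 1.418 * X[, 1] + 1.334 * X[, 2] - 1.585 * X[, 3] -
    1.198 * X[, 4] + 1.631 * X[, 5]
  expect_equal(got$score, unname(manual))
  expect_equal(got$predicted_class, ifelse(manual >= 1.12, "high", "low"))
  # frozen spot values
  expect_equal(score_printed_model(c(0, 0, 0, 0, 0))$score, 0.936)
  expect_equal(score_printed_model(c(1, 1, 1, 1, 1))$score, -0.3)
  expect_equal(score_printed_model(c(0, 1, 0, 0, 1))$score, 3.901)
  expect_equal(score_printed_model(c(0, 1, 0, 0, 1))$predicted_class, "high")
  expect_error(score_printed_model(c(0, 1, 2, 0, 1)), "binary")
  expect_error(score_printed_model(c(0, 1)), "5")
})

simulate_printed_cohort <- function(n, seed) {
  m <- printed_grade_model()
  set.seed(seed)
  X <- sapply(seq_along(m$coefficients), function(i) rbinom(n, 1L, 0.5))
  colnames(X) <- names(m$coefficients)
  y <- rbinom(n, 1L, plogis(m$intercept + drop(X %*% m$coefficients)))
  data.frame(X, grade_high = y, check.names = FALSE)
}

test_that("backward LR selection recovers the generating model", {
  dat <- simulate_printed_cohort(2000, seed = 12)
  vars <- names(printed_grade_model()$coefficients)
  fit <- fit_multivariable_backward(dat, "grade_high", vars)
  expect_setequal(fit$retained, vars)
  td <- tidy(fit)
  est <- setNames(td$estimate[match(vars, td$term)], vars)
  truth <- printed_grade_model()$coefficients
  expect_true(all(abs(est - truth) < 0.25))
  # a pure-noise candidate is eliminated
  set.seed(5)
  dat$noise <- rbinom(nrow(dat), 1L, 0.5)
  fit2 <- fit_multivariable_backward(dat[, c("noise", "grade_high")],
                                     "grade_high", "noise")
  expect_length(fit2$retained, 0)
  # empty candidate list yields the intercept-only model
  fit3 <- fit_multivariable_backward(dat, "grade_high", character(0))
  expect_length(coef(fit3$fit), 1L)
})

test_that("AUC equals the concordant-pair count and handles edge cases", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- sample(round(rnorm(n), 1))
    labs <- rbinom(n, 1, 0.5)
    if (length(unique(labs)) < 2) labs[1:2] <- c(0L, 1L)
    expect_equal(suppressWarnings(roc_auc(scores, labs)$auc),
                 oracle_auc(scores, labs), tolerance = 1e-12)
  }
  # perfectly ranked scores (pROC warns that the CI is degenerate)
  expect_equal(suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc), 1)
  # the binary platelet predictor reproduces (sens + spec) / 2
  x <- rep(c(1, 0, 1, 0), c(60, 9, 21, 15))
  y <- rep(c(1, 1, 0, 0), c(60, 9, 21, 15))
  expect_equal(roc_auc(x, y)$auc, 0.643, tolerance = 5e-4)
  # constant scores degrade to 0.5 with a warning
  expect_warning(rc <- roc_auc(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(77)
  scores <- rnorm(200)
  labs <- rep(c(0L, 1L), 100)
  aucs <- vapply(1:500, function(i) roc_auc(scores, sample(labs))$auc,
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the DeLong test behaves under null, power and monotone maps", {
  set.seed(14)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  good <- y + rnorm(n)
  noise <- rnorm(n)
  # identical scores: no difference by construction
  same <- delong_test(good, good, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # informative vs noise score separates with high power
  rej <- vapply(1:50, function(i) {
    set.seed(400 + i)
    yy <- rbinom(500, 1, 0.5)
    delong_test(yy + rnorm(500), rnorm(500), yy)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  # rank-based: invariant to monotone transformation of either score
  a <- delong_test(good, noise, y)
  b <- delong_test(exp(good / 2), noise, y)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_error(delong_test(rep(1, n), noise, y), "constant")
})

test_that("Hosmer-Lemeshow calibration test has the right null and closed forms", {
  # constant predictions: chi2 reduces to the Pearson statistic of raw
  # counts against a constant expectation (groups merge to one)
  y <- rep(c(0L, 1L), c(30, 20))
  p <- rep(0.35, 50)
  hl <- hosmer_lemeshow(p, y, g = 5)
  o <- 20; e <- 50 * 0.35
  expect_equal(hl$statistic, (o - e)^2 / e + (30 - (50 - e))^2 / (50 - e))
  expect_error(hosmer_lemeshow(runif(50), rbinom(50, 1, 0.5), g = 2), "g >= 3")
  # calibrated fitted model: p-values roughly uniform over replicates (the
  # g - 2 degrees of freedom presume probabilities estimated by a fit)
  set.seed(55)
  pv <- vapply(1:200, function(i) {
    x <- rnorm(1000)
    yy <- rbinom(1000, 1, plogis(-0.5 + x))
    pr <- fitted(glm(yy ~ x, family = binomial()))
    hosmer_lemeshow(pr, yy)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
})

test_that("decision-curve net benefit matches its closed forms", {
  set.seed(66)
  y <- rbinom(400, 1, 0.5)
  p <- ifelse(y == 1, 0.9, 0.1)  # perfect predictions
  dc <- decision_curve(p, y, thresholds = c(0.2, 0.5, 0.8))
  none <- dc[dc$strategy == "treat_none", ]
  expect_true(all(none$net_benefit == 0))
  model_nb <- dc[dc$strategy == "model" & dc$threshold == 0.5, ]
  expect_equal(model_nb$net_benefit, mean(y))  # TP/n = prevalence, FP = 0
  prev <- mean(y)
  all_nb <- dc[dc$strategy == "treat_all", ]
  expect_equal(all_nb$net_benefit,
               prev - (1 - prev) * all_nb$threshold / (1 - all_nb$threshold))
  # thresholds at or beyond 1 are dropped
  dc2 <- decision_curve(p, y, thresholds = c(0.5, 1, 1.5))
  expect_equal(unique(dc2$threshold), 0.5)
})

test_that("nomogram point scales encode the model exactly", {
  m <- printed_grade_model()
  nm <- nomogram_points(m)
  # the largest coefficient magnitude (lymphocyte count) carries 100 points
  expect_equal(nm$points$max_points[nm$points$variable == "lymphocyte_count"],
               100)
  # round-trip: probability from total points equals the logistic inverse
  X <- as.matrix(expand.grid(rep(list(0:1), 5)))
  pts <- X %*% nm$points$points_level1 + (1 - X) %*% nm$points$points_level0
  lp <- m$intercept + X %*% m$coefficients
  expect_equal(nm$total_to_prob(drop(pts)), plogis(drop(lp)),
               tolerance = 1e-9)
  # baseline probability at zero total points
  expect_equal(nm$total_to_prob(0),
               plogis(m$intercept + sum(pmin(0, m$coefficients))))
  # single-variable model gets the full scale
  single <- structure(list(intercept = -1, coefficients = c(xx = 0.7),
                           thresholds = c(xx = 1), cutoff = 0),
                      class = "grade_model")
  expect_equal(nomogram_points(single)$points$max_points, 100)
  zero <- structure(list(intercept = 0, coefficients = c(xx = 0),
                         thresholds = c(xx = 1), cutoff = 0),
                    class = "grade_model")
  expect_error(nomogram_points(zero), "nonzero")
})
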