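# Feature screening: Youden-index dichotomization, 2x2 diagnostic
# statistics, group comparison and univariate logistic regression.

#' Dichotomize a continuous feature at the maximal Youden index
#'
#' Scans all candidate cuts (midpoints between consecutive sorted unique
#' values, plus -Inf and +Inf) in both coding directions and returns the
#' rule maximizing the Youden index J = sensitivity + specificity - 1.
#' Ties are broken toward the smaller cut, then toward coding ">=" as
#' positive.
#'
#' @param values Numeric feature values (no missing).
#' @param labels Binary outcome (1 = positive class).
#' @param feature Optional feature name recorded in the rule.
#' @return An object of class `youden_rule` with fields `feature`, `cut`,
#'   `direction` (`">="` or `"<"` coding positives), `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_dichotomize <- function(values, labels, feature = "feature") {
  labels <- as_binary01(labels)
  stopifnot(length(values) == length(labels))
  if (any(!is.finite(values))) stop("missing values in 'values'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  uq <- sort(unique(values))
  if (length(uq) == 1L) {
    warning("constant feature: Youden index is 0", call. = FALSE)
    rule <- list(feature = feature, cut = uq, direction = ">=",
                 youden_j = 0, sensitivity = NA_real_, specificity = NA_real_)
    return(structure(rule, class = "youden_rule"))
  }
  cuts <- c(-Inf, (head(uq, -1) + tail(uq, -1)) / 2, Inf)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- NULL
  for (cut in cuts) {
    for (dir in c(">=", "<")) {
      pos <- if (dir == ">=") values >= cut else values < cut
      sens <- sum(pos & labels == 1L) / n1
      spec <- sum(!pos & labels == 0L) / n0
      j <- sens + spec - 1
      better <- is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
           (cut < best$cut - 1e-12 ||
              (abs(cut - best$cut) <= 1e-12 && dir == ">=" && best$direction == "<")))
      if (better)
        best <- list(feature = feature, cut = cut, direction = dir,
                     youden_j = j, sensitivity = sens, specificity = spec)
    }
  }
  structure(best, class = "youden_rule")
}

#' @export
print.youden_rule <- function(x, ...) {
  cat(sprintf("<youden_rule> %s: positive when value %s %g (J = %.3f, sens %.3f, spec %.3f)\n",
              x$feature, x$direction, x$cut, x$youden_j, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' @method tidy youden_rule
#' @export
tidy.youden_rule <- function(x, ...) {
  tibble::tibble(feature = x$feature, cut = x$cut, direction = x$direction,
                 youden_j = x$youden_j, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' Apply a Youden rule to new values
#'
#' @param rule A `youden_rule`.
#' @param values Numeric vector.
#' @return Integer 0/1 vector of positives under the rule.
#' @export
apply_rule <- function(rule, values) {
  stopifnot(inherits(rule, "youden_rule"))
  as.integer(if (rule$direction == ">=") values >= rule$cut else values < rule$cut)
}

#' Diagnostic statistics of a 2x2 classification table
#'
#' Sensitivity, specificity, positive and negative predictive value with
#' Clopper-Pearson exact 95% confidence intervals, and the AUC of the
#' binary predictor, `(sensitivity + specificity) / 2`.
#'
#' @param tp,fp,fn,tn Non-negative cell counts; every margin must be > 0.
#' @return An object of class `diagnostic_summary`; `tidy()` returns the
#'   statistics as a tibble (proportions in `[0, 1]`).
#' @examples
#' tidy(contingency_diagnostics(tp = 60, fp = 21, fn = 9, tn = 15))
#' @export
contingency_diagnostics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  margins <- c(sensitivity = tp + fn, specificity = tn + fp,
               ppv = tp + fp, npv = tn + fn)
  if (any(margins == 0))
    stop("undefined statistic(s): ",
         paste(names(margins)[margins == 0], collapse = ", "),
         " (zero margin)", call. = FALSE)
  est <- c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
           ppv = tp / (tp + fp), npv = tn / (tn + fn))
  num <- c(tp, tn, tp, tn)
  ci <- mapply(clopper_pearson, num, margins, SIMPLIFY = FALSE)
  auc <- (est[["sensitivity"]] + est[["specificity"]]) / 2
  # DeLong variance for a binary score
  n1 <- tp + fn; n0 <- tn + fp
  v <- est[["sensitivity"]] * (1 - est[["sensitivity"]]) / (4 * n1) +
    est[["specificity"]] * (1 - est[["specificity"]]) / (4 * n0)
  auc_ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * sqrt(v), 0), 1)
  structure(list(counts = counts, estimates = est,
                 ci = setNames(ci, names(est)), auc = auc, auc_ci = auc_ci),
            class = "diagnostic_summary")
}

#' @method tidy diagnostic_summary
#' @export
tidy.diagnostic_summary <- function(x, ...) {
  tibble::tibble(
    statistic = c(names(x$estimates), "auc"),
    estimate = c(unname(x$estimates), x$auc),
    conf_low = c(vapply(x$ci, `[[`, numeric(1), "lower"), x$auc_ci[1]),
    conf_high = c(vapply(x$ci, `[[`, numeric(1), "upper"), x$auc_ci[2]))
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat("<diagnostic_summary>\n")
  print(tidy(x))
  invisible(x)
}

#' Compare a feature between two groups
#'
#' Continuous features: a Shapiro-Wilk gate on each group picks Student's
#' t-test (both normal at alpha = 0.05) or the Mann-Whitney U test.
#' Categorical features: Pearson chi-squared without continuity correction,
#' switching to Fisher's exact test when any expected cell count is < 5.
#'
#' @param values Feature vector.
#' @param groups Two-group labels.
#' @param kind `"continuous"`, `"categorical"`, or `"auto"` (categorical
#'   when `values` has <= 2 distinct values).
#' @return A one-row tibble with `method`, `statistic`, `p_value`.
#' @export
compare_groups <- function(values, groups,
                           kind = c("auto", "continuous", "categorical")) {
  kind <- match.arg(kind)
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L) stop("need exactly two groups", call. = FALSE)
  g <- droplevels(g)
  if (any(table(g) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (kind == "auto")
    kind <- if (length(unique(values)) <= 2L) "categorical" else "continuous"
  if (kind == "continuous") {
    normal <- all(tapply(values, g, function(v) {
      if (length(unique(v)) < 3L) return(FALSE)
      shapiro.test(v)$p.value > 0.05
    }))
    if (normal) {
      tt <- t.test(values ~ g, var.equal = TRUE)
      tibble::tibble(method = "t", statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(values ~ g))
      tibble::tibble(method = "mann-whitney", statistic = unname(wt$statistic),
                     p_value = wt$p.value)
    }
  } else {
    tab <- table(values, g)
    if (identical(dim(tab), c(1L, 2L)))
      return(tibble::tibble(method = "chi-squared", statistic = 0, p_value = 1))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble::tibble(method = "fisher", statistic = NA_real_,
                     p_value = ft$p.value)
    } else {
      ct <- chisq.test(tab, correct = FALSE)
      tibble::tibble(method = "chi-squared", statistic = unname(ct$statistic),
                     p_value = ct$p.value)
    }
  }
}

#' Univariate logistic regression of a binary outcome on one feature
#'
#' Maximum-likelihood logistic fit with Wald p-value and odds ratio. For a
#' binary feature this reproduces the closed-form 2x2 log-odds ratio.
#' Complete separation (a zero cell against the outcome) is flagged; the
#' p-value then falls back to the likelihood-ratio test, which remains
#' informative when the Wald statistic degenerates.
#'
#' @param x Feature vector (binary or continuous).
#' @param y Binary outcome.
#' @return One-row tibble: `estimate` (log-odds), `odds_ratio`, `std_error`,
#'   `p_value`, `separated`.
#' @export
univariate_logistic <- function(x, y) {
  y <- as_binary01(y, "y")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  co <- summary(fit)$coefficients
  separated <- FALSE
  if (length(unique(x)) == 2L) {
    tab <- table(x, y)
    separated <- any(tab == 0)
  }
  if (!separated) separated <- any(abs(co[-1, "Estimate"]) > 15)
  p <- co["x", "Pr(>|z|)"]
  if (separated) {
    lrt <- anova(glm(y ~ 1, family = binomial()), fit, test = "LRT")
    p <- lrt$`Pr(>Chi)`[2]
  }
  tibble::tibble(estimate = co["x", "Estimate"],
                 odds_ratio = exp(co["x", "Estimate"]),
                 std_error = co["x", "Std. Error"],
                 p_value = p, separated = separated)
}

#' Median imputation of missing numeric values
#'
#' Replaces each missing numeric entry by the median of the observed values
#' in its column; the per-column imputation counts are attached as
#' attribute `"imputed_counts"` and reported via `message()`.
#'
#' @param data A data frame.
#' @return A tibble with missing numeric values imputed.
#' @export
impute_median <- function(data) {
  data <- tibble::as_tibble(data)
  counts <- integer(0)
  for (nm in names(data)) {
    col <- data[[nm]]
    if (!is.numeric(col)) next
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss)) stop(sprintf("column '%s' is entirely missing", nm),
                        call. = FALSE)
    data[[nm]][miss] <- median(col[!miss])
    counts[nm] <- sum(miss)
  }
  if (length(counts))
    message("imputed ", sum(counts), " value(s) in ",
            length(counts), " column(s)")
  attr(data, "imputed_counts") <- counts
  data
}
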