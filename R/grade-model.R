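# The multivariable WHO/ISUP grade model: the published five-variable
# logistic equation, backward likelihood-ratio selection, ROC/AUC with
# DeLong inference, Hosmer-Lemeshow calibration, decision-curve analysis
# and nomogram scoring.

#' The published five-variable grade model
#'
#' The reference logistic score for high WHO/ISUP nuclear grade,
#' \deqn{Y = 0.936 - 1.418 X_1 + 1.334 X_2 - 1.585 X_3 - 1.198 X_4 + 1.631 X_5}
#' where X1..X5 indicate that D_p_ROI_Low, tumor size, serum albumin,
#' platelet count and lymphocyte count exceed their Youden thresholds
#' (13.677e-3 mm^2/s, 6.7 cm, 42.6 g/L, 178e9/L, 1.388e9/L). A case is
#' called high grade when the linear score Y is at or above the operating
#' cutoff 1.12.
#'
#' @return An object of class `grade_model` with `intercept`,
#'   `coefficients` (named, log-odds units), `thresholds` and `cutoff`.
#' @export
printed_grade_model <- function() {
  structure(
    list(intercept = 0.936,
         coefficients = c(D_p_ROI_Low = -1.418, tumor_size = 1.334,
                          serum_albumin = -1.585, platelet_count = -1.198,
                          lymphocyte_count = 1.631),
         thresholds = c(D_p_ROI_Low = 13.677, tumor_size = 6.7,
                        serum_albumin = 42.6, platelet_count = 178,
                        lymphocyte_count = 1.388),
         cutoff = 1.12),
    class = "grade_model")
}

#' @export
print.grade_model <- function(x, ...) {
  cat("<grade_model> Y =", format(x$intercept), "+",
      paste(sprintf("(%+.3f)*%s", x$coefficients, names(x$coefficients)),
            collapse = " + "), "\n  high grade when Y >=", x$cutoff, "\n")
  invisible(x)
}

#' @method tidy grade_model
#' @export
tidy.grade_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)),
                 threshold = c(NA_real_, unname(x$thresholds)))
}

#' Score cases with the published grade model
#'
#' Evaluates the published linear score on binary indicator inputs and
#' classifies at the published cutoff.
#'
#' @param x Binary inputs: a length-5 vector, a matrix, or a data frame
#'   holding the five indicator columns in model order (D_p_ROI_Low, tumor
#'   size, serum albumin, platelet count, lymphocyte count above their
#'   thresholds).
#' @param model A `grade_model` (default [printed_grade_model()]).
#' @return A tibble with `score` (linear predictor Y) and
#'   `predicted_class` (`"high"` / `"low"`).
#' @examples
#' score_printed_model(c(0, 0, 0, 0, 0))  # baseline score 0.936
#' @export
score_printed_model <- function(x, model = printed_grade_model()) {
  stopifnot(inherits(model, "grade_model"))
  k <- length(model$coefficients)
  if (is.data.frame(x)) {
    if (all(names(model$coefficients) %in% names(x)))
      x <- as.matrix(x[names(model$coefficients)])
    else x <- as.matrix(x)
  }
  if (is.null(dim(x))) {
    if (length(x) != k) stop(sprintf("expected %d inputs", k), call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != k) stop(sprintf("expected %d columns", k), call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("inputs must be binary 0/1", call. = FALSE)
  y <- model$intercept + drop(x %*% model$coefficients)
  tibble::tibble(score = y,
                 predicted_class = ifelse(y >= model$cutoff, "high", "low"))
}

#' Backward likelihood-ratio logistic model selection
#'
#' Fits the full maximum-likelihood logistic model on the candidate
#' features, then repeatedly removes the variable with the largest
#' likelihood-ratio removal p-value while that p-value is at or above
#' `p_remove` (default 0.10, the conventional backward-LR default).
#'
#' @param data Data frame of features and outcome.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate feature columns
#'   (pre-screened, e.g. at univariate p < 0.05).
#' @param p_remove Removal threshold for the LR test p-value.
#' @return An object of class `grade_fit`: the final `glm` fit plus the
#'   removal trace; `tidy()`/`glance()` summarize coefficients and fit.
#' @export
fit_multivariable_backward <- function(data, outcome, candidates,
                                       p_remove = 0.10) {
  stopifnot(outcome %in% names(data))
  y <- as_binary01(data[[outcome]], outcome)
  df <- data.frame(.y = y, data[candidates], check.names = FALSE)
  current <- candidates
  trace <- character(0)
  repeat {
    fml <- if (length(current))
      as.formula(paste(".y ~", paste(sprintf("`%s`", current), collapse = "+")))
    else as.formula(".y ~ 1")
    fit <- glm(fml, family = binomial(), data = df)
    if (!fit$converged) stop("logistic fit failed to converge; trace: ",
                             paste(trace, collapse = " -> "), call. = FALSE)
    if (length(current) == 0L) break
    dr <- drop1(fit, test = "LRT")
    pv <- dr$`Pr(>Chi)`[-1]
    names(pv) <- rownames(dr)[-1]
    worst <- which.max(pv)
    if (pv[worst] >= p_remove) {
      drop_name <- gsub("`", "", names(pv)[worst])
      trace <- c(trace, sprintf("%s (p=%.3f)", drop_name, pv[worst]))
      current <- setdiff(current, drop_name)
    } else break
  }
  structure(list(fit = fit, retained = current, removed_trace = trace,
                 outcome = outcome, candidates = candidates),
            class = "grade_fit")
}

#' @export
print.grade_fit <- function(x, ...) {
  cat(sprintf("<grade_fit> retained %d of %d candidates: %s\n",
              length(x$retained), length(x$candidates),
              paste(x$retained, collapse = ", ")))
  if (length(x$removed_trace))
    cat("  removed:", paste(x$removed_trace, collapse = " -> "), "\n")
  invisible(x)
}

#' @method tidy grade_fit
#' @export
tidy.grade_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = gsub("`", "", rownames(co)),
                 estimate = co[, "Estimate"],
                 std_error = co[, "Std. Error"],
                 statistic = co[, "z value"],
                 p_value = co[, "Pr(>|z|)"])
}

#' @method glance grade_fit
#' @export
glance.grade_fit <- function(x, ...) {
  tibble::tibble(n = length(x$fit$y),
                 n_retained = length(x$retained),
                 deviance = x$fit$deviance,
                 null_deviance = x$fit$null.deviance,
                 aic = x$fit$aic,
                 log_lik = as.numeric(logLik(x$fit)))
}

#' ROC curve and AUC with DeLong inference
#'
#' AUC by the Mann-Whitney formulation with tie correction, 95% CI from the
#' DeLong covariance estimator, and the Youden-optimal operating point.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = positive class).
#' @return An object of class `roc_result` with `auc`, `ci`, `sensitivity`,
#'   `specificity`, `threshold` and the underlying `pROC::roc` object;
#'   `autoplot()` draws the curve.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary01(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC 0.5 with degenerate CI", call. = FALSE)
    return(structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                          sensitivity = NA_real_, specificity = NA_real_,
                          threshold = NA_real_, roc = NULL,
                          n = length(labels)),
                     class = "roc_result"))
  }
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  best <- best[1, ]  # lowest threshold on ties
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci = pmin(pmax(ci, 0), 1),
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 threshold = best$threshold, roc = r, n = length(labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), sens %.3f / spec %.3f at %.4g\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity,
              x$threshold))
  invisible(x)
}

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, conf_low = x$ci[1], conf_high = x$ci[2],
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold, n = x$n)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  if (is.null(x$roc))
    return(tibble::tibble(threshold = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_))
  co <- pROC::coords(x$roc, "all", transpose = FALSE)
  tibble::as_tibble(co)
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same cases using
#' the DeLong structural-components covariance estimator.
#'
#' @param scores_a,scores_b Paired risk scores.
#' @param labels Binary outcome shared by both scores.
#' @return One-row tibble with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary01(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(scores_a)) == 1L || length(unique(scores_b)) == 1L)
    stop("constant scores: DeLong test undefined", call. = FALSE)
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    auc_same <- as.numeric(pROC::auc(ra))
    return(tibble::tibble(auc_a = auc_same, auc_b = auc_same, z = 0,
                          p_value = 1))
  }
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 z = unname(tst$statistic), p_value = tst$p.value)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups cases into `g` (default 10) deciles of predicted risk and forms
#' the Pearson statistic of observed vs expected events and non-events per
#' group, on `g - 2` degrees of freedom. Groups with zero expected events
#' (or non-events) are merged with their neighbor, with a message.
#'
#' @param prob Predicted probabilities in (0, 1).
#' @param outcome Binary observed outcomes.
#' @param g Number of risk groups (>= 3).
#' @return One-row tibble `statistic`, `df`, `p_value`; the per-group table
#'   is attached as attribute `"groups"`.
#' @export
hosmer_lemeshow <- function(prob, outcome, g = 10L) {
  outcome <- as_binary01(outcome, "outcome")
  stopifnot(length(prob) == length(outcome))
  if (any(prob <= 0 | prob >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  if (g < 3L) stop("need g >= 3 (df = g - 2 must be positive)", call. = FALSE)
  if (length(prob) < 2L * g)
    stop("need at least 2g observations", call. = FALSE)
  br <- unique(quantile(prob, probs = seq(0, 1, length.out = g + 1)))
  grp <- if (length(br) < 2L) factor(rep("all", length(prob)))
  else cut(prob, breaks = br, include.lowest = TRUE)
  tab <- dplyr::tibble(grp = grp, prob = prob, y = outcome) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(n = dplyr::n(), obs = sum(.data$y),
                     exp = sum(.data$prob), .groups = "drop")
  # merge groups whose expected events or non-events vanish
  while (nrow(tab) > 2L &&
         any(tab$exp < 1e-9 | (tab$n - tab$exp) < 1e-9)) {
    i <- which(tab$exp < 1e-9 | (tab$n - tab$exp) < 1e-9)[1]
    j <- if (i == 1L) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$obs[j] <- tab$obs[j] + tab$obs[i]
    tab$exp[j] <- tab$exp[j] + tab$exp[i]
    tab <- tab[-i, ]
    message("merged a risk group with zero expected count")
  }
  chi2 <- sum((tab$obs - tab$exp)^2 / tab$exp +
                ((tab$n - tab$obs) - (tab$n - tab$exp))^2 / (tab$n - tab$exp))
  df <- nrow(tab) - 2L
  out <- tibble::tibble(
    statistic = chi2, df = df,
    p_value = if (df > 0L) pchisq(chi2, df, lower.tail = FALSE) else NA_real_)
  attr(out, "groups") <- tab
  out
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability pt,
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, against the treat-all and
#' treat-none strategies.
#'
#' @param prob Predicted probabilities.
#' @param outcome Binary observed outcomes.
#' @param thresholds Grid of threshold probabilities in (0, 1); values at
#'   or above 1 are dropped.
#' @return A long tibble `threshold`, `strategy`, `net_benefit`;
#'   `autoplot()` (via [plot_decision_curve()]) draws the curves.
#' @export
decision_curve <- function(prob, outcome,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  outcome <- as_binary01(outcome, "outcome")
  stopifnot(length(prob) == length(outcome))
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(outcome)
  prev <- mean(outcome)
  rows <- purrr::map_dfr(thresholds, function(pt) {
    w <- pt / (1 - pt)
    tp <- sum(prob >= pt & outcome == 1L)
    fp <- sum(prob >= pt & outcome == 0L)
    tibble::tibble(
      threshold = pt,
      strategy = c("model", "treat_all", "treat_none"),
      net_benefit = c(tp / n - fp / n * w,
                      prev - (1 - prev) * w,
                      0))
  })
  class(rows) <- c("decision_curve", class(rows))
  rows
}

#' Plot a decision curve
#'
#' @param x A tibble from [decision_curve()].
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                  color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot decision_curve
#' @export
autoplot.decision_curve <- function(object, ...) plot_decision_curve(object)

#' Nomogram point scales for a logistic model
#'
#' Assigns each variable a point scale proportional to the magnitude of its
#' coefficient (the largest coefficient magnitude maps to 100 points, with
#' the variable's least favorable level at 0 points) and returns the map
#' from total points to predicted probability.
#'
#' @param model A `grade_model` or `grade_fit`.
#' @return An object of class `nomogram_scale`: a list with `points` (a
#'   tibble of per-variable point values at levels 0 and 1), `unit`
#'   (log-odds per point), `baseline` (linear predictor at 0 total points)
#'   and `total_to_prob(total_points)`.
#' @export
nomogram_points <- function(model) {
  if (inherits(model, "grade_fit")) {
    cf <- coef(model$fit)
    intercept <- unname(cf["(Intercept)"])
    beta <- cf[setdiff(names(cf), "(Intercept)")]
    names(beta) <- gsub("`", "", names(beta))
  } else if (inherits(model, "grade_model")) {
    intercept <- model$intercept
    beta <- model$coefficients
  } else stop("'model' must be a grade_model or grade_fit", call. = FALSE)
  if (length(beta) == 0L || all(beta == 0))
    stop("model has no nonzero coefficients", call. = FALSE)
  unit <- max(abs(beta)) / 100
  # indicator variables: contribution at level 0 is 0, at level 1 is beta;
  # points are shifted so each variable's minimum contribution scores 0
  shift <- pmin(0, beta)
  pts0 <- (0 - shift) / unit
  pts1 <- (beta - shift) / unit
  baseline <- intercept + sum(shift)
  points <- tibble::tibble(variable = names(beta), beta = unname(beta),
                           points_level0 = unname(pts0),
                           points_level1 = unname(pts1),
                           max_points = pmax(unname(pts0), unname(pts1)))
  total_to_prob <- function(total_points) plogis(baseline + unit * total_points)
  structure(list(points = points, unit = unit, baseline = baseline,
                 total_to_prob = total_to_prob),
            class = "nomogram_scale")
}

#' @export
print.nomogram_scale <- function(x, ...) {
  cat("<nomogram_scale> 100 points =", format(100 * x$unit), "log-odds\n")
  print(x$points)
  invisible(x)
}

#' @method tidy nomogram_scale
#' @export
tidy.nomogram_scale <- function(x, ...) x$points
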