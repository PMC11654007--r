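# Kaplan-Meier estimation, log-rank comparison and inter-reader agreement.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function with Greenwood variance
#' and the median survival time (smallest time at which S(t) drops to 0.5
#' or below; undefined when the curve never reaches 0.5). Censorings at an
#' event time remain at risk for that event, following the standard
#' convention.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event flags (1 = event, 0 = censored).
#' @return An object of class `km_curve`: a tibble with `time`, `n_risk`,
#'   `n_event`, `survival` and `greenwood_var`, with the `median` and `n`
#'   as attributes; `glance()` summarizes, `autoplot()` draws the step
#'   curve.
#' @examples
#' km <- km_estimate(c(5, 10, 15), c(0, 1, 1))
#' attr(km, "median")
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  events <- as_binary01(events, "events")
  stopifnot(length(times) == length(events), all(times >= 0))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(sf, censored = TRUE)
  curve <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    survival = s$surv,
    # summary.survfit std.err is the Greenwood SE of S(t); undefined once
    # the at-risk set is exhausted (S = 0)
    greenwood_var = ifelse(is.finite(s$std.err^2), s$std.err^2, NA_real_))
  med <- curve$time[curve$survival <= 0.5][1]
  out <- structure(curve, class = c("km_curve", class(curve)))
  attr(out, "median") <- if (is.na(med)) NA_real_ else med
  attr(out, "n") <- length(times)
  out
}

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_event = sum(x$n_event),
                 median = attr(x, "median"),
                 median_reached = !is.na(attr(x, "median")))
}

#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tibble::as_tibble(object)[, c("time", "survival")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Progression-free survival") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event flags.
#' @param groups Two-group labels.
#' @return One-row tibble with `chi2` (1 df) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  events <- as_binary01(events, "events")
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  if (sum(events) == 0L) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  tibble::tibble(chi2 = sd$chisq,
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

band_agreement <- function(v) {
  if (!is.finite(v)) return(NA_character_)
  if (v <= 0) "poor"
  else if (v <= 0.200) "slight"
  else if (v <= 0.400) "fair"
  else if (v <= 0.600) "moderate"
  else if (v <= 0.800) "substantial"
  else "excellent"
}

#' Intraclass correlation between two readers
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC --
#' ICC(2,1) -- for paired continuous measurements from two readers, with
#' the conventional interpretation band (slight / fair / moderate /
#' substantial / excellent).
#'
#' @param a,b Paired measurements from the two readers (n >= 3).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return One-row tibble `statistic`, `value`, `band`.
#' @export
icc_two_reader <- function(a, b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired measurements", call. = FALSE)
  x <- cbind(a, b)
  k <- 2L
  if (var(as.vector(x)) == 0) stop("zero total variance", call. = FALSE)
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  tibble::tibble(statistic = if (type == "agreement") "ICC(2,1)" else "ICC(3,1)",
                 value = val, band = band_agreement(val))
}

#' Cohen's kappa between two readers
#'
#' Unweighted kappa, `(p_o - p_e) / (1 - p_e)`, for paired categorical
#' ratings; when both raters are constant and identical (chance agreement
#' 1) kappa is reported as 1 with a warning.
#'
#' @param a,b Paired categorical ratings.
#' @return One-row tibble `statistic`, `value`, `band`.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(as.character(a), as.character(b))))
  ta <- factor(as.character(a), levels = lev)
  tb <- factor(as.character(b), levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("both raters constant and equal: kappa defined as 1",
            call. = FALSE)
    kap <- 1
  } else kap <- (po - pe) / (1 - pe)
  tibble::tibble(statistic = "kappa", value = kap, band = band_agreement(kap))
}
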