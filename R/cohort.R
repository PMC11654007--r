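# Synthetic patient cohorts with the grade-conditional feature structure
# and progression-free-survival behavior of the ccRCC + venous-tumor-thrombus
# population the package models.

#' Specification of a synthetic patient cohort
#'
#' Defines the sampling law of a synthetic cohort: the high-grade
#' prevalence, per-feature grade-conditional probabilities of exceeding a
#' clinical threshold (continuous features are drawn from grade-conditional
#' log-normals calibrated so the threshold-exceedance probabilities hold),
#' and grade-specific exponential progression-free-survival laws.
#'
#' @param n_patients Number of patients (>= 2).
#' @param prevalence_high_grade Probability of high WHO/ISUP grade.
#' @param feature_rules Data frame with columns `feature`, `threshold`
#'   (`NA` for intrinsically binary features), `p_pos_low`, `p_pos_high`
#'   (grade-conditional probabilities that the feature is "positive", i.e.
#'   at or above threshold), `continuous` (logical) and `sdlog`
#'   (log-normal shape for continuous features). Default:
#'   [default_feature_rules()].
#' @param pfs_law List with per-grade median PFS (months) and censoring
#'   fractions: `median_low`, `median_high`, `censor_frac`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 105L,
                        prevalence_high_grade = 69 / 105,
                        feature_rules = default_feature_rules(),
                        pfs_law = list(median_low = 33.9, median_high = 13.2,
                                       censor_frac = 0.3),
                        seed = 1L) {
  if (n_patients < 2L) stop("'n_patients' must be >= 2", call. = FALSE)
  if (prevalence_high_grade < 0 || prevalence_high_grade > 1)
    stop("'prevalence_high_grade' must lie in [0, 1]", call. = FALSE)
  fr <- tibble::as_tibble(feature_rules)
  req <- c("feature", "threshold", "p_pos_low", "p_pos_high", "continuous", "sdlog")
  if (!all(req %in% names(fr)))
    stop("feature_rules must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(fr$feature)) stop("feature names must be unique", call. = FALSE)
  if (any(fr$p_pos_low < 0 | fr$p_pos_low > 1 | fr$p_pos_high < 0 | fr$p_pos_high > 1))
    stop("conditional probabilities must lie in [0, 1]", call. = FALSE)
  if (pfs_law$median_low <= 0 || pfs_law$median_high <= 0)
    stop("PFS medians must be > 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_high_grade = prevalence_high_grade,
                 feature_rules = fr, pfs_law = pfs_law,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default grade-conditional feature rules
#'
#' The package's reference sampling rules for the imaging, laboratory and
#' clinical features of the synthetic cohort. The grade-conditional
#' probabilities of exceeding each clinical threshold are the observed
#' conditional proportions in a 105-patient training population (36
#' low-grade, 69 high-grade); continuous features are positive-valued,
#' right-skewed clinical measurements and are generated as grade-conditional
#' log-normals calibrated to those exceedance probabilities.
#'
#' Diffusion thresholds are in 1e-3 mm^2/s, tumor size in cm, serum albumin
#' in g/L, platelet and lymphocyte counts in 1e9/L.
#'
#' @return A tibble of feature rules (see [cohort_spec()]).
#' @export
default_feature_rules <- function() {
  tibble::tribble(
    ~feature,               ~threshold, ~p_pos_low, ~p_pos_high, ~continuous, ~sdlog,
    "D_p_ROI_Low",              13.677,    31 / 36,     44 / 69,        TRUE,   0.35,
    "tumor_size",                  6.7,    19 / 36,     50 / 69,        TRUE,   0.30,
    "serum_albumin",              42.6,    17 / 36,     11 / 69,        TRUE,   0.10,
    "platelet_count",              178,    21 / 36,     60 / 69,        TRUE,   0.30,
    "lymphocyte_count",          1.388,    29 / 36,     37 / 69,        TRUE,   0.40,
    "D_t_ROI_Low",               0.925,    18 / 36,     18 / 69,        TRUE,   0.25,
    "ADC_ROI_Low",               1.135,    25 / 36,     20 / 69,        TRUE,   0.25,
    "f_ROI_Low",                 0.262,    25 / 36,     32 / 69,        TRUE,   0.40,
    "hemoglobin",                  121,    27 / 36,     27 / 69,        TRUE,   0.15,
    "serum_urea",                 4.52,    32 / 36,     41 / 69,        TRUE,   0.30,
    "clinical_symptoms",            NA,    21 / 36,     57 / 69,       FALSE,     NA,
    "T2LIA",                        NA,    18 / 36,     49 / 69,       FALSE,     NA,
    "rbc_in_urine",                 NA,    13 / 36,     39 / 69,       FALSE,     NA)
}

# Log-normal meanlog giving P(X >= thr) = p at shape sdlog.
lognormal_meanlog <- function(thr, p, sdlog) {
  log(thr) - sdlog * qnorm(1 - pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Generate a synthetic patient cohort
#'
#' Draws grade labels at the specified prevalence, then each feature from
#' its grade-conditional law: intrinsically binary features as Bernoulli
#' draws, continuous features from grade-conditional log-normals whose
#' threshold-exceedance probability matches the rule. Progression-free
#' survival comes from [generate_survival_times()]. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `patient_id`, `grade_high` (0/1), one column per
#'   feature (continuous value, or 0/1 for binary features), `pfs_months`
#'   and `pfs_event`; the spec is attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec",
                                           call. = FALSE)
  n <- spec$n_patients
  set.seed(child_seed(spec$seed, "cohort-grade"))
  grade <- rbinom(n, 1L, spec$prevalence_high_grade)

  out <- tibble::tibble(patient_id = seq_len(n), grade_high = grade)
  fr <- spec$feature_rules
  for (i in seq_len(nrow(fr))) {
    r <- fr[i, ]
    set.seed(child_seed(spec$seed, paste0("feature-", r$feature)))
    p <- ifelse(grade == 1L, r$p_pos_high, r$p_pos_low)
    if (isTRUE(r$continuous)) {
      ml <- lognormal_meanlog(r$threshold, p, r$sdlog)
      out[[r$feature]] <- exp(rnorm(n, mean = ml, sd = r$sdlog))
    } else {
      out[[r$feature]] <- rbinom(n, 1L, p)
    }
  }
  surv <- generate_survival_times(grade, spec$pfs_law,
                                  seed = child_seed(spec$seed, "survival"))
  out$pfs_months <- surv$time
  out$pfs_event <- surv$event
  attr(out, "spec") <- spec
  out
}

#' Generate grade-stratified progression-free-survival times
#'
#' Event times are exponential with rate `log(2) / median` of the group;
#' censoring times are independent exponentials with rate chosen so the
#' expected censored fraction equals `censor_frac`. The observation is
#' `min(event, censor)` with the corresponding event flag.
#'
#' @param grade_high 0/1 vector of grade labels.
#' @param pfs_law List with `median_low`, `median_high` (months, > 0) and
#'   `censor_frac` in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble with `time` (months) and `event` (1 = progression,
#'   0 = censored).
#' @export
generate_survival_times <- function(grade_high, pfs_law, seed = 1L) {
  if (length(grade_high) == 0L) stop("empty grade label vector", call. = FALSE)
  grade_high <- as_binary01(grade_high, "grade_high")
  med <- ifelse(grade_high == 1L, pfs_law$median_high, pfs_law$median_low)
  if (any(med <= 0)) stop("PFS medians must be > 0", call. = FALSE)
  cf <- pfs_law$censor_frac %||% 0
  if (cf < 0 || cf > 1) stop("'censor_frac' must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  rate <- log(2) / med
  t_event <- rexp(length(med), rate = rate)
  if (cf >= 1) {
    # degenerate: everything censored; report the drawn times as censoring
    return(tibble::tibble(time = t_event, event = 0L))
  }
  if (cf == 0) {
    return(tibble::tibble(time = t_event, event = 1L))
  }
  # for independent exponentials, P(censor < event) = rc / (rc + re)
  rc <- rate * cf / (1 - cf)
  t_cens <- rexp(length(med), rate = rc)
  tibble::tibble(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
}
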