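# File I/O (NIfTI series, bval sidecars, cohort CSV + schema) and the
# end-to-end pipeline orchestrator.

#' Write a phantom to disk
#'
#' Writes the 4D signal as NIfTI, the tumor mask and each ground-truth map
#' as 3D NIfTI, the b-value/NEX table as a two-row plain-text sidecar
#' (b-values on the first row, FSL bval style; NEX counts on the second)
#' and a JSON metadata file.
#'
#' @param phantom A `dwi_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$series$voxel_size
  wn <- function(img, path) {
    nim <- RNifti::asNifti(img)
    RNifti::pixdim(nim) <- if (length(dim(img)) == 4L) c(vs, 1) else vs
    RNifti::writeNifti(nim, path)
    path
  }
  paths <- c(
    dwi = wn(phantom$series$signal, file.path(dir, "dwi.nii.gz")),
    mask = wn(phantom$mask * 1, file.path(dir, "mask.nii.gz")))
  for (m in c("adc", "d_t", "d_p", "f", "s0")) {
    paths[paste0("truth_", m)] <-
      wn(phantom$truth[[m]], file.path(dir, sprintf("truth_%s.nii.gz", m)))
  }
  bval_path <- file.path(dir, "dwi.bval")
  writeLines(c(paste(phantom$series$b_values, collapse = " "),
               paste(phantom$series$nex_per_b, collapse = " ")), bval_path)
  paths["bval"] <- bval_path
  meta_path <- file.path(dir, "phantom.json")
  jsonlite::write_json(
    list(grid_shape = phantom$spec$grid_shape,
         voxel_size_mm = vs,
         b_values = phantom$series$b_values,
         nex_per_b = phantom$series$nex_per_b,
         noise_sigma = phantom$spec$noise_sigma,
         seed = phantom$spec$seed),
    meta_path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  paths["metadata"] <- meta_path
  invisible(paths)
}

#' Read a multi-b DWI series
#'
#' Loads a 4D NIfTI signal volume together with its b-value sidecar (first
#' row b-values in s/mm^2, optional second row of NEX counts) and validates
#' them against each other.
#'
#' @param nifti_path Path to the 4D NIfTI file.
#' @param bval_path Path to the plain-text b-value sidecar.
#' @return A `dwi_series` object.
#' @export
read_dwi <- function(nifti_path, bval_path) {
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D DWI volume", call. = FALSE)
  lines <- readLines(bval_path)
  b <- scan(text = lines[1], quiet = TRUE)
  nex <- if (length(lines) >= 2L && nzchar(trimws(lines[2])))
    as.integer(scan(text = lines[2], quiet = TRUE)) else rep(1L, length(b))
  if (length(b) != dim(img)[4])
    stop(sprintf("bval sidecar has %d entries but the series has %d volumes",
                 length(b), dim(img)[4]), call. = FALSE)
  if (any(b < 0)) stop("negative b-value in sidecar", call. = FALSE)
  if (b[1] != 0 || any(diff(b) <= 0))
    stop("b-values must start at 0 and increase strictly", call. = FALSE)
  if (length(nex) != length(b) || any(nex < 1))
    stop("NEX row must match b-values and be positive", call. = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  new_dwi_series(signal = array(as.numeric(img), dim = dim(img)),
                 b_values = b, nex_per_b = nex, voxel_size = vs)
}

#' Write a cohort with its schema sidecar
#'
#' @param cohort Cohort tibble (e.g. from [generate_cohort()]).
#' @param csv_path Output CSV path; the JSON schema naming each column's
#'   type (and threshold where one exists) is written next to it with
#'   extension `.schema.json`.
#' @return Invisibly, `c(csv, schema)` paths.
#' @export
write_cohort <- function(cohort, csv_path) {
  write.csv(cohort, csv_path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  thr <- if (!is.null(spec))
    setNames(as.list(spec$feature_rules$threshold), spec$feature_rules$feature)
  else list()
  cols <- lapply(names(cohort), function(nm) {
    type <- if (nm == "grade_high") "grade"
    else if (nm == "pfs_months") "time"
    else if (nm == "pfs_event") "event"
    else if (is.numeric(cohort[[nm]]) && !all(cohort[[nm]] %in% c(0, 1)))
      "continuous"
    else if (nm == "patient_id") "id"
    else "binary"
    out <- list(type = type)
    if (!is.null(thr[[nm]]) && !is.na(thr[[nm]])) out$threshold <- thr[[nm]]
    out
  })
  names(cols) <- names(cohort)
  schema_path <- sub("\\.csv$", ".schema.json", csv_path)
  jsonlite::write_json(list(columns = cols), schema_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, schema = schema_path))
}

#' Load a cohort CSV against its schema
#'
#' Reads the table, validates it against the JSON schema (every column
#' must be named in the schema, exactly one grade column, binary event
#' flag) and median-imputes missing numeric values via [impute_median()].
#'
#' @param csv_path Cohort CSV path.
#' @param schema_path JSON schema path (default: `.schema.json` sibling).
#' @return A typed tibble; imputation counts are attached as attribute
#'   `"imputed_counts"` and the schema as `"schema"`.
#' @export
load_cohort <- function(csv_path,
                        schema_path = sub("\\.csv$", ".schema.json", csv_path)) {
  schema <- jsonlite::read_json(schema_path)
  dat <- tibble::as_tibble(read.csv(csv_path))
  unknown <- setdiff(names(dat), names(schema$columns))
  if (length(unknown))
    stop("columns not named in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  types <- vapply(schema$columns[names(dat)], function(c) c$type, character(1))
  if (sum(types == "grade") != 1L)
    stop("schema must name exactly one grade column", call. = FALSE)
  ev <- names(types)[types == "event"]
  for (e in ev) {
    v <- dat[[e]][!is.na(dat[[e]])]
    if (!all(v %in% c(0, 1)))
      stop(sprintf("event column '%s' is not binary", e), call. = FALSE)
  }
  dat <- suppressMessages(impute_median(dat))
  attr(dat, "schema") <- schema
  dat
}

pipeline_stage <- function(manifest, name, expr) {
  res <- tryCatch(list(value = force(expr), error = NULL),
                  error = function(e) list(value = NULL, error = conditionMessage(e)))
  manifest$stages[[name]] <- list(
    status = if (is.null(res$error)) "ok" else "error",
    error = res$error)
  list(manifest = manifest, value = res$value, failed = !is.null(res$error))
}

#' Run the full synthetic-to-survival pipeline
#'
#' Orchestrates phantom simulation, voxel-wise map fitting, ROI feature
#' extraction, cohort generation, Youden screening, grade modelling
#' (either the published equation or a backward-selected refit) and
#' Kaplan-Meier stratification, writing every artifact plus a JSON run
#' manifest under `out_dir`. Deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Global seed fanned out to per-stage child seeds.
#' @param model_source `"printed"` (apply the published five-variable
#'   equation) or `"fit"` (backward-selected refit on the synthetic
#'   cohort).
#' @param phantom Optional [phantom_spec()] override.
#' @param cohort Optional [cohort_spec()] override.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         model_source = c("printed", "fit"),
                         phantom = NULL, cohort = NULL) {
  model_source <- match.arg(model_source)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, model_source = model_source,
                   package_version = as.character(utils::packageVersion("ivimgrade")),
                   stages = list(), files = list())
  finish <- function(m) {
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(m)
  }

  ## 1. phantom simulation + fitting + ROI features
  ph_spec <- phantom %||% phantom_spec(seed = child_seed(seed, "pipeline-phantom"))
  st <- pipeline_stage(manifest, "simulate", {
    ph <- generate_phantom(ph_spec)
    paths <- write_phantom(ph, file.path(out_dir, "phantom"))
    list(ph = ph, paths = paths)
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  ph <- st$value$ph
  manifest$files$simulate <- unname(st$value$paths)

  st <- pipeline_stage(manifest, "fit", {
    maps <- fit_ivim_maps(ph$series, ph$mask)
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    paths <- character(0)
    for (m in c("adc", "d_t", "d_p", "f")) {
      p <- file.path(map_dir, sprintf("%s.nii.gz", m))
      nim <- RNifti::asNifti(maps[[m]])
      RNifti::pixdim(nim) <- maps$voxel_size
      RNifti::writeNifti(nim, p)
      paths <- c(paths, p)
    }
    rep_path <- file.path(map_dir, "fit_report.json")
    jsonlite::write_json(as.list(glance(maps)), rep_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(maps = maps, paths = c(paths, rep_path))
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  maps <- st$value$maps
  manifest$files$fit <- st$value$paths

  st <- pipeline_stage(manifest, "roi", {
    rois <- define_rois(maps, ph$mask)
    feats <- summarize_rois(maps, rois)
    p <- file.path(out_dir, "roi_features.csv")
    write.csv(feats, p, row.names = FALSE)
    list(feats = feats, paths = p)
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  manifest$files$roi <- st$value$paths

  ## 2. cohort generation + screening
  co_spec <- cohort %||% cohort_spec(seed = child_seed(seed, "pipeline-cohort"))
  st <- pipeline_stage(manifest, "cohort", {
    co <- generate_cohort(co_spec)
    paths <- write_cohort(co, file.path(out_dir, "cohort.csv"))
    list(co = co, paths = unname(paths))
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  co <- st$value$co
  manifest$files$cohort <- st$value$paths

  model <- printed_grade_model()
  model_vars <- names(model$coefficients)
  st <- pipeline_stage(manifest, "screen", {
    rules <- lapply(model_vars, function(v)
      youden_dichotomize(co[[v]], co$grade_high, feature = v))
    names(rules) <- model_vars
    rules_path <- file.path(out_dir, "threshold_rules.json")
    jsonlite::write_json(
      lapply(rules, function(r) r[c("feature", "cut", "direction", "youden_j")]),
      rules_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    # Table-4-style diagnostics of each dichotomized predictor at the
    # published thresholds
    diag_rows <- purrr::map_dfr(model_vars, function(v) {
      pos <- as.integer(co[[v]] >= model$thresholds[[v]])
      if (model$coefficients[[v]] < 0) pos <- 1L - pos
      tp <- sum(pos == 1 & co$grade_high == 1)
      fp <- sum(pos == 1 & co$grade_high == 0)
      fn <- sum(pos == 0 & co$grade_high == 1)
      tn <- sum(pos == 0 & co$grade_high == 0)
      d <- contingency_diagnostics(tp, fp, fn, tn)
      dplyr::mutate(tidy(d), feature = v, .before = 1)
    })
    diag_path <- file.path(out_dir, "diagnostics.csv")
    write.csv(diag_rows, diag_path, row.names = FALSE)
    list(rules = rules, paths = c(rules_path, diag_path))
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  manifest$files$screen <- st$value$paths

  ## 3. grade model
  st <- pipeline_stage(manifest, "predict", {
    X <- purrr::map_dfc(model_vars, function(v)
      tibble::tibble(!!v := as.integer(co[[v]] >= model$thresholds[[v]])))
    if (model_source == "printed") {
      scored <- score_printed_model(X, model)
      used_model <- model
      model_json <- list(source = "printed",
                         intercept = model$intercept,
                         coefficients = as.list(model$coefficients),
                         thresholds = as.list(model$thresholds),
                         cutoff = model$cutoff)
    } else {
      fitb <- fit_multivariable_backward(dplyr::bind_cols(X, grade_high = co$grade_high),
                                         "grade_high", model_vars)
      lp <- predict(fitb$fit, type = "link")
      scored <- tibble::tibble(score = lp,
                               predicted_class = ifelse(lp >= model$cutoff,
                                                        "high", "low"))
      used_model <- fitb
      model_json <- list(source = "fit",
                         coefficients = as.list(coef(fitb$fit)),
                         retained = fitb$retained,
                         cutoff = model$cutoff)
    }
    roc <- roc_auc(scored$score, co$grade_high)
    prob <- plogis(scored$score)
    dca <- decision_curve(prob, co$grade_high)
    model_path <- file.path(out_dir, "model.json")
    jsonlite::write_json(model_json, model_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    roc_path <- file.path(out_dir, "roc_curve.csv")
    write.csv(tidy(roc), roc_path, row.names = FALSE)
    dca_path <- file.path(out_dir, "decision_curve.csv")
    write.csv(dca, dca_path, row.names = FALSE)
    list(scored = scored, roc = roc, paths = c(model_path, roc_path, dca_path))
  })
  manifest <- st$manifest
  if (st$failed) return(finish(manifest))
  scored <- st$value$scored
  manifest$files$predict <- st$value$paths
  manifest$auc <- st$value$roc$auc

  ## 4. survival stratification by the predicted class
  st <- pipeline_stage(manifest, "survival", {
    paths <- character(0)
    for (cls in c("low", "high")) {
      sel <- scored$predicted_class == cls
      if (!any(sel)) next
      km <- km_estimate(co$pfs_months[sel], co$pfs_event[sel])
      p <- file.path(out_dir, sprintf("km_%s.csv", cls))
      write.csv(tibble::as_tibble(km), p, row.names = FALSE)
      paths <- c(paths, p)
    }
    lr <- if (length(unique(scored$predicted_class)) == 2L)
      logrank_test(co$pfs_months, co$pfs_event, scored$predicted_class)
    else tibble::tibble(chi2 = NA_real_, p_value = NA_real_)
    lr_path <- file.path(out_dir, "logrank.json")
    jsonlite::write_json(as.list(lr), lr_path, auto_unbox = TRUE, digits = NA)
    list(paths = c(paths, lr_path), lr = lr)
  })
  manifest <- st$manifest
  manifest$files$survival <- if (!st$failed) st$value$paths else NULL
  if (!st$failed) manifest$logrank_p <- st$value$lr$p_value
  finish(manifest)
}
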