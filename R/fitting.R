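# Voxel-wise mono-exponential (ADC) and segmented bi-exponential (IVIM)
# fitting. Diffusion coefficients are held in mm^2/s internally; tabular
# interfaces report them in the conventional 1e-3 mm^2/s units.

new_dwi_series <- function(signal, b_values, nex_per_b, voxel_size) {
  stopifnot(length(dim(signal)) == 4L,
            dim(signal)[4] == length(b_values))
  structure(list(signal = signal, b_values = b_values,
                 nex_per_b = nex_per_b, voxel_size = voxel_size),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_series> %dx%dx%d voxels, b = %s s/mm^2\n",
              d[1], d[2], d[3], paste(x$b_values, collapse = ", ")))
  invisible(x)
}

new_ivim_maps <- function(adc, d_t, d_p, f, s0, valid, voxel_size,
                          n_nonconverged = 0L, n_fitted = sum(valid)) {
  structure(list(adc = adc, d_t = d_t, d_p = d_p, f = f, s0 = s0,
                 valid = valid, voxel_size = voxel_size,
                 n_nonconverged = n_nonconverged, n_fitted = n_fitted),
            class = "ivim_maps")
}

#' @export
print.ivim_maps <- function(x, ...) {
  cat(sprintf("<ivim_maps> %s grid, %d valid voxels (%.1f%% non-converged)\n",
              paste(dim(x$adc), collapse = "x"), sum(x$valid),
              100 * x$n_nonconverged / max(1L, x$n_fitted)))
  invisible(x)
}

#' Mono-exponential ADC fit of one voxel
#'
#' Least-squares fit of the log-linear model `ln(S_b/S_0) = -b * ADC` over
#' the full b-value range, estimating S0 and ADC simultaneously.
#'
#' @param signal Signal intensities, one per b-value.
#' @param b_values Matching b-values (s/mm^2).
#' @return Named vector `c(adc, s0)` (mm^2/s, signal units), or `NA`s with
#'   attribute `valid = FALSE` when any included signal is non-positive.
#' @export
fit_adc <- function(signal, b_values) {
  stopifnot(length(signal) == length(b_values), length(signal) >= 2L)
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    out <- c(adc = NA_real_, s0 = NA_real_)
    attr(out, "valid") <- FALSE
    return(out)
  }
  ls <- log(signal)
  bc <- b_values - mean(b_values)
  slope <- sum(bc * ls) / sum(bc^2)
  intercept <- mean(ls) - slope * mean(b_values)
  out <- c(adc = -slope, s0 = exp(intercept))
  attr(out, "valid") <- TRUE
  out
}

#' Two-point high-b estimate of the true diffusion coefficient
#'
#' First step of the segmented IVIM fit: the log-linear slope through the
#' b = 400 and b = 800 s/mm^2 points, where the perfusion compartment has
#' decayed away, gives D_t in closed form:
#' `d_t = ln(S(400)/S(800)) / 400`.
#'
#' @inheritParams fit_adc
#' @param b_high The two high b-values used (default 400 and 800).
#' @return The D_t estimate (mm^2/s), or `NA` with attribute
#'   `valid = FALSE` when either signal is non-positive.
#' @export
fit_dt_highb <- function(signal, b_values, b_high = c(400, 800)) {
  i <- match(b_high, b_values)
  if (any(is.na(i)))
    stop("b_values must contain the two high b-values", call. = FALSE)
  s <- signal[i]
  if (any(!is.finite(s)) || any(s <= 0)) {
    out <- NA_real_
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- log(s[1] / s[2]) / (b_high[2] - b_high[1])
  attr(out, "valid") <- TRUE
  out
}

#' Segmented bi-exponential IVIM fit of one voxel
#'
#' Second step of the segmented protocol: with D_t fixed at its high-b
#' estimate, the remaining parameters (S0, f, D_p) are obtained from a
#' bounded Levenberg-Marquardt least-squares fit of the bi-exponential
#' model over all b-values.
#'
#' @inheritParams fit_adc
#' @param d_t Optional fixed D_t (mm^2/s); computed by [fit_dt_highb()]
#'   when `NULL`.
#' @param bounds Named list of `c(lo, hi)` box constraints for `d_p`, `f`
#'   and the `s0` multiplier (relative to the measured b=0 signal).
#' @return Named list with `s0`, `f`, `d_p`, `d_t`, `converged`.
#' @export
fit_ivim_segmented <- function(signal, b_values, d_t = NULL,
                               bounds = list(d_p = c(3e-3, 0.5),
                                             f = c(0, 1 - 1e-6),
                                             s0_rel = c(1e-6, 2))) {
  stopifnot(length(signal) == length(b_values))
  if (length(b_values) < 4L)
    stop("need at least 4 b-values for the 3-parameter segmented fit",
         call. = FALSE)
  bad <- list(s0 = NA_real_, f = NA_real_, d_p = NA_real_, d_t = NA_real_,
              converged = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0)) return(bad)
  if (is.null(d_t)) d_t <- as.numeric(fit_dt_highb(signal, b_values))
  if (!is.finite(d_t) || d_t <= 0 || d_t > 3e-3) return(bad)

  s0_meas <- signal[which(b_values == 0)[1]]
  # high-b two-point line extrapolated to b = 0 gives the tissue-only
  # intercept; its deficit relative to the measured S(0) initializes f
  i4 <- which(b_values == 400)[1]
  if (is.na(i4)) i4 <- length(b_values) - 1L
  int_high <- log(signal[i4]) + b_values[i4] * d_t
  f0 <- 1 - exp(int_high) / s0_meas
  f0 <- min(max(f0, 0.01), 0.5)
  dp0 <- min(max(10 * d_t, bounds$d_p[1]), bounds$d_p[2])

  resid_fn <- function(p) {
    p["s0"] * (p["f"] * exp(-b_values * p["d_p"]) +
                 (1 - p["f"]) * exp(-b_values * d_t)) - signal
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(s0 = s0_meas, f = f0, d_p = dp0),
      lower = c(s0 = bounds$s0_rel[1] * s0_meas, f = bounds$f[1],
                d_p = bounds$d_p[1]),
      upper = c(s0 = bounds$s0_rel[2] * s0_meas, f = bounds$f[2],
                d_p = bounds$d_p[2]),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(bad)
  p <- fit$par
  list(s0 = unname(p["s0"]), f = unname(p["f"]), d_p = unname(p["d_p"]),
       d_t = d_t, converged = TRUE)
}

#' Compute voxel-wise ADC and IVIM parameter maps
#'
#' Applies [fit_adc()] and the segmented IVIM fit ([fit_dt_highb()] +
#' [fit_ivim_segmented()]) to every voxel inside a mask, producing
#' voxel-aligned parameter maps with a validity grid. Voxels where either
#' fit fails are marked invalid and excluded from downstream statistics
#' rather than clamped.
#'
#' @param series A `dwi_series` (see [generate_phantom()] or [read_dwi()]).
#' @param mask Logical/0-1 3D array aligned with the series.
#' @return An `ivim_maps` object; `glance()` reports the fraction of
#'   non-converged voxels, `tidy()` returns a per-voxel tibble with the
#'   diffusion coefficients in 1e-3 mm^2/s.
#' @export
fit_ivim_maps <- function(series, mask) {
  stopifnot(inherits(series, "dwi_series"))
  gs <- dim(series$signal)[1:3]
  if (!identical(dim(mask), gs))
    stop("mask is not voxel-aligned with the series", call. = FALSE)
  mask <- array(as.logical(mask), dim = gs)
  vox <- which(mask)
  if (length(vox) == 0L) stop("mask is empty", call. = FALSE)

  nb <- length(series$b_values)
  sigmat <- matrix(series$signal, ncol = nb)[vox, , drop = FALSE]

  mk <- function() array(NA_real_, dim = gs)
  adc <- mk(); d_t <- mk(); d_p <- mk(); f <- mk(); s0 <- mk()
  valid <- array(FALSE, dim = gs)

  n_noncv <- 0L
  for (k in seq_along(vox)) {
    sig <- sigmat[k, ]
    a <- fit_adc(sig, series$b_values)
    iv <- fit_ivim_segmented(sig, series$b_values)
    ok <- isTRUE(attr(a, "valid")) && isTRUE(iv$converged)
    if (ok) {
      v <- vox[k]
      adc[v] <- a[["adc"]]; s0[v] <- iv$s0
      d_t[v] <- iv$d_t; d_p[v] <- iv$d_p; f[v] <- iv$f
      valid[v] <- TRUE
    } else n_noncv <- n_noncv + 1L
  }
  maps <- new_ivim_maps(adc, d_t, d_p, f, s0, valid, series$voxel_size,
                        n_nonconverged = n_noncv, n_fitted = length(vox))
  maps
}

#' @describeIn fit_ivim_maps Per-voxel tibble of fitted parameters
#'   (diffusion coefficients reported in 1e-3 mm^2/s).
#' @param x An `ivim_maps` object.
#' @param ... Unused.
#' @method tidy ivim_maps
#' @export
tidy.ivim_maps <- function(x, ...) {
  vox <- which(x$valid)
  idx <- arrayInd(vox, dim(x$valid))
  out <- tibble::tibble(
    adc = x$adc[vox] * 1e3, d_t = x$d_t[vox] * 1e3,
    d_p = x$d_p[vox] * 1e3, f = x$f[vox], s0 = x$s0[vox])
  tibble::add_column(out, x = idx[, 1], y = idx[, 2], z = idx[, 3],
                     .before = 1)
}

#' @describeIn fit_ivim_maps One-row fit summary (voxel counts,
#'   non-convergence fraction).
#' @method glance ivim_maps
#' @export
glance.ivim_maps <- function(x, ...) {
  tibble::tibble(
    n_fitted = x$n_fitted, n_valid = sum(x$valid),
    n_nonconverged = x$n_nonconverged,
    frac_nonconverged = x$n_nonconverged / max(1L, x$n_fitted))
}
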