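#' Specification of a digital IVIM phantom
#'
#' Builds a validated specification for a rectangular DWI phantom containing
#' an ellipsoidal "tumor" embedded in a background compartment. Each region
#' carries its own IVIM ground truth (`d_t`, `d_p`, `f` in mm^2/s and a b=0
#' signal `s0`); a parameter may be a single value or a length-2 range, in
#' which case voxels draw uniformly from the range.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric length 3, mm (in-plane x, y, slice thickness).
#'   Default 1.484 mm in-plane (38 cm FOV / 256) with 5 mm slices.
#' @param tumor_center Ellipsoid center in voxel coordinates (1-based).
#' @param tumor_radii Ellipsoid radii in voxels.
#' @param tumor,background Named lists with `d_t`, `d_p`, `f`, `s0`; each a
#'   value or a `c(lo, hi)` range. Diffusion coefficients in mm^2/s.
#' @param b_values Non-negative, strictly increasing, starting at 0.
#' @param nex_per_b Positive integer excitation counts, one per b.
#' @param noise_sigma Rician noise level per excitation, in signal units
#'   (>= 0). The default gives b=0 tumor SNR of 50.
#' @param seed Integer seed controlling all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 10L),
                         voxel_size = c(38 * 10 / 256, 38 * 10 / 256, 5),
                         tumor_center = c(32, 32, 5),
                         tumor_radii = c(10, 10, 3),
                         tumor = list(d_t = 1.0e-3, d_p = 20e-3, f = 0.30, s0 = 1000),
                         background = list(d_t = 2.0e-3, d_p = 10e-3, f = 0.10, s0 = 500),
                         b_values = default_protocol()$b_values,
                         nex_per_b = default_protocol()$nex,
                         noise_sigma = 20,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(tumor_center) == 3L, length(tumor_radii) == 3L,
            all(tumor_radii > 0))
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (length(b_values) < 2L || b_values[1] != 0 || any(diff(b_values) <= 0) ||
      any(b_values < 0))
    stop("'b_values' must be non-negative, strictly increasing and contain 0",
         call. = FALSE)
  if (length(nex_per_b) != length(b_values) || any(nex_per_b < 1))
    stop("'nex_per_b' must be positive and match 'b_values' in length",
         call. = FALSE)
  check_region <- function(p, nm) {
    for (fld in c("d_t", "d_p", "f", "s0")) {
      v <- p[[fld]]
      if (is.null(v) || !is.numeric(v) || !length(v) %in% 1:2 || any(!is.finite(v)))
        stop(sprintf("region '%s': '%s' must be a value or range", nm, fld),
             call. = FALSE)
    }
    if (min(p$d_t) <= 0 || min(p$d_p) <= max(p$d_t))
      stop(sprintf("region '%s': requires d_p > d_t > 0", nm), call. = FALSE)
    if (min(p$f) < 0 || max(p$f) >= 1)
      stop(sprintf("region '%s': requires 0 <= f < 1", nm), call. = FALSE)
    if (min(p$s0) <= 0)
      stop(sprintf("region '%s': requires s0 > 0", nm), call. = FALSE)
  }
  check_region(tumor, "tumor")
  check_region(background, "background")
  lo <- tumor_center - tumor_radii
  hi <- tumor_center + tumor_radii
  if (any(lo < 1) || any(hi > grid_shape))
    stop("tumor ellipsoid extends outside the grid", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         tumor_center = tumor_center, tumor_radii = tumor_radii,
         tumor = tumor, background = background,
         b_values = b_values, nex_per_b = as.integer(nex_per_b),
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Draw a per-voxel parameter field: single value -> constant, range -> uniform.
draw_field <- function(v, n) {
  if (length(v) == 1L) rep(v, n) else runif(n, v[1], v[2])
}

# Closed-form voxel-wise log-linear mono-exponential fit of a noiseless
# signal matrix (rows = b, cols = voxels); returns the apparent decay rate.
apparent_adc_matrix <- function(sig, b) {
  ls <- log(sig)
  bc <- b - mean(b)
  slope <- colSums(bc * ls) / sum(bc^2)
  -slope
}

#' Generate a digital IVIM phantom
#'
#' Simulates a 4D multi-b DWI series from a [phantom_spec()]: noiseless
#' voxel signals follow the bi-exponential IVIM model with that voxel's
#' ground truth; measurement noise is Rician (magnitude of the true signal
#' plus complex Gaussian noise), drawn independently per excitation and then
#' magnitude-averaged over the NEX repeats of each b-value. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `dwi_phantom`: a list with
#'   \describe{
#'     \item{series}{`dwi_series` object: 4D signal array, `b_values`,
#'       `nex_per_b`, `voxel_size`.}
#'     \item{truth}{`ivim_maps` object holding the ground-truth `adc`
#'       (apparent coefficient of a mono-exponential fit to the noiseless
#'       signal), `d_t`, `d_p`, `f`, `s0` maps (mm^2/s) and an all-valid
#'       mask.}
#'     \item{mask}{logical 3D tumor mask.}
#'     \item{spec}{the input specification.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 4),
#'                                     tumor_center = c(8, 8, 2),
#'                                     tumor_radii = c(4, 4, 1)))
#' dim(ph$series$signal)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  gs <- spec$grid_shape
  nb <- length(spec$b_values)
  nvox <- prod(gs)

  # ellipsoid tumor mask
  idx <- arrayInd(seq_len(nvox), gs)
  u <- sweep(idx, 2, spec$tumor_center)
  u <- sweep(u, 2, spec$tumor_radii, "/")
  mask_vec <- rowSums(u^2) <= 1
  mask <- array(mask_vec, dim = gs)

  set.seed(child_seed(spec$seed, "phantom-fields"))
  par_of <- function(fld) {
    out <- draw_field(spec$background[[fld]], nvox)
    out[mask_vec] <- draw_field(spec$tumor[[fld]], sum(mask_vec))
    out
  }
  d_t <- par_of("d_t"); d_p <- par_of("d_p"); f <- par_of("f"); s0 <- par_of("s0")

  # noiseless signal: build voxel x b, then transpose to b x voxel
  bvox <- matrix(spec$b_values, nvox, nb, byrow = TRUE)
  m <- (f * exp(-bvox * d_p) + (1 - f) * exp(-bvox * d_t)) * s0
  clean <- t(m)

  sig <- clean
  if (spec$noise_sigma > 0) {
    set.seed(child_seed(spec$seed, "phantom-noise"))
    for (j in seq_len(nb)) {
      nex <- spec$nex_per_b[j]
      acc <- numeric(nvox)
      for (r in seq_len(nex)) {
        re <- clean[j, ] + rnorm(nvox, sd = spec$noise_sigma)
        im <- rnorm(nvox, sd = spec$noise_sigma)
        acc <- acc + sqrt(re^2 + im^2)
      }
      sig[j, ] <- acc / nex
    }
  }

  series <- new_dwi_series(
    signal = array(t(sig), dim = c(gs, nb)),
    b_values = spec$b_values, nex_per_b = spec$nex_per_b,
    voxel_size = spec$voxel_size)

  truth <- new_ivim_maps(
    adc = array(apparent_adc_matrix(clean, spec$b_values), dim = gs),
    d_t = array(d_t, dim = gs), d_p = array(d_p, dim = gs),
    f = array(f, dim = gs), s0 = array(s0, dim = gs),
    valid = array(TRUE, dim = gs), voxel_size = spec$voxel_size)

  structure(list(series = series, truth = truth, mask = mask, spec = spec),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  gs <- x$spec$grid_shape
  cat(sprintf("<dwi_phantom> %dx%dx%d grid, %d b-values, %d tumor voxels, sigma = %g\n",
              gs[1], gs[2], gs[3], length(x$spec$b_values), sum(x$mask),
              x$spec$noise_sigma))
  invisible(x)
}
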