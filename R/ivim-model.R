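#' Bi-exponential IVIM signal model
#'
#' Evaluates the two-compartment intravoxel incoherent motion (IVIM) signal
#' \deqn{S(b) = S(0)\,[f e^{-b D_p} + (1 - f) e^{-b D_t}]}
#' where `d_t` is the true (tissue) diffusion coefficient, `d_p` the
#' pseudo-diffusion coefficient of the perfusion compartment and `f` the
#' perfusion fraction at b = 0.
#'
#' @param s0 Signal at b = 0 (arbitrary units, > 0).
#' @param f Perfusion fraction in `[0, 1)`.
#' @param d_p Pseudo-diffusion coefficient (mm^2/s), `d_p >= d_t`.
#' @param d_t True diffusion coefficient (mm^2/s), > 0.
#' @param b Diffusion weighting(s) in s/mm^2, non-negative; vectorized.
#' @return Numeric vector of signal values, one per `b`.
#' @examples
#' ivim_signal(1000, 0.3, 20e-3, 1.0e-3, c(0, 400, 800))
#' @export
ivim_signal <- function(s0, f, d_p, d_t, b) {
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0)
    stop("'s0' must be a single positive number", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f >= 1)
    stop("'f' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(d_t) || length(d_t) != 1L || d_t <= 0)
    stop("'d_t' must be > 0", call. = FALSE)
  if (!is.numeric(d_p) || length(d_p) != 1L || d_p < d_t)
    stop("'d_p' must satisfy d_p >= d_t", call. = FALSE)
  if (!is.numeric(b) || any(b < 0))
    stop("'b' must be non-negative", call. = FALSE)
  s0 * (f * exp(-b * d_p) + (1 - f) * exp(-b * d_t))
}

# The b-value schedule and per-b excitation counts of the acquisition
# protocol the package models.
#' Default multi-b diffusion protocol
#'
#' The nine-point b-value schedule (s/mm^2) and number of excitations (NEX)
#' per b used throughout the package as the default acquisition protocol.
#'
#' @return A list with components `b_values` and `nex`.
#' @export
default_protocol <- function() {
  list(
    b_values = c(0, 20, 50, 100, 150, 200, 400, 600, 800),
    nex      = c(1L, 2L, 2L, 2L, 2L, 2L, 4L, 4L, 4L)
  )
}
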