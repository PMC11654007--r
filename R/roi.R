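# ROI extraction: whole-tumor summaries over the largest axial section and
# its neighbors, and three fixed-area (50 mm^2) circles placed at the lowest
# mean-ADC locations. Both protocols are deterministic surrogates for the
# manual ROIs of clinical reading.

#' Select the largest tumor section and its axial neighbors
#'
#' Returns the axial slice with the maximal in-mask voxel count together
#' with the adjacent lower and upper slices (clipped at the volume edges,
#' with a warning when fewer than three slices are available). Ties are
#' broken toward the lower slice index.
#'
#' @param mask Logical/0-1 3D array.
#' @return Integer vector of 1 to 3 slice indices (sorted).
#' @export
select_largest_sections <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  counts <- apply(mask, 3, function(s) sum(s != 0))
  if (sum(counts) == 0) stop("mask is empty", call. = FALSE)
  k <- which.max(counts)  # which.max takes the first (lowest) maximum on ties
  sl <- intersect((k - 1L):(k + 1L), seq_len(dim(mask)[3]))
  sl <- sl[counts[sl] > 0]
  if (length(sl) < 3L)
    warning(sprintf("only %d section(s) available around the largest slice; averaging over those",
                    length(sl)), call. = FALSE)
  sort(sl)
}

# Integer in-plane offsets forming a disc of the requested physical area:
# the k = round(area / pixel_area) offsets nearest the center in physical
# distance, with deterministic tie-breaking. This makes the voxelized disc
# area match the nominal area to within one pixel.
disc_offsets <- function(area_mm2, voxel_size) {
  pix <- voxel_size[1] * voxel_size[2]
  k <- max(1L, round(area_mm2 / pix))
  rmax <- ceiling(sqrt(area_mm2 / pi) / min(voxel_size[1:2])) + 2L
  g <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  d2 <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2
  o <- order(d2, g$dx, g$dy)
  g <- g[o[seq_len(k)], , drop = FALSE]
  as.matrix(g)
}

#' Place fixed-area circular ROIs at the lowest-ADC locations
#'
#' Greedy deterministic placement of `k` non-overlapping circular ROIs of
#' fixed physical area inside the tumor mask: among all candidate centers
#' whose circle lies fully in-mask (and off already-used voxels), the circle
#' with the minimal mean ADC is chosen; its voxels are removed and the
#' search repeats. Circles are 2D (single-slice) and searched over all
#' slices.
#'
#' @param adc 3D ADC map (mm^2/s); `NA` voxels are ignored in means.
#' @param mask Logical/0-1 3D array aligned with `adc`.
#' @param voxel_size Numeric length >= 2, in-plane voxel size in mm.
#' @param k Number of circles (default 3).
#' @param area_mm2 Physical area per circle (default 50 mm^2).
#' @return List of `k` ROIs, each a list with `center` (voxel coords) and
#'   `voxels` (matrix of voxel indices); attribute `area_mm2` gives the
#'   realized voxelized area.
#' @export
place_lowest_adc_rois <- function(adc, mask, voxel_size, k = 3L,
                                  area_mm2 = 50) {
  stopifnot(identical(dim(adc), dim(mask)))
  gs <- dim(mask)
  mask <- array(as.logical(mask), dim = gs)
  off <- disc_offsets(area_mm2, voxel_size)
  nvox_circle <- nrow(off)
  if (sum(mask) * voxel_size[1] * voxel_size[2] < k * area_mm2)
    stop(sprintf("mask too small for %d circles of %g mm^2", k, area_mm2),
         call. = FALSE)

  avail <- mask
  rois <- vector("list", k)
  cand <- which(mask)
  cidx <- arrayInd(cand, gs)

  for (ci in seq_len(k)) {
    best_mean <- Inf; best <- NULL
    for (j in seq_len(nrow(cidx))) {
      cx <- cidx[j, 1]; cy <- cidx[j, 2]; cz <- cidx[j, 3]
      xs <- cx + off[, 1]; ys <- cy + off[, 2]
      if (min(xs) < 1L || max(xs) > gs[1] || min(ys) < 1L || max(ys) > gs[2])
        next
      lin <- xs + (ys - 1L) * gs[1] + (cz - 1L) * gs[1] * gs[2]
      if (!all(avail[lin])) next
      m <- mean(adc[lin], na.rm = TRUE)
      if (is.finite(m) && m < best_mean - 1e-15) {
        best_mean <- m
        best <- list(center = c(cx, cy, cz), voxels = cbind(xs, ys, rep(cz, nvox_circle)),
                     lin = lin, mean_adc = m)
      }
    }
    if (is.null(best))
      stop(sprintf("only %d non-overlapping circle(s) of %g mm^2 fit in the mask",
                   ci - 1L, area_mm2), call. = FALSE)
    avail[best$lin] <- FALSE
    rois[[ci]] <- best[c("center", "voxels", "mean_adc")]
  }
  attr(rois, "area_mm2") <- nvox_circle * voxel_size[1] * voxel_size[2]
  rois
}

#' Define the two ROI protocols on a parameter-map set
#'
#' Combines [select_largest_sections()] (whole-tumor ROIs on the largest
#' slice and its two neighbors) and [place_lowest_adc_rois()] (three
#' fixed-area lowest-ADC circles) into an `roi_set`.
#'
#' @param maps An `ivim_maps` object (its ADC map drives circle placement).
#' @param mask Logical/0-1 3D tumor mask.
#' @param k,area_mm2 Passed to [place_lowest_adc_rois()].
#' @return An object of class `roi_set`.
#' @export
define_rois <- function(maps, mask, k = 3L, area_mm2 = 50) {
  stopifnot(inherits(maps, "ivim_maps"))
  gs <- dim(maps$adc)
  if (!identical(dim(mask), gs))
    stop("mask is not voxel-aligned with the maps", call. = FALSE)
  mask <- array(as.logical(mask), dim = gs)
  slices <- select_largest_sections(mask)
  largest <- lapply(slices, function(z) {
    ij <- which(mask[, , z], arr.ind = TRUE)
    cbind(ij, z = rep(z, nrow(ij)))
  })
  low <- place_lowest_adc_rois(maps$adc, mask, maps$voxel_size,
                               k = k, area_mm2 = area_mm2)
  structure(list(largest_slices = slices, largest = largest, low = low,
                 area_mm2 = attr(low, "area_mm2")),
            class = "roi_set")
}

roi_mean <- function(map, valid, voxels, gs) {
  lin <- voxels[, 1] + (voxels[, 2] - 1L) * gs[1] + (voxels[, 3] - 1L) * gs[1] * gs[2]
  lin <- lin[valid[lin]]
  if (length(lin) == 0L)
    stop("an ROI contains no valid voxels", call. = FALSE)
  mean(map[lin])
}

#' Summarize parameter maps over an ROI set
#'
#' Computes the eight imaging features: for each of ADC, D_t, D_p and f,
#' the mean over the three largest-section ROIs (unweighted mean of the
#' per-slice means) and over the three lowest-ADC circles (unweighted mean
#' of the per-circle means). The identical voxel sets -- selected on the
#' ADC map -- are applied to all four maps; invalid voxels are excluded.
#'
#' @param maps An `ivim_maps` object.
#' @param rois An `roi_set` from [define_rois()].
#' @return A one-row tibble with columns `ADC_ROI_largest`, `ADC_ROI_Low`,
#'   `D_t_ROI_largest`, `D_t_ROI_Low`, `D_p_ROI_largest`, `D_p_ROI_Low`,
#'   `f_ROI_largest`, `f_ROI_Low`. Diffusion coefficients are reported in
#'   1e-3 mm^2/s; f is dimensionless.
#' @export
summarize_rois <- function(maps, rois) {
  stopifnot(inherits(maps, "ivim_maps"), inherits(rois, "roi_set"))
  gs <- dim(maps$adc)
  feat <- function(map, scale) {
    lg <- mean(vapply(rois$largest, function(v) roi_mean(map, maps$valid, v, gs),
                      numeric(1)))
    lo <- mean(vapply(rois$low, function(r) roi_mean(map, maps$valid, r$voxels, gs),
                      numeric(1)))
    c(largest = lg * scale, low = lo * scale)
  }
  a <- feat(maps$adc, 1e3); dt <- feat(maps$d_t, 1e3)
  dp <- feat(maps$d_p, 1e3); ff <- feat(maps$f, 1)
  tibble::tibble(
    ADC_ROI_largest = a[["largest"]], ADC_ROI_Low = a[["low"]],
    D_t_ROI_largest = dt[["largest"]], D_t_ROI_Low = dt[["low"]],
    D_p_ROI_largest = dp[["largest"]], D_p_ROI_Low = dp[["low"]],
    f_ROI_largest = ff[["largest"]], f_ROI_Low = ff[["low"]])
}

#' Average the feature vectors of two readers
#'
#' Element-wise mean of two ROI feature rows, mirroring the convention of
#' averaging the measurements of two independent radiologists before
#' analysis.
#'
#' @param vec_a,vec_b One-row data frames with identical numeric columns.
#' @return A one-row tibble of element-wise means.
#' @export
average_readers <- function(vec_a, vec_b) {
  if (!setequal(names(vec_a), names(vec_b)))
    stop("feature sets of the two readers do not match", call. = FALSE)
  vec_b <- vec_b[names(vec_a)]
  tibble::as_tibble((as.data.frame(vec_a) + as.data.frame(vec_b)) / 2)
}
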