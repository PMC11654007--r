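test_that("largest-section selection picks the maximal slice and neighbors", {
  # symmetric ellipsoid centered on slice 5 of 10
  ph <- make_test_phantom(grid_shape = c(32L, 32L, 10L),
                          tumor_center = c(16, 16, 5), tumor_radii = c(8, 8, 3))
  expect_equal(select_largest_sections(ph$mask), c(4L, 5L, 6L))
  # single-slice mask degrades with a warning
  m1 <- array(FALSE, dim = c(8, 8, 5)); m1[3:6, 3:6, 2] <- TRUE
  expect_warning(sl <- select_largest_sections(m1), "section")
  expect_equal(sl, 2L)
  # tie between two equal slices resolves to the lower index
  m2 <- array(FALSE, dim = c(8, 8, 5))
  m2[3:6, 3:6, 2] <- TRUE; m2[3:6, 3:6, 4] <- TRUE
  expect_warning(sl2 <- select_largest_sections(m2))
  expect_true(2L %in% sl2 && !(4L %in% sl2))
  expect_error(select_largest_sections(array(FALSE, c(4, 4, 2))), "empty")
})

test_that("lowest-ADC circles have the right area, stay in-mask, never overlap", {
  ph <- make_test_phantom()
  maps <- ph$truth
  rois <- place_lowest_adc_rois(maps$adc, ph$mask, maps$voxel_size)
  pix <- prod(maps$voxel_size[1:2])
  expect_lt(abs(attr(rois, "area_mm2") - 50), pix)  # within one pixel of 50 mm^2
  seen <- character(0)
  for (r in rois) {
    keys <- apply(r$voxels, 1, paste, collapse = ",")
    expect_length(intersect(keys, seen), 0)          # pairwise disjoint
    seen <- c(seen, keys)
    expect_true(all(ph$mask[r$voxels]))              # fully inside the mask
  }
})

test_that("the first circle lands in a cold low-ADC region", {
  gs <- c(40L, 40L, 3L)
  mask <- array(FALSE, gs); mask[5:36, 5:36, 2] <- TRUE
  adc <- array(2e-3, gs)
  adc[28:36, 28:36, 2] <- 0.5e-3                    # cold block
  vs <- c(1.5, 1.5, 5)
  rois <- place_lowest_adc_rois(adc, mask, vs)
  expect_true(all(rois[[1]]$center[1:2] >= 28))
  # exhaustive check: no in-mask circle has a lower mean than the chosen one
  off <- ivimgrade:::disc_offsets(50, vs)
  best <- Inf
  for (cx in 5:36) for (cy in 5:36) {
    xs <- cx + off[, 1]; ys <- cy + off[, 2]
    if (any(xs < 5 | xs > 36 | ys < 5 | ys > 36)) next
    best <- min(best, mean(adc[cbind(xs, ys, 2)]))
  }
  expect_equal(rois[[1]]$mean_adc, best)
})

test_that("masks too small for the requested circles raise errors", {
  gs <- c(12L, 12L, 2L)
  mask <- array(FALSE, gs); mask[4:9, 4:9, 1] <- TRUE  # 36 px * 2.25 = 81 mm^2
  adc <- array(1e-3, gs)
  expect_error(place_lowest_adc_rois(adc, mask, c(1.5, 1.5, 5)), "too small")
})

test_that("ROI summaries average slices and circles as specified", {
  ph <- make_test_phantom()
  maps <- ph$truth
  rois <- define_rois(maps, ph$mask)
  feats <- summarize_rois(maps, rois)
  # uniform truth: every feature equals the region constant (table units)
  expect_equal(feats$D_t_ROI_largest, 1.0, tolerance = 1e-9)
  expect_equal(feats$D_t_ROI_Low, 1.0, tolerance = 1e-9)
  expect_equal(feats$D_p_ROI_Low, 20, tolerance = 1e-9)
  expect_equal(feats$f_ROI_largest, 0.3, tolerance = 1e-9)
  # ROI_largest is the unweighted mean of per-slice means: constructed case
  m <- maps
  for (z in rois$largest_slices)
    m$adc[, , z] <- (1.0 + 0.1 * (z - min(rois$largest_slices))) * 1e-3
  f2 <- summarize_rois(m, rois)
  expect_equal(f2$ADC_ROI_largest, 1.1, tolerance = 1e-9)
})

test_that("lowest-ADC summaries sit at or below the whole-mask mean", {
  for (seed in 1:8) {
    ph <- generate_phantom(phantom_spec(
      seed = seed, noise_sigma = 0,
      tumor = list(d_t = c(0.8e-3, 1.4e-3), d_p = c(12e-3, 35e-3),
                   f = c(0.15, 0.45), s0 = 1000)))
    rois <- define_rois(ph$truth, ph$mask)
    feats <- summarize_rois(ph$truth, rois)
    expect_lte(feats$ADC_ROI_Low,
               mean(ph$truth$adc[ph$mask]) * 1e3 + 1e-12)
  }
})

test_that("reader averaging is an element-wise mean and commutes", {
  a <- tibble::tibble(ADC_ROI_Low = 1.0, f_ROI_Low = 0.2)
  b <- tibble::tibble(ADC_ROI_Low = 2.0, f_ROI_Low = 0.4)
  ab <- average_readers(a, b)
  expect_equal(ab$ADC_ROI_Low, 1.5)
  expect_equal(ab$f_ROI_Low, 0.3)
  expect_equal(average_readers(b, a), ab)
  expect_equal(average_readers(a, a), a)
  expect_error(average_readers(a, tibble::tibble(other = 1)), "match")
})
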