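b9 <- default_protocol()$b_values

test_that("mono-exponential ADC fit is exact on model-matched input", {
  s <- 1000 * exp(-b9 * 1.5e-3)
  fit <- fit_adc(s, b9)
  expect_equal(fit[["adc"]], 1.5e-3, tolerance = 1e-9)
  expect_equal(fit[["s0"]], 1000, tolerance = 1e-9)
  # constant signal: zero decay
  expect_equal(fit_adc(rep(500, 9), b9)[["adc"]], 0)
  # non-positive signal invalidates the voxel
  out <- fit_adc(c(1000, rep(0, 8)), b9)
  expect_false(attr(out, "valid"))
})

test_that("perfusion inflates the apparent coefficient above D_t", {
  s <- ivim_signal(1000, 0.3, 20e-3, 1.0e-3, b9)
  fit <- fit_adc(s, b9)
  expect_gt(fit[["adc"]], 1.0e-3)
  # cross-check against an explicit least-squares solve of the log model
  co <- stats::lm.fit(cbind(1, -b9), log(s))$coefficients
  expect_equal(fit[["adc"]], unname(co[2]), tolerance = 1e-12)
})

test_that("two-point high-b slope recovers D_t", {
  s <- ivim_signal(1000, 0.3, 20e-3, 1.0e-3, b9)
  dt <- fit_dt_highb(s, b9)
  expect_equal(as.numeric(dt), log(s[b9 == 400] / s[b9 == 800]) / 400)
  expect_equal(as.numeric(dt), 1.001e-3, tolerance = 1e-3)
  # pure mono-exponential input is exact
  s0f <- 900 * exp(-b9 * 1.2e-3)
  expect_equal(as.numeric(fit_dt_highb(s0f, b9)), 1.2e-3, tolerance = 1e-12)
  # equal signals give zero slope; non-positive signal invalidates
  sc <- rep(100, 9)
  expect_equal(as.numeric(fit_dt_highb(sc, b9)), 0)
  sz <- s; sz[9] <- 0
  expect_false(attr(fit_dt_highb(sz, b9), "valid"))
})

test_that("segmented fit recovers noiseless voxels and matches the grid oracle", {
  set.seed(42)
  for (i in 1:10) {
    dt <- runif(1, 0.8e-3, 1.4e-3); dp <- runif(1, 12e-3, 35e-3)
    f <- runif(1, 0.15, 0.45); s0 <- runif(1, 500, 2000)
    s <- ivim_signal(s0, f, dp, dt, b9)
    fit <- fit_ivim_segmented(s, b9)
    expect_true(fit$converged)
    expect_lt(abs(fit$f - f), 0.01)
    expect_lt(abs(fit$d_p - dp) / dp, 0.05)
    sse_fit <- sum((ivim_signal(fit$s0, fit$f, fit$d_p, fit$d_t, b9) - s)^2)
    expect_lte(sse_fit, oracle_segmented_sse(s, b9, fit$d_t) + 1e-6)
  }
})

test_that("segmented fit handles degenerate voxels", {
  # f = 0 limit: perfusion fraction estimated at (near) zero
  s <- 1000 * exp(-b9 * 1.2e-3)
  fit <- fit_ivim_segmented(s, b9)
  expect_true(fit$converged)
  expect_lte(fit$f, 0.01)
  # a zero signal marks the voxel non-converged
  sz <- s; sz[5] <- 0
  expect_false(fit_ivim_segmented(sz, b9)$converged)
  # too few b-values for three free parameters
  expect_error(fit_ivim_segmented(c(1000, 500, 300), c(0, 400, 800)),
               "at least 4")
})

test_that("map computation reproduces uniform ground truth and flags errors", {
  ph <- make_test_phantom(grid_shape = c(16L, 16L, 4L), tumor_center = c(8, 8, 2),
                          tumor_radii = c(4, 4, 1))
  maps <- fit_ivim_maps(ph$series, ph$mask)
  v <- which(ph$mask)
  expect_true(all(maps$valid[v]))
  # the two-point high-b slope carries a tiny (<0.1%) perfusion residue
  expect_equal(unname(range(maps$d_t[v])), c(1e-3, 1e-3), tolerance = 1e-3)
  expect_equal(unname(range(maps$f[v])), c(0.3, 0.3), tolerance = 1e-3)
  expect_equal(unname(range(maps$d_p[v])), c(20e-3, 20e-3), tolerance = 1e-3)
  expect_true(all(abs(maps$adc[v] - ph$truth$adc[v]) < 1e-9))
  # masks that do not align with the grid are rejected
  expect_error(fit_ivim_maps(ph$series, array(TRUE, dim = c(8, 8, 4))),
               "aligned")
  expect_error(fit_ivim_maps(ph$series, array(FALSE, dim = dim(ph$mask))),
               "empty")
  # tidy reports in 1e-3 mm^2/s units
  td <- tidy(maps)
  expect_equal(nrow(td), length(v))
  expect_equal(median(td$d_t), 1, tolerance = 1e-3)
})

test_that("physical ordering d_p >= d_t and adc >= 0 holds on noisy fits", {
  ph <- make_test_phantom(noise_sigma = 20, seed = 3L,
                          grid_shape = c(24L, 24L, 4L),
                          tumor_center = c(12, 12, 2), tumor_radii = c(6, 6, 1))
  maps <- fit_ivim_maps(ph$series, ph$mask)
  v <- which(maps$valid)
  expect_gt(length(v), 100)
  expect_true(all(maps$d_p[v] >= maps$d_t[v]))
  expect_true(all(maps$adc[v] >= 0))
})
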