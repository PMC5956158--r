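# ADC and IVIM map computation: feasibility, closed forms, recovery.

test_that("combine_directions takes the voxel-wise geometric mean", {
  # identical frames per b: output equals the input frame
  arr <- array(rep(c(100, 50), each = 4 * 3), dim = c(2, 2, 1, 6))
  dwi <- dwi_series(arr, bvalues = rep(c(0, 1000), each = 3),
                    direction_index = rep(0:2, 2))
  dc <- combine_directions(dwi)
  expect_equal(dc$bvalues, c(0, 1000))
  expect_equal(as.vector(dc$signal[, , , 1]), rep(100, 4))

  # (8, 27, 64) across directions -> 24
  arr2 <- array(rep(c(8, 27, 64), each = 1), dim = c(1, 1, 1, 3))
  dwi2 <- dwi_series(arr2, bvalues = c(0, 0, 0), direction_index = 0:2)
  expect_equal(as.numeric(combine_directions(dwi2)$signal[1, 1, 1, 1]), 24)

  # zero in one direction annihilates and is counted
  arr3 <- array(c(0, 27, 64), dim = c(1, 1, 1, 3))
  dwi3 <- dwi_series(arr3, bvalues = c(0, 0, 0), direction_index = 0:2)
  dc3 <- combine_directions(dwi3)
  expect_equal(as.numeric(dc3$signal[1, 1, 1, 1]), 0)
  expect_equal(attr(dc3, "n_zero_voxels"), 1L)

  # unequal coverage errors
  arr4 <- array(1, dim = c(1, 1, 1, 3))
  dwi4 <- dwi_series(arr4, bvalues = c(0, 0, 1000), direction_index = c(0, 1, 0))
  expect_error(combine_directions(dwi4), "unequal direction coverage")
})

test_that("IVIM feasibility needs 4 distinct b and both decay regimes", {
  expect_true(check_ivim_feasibility(protocol_bvalues)$feasible)
  v <- check_ivim_feasibility(c(0, 1000))
  expect_false(v$feasible)
  expect_match(v$reason, ">=4 distinct b-values")
  v2 <- check_ivim_feasibility(c(0, 50, 100, 150))
  expect_false(v2$feasible)
  expect_match(v2$reason, ">=2 b-values >= 200")
  v3 <- check_ivim_feasibility(c(200, 400, 600, 1000))
  expect_false(v3$feasible)
  expect_match(v3$reason, ">=2 b-values < 200")
  # duplicated b-values do not count twice
  expect_false(check_ivim_feasibility(rep(c(0, 1000), 5))$feasible)
})

test_that("ADC closed forms: pure exponential, identity, biexponential", {
  dwi <- uniform_dwi(c(1000, 1000 * exp(-1)), c(0, 1000))
  adc <- compute_adc_map(dwi)
  expect_equal(adc$values[1, 1, 1], 1e-3, tolerance = 1e-12)

  dwi0 <- uniform_dwi(c(500, 500), c(0, 1000))
  expect_equal(compute_adc_map(dwi0)$values[1, 1, 1], 0)

  # worked biexponential voxel: S0=1, D=1e-3, D*=10e-3, f=0.2
  s1000 <- biexp_signal(1000, 1, 1e-3, 10e-3, 0.2)
  dwi2 <- uniform_dwi(c(1, s1000), c(0, 1000))
  expect_equal(compute_adc_map(dwi2)$values[1, 1, 1],
               log(1 / s1000) / 1000, tolerance = 1e-12)
  expect_equal(compute_adc_map(dwi2)$values[1, 1, 1], 1.223e-3,
               tolerance = 1e-3)

  expect_error(compute_adc_map(uniform_dwi(c(10, 5), c(0, 600)),
                               fit_config(adc_b_pair = c(0, 1000))),
               "not present")
  # nonpositive signal becomes NaN
  dwi3 <- uniform_dwi(c(0, 10), c(0, 1000))
  expect_true(all(is.nan(compute_adc_map(dwi3)$values)))
})

test_that("noise-free monoexponential ADC equals D to 1e-9 relative", {
  for (D in c(0.4e-3, 1e-3, 2.2e-3)) {
    s <- 800 * exp(-protocol_bvalues * D)
    adc <- compute_adc_map(uniform_dwi(s, protocol_bvalues))
    expect_lt(abs(adc$values[1, 1, 1] - D) / D, 1e-9)
  }
})

test_that("voxel IVIM fit recovers noise-free parameters", {
  s <- biexp_signal(protocol_bvalues, 1000, 1e-3, 15e-3, 0.2)
  p <- fit_ivim_voxel(s, protocol_bvalues)
  expect_identical(p$status, "ok")
  expect_lt(abs(p$D - 1e-3) / 1e-3, 0.01)
  expect_lt(abs(p$f - 0.2), 0.005)
  expect_lt(abs(p$Dstar - 15e-3) / 15e-3, 0.05)
})

test_that("f=0 monoexponential input gives f ~ 0 and D = high-b slope", {
  s <- 900 * exp(-protocol_bvalues * 1.4e-3)
  p <- fit_ivim_voxel(s, protocol_bvalues)
  expect_identical(p$status, "ok")
  expect_lte(p$f, 0.01)
  slope <- log(s[5] / s[6]) / (1000 - 600)
  expect_equal(p$D, slope, tolerance = 1e-9)
})

test_that("nonpositive or infeasible input is flagged, not fitted", {
  s <- biexp_signal(protocol_bvalues, 1000, 1e-3, 15e-3, 0.2)
  s[3] <- 0
  expect_identical(fit_ivim_voxel(s, protocol_bvalues)$status, "degenerate")
  expect_identical(fit_ivim_voxel(c(10, 5), c(0, 1000))$status, "infeasible")
})

test_that("noise-free recovery holds across the physiological bounds box", {
  set.seed(42)
  for (i in 1:50) {
    D <- runif(1, 0.3e-3, 2.5e-3)
    f <- runif(1, 0.05, 0.3)
    Ds <- runif(1, 5e-3, 50e-3)
    s <- biexp_signal(protocol_bvalues, 750, D, Ds, f)
    p <- fit_ivim_voxel(s, protocol_bvalues)
    expect_identical(p$status, "ok")
    expect_lt(abs(p$D - D) / D, 0.01)
    expect_lt(abs(p$f - f), 0.01)
    expect_lt(abs(p$Dstar - Ds) / Ds, 0.05)
  }
})

test_that("perfusion inflates ADC above the fitted tissue D", {
  set.seed(5)
  for (i in 1:10) {
    D <- runif(1, 0.4e-3, 2e-3); f <- runif(1, 0.05, 0.3)
    Ds <- runif(1, 6e-3, 40e-3)
    s <- biexp_signal(protocol_bvalues, 1000, D, Ds, f)
    adc <- compute_adc_map(uniform_dwi(s, protocol_bvalues))$values[1, 1, 1]
    p <- fit_ivim_voxel(s, protocol_bvalues)
    expect_gt(adc, p$D)
  }
})

test_that("fitting is deterministic", {
  set.seed(3)
  s <- biexp_signal(protocol_bvalues, 1000, 1.2e-3, 20e-3, 0.15) *
    exp(rnorm(6, 0, 0.01))
  p1 <- fit_ivim_voxel(s, protocol_bvalues)
  p2 <- fit_ivim_voxel(s, protocol_bvalues)
  expect_identical(p1, p2)
})

test_that("fit_ivim_maps broadcasts the voxel fit and is local", {
  sp <- phantom_spec(shape = c(4, 4, 2), lesions = list(), snr_b0 = Inf)
  ph <- generate_phantom(sp)
  maps <- fit_ivim_maps(ph$dwi)
  expect_true(all(maps$status == "ok"))
  vox <- fit_ivim_voxel(ph$dwi$signal[1, 1, 1, ], ph$dwi$bvalues)
  expect_equal(maps$D$values[2, 3, 1], vox$D, tolerance = 1e-12)
  expect_equal(maps$f$values[4, 4, 2], vox$f, tolerance = 1e-12)
  expect_equal(maps$Dstar$values[1, 2, 2], vox$Dstar, tolerance = 1e-10)

  # zero a single voxel: exactly that voxel becomes NaN in all maps
  dwi2 <- ph$dwi
  dwi2$signal[2, 2, 1, ] <- 0
  maps2 <- fit_ivim_maps(dwi2)
  for (m in maps2[c("D", "Dstar", "f", "S0")]) {
    expect_true(is.nan(m$values[2, 2, 1]))
    expect_equal(sum(!is.finite(m$values)), 1L)
  }

  expect_error(fit_ivim_maps(uniform_dwi(c(10, 5), c(0, 1000))),
               "not feasible")
})

test_that("median fitted D is within 5% of truth at SNR 60", {
  sp <- phantom_spec(shape = c(8, 8, 8), lesions = list(), snr_b0 = 60)
  ph <- generate_phantom(sp, seed = 7)
  maps <- fit_ivim_maps(ph$dwi)
  Dv <- maps$D$values[is.finite(maps$D$values)]
  expect_gt(length(Dv), 300)
  truth <- default_tissues()$background$D
  expect_lt(abs(median(Dv) - truth) / truth, 0.05)
})
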