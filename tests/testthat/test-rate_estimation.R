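test_that("k_off is the reciprocal partially bound lifetime", {
  est <- k_off_from_lifetime(3.6, se = 0.6)
  expect_equal(est$value, 0.2778, tolerance = 1e-3)
  expect_equal(est$se, 0.6 / 3.6^2, tolerance = 1e-10)
  expect_equal(k_off_from_lifetime(1)$value, 1)
  expect_error(k_off_from_lifetime(0), "positive")

  lt <- structure(list(tau = 2, se = 0.2, n_dwells = 50,
                       model = "single", method = "mle",
                       reliable = TRUE), class = "lifetime_estimate")
  expect_equal(k_off_from_lifetime(lt)$value, 0.5)
})

test_that("photobleach-corrected k1 reproduces the printed values", {
  # high power: (1/31.3 - 1/70) / 3e-8 = 5.89e5
  hi <- k_on_photobleach_corrected(31.3, 70, 3.0e-8)
  expect_equal(hi$value, 5.888e5, tolerance = 1e-3)
  # low power: (1/46 - 1/103) / 3e-8 = 4.01e5
  lo <- k_on_photobleach_corrected(46, 103, 3.0e-8)
  expect_equal(lo$value, 4.010e5, tolerance = 1e-3)
  # no waiting/bleach separation -> zero
  expect_equal(k_on_photobleach_corrected(70, 70, 3e-8)$value, 0)
  # no-censoring limit: k(tau, Inf, C) = 1/(tau C)
  expect_equal(k_on_photobleach_corrected(20, Inf, 1e-8)$value,
               1 / (20 * 1e-8))
  expect_error(k_on_photobleach_corrected(30, 70, 0), "> 0")
  expect_warning(k_on_photobleach_corrected(100, 70, 3e-8), "negative")
})

test_that("tau_trace estimators behave on exact and censored data", {
  expect_equal(tau_trace_estimate(rep(70, 30))$tau, 70)
  set.seed(4)
  x <- stats::rexp(1000, 1 / 70)
  est <- tau_trace_estimate(x)
  expect_lt(abs(est$tau - 70), 2 * est$se)
  # censored at a 150 s acquisition cap, MLE recovers the mean within 5%
  xc <- pmin(x, 150)
  estc <- tau_trace_estimate(xc, method = "mle", cap = 150)
  expect_lt(abs(estc$tau - 70) / 70, 0.05)
  # while the raw mean is biased low
  expect_lt(mean(xc), 66)
})

test_that("footprint fraction matches the first-passage closed form", {
  # independent oracle: P(at least one binding in w) = 1 - exp(-k1 C w)
  set.seed(5)
  for (k1 in c(1e5, 5e5)) {
    f <- footprint_fraction(k1, k_off = 0.28, concentration = 30e-9,
                            window = 70, n_paths = 1500)
    expected <- 1 - exp(-k1 * 30e-9 * 70)
    expect_lt(abs(f - expected),
              3 * sqrt(expected * (1 - expected) / 1500))
  }
  expect_equal(footprint_fraction(0), 0)
})

test_that("calibration curve is monotone and invertible", {
  grid <- c(0.5, 1, 2, 4, 7, 10) * 1e5
  curve <- calibrate_f_curve(grid, k_off = 0.28, n_paths = 600,
                             seed = 6)
  expect_s3_class(curve, "calibration_curve")
  expect_gt(curve$a, 0)
  expect_lt(curve$b, 0)
  expect_gte(curve$f0, max(curve$fit_points$f))

  # monotone non-decreasing within Monte-Carlo error
  mc_se <- sqrt(0.25 / 600)
  expect_true(all(diff(curve$fit_points$f_raw) > -2 * mc_se))

  # forward-then-invert returns the grid within fit error
  inv <- vapply(curve$fit_points$f, function(f)
    invert_calibration(min(f, curve$f0 - 1e-6), curve)$value, 0)
  rel <- abs(inv - grid) / grid
  expect_lt(mean(rel), 0.15)

  expect_error(calibrate_f_curve(c(1e5, 2e5), n_paths = 600), ">= 4")
  expect_error(calibrate_f_curve(grid, n_paths = 10), ">= 100")
})

test_that("inverting the printed reference curve reproduces WT k1", {
  printed <- list(f0 = 1.557, a = exp(0.45), b = -2.09, k1_unit = 1e6)
  est <- invert_calibration(1, printed)
  expect_equal(est$value, 4.95e5, tolerance = 2e-3)
  # f = f0 - a means ln(f0 - f) = ln a, so k1 = 0
  expect_equal(invert_calibration(printed$f0 - printed$a,
                                  printed)$value, 0, tolerance = 1e-10)
  expect_error(invert_calibration(1.6, printed), "saturation")
  # uncertainty propagates from se(f)
  withse <- invert_calibration(1, printed, se_f = 0.05)
  expect_equal(withse$se, 0.05 / (2.09 * 0.557) * 1e6, tolerance = 1e-6)
})

test_that("k2 bounds come from the sojourn resolution limit", {
  b <- k2_bound_from_sojourn(0.1)
  expect_equal(b$value, 10)
  expect_equal(b$bound, "lower")
  expect_equal(k2_bound_from_sojourn(0.05)$value, 20)
})

test_that("sub-frame partial sojourns are mostly invisible at k2 = 10", {
  # closed-form oracle: P(sojourn > 1 frame) = exp(-(k2 + k_off) * 0.1)
  # = exp(-1.028) ~ 0.36, so most partial-state passages are shorter
  # than one frame and cannot be resolved
  sc <- scheme_wt()
  cond <- experiment_condition(acquisition_frames = 600)
  d <- generate_dataset(sc, cond, quiet_model(), 60, seed = 7)
  durs <- c()
  for (tr in d$traces) {
    p <- tr$truth$path
    seg_end <- c(p$event_times[-1], p$end_time)
    interior <- p$states == "P" & seg_end < p$end_time
    durs <- c(durs, (seg_end - p$event_times)[interior])
  }
  expect_gt(length(durs), 30)
  frac_resolved <- mean(durs > 0.1)
  expected <- exp(-1.028)
  expect_lt(abs(frac_resolved - expected),
            3 * sqrt(expected * (1 - expected) / length(durs)))
  expect_lt(frac_resolved, 0.5)
})

test_that("apparent branched rates compose the two pathways", {
  # single-path limits
  a0 <- apparent_rates_dkt(c(0, 1), k1_prime = 1, k_rev_prime = 1,
                           k2_prime = 5, k_unlock_prime = 2,
                           k2_direct = 3, k_unlock_direct = 0.7)
  expect_equal(a0$k2_app$value, 3)
  expect_equal(a0$k_rev2_app$value, 0.7)

  a1 <- apparent_rates_dkt(c(1, 0), k1_prime = 1e6, k_rev_prime = 1,
                           k2_prime = 5, k_unlock_prime = 2)
  expect_equal(a1$k2_app$value, 5, tolerance = 1e-5)

  # worked example from the component lifetimes 0.30 s and 0.13 s
  aw <- apparent_rates_dkt(c(0.8, 0.2), k1_prime = 7.7,
                           k_rev_prime = 3.3, k2_prime = 7.7,
                           k_unlock_prime = 1, k2_direct = 2,
                           k_unlock_direct = 1)
  expect_equal(aw$k2_app$value, 0.8 * 7.7 * 7.7 / 11.0 + 0.2 * 2,
               tolerance = 1e-10)
  expect_equal(aw$k2_app$value, 4.712, tolerance = 1e-3)

  expect_error(apparent_rates_dkt(c(0.5, 0.5), k1_prime = 0,
                                  k_rev_prime = 0, k2_prime = 1,
                                  k_unlock_prime = 1),
               "k1' \\+ k_rev'")
  expect_error(apparent_rates_dkt(c(0.5, 0.6), k1_prime = 1,
                                  k_rev_prime = 1, k2_prime = 1,
                                  k_unlock_prime = 1), "sum to 1")
})

test_that("fold-change reports combine association and dissociation", {
  ref <- list(rate_estimate("k_1", 5.0e5, order = 2),
              rate_estimate("k_-1", 0.28))
  # 20x slower binding, 2.5x faster dissociation -> 50-fold Kd
  var <- list(rate_estimate("k_1", 5.0e5 / 20, order = 2),
              rate_estimate("k_-1", 0.28 * 2.5))
  fc <- fold_change_report(ref, var)
  expect_equal(fc$fold[fc$rate == "k_1"], 20)
  expect_equal(fc$fold[fc$rate == "k_-1"], 2.5)
  expect_equal(fc$fold[fc$rate == "Kd_step1"], 50)

  # identical sets give folds of 1
  fc1 <- fold_change_report(ref, ref)
  expect_true(all(fc1$fold == 1))

  # printed k1 contrast for the K-turn mutant
  fck <- fold_change_report(list(rate_estimate("k_1", 5.0e5, order = 2)),
                            list(rate_estimate("k_1", 5.4e4, order = 2)))
  expect_equal(fck$fold, 9.26, tolerance = 1e-2)

  expect_warning(fold_change_report(ref,
                                    list(rate_estimate("k_2", 1))),
                 "no counterpart")
})

test_that("transition_rates recovers generator entries from dwells", {
  sc <- scheme_dncca(k1 = 5e5, k_off = 0.5)
  cond <- experiment_condition(ligand_concentration = 3e-7,  # on 0.15/s
                               acquisition_frames = 1000)
  d <- generate_dataset(sc, cond, quiet_model(), 40, seed = 8)
  tr <- transition_rates(extract_dwells_all(truth_paths(d)),
                         frame_time = 0.1)
  off <- tr[tr$from == 0.4 & tr$to == 0, ]
  expect_lt(abs(off$rate - 0.5), 3 * off$se)
  on <- tr[tr$from == 0 & tr$to == 0.4, ]
  expect_lt(abs(on$rate - 0.15), 3 * on$se)
})
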