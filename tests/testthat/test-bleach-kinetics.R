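# FRAP normalized-difference construction and exponential fitting;
# spot-bleach and half-bleach bound-fraction estimators.

test_that("normalized difference reproduces the model from region series", {
  # constant regions: D = 1 throughout
  d <- normalized_difference(rep(10, 5), rep(4, 5))
  expect_equal(d$value, rep(1, 5))

  # bleached region converging to the unbleached one: D -> 0
  times <- seq(0, 400, by = 20)
  model <- 0.3 + 0.7 * exp(-0.01 * times)
  f_ub <- rep(10, length(times))
  f_b <- f_ub - 6 * model        # shared soluble term + model contrast
  d2 <- normalized_difference(f_ub, f_b, times = times)
  expect_equal(d2$value, model, tolerance = 1e-12)

  expect_error(normalized_difference(rep(5, 5), rep(5, 5)), "bleached")
  expect_error(normalized_difference(1:4, 1:5), "equal length")
})

test_that("recovery fit is exact on noiseless model curves", {
  for (p in list(c(0.488, 1 / 139), c(0.27, 1 / 244), c(0.1, 1 / 60))) {
    crv <- gen_frap_curve(p[1], p[2], noise_sd = 0, frame_interval = 20,
                          n_frames = 30)
    fit <- fit_recovery(crv)
    expect_true(fit$fit_ok)
    expect_equal(fit$a_immobile, p[1], tolerance = 1e-6)
    expect_equal(fit$koff, p[2], tolerance = 1e-6)
    expect_equal(fit$residence_time, 1 / p[2], tolerance = 1e-6)
  }
})

test_that("degenerate recovery curves are flagged, not mis-fit", {
  const <- data.frame(time = seq(0, 100, by = 20), value = 1)
  fc <- fit_recovery(const)
  expect_equal(fc$a_immobile, 1)
  expect_match(fc$note, "pinned")

  rising <- data.frame(time = seq(0, 100, by = 10),
                       value = seq(0.5, 1.5, length.out = 11))
  expect_false(fit_recovery(rising)$fit_ok)
})

test_that("parameter recovery stays within 10% under realistic noise", {
  # STAG1-like early G1 kinetics: slow exchange, small immobile fraction
  res <- t(sapply(1:100, function(s) {
    fit <- fit_recovery(gen_frap_curve(0.27, 1 / 244, noise_sd = 0.02,
                                       frame_interval = 20, n_frames = 30,
                                       seed = s))
    c(a = fit$a_immobile, tau = fit$residence_time)
  }))
  expect_lt(mean(abs(res[, "a"] - 0.27)), 0.05)
  expect_lt(abs(median(res[, "tau"]) - 244) / 244, 0.10)
})

test_that("parameter recovery holds across an (a, residence-time) grid", {
  for (a in c(0.1, 0.3, 0.5)) {
    for (tau in c(60, 120, 240)) {
      res <- t(sapply(1:50, function(s) {
        fit <- fit_recovery(gen_frap_curve(a, 1 / tau, noise_sd = 0.02,
                                           frame_interval = 20, n_frames = 30,
                                           seed = 1000 * tau + s))
        c(fit$a_immobile, fit$residence_time)
      }))
      expect_lt(median(abs(res[, 1] - a) / a), 0.10)
      expect_lt(median(abs(res[, 2] - tau) / tau), 0.10)
    }
  }
})

test_that("spot-bleach raw fraction follows the pre/post window formula", {
  mk <- function(pre, post) {
    times <- seq(0, 30, by = 0.1)
    data.frame(time = times, intensity = ifelse(times <= 0.5, pre, post))
  }
  expect_equal(spotbleach_bound_fraction(mk(100, 100))$raw_pct, 0)
  expect_equal(spotbleach_bound_fraction(mk(100, 60))$raw_pct, 40)

  # scale invariance
  tr <- gen_spotbleach_trace(0.3, 2, noise_sd = 0.01, seed = 3)
  tr2 <- tr; tr2$intensity <- tr2$intensity * 57.3
  expect_equal(spotbleach_bound_fraction(tr)$raw_pct,
               spotbleach_bound_fraction(tr2)$raw_pct, tolerance = 1e-12)

  # plateau of the generator at its planted bound fraction
  raw <- spotbleach_bound_fraction(gen_spotbleach_trace(0.4, 1))$raw_pct
  expect_equal(raw, 40, tolerance = 0.5)

  bad <- data.frame(time = seq(0, 30, 0.1), intensity = -1)
  expect_error(spotbleach_bound_fraction(bad), "prebleach")
})

test_that("reference calibration is the affine map sending free->0, H2B->100", {
  expect_equal(calibrate_bound_fraction(8, 8, 95)$calibrated_pct, 0)
  expect_equal(calibrate_bound_fraction(95, 8, 95)$calibrated_pct, 100)
  expect_equal(calibrate_bound_fraction(51.5, 8, 95)$calibrated_pct, 50)
  # clipping outside the reference range
  expect_equal(calibrate_bound_fraction(2, 8, 95)$calibrated_pct, 0)
  expect_equal(calibrate_bound_fraction(99, 8, 95)$calibrated_pct, 100)
  expect_error(calibrate_bound_fraction(50, 95, 8), "inverted")
})

test_that("half-bleach bound fraction reads soluble loss from the unbleached half", {
  expect_equal(halfbleach_bound_fraction(100, 100), 1)
  expect_equal(halfbleach_bound_fraction(100, 50), 0.5)
  expect_warning(halfbleach_bound_fraction(100, 105), "clipping")

  # two-pool cell: 40% bound; soluble pool mixes instantly and is bleached
  set.seed(8)
  ests <- replicate(200, {
    total <- 100
    bound_ub <- 0.4 * total / 2
    soluble_half <- 0.6 * total / 2
    pre_ub <- bound_ub + soluble_half + rnorm(1, 0, 0.3)
    post_ub <- bound_ub + rnorm(1, 0, 0.3)
    halfbleach_bound_fraction(pre_ub, post_ub)
  })
  expect_equal(mean(ests), 0.40, tolerance = 0.02)
})
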