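# Generators: model-exactness in the noiseless limit, seed reproducibility,
# and the planted ground truth the downstream modules are tested against.

test_that("FRAP curves follow a + (1-a) exp(-koff t) exactly when noiseless", {
  crv <- gen_frap_curve(0.3, 0.01, noise_sd = 0, frame_interval = 10,
                        n_frames = 20)
  expect_equal(crv$value[1], 1.0)
  expect_equal(crv$value, 0.3 + 0.7 * exp(-0.01 * crv$time))

  # fully immobile: constant at 1
  flat <- gen_frap_curve(1, 0.05, noise_sd = 0, n_frames = 10)
  expect_equal(flat$value, rep(1, 10))

  # long-time limit is the immobile fraction (CTCF G1 parameters)
  late <- gen_frap_curve(0.488, 1 / 139, noise_sd = 0, frame_interval = 5000,
                         n_frames = 5)
  expect_equal(tail(late$value, 1), 0.488, tolerance = 1e-6)
})

test_that("generators are reproducible per seed and reject bad parameters", {
  a <- gen_frap_curve(0.3, 0.01, noise_sd = 0.05, seed = 11)
  b <- gen_frap_curve(0.3, 0.01, noise_sd = 0.05, seed = 11)
  c <- gen_frap_curve(0.3, 0.01, noise_sd = 0.05, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))

  expect_error(gen_frap_curve(1.2, 0.01), "a_immobile")
  expect_error(gen_frap_curve(0.3, -1), "koff")
  expect_error(gen_frap_curve(0.3, 0.01, n_frames = 2), "n_frames")
  expect_error(gen_spotbleach_trace(0.4, 1, duration = 0.6), "500 ms")
  expect_error(gen_fcs_acf(10, 1e-3, lags = numeric(0)), "nonempty")
  expect_error(gen_calibration_cells(2, 5, numeric(0)), "nonempty")
})

test_that("spot-bleach traces plateau at the unbound fraction", {
  flat <- gen_spotbleach_trace(0, 1)
  expect_equal(flat$intensity, rep(1, nrow(flat)))

  fast <- gen_spotbleach_trace(1, 1e6)
  expect_equal(tail(fast$intensity, 1), 0)

  tr <- gen_spotbleach_trace(0.4, 1)
  pre <- mean(tr$intensity[tr$time <= 0.5])
  post <- mean(tr$intensity[tr$time >= max(tr$time) - 0.5])
  expect_equal(100 * (pre - post) / pre, 40, tolerance = 0.5)
})

test_that("FCS autocorrelation amplitude and shape match the model", {
  crv <- gen_fcs_acf(10, 1e-3, kappa = 5, lags = c(1e-9, 1e-3))
  expect_equal(crv$value[1], 0.1, tolerance = 1e-5)       # G(0) = 1/N
  # 2D limit at tau = tau_d: half amplitude
  crv2d <- gen_fcs_acf(10, 1e-3, kappa = 1e9, lags = c(1e-3))
  expect_equal(crv2d$value, 0.05, tolerance = 1e-6)
  # generator/fitter roundtrip at the reference particle number
  fit <- fit_acf(gen_fcs_acf(2.05, 5e-4, kappa = 5))
  expect_true(fit$fit_ok)
  expect_equal(fit$n_particles, 2.05, tolerance = 1e-6)
})

test_that("simulated STED images carry their planted ground truth", {
  empty <- gen_sted_image(0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(mean(empty$image), 10, tolerance = 0.05)

  sim <- gen_sted_image(40, seed = 2)
  expect_equal(nrow(sim$image), 750)  # ceil(sqrt(200)*1000/18.88)
  expect_equal(nrow(sim$truth), 40)
  expect_true(all(sim$truth$x >= 0 & sim$truth$x < 750))
  expect_true(all(sim$truth$y >= 0 & sim$truth$y < 750))
  # peak amplitude ~ intensity_gain-fold over background
  expect_equal(max(sim$image) - 10, 60, tolerance = 0.15)

  # dimers double the planted amplitude
  dim_sim <- gen_sted_image(20, dimer_fraction = 0.5, seed = 3)
  expect_equal(sum(dim_sim$truth$dimer), 10)
  expect_setequal(unique(dim_sim$truth$amplitude), c(60, 120))

  # second channel shares exactly the requested positions
  co <- gen_sted_image(30, coloc_fraction = 0.5, seed = 4)
  shared <- merge(co$truth[, c("x", "y")], co$truth2[, c("x", "y")])
  expect_gte(nrow(shared), 15)
})

test_that("trace backbone follows random-walk scaling with loop compaction", {
  tr <- gen_traces(400, n_bins = 50, step_sd = 60, loc_noise_sd = 0, seed = 5)
  # mean squared 3D distance grows as 3 * sep * step_sd^2
  for (sep in c(5, 20)) {
    pairs <- tr[tr$bin_index %in% c(0, sep), ]
    wide <- merge(pairs[pairs$bin_index == 0, c("trace_id", "x", "y", "z")],
                  pairs[pairs$bin_index == sep, c("trace_id", "x", "y", "z")],
                  by = "trace_id")
    msd <- mean((wide$x.x - wide$x.y)^2 + (wide$y.x - wide$y.y)^2 +
                  (wide$z.x - wide$z.y)^2)
    expect_equal(msd, 3 * sep * 60^2, tolerance = 0.15)
  }

  # planted loop pulls members closer than equal-separation outside pairs
  lt <- gen_traces(500, n_bins = 100, step_sd = 60,
                   loops = list(c(10, 60, 0.3)), loc_noise_sd = 0, seed = 6)
  dm <- median_distance_matrix(lt)
  intra <- dm[21, 41]   # bins 20-40, inside the loop, separation 20
  extra <- dm[71, 91]   # bins 70-90, outside, separation 20
  expect_lt(intra, extra)

  # heavy dropout leaves most traces below the 20-point QC cutoff
  sparse <- gen_traces(100, n_bins = 100, missing_fraction = 0.9, seed = 7)
  pts <- table(sparse$trace_id)
  expect_gt(mean(pts < 20), 0.9)
})

test_that("crossing loop intervals are rejected, nesting is accepted", {
  expect_error(gen_traces(5, n_bins = 100,
                          loops = list(c(10, 50, 0.5), c(30, 70, 0.5))),
               "crossing")
  expect_silent(gen_traces(5, n_bins = 100, seed = 1,
                           loops = list(c(10, 70, 0.5), c(20, 40, 0.5),
                                        c(80, 90, 0.5))))
  expect_error(gen_traces(5, n_bins = 100, loops = list(c(10, 120, 0.5))),
               "within")
  expect_error(gen_traces(5, n_bins = 100, loops = list(c(10, 50, 1.5))),
               "compaction")
})

test_that("calibration-cell generator is exact and linear", {
  pairs <- gen_calibration_cells(2, 5, c(0, 50, 100, 200))
  expect_equal(pairs$intensity[pairs$concentration == 0], 5)
  expect_equal(pairs$intensity[pairs$concentration == 100], 55)
  line <- build_calibration_line(pairs)
  expect_equal(line$factor, 2, tolerance = 1e-10)
  expect_equal(line$background, 5, tolerance = 1e-10)
})
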