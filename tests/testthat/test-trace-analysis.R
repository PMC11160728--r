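# Trace analysis: QC semantics, distance/contact matrices against
# constructed and analytic expectations, difference matrices, scaling.

make_trace <- function(id, bins, coords, snr = 10, fit_sd = 50, bc = 100) {
  data.frame(trace_id = id, bin_index = bins,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             snr = snr, fit_sd = fit_sd, barcode_dist = bc)
}

test_that("QC drops failing points, then traces below the point minimum", {
  # 25 points, 19 of which pass -> whole trace removed
  t1 <- make_trace(1, 0:24, matrix(0, 25, 3),
                   snr = c(rep(10, 19), rep(0.5, 6)))
  # exactly 20 passing points -> retained
  t2 <- make_trace(2, 0:24, matrix(0, 25, 3),
                   snr = c(rep(10, 20), rep(0.5, 5)))
  out <- qc_filter(rbind(t1, t2))
  expect_equal(unique(out$trace_id), 2)
  expect_equal(nrow(out), 20)
  rep <- attr(out, "qc_report")
  expect_equal(rep$traces_in, 2)
  expect_equal(rep$traces_kept, 1)

  # all passing: identity; and idempotence
  t3 <- make_trace(3, 0:24, matrix(rnorm(75), 25, 3))
  once <- qc_filter(t3)
  expect_equal(once[, names(t3)], t3, ignore_attr = TRUE)
  twice <- qc_filter(once)
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)

  # generator metadata drives the same filters
  tr <- gen_traces(50, n_bins = 40, low_quality_fraction = 0.5, seed = 3)
  filtered <- qc_filter(tr)
  pass <- tr$snr >= 2 & tr$fit_sd <= 150 & tr$barcode_dist <= 600
  keep <- names(which(table(tr$trace_id[pass]) >= 20))
  expect_setequal(unique(filtered$trace_id), as.numeric(keep))
})

test_that("median distance matrix matches constructed geometry", {
  t1 <- make_trace(1, c(0, 1), rbind(c(0, 0, 0), c(300, 400, 0)))
  dm <- median_distance_matrix(t1, n_bins = 2)
  expect_equal(dm[1, 2], 500)   # 3-4-5 triangle
  expect_equal(dm[2, 1], 500)
  expect_equal(diag(dm), c(0, 0))

  # duplicating traces leaves medians unchanged
  t2 <- t1; t2$trace_id <- 2
  dm2 <- median_distance_matrix(rbind(t1, t2, t1, t2), n_bins = 2)
  expect_equal(unclass(dm2), unclass(dm), ignore_attr = TRUE)
})

test_that("median distances match the random-walk closed form", {
  tr <- gen_traces(500, n_bins = 60, step_sd = 60, loc_noise_sd = 0, seed = 2)
  dm <- median_distance_matrix(tr)
  for (sep in c(2, 10, 30)) {
    idx <- cbind(seq_len(60 - sep), seq_len(60 - sep) + sep)
    expected <- 60 * sqrt(sep) * CHI3_MEDIAN
    expect_equal(mean(dm[idx]), expected, tolerance = 0.05)
  }
  expect_true(isSymmetric(unclass(dm)))
})

test_that("contact maps count threshold crossings per cell", {
  all100 <- make_trace(1, c(0, 1), rbind(c(0, 0, 0), c(100, 0, 0)))
  cm <- contact_map(all100, n_bins = 2)
  expect_equal(cm[1, 2], 1)
  all130 <- make_trace(1, c(0, 1), rbind(c(0, 0, 0), c(130, 0, 0)))
  expect_equal(contact_map(all130, n_bins = 2)[1, 2], 0)

  # 3 of 5 traces in contact at a given pair
  dists <- c(50, 80, 119, 121, 400)
  traces <- do.call(rbind, lapply(1:5, function(i) {
    make_trace(i, c(2, 7), rbind(c(0, 0, 0), c(dists[i], 0, 0)))
  }))
  cm5 <- contact_map(traces, n_bins = 8)
  expect_equal(cm5[3, 8], 0.6)

  # entries weakly decrease as the threshold tightens
  tr <- gen_traces(100, n_bins = 30, seed = 4)
  c120 <- contact_map(tr, 120)
  c80 <- contact_map(tr, 80)
  expect_true(all(c80 <= c120 + 1e-12, na.rm = TRUE))
})

test_that("difference matrices subtract elementwise with NA propagation", {
  tr <- gen_traces(50, n_bins = 20, seed = 5)
  a <- median_distance_matrix(tr)
  expect_equal(unclass(difference_matrix(a, a)),
               matrix(0, 20, 20), ignore_attr = TRUE)
  b <- median_distance_matrix(gen_traces(50, n_bins = 20, seed = 6))
  expect_equal(unclass(difference_matrix(a, b)),
               -unclass(difference_matrix(b, a)), ignore_attr = TRUE)
  expect_error(difference_matrix(a, b[1:10, 1:10]), "shapes")
})

test_that("nested-loop depletion shows as a negative internal block", {
  wt <- gen_traces(300, n_bins = 100, step_sd = 60,
                   loops = list(c(10, 80, 0.5), c(30, 60, 0.4)),
                   seed = 7)
  dstag2 <- gen_traces(300, n_bins = 100, step_sd = 60,
                       loops = list(c(10, 80, 0.5)), seed = 8)
  diff <- difference_matrix(median_distance_matrix(wt),
                            median_distance_matrix(dstag2))
  inner <- diff[35:55, 35:55]
  outer_band <- diff[85:100, 85:100]
  expect_lt(mean(inner[upper.tri(inner)]), 0)
  expect_gt(mean(inner[upper.tri(inner)]),
            -Inf)
  expect_lt(abs(mean(outer_band[upper.tri(outer_band)])),
            abs(mean(inner[upper.tri(inner)])))
})

test_that("scaling curves recover ideal-chain behavior and loop compaction", {
  tr <- gen_traces(400, n_bins = 80, step_sd = 60, loc_noise_sd = 0, seed = 9)
  sc <- scaling_curve(tr)
  se <- scaling_exponent(sc)
  expect_equal(se$alpha, 0.5, tolerance = 0.05)

  looped <- gen_traces(400, n_bins = 80, step_sd = 60, loc_noise_sd = 0,
                       loops = list(c(10, 70, 0.3)), seed = 10)
  scl <- scaling_curve(looped)
  m0 <- sc$medians; ml <- scl$medians
  mid <- m0$separation_kb %in% (c(10, 20, 30) * 12)
  expect_true(all(ml$median_nm[mid] < m0$median_nm[mid]))

  single <- make_trace(1, c(0, 5), rbind(c(0, 0, 0), c(10, 0, 0)))
  attr(single, "bin_kb") <- 12
  sc1 <- scaling_curve(single)
  expect_equal(nrow(sc1$pairs), 1)
  expect_equal(sc1$pairs$separation_kb, 60)
})

test_that("planted loops are recovered as contact-enrichment blocks", {
  tr <- gen_traces(400, n_bins = 100, step_sd = 60,
                   loops = list(c(20, 70, 0.3)), seed = 11)
  blk <- contact_enrichment_block(contact_map(qc_filter(tr)))
  expect_gte(interval_jaccard(blk$start_bin, blk$end_bin, 20, 70), 0.8)
})
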