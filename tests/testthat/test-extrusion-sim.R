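# Loop-extrusion simulator: closed-form limits in the sparse CTCF-free
# regime, geometric invariants (nesting, lattice bounds), CTCF capture,
# and the derived statistics.

sparse_species <- function(density = 0.1, tau = 120, speed = 1, ...) {
  species_params("cohesin", loading_rate = density / tau, koff = 1 / tau,
                 speed = speed, ...)
}

test_that("zero loading gives an empty lattice", {
  sp <- species_params("none", loading_rate = 0, koff = 1 / 120)
  sim <- simulate_extrusion(5, sp, duration = 200, seed = 1)
  expect_equal(nrow(sim$final_state), 0)
  expect_equal(nrow(sim$loop_sizes), 0)
  expect_equal(unname(sim$mean_density), 0)
})

test_that("timestep stability precondition is enforced", {
  sp <- species_params("fast", loading_rate = 0.01, koff = 0.01, speed = 20)
  expect_error(simulate_extrusion(5, sp, duration = 10, dt = 0.1),
               "stability")
})

test_that("runs are reproducible per seed", {
  sp <- sparse_species(density = 1)
  a <- simulate_extrusion(5, sp, duration = 600, seed = 42)
  b <- simulate_extrusion(5, sp, duration = 600, seed = 42)
  c <- simulate_extrusion(5, sp, duration = 600, seed = 43)
  expect_identical(a$final_state, b$final_state)
  expect_identical(a$loop_sizes, b$loop_sizes)
  expect_false(identical(a$loop_sizes, c$loop_sizes))
})

test_that("sparse CTCF-free limit matches birth-death closed forms", {
  sim <- simulate_extrusion(100, sparse_species(), duration = 20000,
                            dt = 0.1, seed = 7)
  expect_gt(nrow(sim$loop_sizes), 1000)
  # E[loop size] = speed / koff = 120 kb
  expect_equal(mean(sim$loop_sizes$size_kb), 120, tolerance = 0.1)
  # steady-state density = loading_rate / koff = 0.1 per Mb
  expect_equal(unname(sim$mean_density), 0.1, tolerance = 0.1)
})

test_that("anchors stay ordered, inside the lattice, and non-crossing", {
  sp <- sparse_species(density = 8)   # dense: many collisions
  sim <- simulate_extrusion(5, sp, duration = 1200, seed = 11)
  fs <- sim$final_state
  expect_true(all(fs$left_anchor <= fs$right_anchor))
  expect_true(all(fs$left_anchor >= 0 & fs$right_anchor < 5000))
  # planarity: nesting_stats raises on crossing intervals
  expect_silent(ns <- nesting_stats(sim))
  expect_true(any(ns$depths >= 0))
})

test_that("convergent CTCF sites capture loop anchors", {
  ct <- data.frame(position_kb = c(50, 950), orientation = c("+", "-"))
  sp <- species_params("s", loading_rate = 2 / 20000, koff = 1 / 20000,
                       speed = 1, ctcf_stall_prob = 1)
  frac <- sapply(1:3, function(s) {
    fs <- simulate_extrusion(1, sp, ctcf_sites = ct, duration = 1e5,
                             dt = 0.1, seed = s)$final_state
    a <- c(fs$left_anchor, fs$right_anchor)
    mean(abs(a - 50) <= 1 | abs(a - 950) <= 1)
  })
  expect_gt(mean(frac), 0.5)
})

test_that("nesting statistics count containment and detect crossing", {
  single <- data.frame(left_anchor = 10, right_anchor = 50)
  ns1 <- nesting_stats(single)
  expect_equal(ns1$depths, 0L)
  expect_equal(ns1$paired_fraction, 0)

  nested <- data.frame(left_anchor = c(100, 150), right_anchor = c(300, 200))
  expect_equal(sort(nesting_stats(nested)$depths), c(0L, 1L))

  crossing <- data.frame(left_anchor = c(100, 150), right_anchor = c(200, 300))
  expect_error(nesting_stats(crossing), "crossing")
})

test_that("encounter pairing is more frequent at high occupancy", {
  pf <- function(dens, seed) {
    sp <- species_params("stag2", loading_rate = dens / 120, koff = 1 / 120,
                         speed = 1, pair_on_encounter = TRUE)
    simulate_extrusion(20, sp, duration = 1200, seed = seed)$paired_fraction
  }
  wins <- sapply(1:5, function(s) pf(8, 100 + s) > pf(3, 200 + s))
  expect_true(all(wins))
})

test_that("loop configurations map to ideal-chain distance matrices", {
  no_loops <- data.frame(left_anchor = integer(0), right_anchor = integer(0))
  d0 <- loops_to_distance_map(no_loops, lattice_kb = 1200, bin_kb = 12,
                              step_nm_per_sqrt_kb = 60)
  expect_equal(dim(d0), c(100, 100))
  expect_true(isSymmetric(unclass(d0)))
  expect_equal(diag(d0), rep(0, 100))
  # pure sqrt scaling of genomic separation
  expect_equal(d0[1, 50], 60 * sqrt((50 - 1) * 12), tolerance = 1e-6)

  one <- data.frame(left_anchor = 240, right_anchor = 600)
  d1 <- loops_to_distance_map(one, lattice_kb = 1200, bin_kb = 12)
  expect_lt(d1[21, 49], d0[21, 49])          # inside the loop: closer
  expect_equal(d1[80, 95], d0[80, 95])       # outside: unchanged

  both <- data.frame(left_anchor = c(240, 360), right_anchor = c(600, 480))
  d2 <- loops_to_distance_map(both, lattice_kb = 1200, bin_kb = 12)
  expect_lt(d2[31, 39], d1[31, 39])          # nesting compacts further
  expect_true(all(d2 <= d1 + 1e-9))
})
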