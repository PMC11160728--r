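# Stochastic 1D two-species loop-extrusion simulator: sparse slow-exchanging
# (STAG1-like) and dense fast-exchanging (STAG2-like) extruders, CTCF
# boundary stalling, encounter-induced stalling/pairing. The stepping engine
# is compiled (see src/extrusion_core.cpp); this file holds the user-facing
# interface and the derived statistics.

#' Define a loop-extruder species
#'
#' @param name species label.
#' @param loading_rate loading events per Mb per second. At steady state
#'   the bound density approaches `loading_rate / koff` per Mb.
#' @param koff unloading rate (1/s); mean residence time is `1/koff`.
#' @param speed total loop-growth rate (kb/s), split equally between the
#'   two arms. The canonical in-vitro estimate is ~1 kb/s, which with a
#'   120 s residence time gives 120 kb loops.
#' @param ctcf_stall_prob probability that an arm passing a CTCF site of
#'   the orientation facing it stalls there permanently.
#' @param pair_on_encounter mark both extruders as paired when one blocks
#'   against the other (models encounter-induced dimerization).
#' @return a one-row data.frame.
#' @seealso [simulate_extrusion()]
#' @export
#' @examples
#' species_params("STAG2", loading_rate = 8 / 120, koff = 1 / 120)
species_params <- function(name, loading_rate, koff, speed = 1,
                           ctcf_stall_prob = 0, pair_on_encounter = FALSE) {
  check_positive(loading_rate, "loading_rate", strict = FALSE)
  check_positive(koff, "koff")
  check_positive(speed, "speed", strict = FALSE)
  check_fraction(ctcf_stall_prob, "ctcf_stall_prob")
  data.frame(name = name, loading_rate = loading_rate, koff = koff,
             speed = speed, ctcf_stall_prob = ctcf_stall_prob,
             pair_on_encounter = pair_on_encounter,
             stringsAsFactors = FALSE)
}

#' Simulate loop extrusion on a 1D lattice
#'
#' Fixed-timestep stochastic dynamics on a lattice of 1 kb sites. Per step:
#' (i) each species loads at a uniform random unoccupied site with
#' probability `loading_rate * lattice_mb * dt`; (ii) each unstalled arm
#' grows outward at `speed/2` kb/s; (iii) an arm crossing a CTCF site of
#' the orientation facing it stalls there permanently with the species'
#' stall probability (`+` sites stall left-moving arms, `-` sites stall
#' right-moving arms, so a convergent `+ ... -` pair captures loops);
#' (iv) an arm that would collide with another extruder's anchor blocks at
#' the adjacent site — anchors never cross, which keeps all loop intervals
#' nested or disjoint — and, for species with `pair_on_encounter`, both
#' extruders are marked paired; (v) each extruder unloads with probability
#' `koff * dt`, recording its completed loop size.
#'
#' In the sparse, CTCF-free limit the mean completed loop size is
#' `speed / koff` and the steady-state density `loading_rate / koff` per Mb.
#'
#' @param lattice_mb lattice length (Mb).
#' @param species a data.frame of species rows from [species_params()]
#'   (rbind several for multi-species runs).
#' @param ctcf_sites `NULL` or a data.frame with columns `position_kb` and
#'   `orientation` (`"+"`/`"-"`).
#' @param duration simulated time (s). For steady-state statistics run at
#'   least `10 / min(koff)`.
#' @param dt timestep (s); must satisfy `dt * max(speed) <= 1` kb.
#' @param record_every interval (s) for the density time series.
#' @param seed integer seed or `NULL`.
#' @return a `sim_result` list: `final_state` (one row per extruder still
#'   bound: anchors in kb, stall flags, `paired_with`, `adjacent`),
#'   `loop_sizes` (completed loops: `species`, `size_kb`), `density` (time
#'   series of bound complexes per Mb per species), `mean_density`
#'   (time-averaged, per species), `paired_fraction`, `species`, `seed`.
#' @seealso [nesting_stats()], [loops_to_distance_map()]
#' @export
#' @examples
#' sp <- species_params("cohesin", loading_rate = 0.1 / 120, koff = 1 / 120)
#' sim <- simulate_extrusion(10, sp, duration = 2400, seed = 1)
#' mean(sim$loop_sizes$size_kb)
simulate_extrusion <- function(lattice_mb, species, ctcf_sites = NULL,
                               duration = 1200, dt = 0.1,
                               record_every = 10, seed = NULL) {
  check_positive(lattice_mb, "lattice_mb")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  stopifnot(is.data.frame(species), nrow(species) >= 1)
  if (dt * max(species$speed) > 1) {
    stop("stability violation: dt * max(speed) must be <= 1 kb", call. = FALSE)
  }
  n_sites <- as.integer(round(lattice_mb * 1000))
  if (is.null(ctcf_sites) || nrow(ctcf_sites) == 0) {
    ctcf_pos <- integer(0)
    ctcf_dir <- integer(0)
  } else {
    stopifnot(all(c("position_kb", "orientation") %in% names(ctcf_sites)))
    if (!all(ctcf_sites$orientation %in% c("+", "-"))) {
      stop("CTCF orientation must be '+' or '-'", call. = FALSE)
    }
    ctcf_pos <- as.integer(round(ctcf_sites$position_kb))
    if (any(ctcf_pos < 0 | ctcf_pos >= n_sites)) {
      stop("CTCF site outside lattice", call. = FALSE)
    }
    ctcf_dir <- ifelse(ctcf_sites$orientation == "+", 1L, -1L)
  }

  raw <- with_seed(seed, .simulate_extrusion_cpp(
    n_sites,
    species$loading_rate * lattice_mb,
    species$koff, species$speed, species$ctcf_stall_prob,
    species$pair_on_encounter,
    ctcf_pos, ctcf_dir, duration, dt, record_every))

  fin <- raw$final
  fin$species <- species$name[fin$species_idx]
  fin$species_idx <- NULL
  loops <- data.frame(species = species$name[raw$loop_species],
                      size_kb = raw$loop_sizes,
                      stringsAsFactors = FALSE)
  dens <- as.data.frame(raw$record_counts / lattice_mb)
  names(dens) <- species$name
  dens <- cbind(time = raw$record_time, dens)
  paired <- if (nrow(fin) == 0) NA_real_ else {
    mean(!is.na(fin$paired_with) | fin$adjacent)
  }
  structure(list(final_state = fin,
                 loop_sizes = loops,
                 density = dens,
                 mean_density = setNames(raw$mean_count / lattice_mb,
                                         species$name),
                 paired_fraction = paired,
                 species = species, lattice_mb = lattice_mb,
                 duration = duration, dt = dt, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Loop-extrusion simulation: %.3g Mb lattice, %.4g s, dt = %.3g s\n",
              x$lattice_mb, x$duration, x$dt))
  cat(sprintf("  %d extruders bound at end, %d completed loops recorded\n",
              nrow(x$final_state), nrow(x$loop_sizes)))
  cat("  mean density (/Mb):",
      paste(sprintf("%s = %.3g", names(x$mean_density), x$mean_density),
            collapse = ", "), "\n")
  if (!is.na(x$paired_fraction)) {
    cat(sprintf("  paired fraction: %.3f\n", x$paired_fraction))
  }
  invisible(x)
}

#' Nesting depth histogram and paired fraction of an extruder configuration
#'
#' The depth of each loop is the number of other loops strictly containing
#' it; a configuration produced by a blocking extrusion process is always
#' pairwise nested or disjoint, and crossing intervals raise an error. The
#' paired fraction counts extruders that were marked paired on encounter or
#' whose anchor sits immediately adjacent to another extruder's anchor.
#'
#' @param states a data.frame with columns `left_anchor`, `right_anchor`
#'   and optionally `paired_with` / `adjacent` (e.g. `final_state` of a
#'   [simulate_extrusion()] run), or a `sim_result`.
#' @return list with `depths` (per loop), `depth_histogram` (table) and
#'   `paired_fraction`.
#' @export
nesting_stats <- function(states) {
  if (inherits(states, "sim_result")) states <- states$final_state
  n <- nrow(states)
  if (n == 0) {
    return(list(depths = integer(0), depth_histogram = table(integer(0)),
                paired_fraction = NA_real_))
  }
  l <- states$left_anchor
  r <- states$right_anchor
  depths <- integer(n)
  for (i in seq_len(n)) {
    inside <- l < l[i] & r > r[i]
    crossing <- (l < l[i] & r > l[i] & r < r[i]) |
      (l > l[i] & l < r[i] & r > r[i])
    if (any(crossing)) {
      stop("crossing loop intervals: invariant violation", call. = FALSE)
    }
    depths[i] <- sum(inside)
  }
  paired <- rep(FALSE, n)
  if ("paired_with" %in% names(states)) paired <- paired | !is.na(states$paired_with)
  if ("adjacent" %in% names(states)) paired <- paired | states$adjacent
  # adjacency from anchor positions when flags are absent
  if (!any(c("paired_with", "adjacent") %in% names(states)) && n > 1) {
    anchors <- c(l, r)
    owner <- rep(seq_len(n), 2)
    for (i in seq_len(n)) {
      near <- abs(anchors - l[i]) == 1 | abs(anchors - r[i]) == 1
      paired[i] <- any(near & owner != i)
    }
  }
  list(depths = depths,
       depth_histogram = table(factor(depths, levels = 0:max(depths))),
       paired_fraction = mean(paired))
}

#' Expected pairwise distance map implied by a loop configuration
#'
#' Bridges the 1D simulator to trace-style distance matrices: looped-out
#' chromatin contributes less effective contour between two genomic bins.
#' Each kb covered by `d` nested loops contributes `compaction^d` kb of
#' effective contour, and the expected spatial distance follows ideal-chain
#' scaling, `step_nm_per_sqrt_kb * sqrt(effective contour)`.
#'
#' @param states extruder states (`left_anchor`/`right_anchor` in kb) or a
#'   `sim_result`.
#' @param lattice_kb lattice length (kb); taken from the `sim_result` when
#'   available.
#' @param bin_kb genomic bin width (kb); bins must cover the lattice.
#' @param step_nm_per_sqrt_kb chain prefactor (nm per sqrt(kb)).
#' @param compaction contour weight of looped-out chromatin, in (0, 1].
#' @return symmetric distance matrix (nm) with zero diagonal, one row per
#'   bin, with attribute `bin_kb`.
#' @export
loops_to_distance_map <- function(states, lattice_kb = NULL, bin_kb = 12,
                                  step_nm_per_sqrt_kb = 60,
                                  compaction = 0.25) {
  if (inherits(states, "sim_result")) {
    if (is.null(lattice_kb)) lattice_kb <- states$lattice_mb * 1000
    states <- states$final_state
  }
  if (is.null(lattice_kb)) stop("`lattice_kb` is required", call. = FALSE)
  check_positive(bin_kb, "bin_kb")
  check_positive(step_nm_per_sqrt_kb, "step_nm_per_sqrt_kb")
  if (compaction <= 0 || compaction > 1) {
    stop("`compaction` must be in (0, 1]", call. = FALSE)
  }
  n_bins <- floor(lattice_kb / bin_kb)
  if (n_bins < 2) stop("bins must cover the lattice", call. = FALSE)

  depth <- rep(0L, lattice_kb)  # nesting depth of each kb segment
  for (i in seq_len(nrow(states))) {
    a <- states$left_anchor[i]
    b <- states$right_anchor[i]
    if (b > a) depth[(a + 1):b] <- depth[(a + 1):b] + 1L
  }
  w <- compaction^depth
  cumw <- c(0, cumsum(w))
  centers <- (seq_len(n_bins) - 0.5) * bin_kb  # kb coordinates
  wc <- cumw[pmin(round(centers) + 1, length(cumw))]
  d <- step_nm_per_sqrt_kb * sqrt(abs(outer(wc, wc, "-")))
  dimnames(d) <- NULL
  attr(d, "bin_kb") <- bin_kb
  d
}
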