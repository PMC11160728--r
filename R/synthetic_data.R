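# Synthetic-data generators: every input class consumed by the analysis
# modules can be produced here with known ground truth. Noise is additive
# Gaussian throughout; seeds are explicit arguments and never touch the
# caller's RNG state.

#' Generate a FRAP recovery curve with known kinetics
#'
#' Simulates the normalized-difference FRAP readout
#' \eqn{D(t) = a + (1 - a) e^{-k_{off} t}} sampled at regular frame
#' intervals, with optional additive Gaussian noise. `a` is the immobile
#' (stably bound) fraction and `koff` the unbinding rate of the dynamically
#' exchanging pool; its chromatin residence time is `1/koff`.
#'
#' @param a_immobile immobile fraction in `[0, 1]`.
#' @param koff unbinding rate constant (1/s), `> 0`.
#' @param noise_sd additive Gaussian sd on the normalized values.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames (>= 3); the first frame is `t = 0`,
#'   the first post-bleach frame.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `recovery_curve` data.frame with columns `time` (s) and `value`.
#' @seealso [fit_recovery()], [normalized_difference()]
#' @export
#' @examples
#' crv <- gen_frap_curve(0.488, 1 / 139, noise_sd = 0.02,
#'                       frame_interval = 20, n_frames = 30, seed = 1)
#' fit_recovery(crv)
gen_frap_curve <- function(a_immobile, koff, noise_sd = 0,
                           frame_interval = 20, n_frames = 30, seed = NULL) {
  check_fraction(a_immobile, "a_immobile")
  check_positive(koff, "koff")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(frame_interval, "frame_interval")
  check_count(n_frames, "n_frames", min = 3)
  times <- (seq_len(n_frames) - 1) * frame_interval
  values <- a_immobile + (1 - a_immobile) * exp(-koff * times)
  if (noise_sd > 0) {
    values <- values + with_seed(seed, rnorm(n_frames, 0, noise_sd))
  }
  structure(data.frame(time = times, value = values),
            class = c("recovery_curve", "data.frame"))
}

#' Generate a spot-bleach depletion trace with a known bound fraction
#'
#' Emulates continuous point illumination of a chromatin spot: the
#' chromatin-bound pool is bleached away while the unbound pool is
#' continuously replenished from the large soluble reservoir. The recorded
#' trace opens with a 500 ms pre-bleach window at the undepleted intensity
#' (the reference window used by [spotbleach_bound_fraction()]); depletion
#' then follows
#' \eqn{I(t) = (1 - f_b) + f_b e^{-k_{bleach} t}} with `t` measured from the
#' end of that window, so that for `bleach_rate * duration >> 1` the plateau
#' equals the unbound fraction.
#'
#' @param bound_fraction chromatin-bound fraction in `[0, 1]`.
#' @param bleach_rate depletion rate of the bound pool (1/s).
#' @param duration total illumination time (s), default 30 as in the assay.
#' @param dt sampling interval (s); the 500 ms analysis windows must contain
#'   at least one sample.
#' @param noise_sd additive Gaussian sd (fraction of the prebleach level).
#' @param seed integer seed or `NULL`.
#' @return a `depletion_trace` data.frame with columns `time` (s) and
#'   `intensity` (normalized units).
#' @seealso [spotbleach_bound_fraction()]
#' @export
gen_spotbleach_trace <- function(bound_fraction, bleach_rate, duration = 30,
                                 dt = 0.05, noise_sd = 0, seed = NULL) {
  check_fraction(bound_fraction, "bound_fraction")
  check_positive(bleach_rate, "bleach_rate", strict = FALSE)
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (duration / dt < 2 * (0.5 / dt) || duration < 1) {
    stop("trace must cover at least two 500 ms windows", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  t_post <- pmax(times - 0.5, 0)
  intensity <- ifelse(times <= 0.5, 1,
                      (1 - bound_fraction) +
                        bound_fraction * exp(-bleach_rate * t_post))
  if (noise_sd > 0) {
    intensity <- intensity + with_seed(seed, rnorm(length(times), 0, noise_sd))
  }
  structure(data.frame(time = times, intensity = intensity),
            class = c("depletion_trace", "data.frame"))
}

#' Generate an FCS autocorrelation curve for free 3D diffusion
#'
#' Produces \eqn{G(\tau) = \frac{1}{N}\left(1 + \tau/\tau_D\right)^{-1}
#' \left(1 + \tau/(\kappa^2 \tau_D)\right)^{-1/2}} for a mean particle
#' number `N` in the effective confocal volume, with optional relative
#' Gaussian noise.
#'
#' @param n_particles mean particle number in the detection volume (> 0).
#' @param tau_d diffusion time through the focus (s).
#' @param kappa axial-to-lateral ratio of the detection volume (>= 1).
#' @param lags lag times (s), nonempty, sorted ascending.
#' @param noise_sd relative noise sd (fraction of `G` at each lag).
#' @param seed integer seed or `NULL`.
#' @return an `acf_curve` data.frame with columns `lag` (s) and `value`.
#' @seealso [fit_acf()]
#' @export
gen_fcs_acf <- function(n_particles, tau_d, kappa = 5,
                        lags = 10^seq(-6, 0, length.out = 100),
                        noise_sd = 0, seed = NULL) {
  check_positive(n_particles, "n_particles")
  check_positive(tau_d, "tau_d")
  if (!is.numeric(kappa) || kappa < 1) {
    stop("`kappa` must be >= 1", call. = FALSE)
  }
  if (length(lags) == 0) stop("`lags` must be nonempty", call. = FALSE)
  if (is.unsorted(lags)) stop("`lags` must be sorted ascending", call. = FALSE)
  g <- acf_model(lags, n_particles, tau_d, kappa, offset = 0)
  if (noise_sd > 0) {
    g <- g + with_seed(seed, rnorm(length(lags), 0, noise_sd * g))
  }
  structure(data.frame(lag = lags, value = g),
            class = c("acf_curve", "data.frame"))
}

# Diffusion ACF model shared by generator and fitter.
acf_model <- function(tau, n, tau_d, kappa, offset = 0) {
  (1 / n) * (1 + tau / tau_d)^-1 * (1 + tau / (kappa^2 * tau_d))^-0.5 + offset
}

#' Simulate a STED-like image of diffraction-limited protein spots
#'
#' Plants `n_spots` single-pixel impulses at random positions in a square
#' field, blurs them with a Gaussian of sd `blur_sigma` pixels (kernel
#' normalized to unit peak, so the planted peak amplitude stays
#' `intensity_gain`-fold above the background level) and adds a constant
#' noisy background. A fraction of spots can be planted at twice the
#' amplitude, modelling pairs of complexes too close to resolve. An optional
#' second channel shares a chosen fraction of spot positions with the first,
#' for colocalization analysis.
#'
#' The image side length is `ceil(sqrt(field_area) * 1000 / pixel_size)`
#' pixels (750 px for the defaults of 200 um^2 at 18.88 nm pixels).
#'
#' @param n_spots number of spots in channel 1 (and channel 2 if simulated).
#' @param field_area imaged area (um^2).
#' @param pixel_size pixel size (nm).
#' @param blur_sigma Gaussian blur sd (pixels).
#' @param intensity_gain spot peak amplitude as a fold over `background`.
#' @param dimer_fraction fraction of channel-1 spots planted at 2x amplitude.
#' @param coloc_fraction if not `NULL`, a second channel is generated with
#'   this fraction of its spots copied from channel-1 positions.
#' @param background constant background level (intensity units). The
#'   background model is a free parameter of the simulation.
#' @param background_sd additive Gaussian noise sd on every pixel.
#' @param min_separation minimum pairwise distance between planted spots
#'   (pixels, enforced by rejection sampling; 0 disables).
#' @param seed integer seed or `NULL`.
#' @return a `sted_sim` list with `image` (matrix), `truth` (data.frame with
#'   0-based `x`, `y` pixel positions, `amplitude`, `dimer`), and — when
#'   `coloc_fraction` is given — `image2`, `truth2`.
#' @seealso [segment_spots()], [pearson_colocalization()]
#' @export
gen_sted_image <- function(n_spots, field_area = 200, pixel_size = 18.88,
                           blur_sigma = 2.6, intensity_gain = 6,
                           dimer_fraction = 0, coloc_fraction = NULL,
                           background = 10, background_sd = 1,
                           min_separation = 0, seed = NULL) {
  check_count(n_spots, "n_spots", min = 0)
  check_positive(field_area, "field_area")
  check_positive(pixel_size, "pixel_size")
  check_positive(blur_sigma, "blur_sigma")
  check_positive(intensity_gain, "intensity_gain")
  check_fraction(dimer_fraction, "dimer_fraction")
  if (!is.null(coloc_fraction)) check_fraction(coloc_fraction, "coloc_fraction")
  side <- as.integer(ceiling(sqrt(field_area) * 1000 / pixel_size))

  with_seed(seed, {
    pos1 <- sample_spot_positions(n_spots, side, min_separation)
    dimer <- rep(FALSE, n_spots)
    if (n_spots > 0 && dimer_fraction > 0) {
      n_dim <- round(dimer_fraction * n_spots)
      dimer[sample.int(n_spots, n_dim)] <- TRUE
    }
    amp <- intensity_gain * background * ifelse(dimer, 2, 1)
    truth1 <- data.frame(x = pos1$x, y = pos1$y, amplitude = amp, dimer = dimer)
    img1 <- render_spot_image(truth1, side, blur_sigma, background, background_sd)
    out <- list(image = img1, truth = truth1, side = side,
                pixel_size = pixel_size, background = background)
    if (!is.null(coloc_fraction)) {
      n_shared <- round(coloc_fraction * n_spots)
      shared <- if (n_shared > 0) sample.int(n_spots, n_shared) else integer(0)
      pos2 <- sample_spot_positions(n_spots - n_shared, side, min_separation)
      truth2 <- data.frame(
        x = c(truth1$x[shared], pos2$x),
        y = c(truth1$y[shared], pos2$y),
        amplitude = intensity_gain * background,
        dimer = FALSE)
      out$image2 <- render_spot_image(truth2, side, blur_sigma,
                                      background, background_sd)
      out$truth2 <- truth2
    }
    structure(out, class = "sted_sim")
  })
}

sample_spot_positions <- function(n, side, min_separation) {
  if (n == 0) return(list(x = integer(0), y = integer(0)))
  x <- sample.int(side, n, replace = TRUE) - 1L
  y <- sample.int(side, n, replace = TRUE) - 1L
  if (min_separation > 0) {
    for (attempt in 1:200) {
      d <- as.matrix(stats::dist(cbind(x, y)))
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < min_separation)
      if (length(bad) == 0) break
      x[bad] <- sample.int(side, length(bad), replace = TRUE) - 1L
      y[bad] <- sample.int(side, length(bad), replace = TRUE) - 1L
    }
  }
  list(x = x, y = y)
}

# Render impulses, blur with a unit-peak Gaussian kernel, add background.
# Consumes RNG (background noise): callers manage seeding.
render_spot_image <- function(truth, side, blur_sigma, background,
                              background_sd) {
  img <- matrix(0, side, side)
  if (nrow(truth) > 0) {
    img[cbind(truth$y + 1L, truth$x + 1L)] <-
      img[cbind(truth$y + 1L, truth$x + 1L)] + truth$amplitude
    half <- ceiling(4 * blur_sigma)
    ax <- (-half):half
    k <- exp(-outer(ax^2, ax^2, "+") / (2 * blur_sigma^2))
    img <- EBImage::filter2(img, k)
  }
  img + background + matrix(rnorm(side * side, 0, background_sd), side, side)
}

#' Simulate 3D chromatin traces with planted loops
#'
#' The backbone of each trace is a Gaussian chain: successive genomic bins
#' are connected by 3D steps with per-axis sd `step_sd` nm. Within a planted
#' loop interval the steps are multiplied by the loop's compaction factor
#' (factors multiply where loops nest), bringing loop members closer in
#' space. Gaussian localization noise is added per point and a fraction of
#' points is dropped at random. Per-point quality-control columns (`snr`,
#' `fit_sd`, `barcode_dist`) are filled from the generation metadata:
#' ordinary points draw values that pass the default [qc_params()], while a
#' `low_quality_fraction` of points draws clearly failing values.
#'
#' @param n_traces number of traces.
#' @param n_bins genomic bins per trace (e.g. 100 bins of 12 kb).
#' @param step_sd per-axis backbone step sd (nm per bin).
#' @param loops list of loops, each `c(start_bin, end_bin, compaction)` with
#'   0-based bins and compaction in `(0, 1]`. Intervals must be nested or
#'   disjoint; partially overlapping ("crossing") loops are rejected.
#' @param loc_noise_sd per-axis localization noise sd (nm).
#' @param missing_fraction fraction of points dropped at random.
#' @param low_quality_fraction fraction of surviving points given failing QC
#'   metrics.
#' @param bin_kb genomic bin width (kb), stored as an attribute.
#' @param seed integer seed or `NULL`.
#' @return a `trace_table` data.frame with columns `trace_id`, `bin_index`
#'   (0-based), `x`, `y`, `z` (nm), `snr`, `fit_sd`, `barcode_dist`.
#' @seealso [qc_filter()], [median_distance_matrix()]
#' @export
gen_traces <- function(n_traces, n_bins = 100, step_sd = 60,
                       loops = list(), loc_noise_sd = 20,
                       missing_fraction = 0, low_quality_fraction = 0,
                       bin_kb = 12, seed = NULL) {
  check_count(n_traces, "n_traces", min = 1)
  check_count(n_bins, "n_bins", min = 2)
  check_positive(step_sd, "step_sd")
  check_positive(loc_noise_sd, "loc_noise_sd", strict = FALSE)
  check_fraction(missing_fraction, "missing_fraction")
  check_fraction(low_quality_fraction, "low_quality_fraction")
  loops <- validate_loops(loops, n_bins)

  # Per-step compaction: step j connects bin j-1 to bin j (1-based steps).
  step_scale <- rep(1, n_bins - 1)
  for (lp in loops) {
    inside <- seq_len(n_bins - 1) > lp[1] & seq_len(n_bins - 1) <= lp[2]
    step_scale[inside] <- step_scale[inside] * lp[3]
  }

  with_seed(seed, {
    res <- vector("list", n_traces)
    for (tr in seq_len(n_traces)) {
      steps <- matrix(rnorm(3 * (n_bins - 1), 0, step_sd), ncol = 3) * step_scale
      pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
      pos <- pos + matrix(rnorm(3 * n_bins, 0, loc_noise_sd), ncol = 3)
      keep <- runif(n_bins) >= missing_fraction
      n_keep <- sum(keep)
      if (n_keep == 0) next
      lowq <- runif(n_keep) < low_quality_fraction
      res[[tr]] <- data.frame(
        trace_id = tr,
        bin_index = which(keep) - 1L,
        x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
        snr = ifelse(lowq, abs(rnorm(n_keep, 1, 0.3)),
                     abs(rnorm(n_keep, 10, 2))),
        fit_sd = ifelse(lowq, abs(rnorm(n_keep, 400, 60)),
                        abs(rnorm(n_keep, 50, 10))),
        barcode_dist = ifelse(lowq, abs(rnorm(n_keep, 1500, 250)),
                              abs(rnorm(n_keep, 200, 80))))
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "bin_kb") <- bin_kb
    attr(out, "n_bins") <- n_bins
    class(out) <- c("trace_table", "data.frame")
    out
  })
}

# Loops must be nested or disjoint; crossing intervals are a geometry the
# extrusion process cannot produce and are rejected up front.
validate_loops <- function(loops, n_bins) {
  loops <- lapply(loops, function(lp) {
    lp <- as.numeric(lp)
    if (length(lp) != 3) {
      stop("each loop must be c(start_bin, end_bin, compaction)", call. = FALSE)
    }
    if (lp[1] < 0 || lp[2] >= n_bins || lp[1] >= lp[2]) {
      stop("loop interval must lie within [0, n_bins)", call. = FALSE)
    }
    if (lp[3] <= 0 || lp[3] > 1) {
      stop("compaction factor must be in (0, 1]", call. = FALSE)
    }
    lp
  })
  if (length(loops) > 1) {
    for (i in seq_along(loops)) {
      for (j in seq_along(loops)) {
        if (i >= j) next
        a <- loops[[i]]; b <- loops[[j]]
        disjoint <- a[2] <= b[1] || b[2] <= a[1]
        nested <- (a[1] <= b[1] && b[2] <= a[2]) || (b[1] <= a[1] && a[2] <= b[2])
        if (!disjoint && !nested) {
          stop("crossing loop intervals: loops must be nested or disjoint",
               call. = FALSE)
        }
      }
    }
  }
  loops
}

#' Generate paired intensity/concentration calibration measurements
#'
#' Emulates cells expressing known concentrations of a fluorescent protein,
#' measured as `intensity = concentration / slope + background + noise`, the
#' input for [build_calibration_line()].
#'
#' @param slope calibration factor (nM per background-corrected intensity
#'   unit).
#' @param background intensity offset at zero concentration.
#' @param concentrations nM values, nonempty.
#' @param noise_sd additive Gaussian sd on intensities (intensity units).
#' @param seed integer seed or `NULL`.
#' @return data.frame with columns `concentration` (nM) and `intensity`.
#' @export
gen_calibration_cells <- function(slope, background, concentrations,
                                  noise_sd = 0, seed = NULL) {
  check_positive(slope, "slope")
  if (length(concentrations) == 0) {
    stop("`concentrations` must be nonempty", call. = FALSE)
  }
  intensity <- concentrations / slope + background
  if (noise_sd > 0) {
    intensity <- intensity +
      with_seed(seed, rnorm(length(concentrations), 0, noise_sd))
  }
  data.frame(concentration = concentrations, intensity = intensity)
}
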