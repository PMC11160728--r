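# Photobleaching kinetics: FRAP normalized-difference curves and single
# exponential fitting with an immobile fraction; spot-bleach bound-fraction
# estimation with reference calibration; half-nucleus bleach bound fraction.

#' Normalized difference between unbleached and bleached regions
#'
#' Builds the FRAP readout
#' \eqn{D(t) = \frac{F_{ub}(t) - F_b(t)}{F_{ub}(0) - F_b(0)}}
#' from per-region mean intensity series. `t = 0` is the first post-bleach
#' frame; `D` starts at 1 by construction and decays to the immobile
#' fraction as the bleached and unbleached pools equilibrate.
#'
#' @param unbleached mean intensities of the unbleached region per frame.
#' @param bleached mean intensities of the bleached region, same length.
#' @param times frame times (s); default regular frames starting at 0.
#' @param frame_interval seconds between frames when `times` is `NULL`.
#' @return a `recovery_curve` data.frame (`time`, `value`).
#' @seealso [fit_recovery()]
#' @export
normalized_difference <- function(unbleached, bleached, times = NULL,
                                  frame_interval = 20) {
  if (length(unbleached) != length(bleached)) {
    stop("region series must have equal length", call. = FALSE)
  }
  if (length(unbleached) < 3) stop("need at least 3 frames", call. = FALSE)
  d0 <- unbleached[1] - bleached[1]
  if (!is.finite(d0) || d0 == 0) {
    stop("zero initial difference: nothing was bleached", call. = FALSE)
  }
  if (is.null(times)) times <- (seq_along(unbleached) - 1) * frame_interval
  structure(data.frame(time = times, value = (unbleached - bleached) / d0),
            class = c("recovery_curve", "data.frame"))
}

#' Fit a single exponential with immobile fraction to a FRAP curve
#'
#' Fits \eqn{D(t) = a + (1 - a) e^{-k_{off} t}} by bounded nonlinear least
#' squares with \eqn{a \in [0, 1]} and \eqn{k_{off} > 0}. `a` is the
#' immobile (stably bound) fraction that does not exchange during the
#' measurement; `1/koff` is the residence time of the dynamically bound
#' pool. Initialization: `a` from the last observed value, `koff` from the
#' time at which the curve first falls below half of its total decay. A
#' curve that rises instead of recovering is flagged (`fit_ok = FALSE`); a
#' constant curve returns `a` at that level with `koff` pinned at its lower
#' bound and a note.
#'
#' @param curve a `recovery_curve` data.frame (`time`, `value`), >= 5
#'   frames. A warning is issued when the sampled window is shorter than one
#'   expected half-life of the fitted decay.
#' @param koff_min lower bound on `koff` (1/s).
#' @return a `kinetic_fit` list: `a_immobile`, `koff`, `residence_time`
#'   (= 1/koff, s), `ci` (95% half-widths for `a` and `koff` when
#'   available), `fit_ok`, `note`.
#' @export
#' @examples
#' crv <- gen_frap_curve(0.488, 1 / 139, frame_interval = 20, n_frames = 30)
#' fit_recovery(crv)
fit_recovery <- function(curve, koff_min = 1e-6) {
  if (!is.data.frame(curve) || !all(c("time", "value") %in% names(curve))) {
    stop("`curve` must be a data.frame with columns `time` and `value`",
         call. = FALSE)
  }
  if (nrow(curve) < 5) stop("need at least 5 frames", call. = FALSE)
  tt <- curve$time
  vv <- curve$value

  mk <- function(a, koff, ok, note = NA_character_, ci = c(a = NA, koff = NA)) {
    structure(list(a_immobile = a, koff = koff,
                   residence_time = 1 / koff, ci = ci,
                   fit_ok = ok, note = note),
              class = "kinetic_fit")
  }

  total_decay <- vv[1] - vv[length(vv)]
  if (sd(vv) < 1e-12 || abs(total_decay) < 1e-12 && sd(vv) < 1e-6) {
    # Constant curve: fully immobile at the observed level.
    return(mk(min(max(vv[1], 0), 1), koff_min, TRUE,
              note = "constant curve: koff pinned at lower bound"))
  }
  slope <- unname(coef(lm(vv ~ tt))[2])
  if (slope > 0 && vv[length(vv)] > vv[1]) {
    return(mk(NA_real_, NA_real_, FALSE,
              note = "curve increases over time: not a recovery"))
  }

  a0 <- min(max(vv[length(vv)], 0), 1)
  half_level <- a0 + (vv[1] - a0) / 2
  i_half <- which(vv <= half_level & tt > 0)[1]
  koff0 <- if (is.na(i_half)) 1 / max(median(tt), 1) else log(2) / tt[i_half]
  koff0 <- max(koff0, koff_min)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ a + (1 - a) * exp(-koff * time),
      data = data.frame(time = tt, value = vv),
      start = list(a = a0, koff = koff0),
      lower = c(a = 0, koff = koff_min), upper = c(a = 1, koff = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(mk(NA_real_, NA_real_, FALSE, note = "optimizer failed to converge"))
  }
  p <- coef(fit)
  ci <- tryCatch({
    se <- summary(fit)$coefficients[, "Std. Error"]
    c(a = unname(1.96 * se["a"]), koff = unname(1.96 * se["koff"]))
  }, error = function(e) c(a = NA_real_, koff = NA_real_))
  note <- NA_character_
  if (max(tt) < log(2) / p["koff"]) {
    warning("curve spans less than one expected half-life; parameters poorly constrained",
            call. = FALSE)
    note <- "short observation window"
  }
  mk(unname(p["a"]), unname(p["koff"]), TRUE, note = note, ci = ci)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("FRAP kinetic fit:", if (x$fit_ok) "converged" else "FAILED", "\n")
  if (x$fit_ok) {
    cat(sprintf("  immobile fraction a = %.3f, koff = %.4g /s (residence %.4g s)\n",
                x$a_immobile, x$koff, x$residence_time))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Raw chromatin-bound fraction from a spot-bleach depletion trace
#'
#' The bound fraction is the fractional intensity lost during continuous
#' point illumination:
#' `100 * (mean(first 500 ms) - mean(last 500 ms)) / mean(first 500 ms)`.
#' The bound pool at the spot is bleached away while the unbound pool is
#' replenished from the soluble reservoir, so the depletion plateau reports
#' the unbound fraction.
#'
#' @param trace a `depletion_trace` data.frame (`time`, `intensity`)
#'   covering at least 1 s, regularly sampled.
#' @param window analysis window (s), default 0.5.
#' @return a `bound_fraction` list with `raw_pct` (percent); `calibrated_pct`
#'   is filled by [calibrate_bound_fraction()].
#' @export
#' @examples
#' tr <- gen_spotbleach_trace(0.4, bleach_rate = 1)
#' spotbleach_bound_fraction(tr)$raw_pct  # ~40
spotbleach_bound_fraction <- function(trace, window = 0.5) {
  if (!is.data.frame(trace) || !all(c("time", "intensity") %in% names(trace))) {
    stop("`trace` must be a data.frame with columns `time` and `intensity`",
         call. = FALSE)
  }
  span <- diff(range(trace$time))
  if (span < 1) stop("trace must cover at least 1 s", call. = FALSE)
  t0 <- min(trace$time)
  t1 <- max(trace$time)
  pre <- trace$intensity[trace$time <= t0 + window]
  post <- trace$intensity[trace$time >= t1 - window]
  if (length(pre) < 1 || length(post) < 1) {
    stop("each 500 ms window must contain at least one sample", call. = FALSE)
  }
  pre_mean <- mean(pre)
  if (!is.finite(pre_mean) || pre_mean <= 0) {
    stop("non-positive prebleach mean", call. = FALSE)
  }
  structure(list(raw_pct = 100 * (pre_mean - mean(post)) / pre_mean,
                 calibrated_pct = NA_real_,
                 references = c(free_pct = NA_real_, h2b_pct = NA_real_)),
            class = "bound_fraction")
}

#' Calibrate a raw spot-bleach bound fraction against reference constructs
#'
#' Maps the raw percentage onto the affine scale anchored by a freely
#' diffusing reference (0% bound) and a histone reference (~100% bound):
#' `100 * (raw - free) / (h2b - free)`, clipped to `[0, 100]`. This is the
#' unique affine map sending the references to 0 and 100.
#'
#' @param raw_pct raw bound fraction (percent) or a `bound_fraction`.
#' @param free_reference_pct raw percentage measured for free monomeric GFP.
#' @param h2b_reference_pct raw percentage measured for H2B-GFP; must exceed
#'   `free_reference_pct`.
#' @return a `bound_fraction` list with both `raw_pct` and `calibrated_pct`.
#' @export
#' @examples
#' calibrate_bound_fraction(51.5, 8, 95)$calibrated_pct  # 50
calibrate_bound_fraction <- function(raw_pct, free_reference_pct,
                                     h2b_reference_pct) {
  if (inherits(raw_pct, "bound_fraction")) raw_pct <- raw_pct$raw_pct
  if (h2b_reference_pct <= free_reference_pct) {
    stop("references inverted: h2b_reference_pct must exceed free_reference_pct",
         call. = FALSE)
  }
  cal <- 100 * (raw_pct - free_reference_pct) /
    (h2b_reference_pct - free_reference_pct)
  structure(list(raw_pct = raw_pct,
                 calibrated_pct = min(max(cal, 0), 100),
                 references = c(free_pct = free_reference_pct,
                                h2b_pct = h2b_reference_pct)),
            class = "bound_fraction")
}

#' @export
print.bound_fraction <- function(x, ...) {
  cat(sprintf("Bound fraction: raw %.2f%%", x$raw_pct))
  if (!is.na(x$calibrated_pct)) {
    cat(sprintf(", calibrated %.2f%%", x$calibrated_pct))
  }
  cat("\n")
  invisible(x)
}

#' Bound fraction from half-nucleus bleaching of the soluble pool
#'
#' After repeated bleaching of half the nucleus, the freely diffusing pool
#' is fully depleted while chromatin-bound molecules in the unbleached half
#' are untouched. The soluble fraction is therefore read from the intensity
#' loss in the unbleached half, `s = 1 - post_ub / pre_ub`, and the bound
#' fraction is `1 - s`, clipped to `[0, 1]`.
#'
#' @param pre_ub,post_ub mean intensity of the unbleached half before/after
#'   the bleach train.
#' @param pre_b,post_b mean intensity of the bleached half (accepted for a
#'   complete record; not used by this estimator).
#' @return bound fraction in `[0, 1]`.
#' @export
halfbleach_bound_fraction <- function(pre_ub, post_ub, pre_b = NA,
                                      post_b = NA) {
  check_positive(pre_ub, "pre_ub")
  if (post_ub > pre_ub) {
    warning("post-bleach exceeds pre-bleach in the unbleached half; clipping",
            call. = FALSE)
  }
  min(max(post_ub / pre_ub, 0), 1)
}
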