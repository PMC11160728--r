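# FCS-calibrated imaging: autocorrelation fitting, effective confocal
# volume, intensity-to-concentration calibration, absolute copy numbers.

#' Fit a diffusion model to an FCS autocorrelation curve
#'
#' Fits \eqn{G(\tau) = \frac{1}{N}(1 + \tau/\tau_D)^{-1}
#' (1 + \tau/(\kappa^2\tau_D))^{-1/2} + G_\infty} by weighted nonlinear
#' least squares (Levenberg-Marquardt). `N` is the mean particle number in
#' the effective detection volume — the amplitude `G(0) = 1/N` is what makes
#' FCS an absolute concentration measurement. No triplet/blinking term is
#' included. On optimizer failure the fit is returned with
#' `fit_ok = FALSE` rather than an error.
#'
#' @param curve an `acf_curve` data.frame (columns `lag`, `value`), >= 5
#'   points.
#' @param kappa_fixed if not `NULL` (default 5), the axial ratio is held at
#'   this value; pass `NULL` to fit it.
#' @param fit_offset fit a constant offset term (default `TRUE`).
#' @return an `fcs_fit` list: `n_particles`, `tau_d`, `kappa`, `offset`,
#'   `fit_ok`, `r_squared`.
#' @seealso [gen_fcs_acf()], [effective_volume()]
#' @export
#' @examples
#' crv <- gen_fcs_acf(10, 1e-3, kappa = 5)
#' fit_acf(crv)$n_particles
fit_acf <- function(curve, kappa_fixed = 5, fit_offset = TRUE) {
  if (!is.data.frame(curve) || !all(c("lag", "value") %in% names(curve))) {
    stop("`curve` must be a data.frame with columns `lag` and `value`",
         call. = FALSE)
  }
  if (nrow(curve) < 5) stop("need at least 5 lag points", call. = FALSE)
  lag <- curve$lag
  val <- curve$value

  failed <- list(n_particles = NA_real_, tau_d = NA_real_,
                 kappa = if (is.null(kappa_fixed)) NA_real_ else kappa_fixed,
                 offset = 0, fit_ok = FALSE, r_squared = NA_real_)
  class(failed) <- "fcs_fit"
  if (max(val) <= 0 || sd(val) == 0) return(failed)

  # Moment-based starts: amplitude ~ 1/N, tau_d ~ lag at half amplitude.
  g0 <- max(val)
  n0 <- max(1 / g0, 1e-6)
  i_half <- which(val <= g0 / 2)[1]
  tau0 <- if (is.na(i_half)) median(lag[lag > 0]) else max(lag[i_half], min(lag[lag > 0]))

  fit <- tryCatch({
    if (is.null(kappa_fixed)) {
      minpack.lm::nlsLM(
        value ~ acf_model(lag, n, tau_d, kappa, offset),
        data = data.frame(lag = lag, value = val),
        start = list(n = n0, tau_d = tau0, kappa = 5,
                     offset = if (fit_offset) 0 else 0),
        lower = c(1e-9, 1e-12, 1, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        value ~ acf_model(lag, n, tau_d, kappa_fixed, offset),
        data = data.frame(lag = lag, value = val),
        start = list(n = n0, tau_d = tau0, offset = 0),
        lower = c(1e-9, 1e-12, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed)

  p <- coef(fit)
  resid <- val - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((val - mean(val))^2)
  out <- list(n_particles = unname(p["n"]),
              tau_d = unname(p["tau_d"]),
              kappa = if (is.null(kappa_fixed)) unname(p["kappa"]) else kappa_fixed,
              offset = unname(p["offset"]),
              fit_ok = is.finite(p["n"]) && p["n"] > 0,
              r_squared = r2)
  class(out) <- "fcs_fit"
  out
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS fit:", if (x$fit_ok) "converged" else "FAILED", "\n")
  if (x$fit_ok) {
    cat(sprintf("  N = %.4g particles, tau_D = %.4g s, kappa = %.3g, R^2 = %.4f\n",
                x$n_particles, x$tau_d, x$kappa, x$r_squared))
  }
  invisible(x)
}

#' Effective confocal volume from a reference-dye FCS fit
#'
#' With a reference dye of known concentration `C` (e.g. 10 nM Atto488), the
#' fitted particle number gives the effective detection volume
#' \eqn{V_{eff} = N / (C N_A)}.
#'
#' @param fit an `fcs_fit` with `fit_ok = TRUE`, or a bare particle number.
#' @param reference_concentration dye concentration (nM), > 0.
#' @return volume in liters (fL scale for a confocal spot).
#' @export
#' @examples
#' effective_volume(2.05, 10) # ~3.4e-16 L = 0.34 fL
effective_volume <- function(fit, reference_concentration) {
  n <- particle_number(fit)
  check_positive(reference_concentration, "reference_concentration")
  check_positive(n, "n_particles", strict = FALSE)
  n / (reference_concentration * 1e-9 * AVOGADRO)
}

#' Concentration from an FCS particle number
#'
#' Inverse of [effective_volume()]: `C = N / (V_eff * N_A)`, in nM.
#'
#' @param fit an `fcs_fit` with `fit_ok = TRUE`, or a bare particle number.
#' @param veff effective volume (liters), > 0.
#' @return concentration in nM.
#' @export
concentration_from_fcs <- function(fit, veff) {
  n <- particle_number(fit)
  check_positive(veff, "veff")
  check_positive(n, "n_particles", strict = FALSE)
  n / (veff * AVOGADRO) * 1e9
}

particle_number <- function(fit) {
  if (inherits(fit, "fcs_fit")) {
    if (!isTRUE(fit$fit_ok)) stop("FCS fit did not converge", call. = FALSE)
    fit$n_particles
  } else {
    fit
  }
}

#' Build the intensity-to-concentration calibration line
#'
#' Ordinary least-squares regression of measured intensity on the FCS-derived
#' absolute concentration across calibration cells. The calibration factor is
#' the nM gained per background-corrected intensity unit; the background is
#' the intensity intercept at zero concentration.
#'
#' @param pairs data.frame with columns `concentration` (nM) and `intensity`.
#' @return a `calibration_line` list: `factor` (nM per intensity unit),
#'   `background` (intensity units), `r_squared`.
#' @seealso [gen_calibration_cells()], [image_to_numbers()]
#' @export
#' @examples
#' pairs <- gen_calibration_cells(2, 5, c(0, 50, 100, 200))
#' build_calibration_line(pairs)
build_calibration_line <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("concentration", "intensity") %in% names(pairs))) {
    stop("`pairs` must have columns `concentration` and `intensity`",
         call. = FALSE)
  }
  if (nrow(pairs) < 3) stop("need at least 3 calibration pairs", call. = FALSE)
  if (diff(range(pairs$concentration)) == 0) {
    stop("calibration concentrations must span a nonzero range", call. = FALSE)
  }
  m <- lm(intensity ~ concentration, data = pairs)
  slope <- unname(coef(m)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate calibration: nonpositive intensity/concentration slope",
         call. = FALSE)
  }
  ss_res <- sum(residuals(m)^2)
  ss_tot <- sum((pairs$intensity - mean(pairs$intensity))^2)
  out <- list(factor = 1 / slope,
              background = unname(coef(m)[1]),
              r_squared = 1 - ss_res / ss_tot)
  class(out) <- "calibration_line"
  out
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line: %.4g nM per intensity unit, background %.4g AU, R^2 = %.4f\n",
              x$factor, x$background, x$r_squared))
  invisible(x)
}

#' Convert a masked intensity image to concentration and copy number
#'
#' Applies the calibration line voxel-wise: `C = factor * (I - background)`,
#' clipped at zero (copy numbers are nonnegative). The compartment
#' concentration is the mean over the mask; the total copy number integrates
#' `C * voxel_volume * N_A` over the mask, i.e. background-corrected
#' intensities are summed and scaled by the calibration factor.
#'
#' @param intensity_image numeric array (2D or 3D) of intensities.
#' @param mask logical array of the same shape, nonempty.
#' @param line a `calibration_line`.
#' @param voxel_volume volume of one voxel in liters, > 0.
#' @return list with `concentration_nM` (mean over mask) and `copies`
#'   (total protein number in the masked compartment).
#' @export
#' @examples
#' line <- list(factor = 1, background = 0)
#' img <- array(10, c(4, 4, 4))  # uniform 10 nM equivalent
#' image_to_numbers(img, array(TRUE, dim(img)), line, 1e-15)
image_to_numbers <- function(intensity_image, mask, line, voxel_volume) {
  if (!all(dim(intensity_image) == dim(mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  check_positive(voxel_volume, "voxel_volume")
  conc <- pmax(line$factor * (intensity_image[mask] - line$background), 0)
  list(concentration_nM = mean(conc),
       copies = sum(conc) * 1e-9 * voxel_volume * AVOGADRO)
}
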