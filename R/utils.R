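# Shared internal helpers.

#' Avogadro constant (1/mol)
#' @keywords internal
#' @noRd
AVOGADRO <- 6.02214076e23

# Evaluate `code` under a fixed RNG seed without touching the caller's
# global RNG state. All stochastic generators route through this so that
# seeds are explicit arguments, never global side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Printed table values use conventional half-up rounding, unlike base R's
#' round-half-to-even. Exported because reproducing published table cells at
#' printed precision depends on it.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.75, 1)   # 2.8
#' round_half_up(0.885, 2)  # 0.89
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Parameter validation helpers ------------------------------------------------

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "nonnegative"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == floor(x)
  if (!ok) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
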