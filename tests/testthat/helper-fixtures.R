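# Shared helpers for the test suite. Fixtures are built in code.

# Jaccard overlap of two inclusive integer intervals.
interval_jaccard <- function(a1, b1, a2, b2) {
  inter <- max(0, min(b1, b2) - max(a1, a2) + 1)
  inter / ((b1 - a1 + 1) + (b2 - a2 + 1) - inter)
}

# Small synthetic two-spot STED-like image: Gaussian peaks of amplitude
# `amp` (sd `sigma` px) over a constant noisy background.
two_spot_image <- function(centers, n = 100, amp = 60, sigma = 2.6,
                           background = 10, noise_sd = 0.5, seed = 42) {
  img <- matrix(background, n, n)
  for (p in centers) {
    img <- img + amp * exp(-outer((1:n - p[1])^2, (1:n - p[2])^2, "+") /
                             (2 * sigma^2))
  }
  set.seed(seed)
  img + matrix(rnorm(n * n, 0, noise_sd), n, n)
}

# Median of the chi distribution with 3 df: |N(0, I3)| has median
# sqrt(qchisq(0.5, 3)); multiply by the per-axis sd for 3D step medians.
CHI3_MEDIAN <- sqrt(qchisq(0.5, 3))
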