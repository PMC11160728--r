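# Downstream analysis of 3D chromatin traces: per-point and per-trace QC,
# median pairwise distance matrices, contact maps at a distance threshold,
# difference matrices, scaling curves, and contact-enrichment block
# detection for recovering loop domains.

#' Quality-control thresholds for trace points
#'
#' The numeric defaults are configurable conventions of this package (data
#' sets differ in their signal scales); the structural rule — drop failing
#' points, then drop traces with fewer than `min_points` surviving points —
#' is fixed.
#'
#' @param min_snr minimum signal-to-background ratio of a spot fit.
#' @param max_fit_sd maximum fit sd (nm).
#' @param max_barcode_dist maximum distance of a fit center to its regional
#'   barcode (nm).
#' @param min_points minimum high-quality points for a trace to be kept
#'   (default 20).
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_snr = 2, max_fit_sd = 150,
                      max_barcode_dist = 600, min_points = 20) {
  check_positive(min_snr, "min_snr")
  check_positive(max_fit_sd, "max_fit_sd")
  check_positive(max_barcode_dist, "max_barcode_dist")
  check_count(min_points, "min_points", min = 1)
  structure(list(min_snr = min_snr, max_fit_sd = max_fit_sd,
                 max_barcode_dist = max_barcode_dist,
                 min_points = min_points),
            class = "qc_params")
}

#' Filter a trace table on per-point quality, then on trace completeness
#'
#' Points failing any per-point threshold are dropped first; traces left
#' with fewer than `min_points` high-quality positions are then removed
#' entirely. The operation is idempotent. Stage-wise counts are attached as
#' attribute `qc_report`.
#'
#' @param traces a `trace_table` data.frame (columns `trace_id`,
#'   `bin_index`, `x`, `y`, `z`, `snr`, `fit_sd`, `barcode_dist`).
#' @param params a [qc_params()].
#' @return the filtered `trace_table`.
#' @export
qc_filter <- function(traces, params = qc_params()) {
  needed <- c("trace_id", "bin_index", "x", "y", "z")
  if (!all(needed %in% names(traces))) {
    stop("trace table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  pass <- rep(TRUE, nrow(traces))
  if ("snr" %in% names(traces)) pass <- pass & traces$snr >= params$min_snr
  if ("fit_sd" %in% names(traces)) pass <- pass & traces$fit_sd <= params$max_fit_sd
  if ("barcode_dist" %in% names(traces)) {
    pass <- pass & traces$barcode_dist <= params$max_barcode_dist
  }
  kept <- traces[pass, , drop = FALSE]
  n_per_trace <- table(kept$trace_id)
  keep_traces <- names(n_per_trace)[n_per_trace >= params$min_points]
  out <- kept[kept$trace_id %in% keep_traces, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("bin_kb", "n_bins")) attr(out, a) <- attr(traces, a)
  attr(out, "qc_report") <- list(
    points_in = nrow(traces), points_pass = nrow(kept),
    traces_in = length(unique(traces$trace_id)),
    traces_kept = length(keep_traces))
  class(out) <- c("trace_table", "data.frame")
  out
}

# All within-trace pairwise distances in long form: 0-based bins i < j and
# the Euclidean 3D distance, concatenated over traces.
pairwise_long <- function(traces) {
  split_idx <- split(seq_len(nrow(traces)), traces$trace_id)
  res <- lapply(split_idx, function(rows) {
    m <- length(rows)
    if (m < 2) return(NULL)
    ord <- rows[order(traces$bin_index[rows])]
    bins <- traces$bin_index[ord]
    d <- as.numeric(stats::dist(cbind(traces$x[ord], traces$y[ord],
                                      traces$z[ord])))
    jj <- rep(seq_len(m - 1), (m - 1):1)          # condensed-dist ordering
    ii <- unlist(lapply(seq_len(m - 1), function(k) (k + 1):m), use.names = FALSE)
    data.frame(i = bins[jj], j = bins[ii], d = d)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  rownames(out) <- NULL
  out
}

trace_n_bins <- function(traces, n_bins = NULL) {
  if (!is.null(n_bins)) return(n_bins)
  nb <- attr(traces, "n_bins")
  if (is.null(nb)) nb <- max(traces$bin_index) + 1L
  nb
}

#' Median pairwise 3D distance matrix over traces
#'
#' Entry (i, j) is the median, over traces containing both bins, of the
#' Euclidean 3D distance between the bins' fitted positions. Cells with no
#' samples are `NA`. Per-cell sample counts are attached as attribute
#' `n_samples`.
#'
#' @param traces a `trace_table`.
#' @param n_bins number of genomic bins (default from the table's
#'   attribute, else `max(bin_index) + 1`).
#' @return symmetric `n_bins x n_bins` matrix (nm) with zero diagonal and
#'   attributes `n_samples` and `bin_kb`.
#' @export
median_distance_matrix <- function(traces, n_bins = NULL) {
  if (nrow(traces) == 0) stop("need at least one trace", call. = FALSE)
  nb <- trace_n_bins(traces, n_bins)
  pl <- pairwise_long(traces)
  m <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  if (nrow(pl) > 0) {
    key <- pl$i * nb + pl$j
    med <- tapply(pl$d, key, median)
    n <- tapply(pl$d, key, length)
    ks <- as.numeric(names(med))
    ii <- (ks %/% nb) + 1
    jj <- (ks %% nb) + 1
    m[cbind(ii, jj)] <- as.numeric(med)
    m[cbind(jj, ii)] <- as.numeric(med)
    cnt[cbind(ii, jj)] <- as.integer(n)
    cnt[cbind(jj, ii)] <- as.integer(n)
  }
  diag(m) <- 0
  attr(m, "n_samples") <- cnt
  attr(m, "bin_kb") <- attr(traces, "bin_kb")
  m
}

#' Contact frequency map at a 3D distance threshold
#'
#' Entry (i, j) is the fraction of traces containing both bins whose 3D
#' distance falls below the threshold (120 nm by convention for chromatin
#' tracing at this resolution).
#'
#' @param traces a `trace_table`.
#' @param threshold contact distance (nm), > 0.
#' @param n_bins number of genomic bins (see [median_distance_matrix()]).
#' @return symmetric matrix of contact frequencies in `[0, 1]` (diagonal
#'   1), with attributes `n_samples`, `threshold` and `bin_kb`.
#' @export
contact_map <- function(traces, threshold = 120, n_bins = NULL) {
  check_positive(threshold, "threshold")
  if (nrow(traces) == 0) stop("need at least one trace", call. = FALSE)
  nb <- trace_n_bins(traces, n_bins)
  pl <- pairwise_long(traces)
  m <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  if (nrow(pl) > 0) {
    key <- pl$i * nb + pl$j
    frac <- tapply(pl$d < threshold, key, mean)
    n <- tapply(pl$d, key, length)
    ks <- as.numeric(names(frac))
    ii <- (ks %/% nb) + 1
    jj <- (ks %% nb) + 1
    m[cbind(ii, jj)] <- as.numeric(frac)
    m[cbind(jj, ii)] <- as.numeric(frac)
    cnt[cbind(ii, jj)] <- as.integer(n)
    cnt[cbind(jj, ii)] <- as.integer(n)
  }
  diag(m) <- 1
  attr(m, "n_samples") <- cnt
  attr(m, "threshold") <- threshold
  attr(m, "bin_kb") <- attr(traces, "bin_kb")
  m
}

#' Elementwise difference of two distance (or contact) matrices
#'
#' Computes `a - b` (e.g. control minus depletion) with `NA` propagation:
#' cells missing in either input are missing in the difference. The result
#' is antisymmetric under operand swap.
#'
#' @param a,b matrices of identical shape (and `bin_kb`, when annotated).
#' @return matrix of differences.
#' @export
difference_matrix <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrix shapes differ", call. = FALSE)
  ba <- attr(a, "bin_kb"); bb <- attr(b, "bin_kb")
  if (!is.null(ba) && !is.null(bb) && ba != bb) {
    stop("bin widths differ", call. = FALSE)
  }
  out <- unclass(a) - unclass(b)
  attr(out, "bin_kb") <- ba
  out
}

#' Distance-versus-genomic-separation scaling data
#'
#' Collects every within-trace pairwise 3D distance keyed by its genomic
#' separation `|i - j| * bin_kb`, plus the per-separation median — the
#' standard polymer scaling plot. For an ideal chain the median distance
#' grows as separation^0.5.
#'
#' @param traces a `trace_table`.
#' @param bin_kb genomic bin width (kb); default from the table attribute.
#' @return a `scaling_curve` list: `pairs` (long data.frame of
#'   `separation_kb`, `distance_nm`) and `medians` (per-separation
#'   `median_nm` and `n`).
#' @seealso [scaling_exponent()]
#' @export
scaling_curve <- function(traces, bin_kb = NULL) {
  if (nrow(traces) == 0) stop("need at least one trace", call. = FALSE)
  if (is.null(bin_kb)) bin_kb <- attr(traces, "bin_kb")
  if (is.null(bin_kb)) bin_kb <- 1
  pl <- pairwise_long(traces)
  sep <- (pl$j - pl$i) * bin_kb
  med <- tapply(pl$d, sep, median)
  n <- tapply(pl$d, sep, length)
  structure(list(
    pairs = data.frame(separation_kb = sep, distance_nm = pl$d),
    medians = data.frame(separation_kb = as.numeric(names(med)),
                         median_nm = as.numeric(med),
                         n = as.integer(n))),
    class = "scaling_curve")
}

#' Scaling exponent of median distance versus genomic separation
#'
#' Fits `log(median distance) ~ log(separation)` by ordinary least squares
#' over the per-separation medians of a [scaling_curve()].
#'
#' @param sc a `scaling_curve`.
#' @param min_n drop separations supported by fewer pairs than this.
#' @return list with `alpha` (the exponent), `prefactor_nm` (distance at
#'   1 kb implied by the fit) and `r_squared`.
#' @export
scaling_exponent <- function(sc, min_n = 10) {
  med <- sc$medians
  med <- med[med$n >= min_n & med$separation_kb > 0 & med$median_nm > 0, ]
  if (nrow(med) < 3) stop("too few separations for an exponent fit", call. = FALSE)
  m <- lm(log(median_nm) ~ log(separation_kb), data = med)
  list(alpha = unname(coef(m)[2]),
       prefactor_nm = exp(unname(coef(m)[1])),
       r_squared = summary(m)$r.squared)
}

#' Locate the strongest contact-enrichment block in a contact map
#'
#' Scores every candidate genomic interval by the total enrichment of its
#' internal contacts over the distance-decay expectation (the per-diagonal
#' mean of the map), excluding the two diagonals nearest the main diagonal,
#' and returns the interval with the highest score. Inside a looped region
#' every cell is enriched relative to the per-separation average, so the
#' summed enrichment is maximized by the full loop interval rather than by
#' an intense sub-block; this recovers loop or domain boundaries from the
#' block structure they imprint on the map.
#'
#' @param cmap a contact map from [contact_map()].
#' @param min_len minimum interval length (bins).
#' @return list with `start_bin`, `end_bin` (0-based, inclusive), `score`
#'   (summed contact enrichment inside the block) and `mean_enrichment`.
#' @export
contact_enrichment_block <- function(cmap, min_len = 5) {
  n <- nrow(cmap)
  m <- unclass(cmap)
  sep <- abs(row(m) - col(m))
  expected <- tapply(m[upper.tri(m)], sep[upper.tri(m)], mean, na.rm = TRUE)
  e <- m - matrix(expected[as.character(sep)], n, n)
  use <- sep >= 2 & upper.tri(m) & !is.na(e)
  ew <- ifelse(use, e, 0)
  cw <- ifelse(use, 1, 0)
  # summed-area tables make every block mean O(1)
  se <- apply(apply(ew, 2, cumsum), 1, cumsum)  # se[j, i] = sum rows<=i, cols<=j
  sc <- apply(apply(cw, 2, cumsum), 1, cumsum)
  block_stat <- function(a, b) { # 1-based inclusive rows/cols a..b
    s <- function(tab) {
      tab[b, b] - (if (a > 1) tab[a - 1, b] else 0) -
        (if (a > 1) tab[b, a - 1] else 0) +
        (if (a > 1) tab[a - 1, a - 1] else 0)
    }
    c(s(t(se)), s(t(sc)))
  }
  best <- list(start_bin = NA_integer_, end_bin = NA_integer_, score = -Inf,
               mean_enrichment = NA_real_)
  for (a in 1:(n - min_len + 1)) {
    for (b in (a + min_len - 1):n) {
      st <- block_stat(a, b)
      if (st[2] < 3) next
      if (st[1] > best$score) {
        best <- list(start_bin = a - 1L, end_bin = b - 1L, score = st[1],
                     mean_enrichment = st[1] / st[2])
      }
    }
  }
  best
}
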