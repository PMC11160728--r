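# Per-megabase chromatin occupancy: combines absolute copy numbers with
# bound fractions into bound-complex densities, plus loop-size arithmetic
# and a closed-form extruder encounter model.

#' Genome model used as the per-megabase divisor
#'
#' Bound-complex densities are expressed per megabase of genomic DNA. The
#' default divisor is `7,900 Mb x 2` = 15,800 Mb: the HeLa genome per
#' nucleus times two daughter nuclei in early G1. Published summary tables
#' use the same 15,800 Mb divisor for the single-nucleus G1 stage as well;
#' [build_occupancy_table()] keeps that convention by default so its output
#' matches the printed densities, and flags the inconsistency instead of
#' resolving it (see the methods vignette).
#'
#' @param genome_mb_per_copy megabases per genome copy (default 7,900).
#' @param n_genome_copies number of genome copies over which bound
#'   complexes are distributed (default 2).
#' @return a `genome_model` list.
#' @export
genome_model <- function(genome_mb_per_copy = 7900, n_genome_copies = 2) {
  check_positive(genome_mb_per_copy, "genome_mb_per_copy")
  check_positive(n_genome_copies, "n_genome_copies")
  structure(list(genome_mb_per_copy = genome_mb_per_copy,
                 n_genome_copies = n_genome_copies),
            class = "genome_model")
}

#' Number of chromatin-bound copies
#'
#' `nuclear_copies * bound_fraction`, the absolute number of complexes
#' engaged on chromatin.
#'
#' @param nuclear_copies total copies in the nucleus (>= 0).
#' @param bound_fraction fraction bound, in `[0, 1]`.
#' @return unrounded product. Use [round_half_up()] (or `display = TRUE`
#'   rounding to the nearest 10) for table display.
#' @param display round to the nearest 10 for display.
#' @export
#' @examples
#' bound_copies(125500, 0.62)  # 77810
bound_copies <- function(nuclear_copies, bound_fraction, display = FALSE) {
  if (any(nuclear_copies < 0)) stop("negative copy number", call. = FALSE)
  if (any(bound_fraction < 0 | bound_fraction > 1, na.rm = TRUE)) {
    stop("bound_fraction must lie in [0, 1]", call. = FALSE)
  }
  out <- nuclear_copies * bound_fraction
  if (display) out <- round_half_up(out / 10) * 10
  out
}

#' Bound complexes per megabase of genomic DNA
#'
#' Assumes an equal distribution of the bound complexes over the genome:
#' `bound_copies / (genome_mb_per_copy * n_genome_copies)`.
#'
#' @param bound_copies number of chromatin-bound complexes.
#' @param genome a [genome_model()].
#' @param display round half-up to 1 decimal as printed in summary tables.
#' @return complexes per Mb.
#' @export
#' @examples
#' per_mb(80030, genome_model())  # ~5.065; 5.1 with display = TRUE
per_mb <- function(bound_copies, genome = genome_model(), display = FALSE) {
  div <- genome$genome_mb_per_copy * genome$n_genome_copies
  if (div <= 0) stop("genome size must be positive", call. = FALSE)
  out <- bound_copies / div
  if (display) out <- round_half_up(out, 1)
  out
}

#' Long-term bound complexes per megabase
#'
#' Scales the per-Mb density by the long-term (stably) bound fraction from
#' FRAP — the pool that does not exchange during the observation window.
#'
#' @param per_mb bound-complex density (per Mb).
#' @param longterm_frac stably bound fraction in `[0, 1]`.
#' @param display round half-up to 1 decimal.
#' @return complexes per Mb that are stably bound.
#' @export
longterm_per_mb <- function(per_mb, longterm_frac, display = FALSE) {
  if (any(longterm_frac < 0 | longterm_frac > 1, na.rm = TRUE)) {
    stop("longterm_frac must lie in [0, 1]", call. = FALSE)
  }
  out <- per_mb * longterm_frac
  if (display) out <- round_half_up(out, 1)
  out
}

#' Build a per-protein chromatin occupancy table
#'
#' Combines raw measurements (absolute nuclear copy numbers, bound fractions
#' from spot-bleach and FRAP, residence times, long-term bound fractions)
#' into the derived occupancy columns: bound copies, bound complexes per Mb
#' and long-term bound complexes per Mb.
#'
#' Bound-fraction precedence: the FRAP estimate is used when present, with
#' the spot-bleach estimate as fallback (the FRAP fit can fail for weakly
#' recovering proteins). Rows with no bound fraction at all are flagged via
#' `bound_fraction_source = "none"` rather than dropped.
#'
#' @param records data.frame with columns `protein`, `stage`,
#'   `nuclear_copies`, `bound_frac_spotbleach`, `bound_frac_frap` (NA
#'   allowed), and optionally `residence_time` and `longterm_frac`.
#' @param genome a [genome_model()]; the same divisor is applied to every
#'   row.
#' @return an `occupancy_table` data.frame: the input plus
#'   `bound_fraction_used`, `bound_fraction_source`, `bound_copies`,
#'   `per_mb`, `longterm_per_mb` (derived columns unrounded; display
#'   rounding is the caller's concern, see [round_half_up()]).
#' @seealso [occupancy_reference()] for the packaged measurement fixture.
#' @export
#' @examples
#' ref <- occupancy_reference()
#' occ <- build_occupancy_table(ref)
#' subset(occ, protein == "CTCF", c(stage, bound_copies, per_mb))
build_occupancy_table <- function(records, genome = genome_model()) {
  needed <- c("protein", "stage", "nuclear_copies", "bound_frac_spotbleach")
  if (!all(needed %in% names(records))) {
    stop("records must include columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    out <- cbind(records, bound_fraction_used = numeric(0),
                 bound_fraction_source = character(0),
                 bound_copies = numeric(0), per_mb = numeric(0),
                 longterm_per_mb = numeric(0))
    class(out) <- c("occupancy_table", "data.frame")
    return(out)
  }
  frap <- if ("bound_frac_frap" %in% names(records)) {
    records$bound_frac_frap
  } else {
    rep(NA_real_, nrow(records))
  }
  sb <- records$bound_frac_spotbleach
  used <- ifelse(!is.na(frap), frap, sb)
  source <- ifelse(!is.na(frap), "frap", ifelse(!is.na(sb), "spotbleach", "none"))
  if (any(source == "none")) {
    warning("rows without any bound fraction are flagged with source = 'none'",
            call. = FALSE)
  }
  bc <- ifelse(is.na(used), NA_real_,
               bound_copies(records$nuclear_copies, ifelse(is.na(used), 0, used)))
  pm <- per_mb(bc, genome)
  lt <- if ("longterm_frac" %in% names(records)) {
    ifelse(is.na(records$longterm_frac), NA_real_, pm * records$longterm_frac)
  } else {
    rep(NA_real_, nrow(records))
  }
  out <- records
  out$bound_fraction_used <- used
  out$bound_fraction_source <- source
  out$bound_copies <- bc
  out$per_mb <- pm
  out$longterm_per_mb <- lt
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Packaged reference measurements for Condensin/Cohesin/CTCF occupancy
#'
#' Raw measurement columns (nuclear copy numbers, spot-bleach and FRAP bound
#' fractions, residence times, long-term bound fractions) for the SMC
#' subunits SMC4, NCAPH, NCAPH2, the Cohesin subunits RAD21, STAG1, STAG2
#' and CTCF, at two cell-cycle stages: early G1 (20 min past anaphase
#' onset) and G1 (2-4 h past anaphase onset). The `pub_*` columns carry the
#' published derived values at their printed rounding, for cross-checking
#' [build_occupancy_table()] output.
#'
#' @return data.frame, one row per protein and stage.
#' @export
occupancy_reference <- function() {
  path <- system.file("extdata", "occupancy_reference_eg1_g1.csv",
                      package = "loopquant", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Expected loop size from extrusion speed and residence time
#'
#' A loop extruder that stays bound for `1/koff` seconds while growing its
#' loop at `speed` kb/s produces loops of `speed * residence_time` kb: at
#' the canonical 1 kb/s and a 120 s residence time, 120 kb loops.
#'
#' @param speed total loop-growth rate (kb/s), nonnegative.
#' @param residence_time mean chromatin-bound time (s), nonnegative.
#' @return expected loop size (kb).
#' @export
#' @examples
#' loop_size(1, 120)  # 120 kb
loop_size <- function(speed, residence_time) {
  if (any(speed < 0) || any(residence_time < 0)) {
    stop("speed and residence_time must be nonnegative", call. = FALSE)
  }
  speed * residence_time
}

#' Closed-form probability that an extruder's loop overlaps a neighbor
#'
#' Under Poisson placement of extruders at `density` complexes per Mb, each
#' holding a loop of `loop_kb` kb, the probability that a random extruder's
#' loop interval overlaps at least one neighboring loop anchor is
#' \eqn{1 - e^{-\rho L}}. This is the closed-form companion to the
#' observation that encounters between neighboring complexes become much
#' more likely as occupancy rises from ~3 to ~8 complexes per Mb.
#'
#' @param density bound-extruder density (complexes per Mb), nonnegative.
#' @param loop_kb loop size (kb), nonnegative.
#' @return probability in `[0, 1)`.
#' @export
#' @examples
#' encounter_probability(3, 120)  # 0.302
#' encounter_probability(8, 120)  # 0.617
encounter_probability <- function(density, loop_kb) {
  if (any(density < 0) || any(loop_kb < 0)) {
    stop("density and loop_kb must be nonnegative", call. = FALSE)
  }
  1 - exp(-density * loop_kb / 1000)
}
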