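#' Benchmark configuration
#'
#' Collects every numeric threshold of the pipeline: the snapshot year grid,
#' the redundancy-removal identity cutoff, the minimum number of sequences an
#' alignment needs to be workable, the reference year for relative series,
#' and the per-method selection thresholds.
#'
#' @param years ordered snapshot years (default 1994 to 2014 in steps of 2).
#' @param redundancy_identity pairwise identity above which a sequence is
#'   considered redundant (default 0.95).
#' @param min_sequences minimum post-redundancy alignment size (default 15;
#'   the classical alternative is 10).
#' @param reference_year year that relative series are normalized to; must be
#'   in `years`.
#' @param xdet_rho_min Spearman correlation threshold for Xdet-like selection.
#' @param et_score_max ET-like integer-rank threshold ("score 2.0 or better").
#' @param teao_score_max TEA-O-like score threshold.
#' @param s3det_ari_min adjusted-Rand threshold for S3det-like SDP selection.
#' @param max_gap_frac_conserved gap fraction cap for a column to count as
#'   fully conserved.
#' @param max_gap_frac gap fraction above which a column is unscorable by any
#'   method.
#' @param homolog_evalue,structure_evalue,structure_identity_min,structure_coverage_min
#'   adapter settings for real-data retrieval (recorded, not used by the
#'   synthetic core).
#' @param seed integer seed used for the stochastic components of scoring
#'   (k-means restarts in the S3det-like method).
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(years = seq(1994L, 2014L, by = 2L),
                             redundancy_identity = 0.95,
                             min_sequences = 15L,
                             reference_year = 2014L,
                             xdet_rho_min = 0.8,
                             et_score_max = 2.0,
                             teao_score_max = 0.3,
                             s3det_ari_min = 0.8,
                             max_gap_frac_conserved = 0.1,
                             max_gap_frac = 0.5,
                             homolog_evalue = 1e-4,
                             structure_evalue = 1e-3,
                             structure_identity_min = 0.25,
                             structure_coverage_min = 0.50,
                             seed = 1L) {
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) stop_invalid("years must be strictly increasing")
  if (redundancy_identity <= 0 || redundancy_identity >= 1)
    stop_invalid("redundancy_identity must be in (0,1)")
  reference_year <- as.integer(reference_year)
  if (!reference_year %in% years) stop_invalid("reference_year must be one of years")
  structure(list(
    years = years, redundancy_identity = redundancy_identity,
    min_sequences = as.integer(min_sequences), reference_year = reference_year,
    xdet_rho_min = xdet_rho_min, et_score_max = et_score_max,
    teao_score_max = teao_score_max, s3det_ari_min = s3det_ari_min,
    max_gap_frac_conserved = max_gap_frac_conserved, max_gap_frac = max_gap_frac,
    homolog_evalue = homolog_evalue, structure_evalue = structure_evalue,
    structure_identity_min = structure_identity_min,
    structure_coverage_min = structure_coverage_min,
    seed = as.integer(seed)
  ), class = "benchmark_config")
}

#' Historical snapshot of a family at a cutoff year
#'
#' Keeps exactly the members whose publication date is at or before the
#' cutoff year, preserving input order. An empty result is a valid snapshot.
#'
#' @param family data frame with columns `seq_id`, `residues`, `year`.
#' @param year integer cutoff year.
#' @param family_id optional identifier carried in the result.
#' @return an object of class `family_snapshot`: the retained members plus
#'   provenance counts (`n_total_hits`, `n_after_redundancy`).
#' @export
snapshot_at <- function(family, year, family_id = "family") {
  if (nrow(family) == 0L) stop_invalid("empty family")
  keep <- !is.na(family$year) & family$year <= year
  members <- family[keep, , drop = FALSE]
  rownames(members) <- NULL
  structure(list(family_id = family_id, cutoff_year = as.integer(year),
                 members = members,
                 n_total_hits = nrow(members),
                 n_after_redundancy = nrow(members),
                 redundancy_filtered = FALSE),
            class = "family_snapshot")
}

#' @export
print.family_snapshot <- function(x, ...) {
  cat(sprintf("family_snapshot %s @ %d: %d sequences (of %d hits)%s\n",
              x$family_id, x$cutoff_year, x$n_after_redundancy, x$n_total_hits,
              if (x$redundancy_filtered) ", redundancy-filtered" else ""))
  invisible(x)
}

#' Pairwise sequence identity over an alignment
#'
#' Fraction of identical residue pairs over the columns in which at least one
#' of the two sequences has a residue: double-gap columns are excluded from
#' the denominator and a gap against a residue counts as a mismatch. Returns
#' 0 when no column qualifies.
#'
#' @param a,b aligned residue strings (or character vectors) of equal length.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(a, "", fixed = TRUE)[[1]] else a
  bv <- if (length(b) == 1L) strsplit(b, "", fixed = TRUE)[[1]] else b
  if (length(av) != length(bv)) stop_invalid("aligned sequences differ in length")
  informative <- av != GAP | bv != GAP
  if (!any(informative)) return(0)
  sum(av == bv & av != GAP & informative) / sum(informative)
}

# all-pairs identity matrix on a character msa matrix; used by several modules
identity_matrix <- function(msa) {
  msa <- as_msa(msa)
  n <- nrow(msa)
  D <- matrix(1, n, n, dimnames = list(rownames(msa), rownames(msa)))
  if (n < 2L) return(D)
  gap <- msa == GAP
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      informative <- !(gap[i, ] & gap[j, ])
      denom <- sum(informative)
      D[i, j] <- D[j, i] <- if (denom == 0L) 0 else
        sum(msa[i, ] == msa[j, ] & !gap[i, ] & informative) / denom
    }
  }
  D
}

#' Greedy redundancy removal
#'
#' Sweeps the snapshot in input order and keeps a sequence iff its identity
#' to every previously kept sequence is at or below the threshold; the first
#' sequence is always kept. All retained pairs therefore satisfy the
#' threshold, and the operation is idempotent.
#'
#' @param snapshot a [snapshot_at()] result (or a bare family data frame).
#' @param identity_threshold identity above which a sequence is dropped.
#' @return the filtered `family_snapshot` with updated provenance.
#' @export
remove_redundancy <- function(snapshot, identity_threshold = 0.95) {
  if (identity_threshold <= 0 || identity_threshold >= 1)
    stop_invalid("identity_threshold must be in (0,1)")
  if (is.data.frame(snapshot)) {
    snapshot <- structure(list(family_id = "family", cutoff_year = NA_integer_,
                               members = snapshot, n_total_hits = nrow(snapshot),
                               n_after_redundancy = nrow(snapshot),
                               redundancy_filtered = FALSE),
                          class = "family_snapshot")
  }
  m <- snapshot$members
  if (nrow(m) <= 1L) {
    snapshot$redundancy_filtered <- TRUE
    return(snapshot)
  }
  chars <- as_msa(m)
  kept <- 1L
  for (i in 2L:nrow(m)) {
    ident <- vapply(kept, function(k) pairwise_identity(chars[k, ], chars[i, ]), 0)
    if (all(ident <= identity_threshold)) kept <- c(kept, i)
  }
  snapshot$members <- m[kept, , drop = FALSE]
  rownames(snapshot$members) <- NULL
  snapshot$n_after_redundancy <- length(kept)
  snapshot$redundancy_filtered <- TRUE
  snapshot
}

#' Is a snapshot large enough to analyse?
#'
#' @param snapshot a `family_snapshot`.
#' @param min_sequences minimum number of (post-redundancy) sequences.
#' @return `TRUE` iff the snapshot holds at least `min_sequences` members.
#' @export
workable <- function(snapshot, min_sequences = 15L) {
  snapshot$n_after_redundancy >= min_sequences
}

#' Per-year count of workable families
#'
#' For every year of the configuration, counts the families whose
#' redundancy-filtered snapshot passes [workable()].
#'
#' @param families named list of family data frames.
#' @param config a [benchmark_config()].
#' @return data frame with columns `year`, `n_workable`.
#' @export
coverage_series <- function(families, config = benchmark_config()) {
  counts <- vapply(config$years, function(y) {
    sum(vapply(families, function(fam) {
      if (nrow(fam) == 0L) return(FALSE)
      snap <- remove_redundancy(snapshot_at(fam, y), config$redundancy_identity)
      workable(snap, config$min_sequences)
    }, logical(1)))
  }, integer(1))
  data.frame(year = config$years, n_workable = counts)
}

#' Per-year fraction of sequences surviving redundancy removal
#'
#' The ratio of post- to pre-redundancy snapshot sizes per year; years whose
#' snapshot is empty are reported as `NA`.
#'
#' @param family a family data frame.
#' @param config a [benchmark_config()].
#' @return data frame with columns `year`, `n_total`, `n_kept`, `fraction`.
#' @export
redundancy_series <- function(family, config = benchmark_config()) {
  rows <- lapply(config$years, function(y) {
    snap <- snapshot_at(family, y)
    if (snap$n_total_hits == 0L)
      return(data.frame(year = y, n_total = 0L, n_kept = 0L, fraction = NA_real_))
    filt <- remove_redundancy(snap, config$redundancy_identity)
    data.frame(year = y, n_total = snap$n_total_hits,
               n_kept = filt$n_after_redundancy,
               fraction = filt$n_after_redundancy / snap$n_total_hits)
  })
  do.call(rbind, rows)
}
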