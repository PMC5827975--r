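# Structural evaluation (relative distance to binding sites) and the
# temporal aggregation of the whole benchmark.

#' Distance from a residue to the binding sites
#'
#' Minimum Euclidean distance from the residue's representative point to any
#' binding residue's point (0 for binding residues themselves).
#'
#' @param residue_index 1-based residue index into the structure.
#' @param structure a `structure_model`.
#' @return distance in Angstrom.
#' @export
residue_site_distance <- function(residue_index, structure) {
  if (!any(structure$binding)) stop_invalid("structure has no binding residues")
  p <- structure$coords[residue_index, , drop = FALSE]
  b <- structure$coords[structure$binding, , drop = FALSE]
  min(sqrt(rowSums(sweep(b, 2, as.numeric(p))^2)))
}

all_site_distances <- function(structure) {
  if (!any(structure$binding)) stop_invalid("structure has no binding residues")
  b <- structure$coords[structure$binding, , drop = FALSE]
  apply(structure$coords, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
}

#' Relative distance of a predicted residue set to the binding sites
#'
#' Mean site distance of the residues mapped from the selected columns,
#' divided by the mean site distance of all mapped residues. Values below 1
#' indicate that the prediction lies closer to the binding sites than
#' expected by chance; an empty mapped selection yields `NA` (recorded, not
#' an error).
#'
#' @param selected_cols 1-based alignment column indices.
#' @param structure a `structure_model` with a `column_map`.
#' @return positive ratio, or `NA` if nothing maps.
#' @export
relative_distance <- function(selected_cols, structure) {
  map <- structure$column_map
  mapped_all <- map[!is.na(map)]
  if (!length(mapped_all)) return(NA_real_)
  d <- all_site_distances(structure)
  sel <- selected_cols[selected_cols >= 1 & selected_cols <= length(map)]
  mapped_sel <- map[sel]
  mapped_sel <- mapped_sel[!is.na(mapped_sel)]
  if (!length(mapped_sel)) return(NA_real_)
  mean(d[mapped_sel]) / mean(d[mapped_all])
}

#' Relative temporal series
#'
#' Divides a per-year series by its value at the reference year. Missing
#' values propagate; a zero or missing reference makes the whole series
#' missing.
#'
#' @param values named numeric vector (names = years).
#' @param reference_year year present in `values`.
#' @return named numeric vector of ratios (reference entry 1 where defined).
#' @export
relative_series <- function(values, reference_year) {
  ref <- values[as.character(reference_year)]
  if (length(ref) != 1L || is.na(ref))
    stop_invalid("reference year not present in series")
  if (ref == 0) return(stats::setNames(rep(NA_real_, length(values)), names(values)))
  values / as.numeric(ref)
}

#' Five-number summary
#'
#' Minimum, lower quartile, median, upper quartile and maximum (quartiles by
#' linear interpolation, the convention of [stats::quantile()] type 7), plus
#' the number of non-missing values. Empty input yields all-`NA` with n = 0.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return named vector `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
summarize_distribution <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) {
    return(c(min = NA_real_, q1 = NA_real_, median = NA_real_,
             q3 = NA_real_, max = NA_real_, n = 0))
  }
  q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5], n = length(v))
}

score_snapshot_msa <- function(msa, config) {
  tl <- build_tree(msa)
  s3 <- s3det_like(msa, config)
  list(
    conservation = conserved_positions(msa, config$max_gap_frac_conserved),
    xdet = xdet_scores(msa, rho_min = config$xdet_rho_min,
                       max_gap_frac = config$max_gap_frac),
    et = et_scores(msa, tl, config$et_score_max, config$max_gap_frac),
    teao = teao_scores(msa, tl, config$teao_score_max, config$max_gap_frac),
    s3det = s3$scores,
    partition = s3$partition
  )
}

#' Run the full temporal benchmark
#'
#' For every family and every configured year: build the historical snapshot
#' (publication-date filter), remove redundancy, gate on the minimum
#' alignment size, apply the five detectors, and score each method's
#' selected columns by their relative distance to the binding sites of the
#' family's structure. Deterministic given the configuration seed.
#'
#' @param dataset an `sdp_dataset` from [simulate_benchmark_data()], or any
#'   list with named `families` and `structures` components.
#' @param config a [benchmark_config()].
#' @return an object of class `sdp_benchmark`: `records` (one row per
#'   family x year x method, with provenance counts, selection sizes, SDP
#'   counts and relative distances), `subfamilies` (detected cluster counts
#'   per family x year), `coverage`, `redundancy`, and the `config`.
#' @export
run_benchmark <- function(dataset, config = benchmark_config()) {
  families <- dataset$families
  structures <- dataset$structures
  stopifnot(length(families) >= 1L)
  methods <- c("conservation", "xdet", "et", "teao", "s3det")
  recs <- list(); subf <- list()
  for (fid in names(families)) {
    fam <- families[[fid]]
    fam <- fam[order(fam$year, fam$seq_id), , drop = FALSE]
    st <- structures[[fid]]
    for (y in config$years) {
      snap <- snapshot_at(fam, y, family_id = fid)
      n_total <- snap$n_total_hits
      snap <- remove_redundancy(snap, config$redundancy_identity)
      ok <- workable(snap, config$min_sequences)
      if (!ok) {
        recs[[length(recs) + 1L]] <- data.frame(
          family_id = fid, cutoff_year = y, method = methods,
          n_total = n_total, n_kept = snap$n_after_redundancy, workable = FALSE,
          n_selected = NA_integer_, n_sdp = NA_integer_,
          relative_distance = NA_real_, stringsAsFactors = FALSE)
        next
      }
      msa <- as_msa(snap$members)
      sc <- score_snapshot_msa(msa, config)
      for (meth in methods) {
        tab <- sc[[meth]]
        sel <- selected_columns(tab)
        sdp <- selected_columns(tab, sdp_only = TRUE)
        if (meth == "conservation") sdp <- integer()
        rd <- if (is.null(st)) NA_real_ else relative_distance(sel, st)
        recs[[length(recs) + 1L]] <- data.frame(
          family_id = fid, cutoff_year = y, method = meth,
          n_total = n_total, n_kept = snap$n_after_redundancy, workable = TRUE,
          n_selected = length(sel), n_sdp = length(sdp),
          relative_distance = rd, stringsAsFactors = FALSE)
      }
      subf[[length(subf) + 1L]] <- data.frame(
        family_id = fid, cutoff_year = y,
        n_subfamilies = subfamily_count(sc$partition),
        silhouette = sc$partition$silhouette, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    records = do.call(rbind, recs),
    subfamilies = if (length(subf)) do.call(rbind, subf) else NULL,
    coverage = coverage_series(families, config),
    redundancy = do.call(rbind, lapply(names(families), function(fid) {
      cbind(family_id = fid, redundancy_series(families[[fid]], config))
    })),
    config = config
  ), class = "sdp_benchmark")
}

#' @export
print.sdp_benchmark <- function(x, ...) {
  r <- x$records
  cat(sprintf("sdp_benchmark: %d families, years %d-%d, %d records\n",
              length(unique(r$family_id)), min(r$cutoff_year),
              max(r$cutoff_year), nrow(r)))
  cov <- x$coverage
  cat(sprintf("workable families: %d @ %d -> %d @ %d\n",
              cov$n_workable[1], cov$year[1],
              cov$n_workable[nrow(cov)], cov$year[nrow(cov)]))
  invisible(x)
}

#' Summarize a benchmark into per-year temporal series
#'
#' Produces the figure-style aggregates: per-year five-number summaries of
#' the relative (to the reference year) sequence counts, selection counts,
#' detected subfamily numbers, and of the relative distances to binding
#' sites, per method.
#'
#' @param object an `sdp_benchmark`.
#' @param ... unused.
#' @return list of data frames: `counts_rel`, `sdp_counts_rel`,
#'   `subfamilies_rel`, `sequences_rel`, `distance`.
#' @export
summary.sdp_benchmark <- function(object, ...) {
  r <- object$records
  ref_year <- object$config$reference_year
  per_family_rel <- function(df, col) {
    out <- lapply(split(df, df$family_id), function(d) {
      v <- stats::setNames(d[[col]], d$cutoff_year)
      ref <- v[as.character(ref_year)]
      if (length(ref) != 1L || is.na(ref) || ref == 0) return(NULL)
      data.frame(family_id = d$family_id[1], cutoff_year = d$cutoff_year,
                 rel = as.numeric(v) / as.numeric(ref))
    })
    do.call(rbind, out)
  }
  summarize_by_year <- function(df, col) {
    if (is.null(df) || !nrow(df)) return(NULL)
    out <- lapply(split(df, df$cutoff_year), function(d) {
      s <- summarize_distribution(d[[col]])
      data.frame(cutoff_year = d$cutoff_year[1], t(s))
    })
    do.call(rbind, out)
  }
  by_method <- function(col, relative = TRUE) {
    res <- lapply(split(r, r$method), function(d) {
      if (relative) {
        rel <- per_family_rel(d, col)
        s <- summarize_by_year(rel, "rel")
      } else {
        s <- summarize_by_year(d, col)
      }
      if (is.null(s)) return(NULL)
      cbind(method = d$method[1], s)
    })
    do.call(rbind, res)
  }
  seqs <- r[r$method == "conservation", ]
  list(
    sequences_rel = summarize_by_year(per_family_rel(seqs, "n_total"), "rel"),
    counts_rel = by_method("n_selected"),
    sdp_counts_rel = by_method("n_sdp"),
    subfamilies_rel = if (is.null(object$subfamilies)) NULL else
      summarize_by_year(per_family_rel(object$subfamilies, "n_subfamilies"), "rel"),
    distance = by_method("relative_distance", relative = FALSE)
  )
}
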