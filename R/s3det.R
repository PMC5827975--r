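# S3det-like subfamily and SDP detection: correspondence analysis of the
# binary sequence x (column, residue) indicator table, k-means clustering of
# the sequence coordinates, and SDP scoring against the detected partition.

#' Correspondence analysis of an alignment's indicator table
#'
#' Codes the alignment as a binary sequence x (column, residue) indicator
#' table (gap is not a category; columns with a single residue class or more
#' than `max_gap_frac` gaps are left out) and performs correspondence
#' analysis via the singular value decomposition of the standardized-residual
#' matrix. Axes whose inertia (squared singular value) exceeds the mean
#' inertia are retained, at least one.
#'
#' @param msa alignment.
#' @param max_gap_frac gap cap for a column to enter the coding.
#' @return list with `row_coords` (principal coordinates of the sequences on
#'   the retained axes), `singular_values` (all), `axes_kept`.
#' @export
msa_correspondence <- function(msa, max_gap_frac = 0.5) {
  m <- code_msa(msa)
  n <- nrow(m)
  blocks <- lapply(seq_len(ncol(m)), function(p) {
    col <- m[, p]
    if (mean(col == GAP_CODE) > max_gap_frac) return(NULL)
    res <- sort(unique(col[col != GAP_CODE]))
    if (length(res) < 2L) return(NULL)
    ind <- outer(col, res, "==") + 0
    colnames(ind) <- paste0("c", p, "_", AA20[res])
    ind
  })
  X <- do.call(cbind, blocks)
  if (is.null(X) || ncol(X) < 2L)
    stop_invalid("alignment has no informative columns for correspondence analysis")
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  d <- sv$d
  nz <- d > max(d) * 1e-9
  keep <- which(d^2 > mean(d[nz]^2))
  if (!length(keep)) keep <- 1L
  F <- sweep(sv$u[, keep, drop = FALSE] %*% diag(d[keep], length(keep)),
             1, sqrt(r), "/")
  rownames(F) <- rownames(m)
  list(row_coords = F, singular_values = d, axes_kept = keep)
}

#' S3det-like subfamily detection and SDP scores
#'
#' Clusters the sequence coordinates from [msa_correspondence()] with
#' k-means (10 restarts, candidate counts 2..min(10, N-1)), picking the count
#' with the highest mean silhouette width (ties toward fewer clusters; a
#' single cluster is reported when the best silhouette is below 0.25). Each
#' column is then scored by the adjusted Rand index between the partition its
#' residues induce on the sequences (gapped sequences excluded) and the
#' majority-residue coarsening of the detected clusters, i.e. how well the
#' column's conservation pattern respects the detected subfamily structure at
#' its own granularity. Degenerate columns (a single residue class, or gap
#' fraction above the cap) are unscorable.
#'
#' @param msa alignment.
#' @param config a [benchmark_config()] (supplies the selection threshold,
#'   the gap cap and the k-means seed).
#' @return list with `partition` (named cluster vector + `n_clusters` +
#'   `silhouette`) and `scores` (a `score_table`, `method = "s3det"`).
#' @export
s3det_like <- function(msa, config = benchmark_config()) {
  m <- code_msa(msa)
  n <- nrow(m)
  ca <- msa_correspondence(m, max_gap_frac = config$max_gap_frac)
  F <- ca$row_coords
  kmax <- min(10L, n - 1L)
  best <- list(k = 1L, sil = -Inf, cl = stats::setNames(rep(1L, n), rownames(m)))
  if (kmax >= 2L) {
    dF <- stats::dist(F)
    with_seed(config$seed, {
      for (k in 2:kmax) {
        km <- stats::kmeans(F, k, nstart = 10)
        sil <- mean(cluster::silhouette(km$cluster, dF)[, 3])
        if (sil > best$sil + 1e-9) {  # strict improvement: ties keep fewer
          best <- list(k = k, sil = sil,
                       cl = stats::setNames(km$cluster, rownames(m)))
        }
      }
    })
    if (best$sil < 0.25)
      best <- list(k = 1L, sil = best$sil,
                   cl = stats::setNames(rep(1L, n), rownames(m)))
  }
  cl <- best$cl

  score <- vapply(seq_len(ncol(m)), function(p) {
    col <- m[, p]
    if (mean(col == GAP_CODE) > config$max_gap_frac) return(NA_real_)
    ok <- col != GAP_CODE
    res <- col[ok]
    if (length(unique(res)) < 2L) return(NA_real_)
    if (best$k < 2L) return(NA_real_)
    clv <- cl[ok]
    # majority residue of each detected cluster reconstructs the coarsest
    # cluster-respecting version of the column's partition
    maj <- vapply(split(res, clv), function(v)
      as.integer(names(which.max(table(v)))), 0L)
    recon <- maj[as.character(clv)]
    mclust::adjustedRandIndex(res, recon)
  }, 0)
  sel <- !is.na(score) & score >= config$s3det_ari_min
  list(partition = list(cluster_of = cl, n_clusters = best$k,
                        silhouette = best$sil),
       scores = new_score_table("s3det", score, sel, config$s3det_ari_min, ">="))
}

#' Number of detected subfamilies
#'
#' @param partition the `partition` component of [s3det_like()] (or any list
#'   with a `cluster_of` vector).
#' @return number of distinct cluster labels.
#' @export
subfamily_count <- function(partition) {
  length(unique(partition$cluster_of))
}
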