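# Xdet-like detection: a position is a candidate SDP when the matrix of
# residue similarities within the column mirrors the matrix of overall
# sequence similarities, measured by Spearman rank correlation.

default_substitution_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
}

#' Overall sequence-similarity matrix
#'
#' Entry (i, j) is the mean substitution-matrix score of the residue pairs of
#' sequences i and j over the columns in which both have a residue; columns
#' with a gap in either sequence are excluded. `NA` when no column qualifies.
#'
#' @param msa alignment with at least 2 sequences.
#' @param substitution_matrix 20x20 scoring matrix (default BLOSUM62).
#' @return symmetric N x N matrix (diagonal is the self score, ignored
#'   downstream).
#' @export
sequence_similarity_matrix <- function(msa, substitution_matrix = NULL) {
  if (is.null(substitution_matrix)) substitution_matrix <- default_substitution_matrix()
  m <- code_msa(msa)
  n <- nrow(m)
  if (n < 2L) stop_invalid("need at least 2 sequences")
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      both <- m[i, ] != GAP_CODE & m[j, ] != GAP_CODE
      S[i, j] <- S[j, i] <- if (!any(both)) NA_real_ else
        mean(substitution_matrix[cbind(m[i, both], m[j, both])])
    }
  }
  S
}

#' Positional similarity matrix for one column
#'
#' Entry (i, j) is the substitution score of the residues of sequences i and
#' j at the column; pairs involving a gap are `NA` and are excluded from the
#' downstream correlation.
#'
#' @param msa alignment.
#' @param column 1-based column index.
#' @param substitution_matrix 20x20 scoring matrix (default BLOSUM62).
#' @return symmetric N x N matrix with `NA` for gapped pairs.
#' @export
position_similarity_matrix <- function(msa, column, substitution_matrix = NULL) {
  if (is.null(substitution_matrix)) substitution_matrix <- default_substitution_matrix()
  m <- code_msa(msa)
  if (column < 1L || column > ncol(m)) stop_invalid("invalid column index")
  col <- m[, column]
  n <- length(col)
  P <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  ok <- col != GAP_CODE
  if (any(ok)) {
    sub <- substitution_matrix[col[ok], col[ok], drop = FALSE]
    P[ok, ok] <- sub
  }
  P
}

#' Xdet-like SDP scores
#'
#' For every column, the Spearman rank correlation (average-rank tie
#' handling) between the upper-triangle entries of the positional similarity
#' matrix and those of the overall sequence-similarity matrix, over pairs
#' where both are defined. Columns whose positional vector is constant, has
#' fewer than 3 defined pairs, or exceeds the gap cap are unscorable (`NA`)
#' and never selected.
#'
#' @param msa alignment with at least 3 sequences.
#' @param substitution_matrix 20x20 scoring matrix (default BLOSUM62).
#' @param rho_min selection threshold (selected iff score >= `rho_min`).
#' @param max_gap_frac columns with a larger gap fraction are unscorable.
#' @return a `score_table` with `method = "xdet"`.
#' @export
xdet_scores <- function(msa, substitution_matrix = NULL, rho_min = 0.8,
                        max_gap_frac = 0.5) {
  if (is.null(substitution_matrix)) substitution_matrix <- default_substitution_matrix()
  m <- code_msa(msa)
  if (nrow(m) < 3L) stop_invalid("need at least 3 sequences")
  S <- sequence_similarity_matrix(m, substitution_matrix)
  ut <- upper.tri(S)
  y <- S[ut]
  gapfrac <- colMeans(m == GAP_CODE)
  score <- vapply(seq_len(ncol(m)), function(p) {
    if (gapfrac[p] > max_gap_frac) return(NA_real_)
    col <- m[, p]
    ok <- col != GAP_CODE
    P <- matrix(NA_real_, nrow(m), nrow(m))
    if (any(ok)) P[ok, ok] <- substitution_matrix[col[ok], col[ok], drop = FALSE]
    x <- P[ut]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < 3L) return(NA_real_)
    if (length(unique(x[use])) < 2L || length(unique(y[use])) < 2L) return(NA_real_)
    stats::cor(x[use], y[use], method = "spearman")
  }, 0)
  sel <- !is.na(score) & score >= rho_min
  new_score_table("xdet", score, sel, rho_min, ">=")
}
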