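#' TEA-O-like two-entropies score
#'
#' Locates every column in the plane of global entropy versus average
#' within-group entropy across tree levels, and scores it by its distance to
#' the ideal SDP corner. Concretely, with H_global the 21-symbol column
#' entropy normalized by log2(21), and H_within the mean over levels
#' 2..N of the mean normalized within-group entropy at that level, the score
#' is the Euclidean distance from (H_global, H_within) to (1, 0) scaled by
#' 1/sqrt(2) into `[0, 1]`. An ideal SDP (maximal global diversity, zero
#' within-group diversity at every cut) scores 0; a fully conserved column
#' scores 1/sqrt(2).
#'
#' @param msa alignment.
#' @param tl a `tree_levels` object (built with [build_tree()] if missing).
#' @param score_max selection threshold: selected iff score <= `score_max`.
#' @param max_gap_frac columns with a larger gap fraction are unscorable.
#' @return a `score_table` with `method = "teao"`.
#' @export
teao_scores <- function(msa, tl = NULL, score_max = 0.3, max_gap_frac = 0.5) {
  m <- code_msa(msa)
  if (is.null(tl)) tl <- build_tree(msa)
  if (!setequal(colnames(tl$membership), rownames(m)))
    stop_invalid("tree is not over exactly the alignment's sequences")
  mem <- tl$membership[, rownames(m), drop = FALSE]
  n <- nrow(m); P <- ncol(m)
  hmax <- log2(21)
  h_global <- apply(m, 2, entropy_bits) / hmax

  col_entropies_of_rows <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    counts <- matrix(tabulate(sub + 21L * (col(sub) - 1L), nbins = 21L * P),
                     nrow = 21L)
    pr <- counts / length(rows)
    colSums(ifelse(pr > 0, -pr * log2(pr), 0))
  }

  levels_used <- 2:nrow(mem)
  h_within_sum <- numeric(P)
  for (l in levels_used) {
    groups <- split(seq_len(n), mem[l, ])
    lev <- rowMeans(matrix(vapply(groups, col_entropies_of_rows, numeric(P)),
                           nrow = P))
    h_within_sum <- h_within_sum + lev / hmax
  }
  h_within <- h_within_sum / length(levels_used)

  score <- sqrt((1 - h_global)^2 + h_within^2) / sqrt(2)
  gapfrac <- colMeans(m == GAP_CODE)
  score[gapfrac > max_gap_frac] <- NA_real_
  sel <- !is.na(score) & score <= score_max
  new_score_table("teao", score, sel, score_max, "<=")
}
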