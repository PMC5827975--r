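#' Evolutionary-Trace-like integer ranks
#'
#' The score of a column is the smallest tree-cut level at which the column
#' is invariant (a single non-gap residue type, gaps ignored, all-gap groups
#' vacuously invariant) within every group of that level. Rank 1 is exactly
#' full conservation; a column never invariant up to the leaf level receives
#' N + 1. Columns above the gap cap are unscorable.
#'
#' @param msa alignment.
#' @param tl a `tree_levels` object over exactly the alignment's sequences
#'   (built with [build_tree()] if missing).
#' @param score_max selection threshold: selected iff score <= `score_max`.
#' @param max_gap_frac columns with a larger gap fraction are unscorable.
#' @return a `score_table` with `method = "et"` and integer scores.
#' @export
et_scores <- function(msa, tl = NULL, score_max = 2.0, max_gap_frac = 0.5) {
  m <- code_msa(msa)
  if (is.null(tl)) tl <- build_tree(msa)
  if (!setequal(colnames(tl$membership), rownames(m)))
    stop_invalid("tree is not over exactly the alignment's sequences")
  mem <- tl$membership[, rownames(m), drop = FALSE]
  n <- nrow(m); P <- ncol(m)
  gapfrac <- colMeans(m == GAP_CODE)
  score <- rep.int(NA_integer_, P)
  unresolved <- which(gapfrac <= max_gap_frac)
  for (l in seq_len(nrow(mem))) {
    if (!length(unresolved)) break
    g <- mem[l, ]
    ok <- rep(TRUE, length(unresolved))
    for (grp in split(seq_len(n), g)) {
      sub <- m[grp, unresolved, drop = FALSE]
      # distinct non-gap residues per column within this group
      ndistinct <- apply(sub, 2, function(col) length(unique(col[col != GAP_CODE])))
      ok <- ok & ndistinct <= 1L
      if (!any(ok)) break
    }
    score[unresolved[ok]] <- l
    unresolved <- unresolved[!ok]
  }
  score[unresolved] <- n + 1L
  score[gapfrac > max_gap_frac] <- NA_integer_
  sel <- !is.na(score) & score <= score_max
  new_score_table("et", score, sel, score_max, "<=")
}
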