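#' Shannon entropy of an alignment column
#'
#' Base-2 Shannon entropy over the symbol frequencies of a column, with the
#' gap character treated as a 21st symbol. Zero iff the column carries a
#' single symbol.
#'
#' @param column character vector of residues (one per sequence) or a
#'   single string.
#' @return entropy in bits.
#' @export
column_entropy <- function(column) {
  if (length(column) == 1L && nchar(column) > 1L)
    column <- strsplit(column, "", fixed = TRUE)[[1]]
  if (length(column) == 0L) stop_invalid("empty column")
  codes <- match(column, AA21)
  if (anyNA(codes)) stop_invalid("illegal residue character in column")
  entropy_bits(codes)
}

# constructor for the per-method score container
new_score_table <- function(method, score, selected, threshold, direction) {
  df <- data.frame(column = seq_along(score), score = score,
                   selected = selected)
  attr(df, "method") <- method
  attr(df, "threshold") <- threshold
  attr(df, "direction") <- direction
  class(df) <- c("score_table", "data.frame")
  df
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table [%s]: %d columns, %d selected (threshold %s %s)\n",
              attr(x, "method"), nrow(x), sum(x$selected, na.rm = TRUE),
              attr(x, "direction"), format(attr(x, "threshold"))))
  nsc <- sum(is.na(x$score))
  if (nsc) cat(sprintf("  %d unscorable column(s)\n", nsc))
  invisible(x)
}

#' Selected columns of a score table
#'
#' @param x a `score_table`.
#' @param sdp_only for the ET-like method, drop fully conserved columns
#'   (integer rank 1), which the root-level cut renders and which are not
#'   SDPs; ignored for the other methods.
#' @return integer vector of selected column indices (1-based).
#' @export
selected_columns <- function(x, sdp_only = FALSE) {
  sel <- which(!is.na(x$selected) & x$selected)
  if (sdp_only && identical(attr(x, "method"), "et"))
    sel <- sel[x$score[sel] > 1]
  sel
}

#' Fully conserved positions
#'
#' A column is selected iff its non-gap residues are a single type and its
#' gap fraction does not exceed `max_gap_frac` (a column of one residue plus
#' many gaps is not fully conserved). The reported score is the 21-symbol
#' column entropy in bits.
#'
#' @param msa alignment (character matrix, named string vector, or family
#'   data frame).
#' @param max_gap_frac gap-fraction cap for selection.
#' @return a `score_table` with `method = "conservation"`.
#' @export
conserved_positions <- function(msa, max_gap_frac = 0.1) {
  m <- code_msa(msa)
  score <- apply(m, 2, entropy_bits)
  one_residue <- apply(m, 2, function(col) {
    res <- col[col != GAP_CODE]
    length(res) > 0L && length(unique(res)) == 1L
  })
  gapfrac <- colMeans(m == GAP_CODE)
  sel <- one_residue & gapfrac <= max_gap_frac
  new_score_table("conservation", score, sel, 0.0, "==")
}
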