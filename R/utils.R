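# Internal helpers shared across modules.

# The 20 standard amino acids, in Biostrings/BLOSUM order, plus the gap symbol.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP <- "-"
AA21 <- c(AA20, GAP)
GAP_CODE <- 21L

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Coerce an alignment into the canonical internal form: a character matrix,
# one row per sequence (rownames = sequence ids), one column per position.
# Accepts a matrix, a named character vector of aligned strings, or a
# data frame with seq_id/residues columns (the timed-family layout).
as_msa <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("seq%03d", seq_len(nrow(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("seq_id", "residues") %in% names(x)))
    v <- stats::setNames(as.character(x$residues), as.character(x$seq_id))
    return(as_msa(v))
  }
  if (is.character(x)) {
    if (length(x) == 0L) stop_invalid("empty alignment")
    n <- nchar(x)
    if (length(unique(n)) != 1L) stop_invalid("ragged alignment: unequal sequence lengths")
    m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                nrow = length(x), byrow = TRUE)
    rownames(m) <- if (is.null(names(x))) sprintf("seq%03d", seq_along(x)) else names(x)
    return(m)
  }
  stop_invalid("cannot interpret object of class ", class(x)[1], " as an alignment")
}

# Integer coding 1..20 for residues, 21 for gap. Unknown characters error.
# Already-coded integer matrices pass through.
code_msa <- function(msa) {
  if (is.matrix(msa) && is.integer(msa)) return(msa)
  msa <- as_msa(msa)
  codes <- match(msa, AA21)
  if (anyNA(codes)) {
    bad <- unique(msa[is.na(codes)])
    stop_invalid("illegal residue character(s): ", paste(bad, collapse = " "))
  }
  m <- matrix(as.integer(codes), nrow = nrow(msa), dimnames = dimnames(msa))
  m
}

msa_strings <- function(msa) {
  msa <- as_msa(msa)
  stats::setNames(apply(msa, 1, paste, collapse = ""), rownames(msa))
}

# Shannon entropy (bits) of an integer code vector over nbins symbols.
entropy_bits <- function(codes, nbins = 21L) {
  tb <- tabulate(codes, nbins = nbins)
  p <- tb[tb > 0] / length(codes)
  -sum(p * log2(p))
}

gap_fraction <- function(col_codes) mean(col_codes == GAP_CODE)
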