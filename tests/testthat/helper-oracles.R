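# Independent oracles and small fixture builders used across the suite.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA, AA]
})

# --- brute-force Spearman with average-rank ties -------------------------
avg_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

spearman_oracle <- function(x, y) {
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# independent Xdet computation: similarity matrices by naive loops, then
# the brute-force Spearman above
xdet_oracle <- function(chars) {
  n <- nrow(chars); P <- ncol(chars)
  seqsim <- matrix(NA_real_, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    both <- chars[i, ] != "-" & chars[j, ] != "-"
    if (any(both))
      seqsim[i, j] <- mean(blosum62[cbind(chars[i, both], chars[j, both])])
  }
  ut <- upper.tri(seqsim)
  y <- seqsim[ut]
  vapply(seq_len(P), function(p) {
    if (mean(chars[, p] == "-") > 0.5) return(NA_real_)
    pm <- matrix(NA_real_, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (chars[i, p] != "-" && chars[j, p] != "-")
        pm[i, j] <- blosum62[chars[i, p], chars[j, p]]
    }
    x <- pm[ut]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < 3) return(NA_real_)
    if (length(unique(x[use])) < 2 || length(unique(y[use])) < 2) return(NA_real_)
    spearman_oracle(x[use], y[use])
  }, 0)
}

# --- brute-force ET via pairwise MRCA-kept equivalence -------------------
# At level l the l-1 shallowest internal nodes are cut; two leaves share a
# group iff their MRCA is still uncut. Scores columns by the first level at
# which every group carries a single non-gap residue type.
et_oracle <- function(chars, tree) {
  ntip <- length(tree$tip.label)
  depth <- as.numeric(ape::dist.nodes(tree)[ntip + 1, ])
  internal <- (ntip + 1):(ntip + tree$Nnode)
  cut_order <- internal[order(depth[internal])]
  mrca <- matrix(0L, ntip, ntip)
  for (i in 1:(ntip - 1)) for (j in (i + 1):ntip)
    mrca[i, j] <- mrca[j, i] <- ape::getMRCA(tree, c(i, j))
  idx <- match(tree$tip.label, rownames(chars))
  vapply(seq_len(ncol(chars)), function(p) {
    col <- chars[idx, p]
    for (l in 1:ntip) {
      cut <- cut_order[seq_len(l - 1)]
      grp <- integer(ntip); gid <- 0L
      for (i in seq_len(ntip)) {
        if (grp[i] > 0L) next
        gid <- gid + 1L
        grp[i] <- gid
        if (i < ntip) {
          for (j in (i + 1):ntip) {
            if (grp[j] == 0L && !(mrca[i, j] %in% cut)) grp[j] <- gid
          }
        }
      }
      ok <- all(vapply(split(col, grp), function(v) {
        v <- v[v != "-"]
        length(unique(v)) <= 1
      }, TRUE))
      if (ok) return(l)
    }
    ntip + 1L
  }, 0L)
}

# --- naive TEA-O reimplementation ----------------------------------------
teao_oracle <- function(chars, tl) {
  idx <- colnames(tl$membership)
  n <- nrow(chars)
  ent <- function(v) {
    tb <- table(v) / length(v)
    -sum(tb * log2(tb))
  }
  hmax <- log2(21)
  vapply(seq_len(ncol(chars)), function(p) {
    if (mean(chars[, p] == "-") > 0.5) return(NA_real_)
    hg <- ent(chars[, p]) / hmax
    hw_levels <- vapply(2:n, function(l) {
      groups <- split(idx, tl$membership[l, ])
      mean(vapply(groups, function(g) ent(chars[g, p]) / hmax, 0))
    }, 0)
    sqrt((1 - hg)^2 + mean(hw_levels)^2) / sqrt(2)
  }, 0)
}

# --- fixture builders -----------------------------------------------------
random_msa <- function(n, p, gap_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(AA, n * p, replace = TRUE), n, p)
  if (gap_frac > 0) m[runif(n * p) < gap_frac] <- "-"
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# a family generated under the package's default study conditions
study_family <- function(seed, n_subfamilies = 4, seqs_per_subfamily = 8,
                         n_columns = 200, n_conserved = 10, n_sdp = 10,
                         sdp_residue_groups = "deepest-split") {
  tree <- simulate_tree(n_subfamilies, seqs_per_subfamily, 0.25, 6.0)
  profile <- site_class_profile(
    n_columns, conserved_cols = seq_len(n_conserved),
    sdp_cols = n_conserved + seq_len(n_sdp),
    sdp_residue_groups = sdp_residue_groups,
    substitution_rate = 1.0)
  ev <- evolve_family(tree, profile, seed = seed)
  ev$msa <- sdpbench:::as_msa(ev$family)
  ev$conserved_cols <- profile$conserved_cols
  ev$sdp_cols <- profile$sdp_cols
  ev$neutral_cols <- profile$neutral_cols
  ev
}

recall_precision <- function(selected, truth_cols, all_cols) {
  tp <- length(intersect(selected, truth_cols))
  list(recall = tp / length(truth_cols),
       precision = if (length(selected)) tp / length(selected) else NA_real_)
}
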