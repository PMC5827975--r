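#' Site-class profile for a simulated family
#'
#' Describes how the columns of a simulated alignment are partitioned into the
#' three site classes that the benchmark scores: fully conserved positions,
#' specificity-determining positions (SDPs), and neutrally evolving positions.
#'
#' Two SDP flavours are supported. In `"one-residue-per-subfamily"` mode every
#' subfamily is internally invariant and at least two distinct residues occur
#' across subfamilies; how residues are distributed over subfamilies is
#' controlled by `sdp_residue_groups`: with `"deepest-split"` (default) the
#' residue changes at the deepest divergence of the subfamily tree, so the two
#' basal lineages carry different residues (the classic pattern of functional
#' specificity arising at an ancient duplication); with `"per-subfamily"` every
#' subfamily receives its own residue. In `"conserved-in-one-subfamily"` mode
#' one designated subfamily is invariant and all other sequences draw residues
#' uniformly.
#'
#' @param n_columns total number of alignment columns.
#' @param conserved_cols,sdp_cols integer column indices (1-based, disjoint);
#'   all remaining columns are neutral.
#' @param sdp_mode one of `"one-residue-per-subfamily"`,
#'   `"conserved-in-one-subfamily"`; recycled over `sdp_cols`.
#' @param sdp_residue_groups `"deepest-split"` or `"per-subfamily"` (see
#'   Details); only used in `"one-residue-per-subfamily"` mode.
#' @param substitution_rate expected substitutions per site per unit branch
#'   length for neutral columns (uniform replacement model).
#' @param gap_col_fraction per-column fraction of sequences gapped in neutral
#'   columns (0 disables gap injection).
#' @return an object of class `site_class_profile`.
#' @export
site_class_profile <- function(n_columns,
                               conserved_cols = integer(),
                               sdp_cols = integer(),
                               sdp_mode = "one-residue-per-subfamily",
                               sdp_residue_groups = c("deepest-split", "per-subfamily"),
                               substitution_rate = 1.0,
                               gap_col_fraction = 0) {
  n_columns <- as.integer(n_columns)
  conserved_cols <- as.integer(conserved_cols)
  sdp_cols <- as.integer(sdp_cols)
  sdp_residue_groups <- match.arg(sdp_residue_groups)
  if (n_columns < 1L) stop_invalid("n_columns must be positive")
  if (substitution_rate < 0) stop_invalid("substitution_rate must be >= 0")
  if (gap_col_fraction < 0 || gap_col_fraction >= 1)
    stop_invalid("gap_col_fraction must be in [0, 1)")
  all_idx <- c(conserved_cols, sdp_cols)
  if (anyDuplicated(all_idx)) stop_invalid("conserved_cols and sdp_cols must be disjoint")
  if (length(all_idx) > n_columns)
    stop_invalid("more planted classes than columns")
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > n_columns))
    stop_invalid("planted column indices out of range")
  sdp_mode <- rep_len(sdp_mode, length(sdp_cols))
  ok <- sdp_mode %in% c("one-residue-per-subfamily", "conserved-in-one-subfamily")
  if (!all(ok)) stop_invalid("unknown sdp_mode: ", paste(unique(sdp_mode[!ok]), collapse = ", "))
  structure(list(
    n_columns = n_columns,
    conserved_cols = conserved_cols,
    sdp_cols = sdp_cols,
    sdp_mode = sdp_mode,
    sdp_residue_groups = sdp_residue_groups,
    neutral_cols = setdiff(seq_len(n_columns), all_idx),
    substitution_rate = substitution_rate,
    gap_col_fraction = gap_col_fraction
  ), class = "site_class_profile")
}

#' Accumulation model for publication dates
#'
#' Describes the exponential growth of database content over a timeline:
#' the expected number of sequences published up to year `y` is proportional
#' to `growth_rate^y`, and the cumulative count at `end_year` equals `n_final`.
#'
#' `discovery_bias` controls how strongly early publication favours sequences
#' similar to an anchor sequence (databases grew outward from a handful of
#' well-studied organisms, so early family members cluster phylogenetically).
#' At 0 the year-to-sequence pairing is uniform.
#'
#' @param start_year,end_year inclusive integer timeline bounds.
#' @param growth_rate per-year multiplicative factor, must exceed 1.
#' @param n_final cumulative number of sequences at `end_year`.
#' @param discovery_bias non-negative; strength of the similarity-ordered
#'   pairing of early years to anchor-like sequences.
#' @return an object of class `accumulation_model`.
#' @export
accumulation_model <- function(start_year = 1994L, end_year = 2014L,
                               growth_rate = 1.4, n_final,
                               discovery_bias = 1.5) {
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  if (end_year < start_year) stop_invalid("end_year before start_year")
  if (growth_rate <= 1) stop_invalid("growth_rate must be > 1")
  if (discovery_bias < 0) stop_invalid("discovery_bias must be >= 0")
  structure(list(start_year = start_year, end_year = end_year,
                 growth_rate = growth_rate, n_final = as.integer(n_final),
                 discovery_bias = discovery_bias),
            class = "accumulation_model")
}

#' Simulate a subfamily-structured ultrametric tree
#'
#' Builds a rooted ultrametric tree containing `n_subfamilies` monophyletic
#' clades of `seqs_per_subfamily` leaves each. Subfamilies are modelled as
#' star radiations (every leaf hangs on a pendant branch of length
#' `within_depth` from its clade root); the between-subfamily backbone is a
#' balanced hierarchy of total depth `between_depth` whose non-root splits
#' approach the clades geometrically (the split below a node at depth d sits
#' at `d + split_frac * (between_depth - d)`), so the deepest divergence is at
#' the root. Leaf labels are `SF<k>_<i>` and carry the subfamily assignment.
#'
#' @param n_subfamilies,seqs_per_subfamily counts, both at least 2.
#' @param within_depth pendant branch length inside a subfamily.
#' @param between_depth depth of the between-subfamily backbone.
#' @param seed integer seed (the default topology is deterministic; the seed
#'   is honoured for reproducibility of any future stochastic variants).
#' @param split_frac fraction in (0,1) placing successive backbone splits.
#' @return an [ape::phylo] tree with a `subfamily` attribute (named vector).
#' @export
simulate_tree <- function(n_subfamilies, seqs_per_subfamily,
                          within_depth, between_depth,
                          seed = NULL, split_frac = 0.7) {
  n_subfamilies <- as.integer(n_subfamilies)
  seqs_per_subfamily <- as.integer(seqs_per_subfamily)
  if (n_subfamilies < 2L || seqs_per_subfamily < 2L)
    stop_invalid("counts must be >= 2")
  if (within_depth <= 0 || between_depth <= 0)
    stop_invalid("depths must be > 0")
  if (split_frac <= 0 || split_frac >= 1) stop_invalid("split_frac must be in (0,1)")

  clade_txt <- function(k) {
    tips <- sprintf("SF%d_%02d:%g", k, seq_len(seqs_per_subfamily), within_depth)
    paste0("(", paste(tips, collapse = ","), ")")
  }
  # Recursive balanced bisection of the subfamily set. `subtree(ids, d)` is the
  # Newick string (without trailing branch length) of a split node at depth d;
  # clade roots sit at between_depth, deeper backbone splits approach them
  # geometrically via split_frac.
  subtree <- function(ids, d_node) {
    child <- function(hids) {
      if (length(hids) == 1L) {
        sprintf("%s:%g", clade_txt(hids), between_depth - d_node)
      } else {
        d_child <- d_node + split_frac * (between_depth - d_node)
        sprintf("%s:%g", subtree(hids, d_child), d_child - d_node)
      }
    }
    h <- ceiling(length(ids) / 2)
    sprintf("(%s,%s)", child(ids[seq_len(h)]), child(ids[-seq_len(h)]))
  }
  txt <- paste0(subtree(seq_len(n_subfamilies), 0), ";")
  tree <- ape::read.tree(text = txt)
  sf <- as.integer(sub("^SF(\\d+)_.*$", "\\1", tree$tip.label))
  attr(tree, "subfamily") <- stats::setNames(sf, tree$tip.label)
  tree
}

subfamily_of_tips <- function(tree) {
  sf <- attr(tree, "subfamily")
  if (is.null(sf)) {
    sf <- stats::setNames(as.integer(sub("^SF(\\d+)_.*$", "\\1", tree$tip.label)),
                          tree$tip.label)
  }
  if (anyNA(sf)) stop_invalid("tree leaves must be labelled with their subfamily (SF<k>_<i>)")
  sf[tree$tip.label]
}

# Evolve one neutral column along the tree: Poisson substitution events at
# `rate` per unit branch length; each event replaces the state by a uniform
# draw from the 20 amino acids (so P(child == parent) = exp(-rate*t) plus the
# 1/20 chance of redrawing the same residue).
evolve_neutral_column <- function(tree, rate) {
  ntip <- length(tree$tip.label)
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- sample.int(20L, 1L)
  eo <- stats::reorder(tree, "cladewise")
  keep <- stats::runif(nrow(eo$edge)) < exp(-rate * eo$edge.length)
  for (i in seq_len(nrow(eo$edge))) {
    state[eo$edge[i, 2L]] <-
      if (keep[i]) state[eo$edge[i, 1L]] else sample.int(20L, 1L)
  }
  state[seq_len(ntip)]
}

#' Evolve an aligned family with planted site classes
#'
#' Generates a gapless (unless gap injection is configured), pre-aligned
#' family on the leaves of `tree` according to a [site_class_profile()]:
#' conserved columns carry one residue everywhere, SDP columns follow their
#' configured flavour, and neutral columns evolve under a uniform-replacement
#' substitution process along the tree.
#'
#' @param tree a tree from [simulate_tree()] (leaf labels carry subfamilies).
#' @param profile a [site_class_profile()].
#' @param seed integer seed; the result is reproducible given the seed.
#' @return a list with components `family` (data frame `seq_id`, `residues`,
#'   `year` = NA) and `truth` (list: `subfamily_of`, `site_class_of`,
#'   `sdp_mode_of`, `binding_cols` placeholder).
#' @export
evolve_family <- function(tree, profile, seed = NULL) {
  stopifnot(inherits(profile, "site_class_profile"))
  sf <- subfamily_of_tips(tree)
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    P <- profile$n_columns
    M <- matrix(0L, nrow = ntip, ncol = P, dimnames = list(tree$tip.label, NULL))
    class_of <- rep("neutral", P)
    class_of[profile$conserved_cols] <- "conserved"
    class_of[profile$sdp_cols] <- "sdp"

    # deepest-split bipartition of the subfamilies
    root <- ntip + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    desc_tips <- function(n) {
      if (n <= ntip) return(n)
      out <- n
      repeat {
        nxt <- tree$edge[tree$edge[, 1L] %in% out[out > ntip], 2L]
        new <- setdiff(nxt, out)
        if (!length(new)) break
        out <- c(out, new)
      }
      out[out <= ntip]
    }
    half <- integer(ntip)
    half[desc_tips(kids[1L])] <- 1L
    for (k in kids[-1L]) half[desc_tips(k)] <- 2L

    for (p in profile$conserved_cols) M[, p] <- sample.int(20L, 1L)

    mode_of <- rep(NA_character_, P)
    for (i in seq_along(profile$sdp_cols)) {
      p <- profile$sdp_cols[i]
      mode_of[p] <- profile$sdp_mode[i]
      if (profile$sdp_mode[i] == "one-residue-per-subfamily") {
        if (profile$sdp_residue_groups == "per-subfamily") {
          res <- sample.int(20L, length(unique(sf)))
          M[, p] <- res[match(sf, sort(unique(sf)))]
        } else {
          res <- sample.int(20L, 2L)
          M[, p] <- res[half]
        }
      } else { # conserved-in-one-subfamily
        target <- sample(sort(unique(sf)), 1L)
        r <- sample.int(20L, 1L)
        other <- sample.int(20L, ntip, replace = TRUE)
        M[, p] <- ifelse(sf == target, r, other)
      }
    }

    for (p in profile$neutral_cols)
      M[, p] <- evolve_neutral_column(tree, profile$substitution_rate)

    chars <- matrix(AA20[M], nrow = ntip, dimnames = dimnames(M))
    if (profile$gap_col_fraction > 0) {
      ngap <- round(profile$gap_col_fraction * ntip)
      for (p in profile$neutral_cols) {
        if (ngap > 0) chars[sample.int(ntip, ngap), p] <- GAP
      }
    }
    fam <- data.frame(
      seq_id = tree$tip.label,
      residues = apply(chars, 1, paste, collapse = ""),
      year = NA_integer_,
      stringsAsFactors = FALSE, row.names = NULL
    )
    truth <- list(
      subfamily_of = sf,
      site_class_of = stats::setNames(class_of, seq_len(P)),
      sdp_mode_of = mode_of,
      half_of = stats::setNames(half, tree$tip.label),
      binding_cols = integer()
    )
    list(family = fam, truth = truth)
  })
}

#' Assign publication dates under an accumulation model
#'
#' Draws one publication year per sequence i.i.d. from the geometric year
#' distribution implied by the model (so cumulative counts are approximately
#' geometric in expectation and the count at `end_year` is exactly `n_final`),
#' then pairs the sorted years with sequences ordered by similarity to an
#' anchor sequence (the first one) perturbed by noise, with strength
#' `discovery_bias`. With bias 0 the pairing is uniform. Shuffling the input
#' order changes only which sequence gets which year, never the cumulative
#' count curve.
#'
#' @param family data frame with `seq_id` and `residues` columns.
#' @param model an [accumulation_model()]; `n_final` must not exceed the
#'   number of sequences supplied. If fewer, the `n_final` sequences ranked
#'   earliest are kept and the rest dropped.
#' @param seed integer seed.
#' @return the family data frame with `year` filled in, `n_final` rows.
#' @export
assign_dates <- function(family, model, seed = NULL) {
  stopifnot(inherits(model, "accumulation_model"))
  if (nrow(family) == 0L) stop_invalid("empty family")
  n_final <- model$n_final
  if (is.na(n_final)) n_final <- nrow(family)
  if (n_final > nrow(family))
    stop_invalid("n_final exceeds the number of sequences provided")
  years <- model$start_year:model$end_year
  w <- model$growth_rate^(years - model$start_year)
  with_seed(seed, {
    draw <- sort(sample(years, n_final, replace = TRUE, prob = w / sum(w)))
    msa <- as_msa(family)
    anchor <- msa[1L, ]
    d <- vapply(seq_len(nrow(msa)), function(i) 1 - mean(msa[i, ] == anchor), 0)
    score <- model$discovery_bias * rank(d, ties.method = "first") +
      stats::rnorm(nrow(msa)) * nrow(msa) / 8
    ord <- order(score)
    chosen <- ord[seq_len(n_final)]
    out <- family[chosen, , drop = FALSE]
    out$year <- as.integer(draw)  # earliest years to the most anchor-like sequences
    out <- out[order(out$year, out$seq_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Synthetic structure with a binding pocket
#'
#' Places one representative 3-D point per alignment column: binding columns
#' inside a pocket of radius `pocket_radius` (mutually within the pocket
#' diameter), near columns on a shell within `1.5 * pocket_radius` of the
#' pocket centroid, and all remaining columns along a self-avoiding random
#' walk constrained to stay at least `3 * pocket_radius` from the centroid.
#'
#' @param n_columns number of alignment columns (= residues; identity map).
#' @param binding_cols,near_cols disjoint 1-based column index sets.
#' @param seed integer seed.
#' @param pocket_radius pocket radius in Angstrom.
#' @return an object of class `structure_model`: `coords` (n x 3 matrix),
#'   `binding` (logical), `column_map` (identity), `pocket_radius`.
#' @export
synth_structure <- function(n_columns, binding_cols, near_cols = integer(),
                            seed = NULL, pocket_radius = 5) {
  n_columns <- as.integer(n_columns)
  binding_cols <- as.integer(binding_cols); near_cols <- as.integer(near_cols)
  if (length(intersect(binding_cols, near_cols)))
    stop_invalid("binding_cols and near_cols must be disjoint")
  idx <- c(binding_cols, near_cols)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_columns))
    stop_invalid("column indices out of range")
  if (!length(binding_cols)) stop_invalid("need at least one binding column")
  rp <- pocket_radius
  with_seed(seed, {
    coords <- matrix(NA_real_, n_columns, 3)
    unit_dir <- function(n) {
      v <- matrix(stats::rnorm(3 * n), n, 3)
      v / sqrt(rowSums(v^2))
    }
    # pocket: uniform in a ball of radius rp/2 about the origin
    nb <- length(binding_cols)
    coords[binding_cols, ] <- unit_dir(nb) * (rp / 2 * stats::runif(nb)^(1 / 3))
    if (length(near_cols)) {
      nn <- length(near_cols)
      coords[near_cols, ] <- unit_dir(nn) * stats::runif(nn, rp, 1.5 * rp)
    }
    far <- setdiff(seq_len(n_columns), idx)
    if (length(far)) {
      pos <- c(4 * rp, 0, 0)
      placed <- matrix(NA_real_, length(far), 3)
      for (i in seq_along(far)) {
        repeat {
          cand <- pos + unit_dir(1) * 3.8
          if (sqrt(sum(cand^2)) < 3 * rp) next
          if (i > 1L) {
            d2 <- rowSums(sweep(placed[seq_len(i - 1L), , drop = FALSE], 2, cand)^2)
            if (min(d2) < 1) next
          }
          break
        }
        placed[i, ] <- cand
        pos <- cand
      }
      coords[far, ] <- placed
    }
    binding <- rep(FALSE, n_columns); binding[binding_cols] <- TRUE
    structure(list(coords = coords, binding = binding,
                   column_map = seq_len(n_columns),
                   pocket_radius = rp),
              class = "structure_model")
  })
}

#' Simulate a complete benchmark dataset
#'
#' Bundles [simulate_tree()], [evolve_family()], [assign_dates()] and
#' [synth_structure()] into the study conditions used throughout the package:
#' subfamily-structured families with planted conserved and SDP columns,
#' exponentially accumulating publication dates, optional redundant
#' near-clones, and a synthetic structure in which the binding pocket is made
#' of planted conserved columns and the near shell holds the SDPs plus the
#' remaining conserved columns.
#'
#' @param n_families number of families to generate.
#' @param seed integer seed driving everything.
#' @param n_subfamilies,seqs_per_subfamily,within_depth,between_depth tree
#'   parameters (see [simulate_tree()]).
#' @param n_columns,n_conserved,n_sdp site-class counts.
#' @param substitution_rate neutral substitution rate.
#' @param sdp_residue_groups passed to [site_class_profile()].
#' @param start_year,end_year,growth_rate,discovery_bias date model.
#' @param redundancy_fraction fraction of sequences duplicated as near-clones
#'   (mutated only in neutral columns, dated no earlier than their source) to
#'   emulate database redundancy; 0 disables.
#' @param pocket_radius pocket radius for the synthetic structures.
#' @return an object of class `sdp_dataset`: named lists `families`,
#'   `truth`, `structures`, plus the generating `params`.
#' @export
simulate_benchmark_data <- function(n_families = 5, seed = 1,
                                    n_subfamilies = 4, seqs_per_subfamily = 8,
                                    within_depth = 0.25, between_depth = 6.0,
                                    n_columns = 200, n_conserved = 10, n_sdp = 10,
                                    substitution_rate = 1.0,
                                    sdp_residue_groups = "deepest-split",
                                    start_year = 1994, end_year = 2014,
                                    growth_rate = 1.4, discovery_bias = 1.5,
                                    redundancy_fraction = 0.15,
                                    pocket_radius = 5) {
  fams <- vector("list", n_families)
  truths <- vector("list", n_families)
  structs <- vector("list", n_families)
  ids <- sprintf("fam%02d", seq_len(n_families))
  for (f in seq_len(n_families)) {
    fseed <- seed * 1000L + f
    tree <- simulate_tree(n_subfamilies, seqs_per_subfamily,
                          within_depth, between_depth, seed = fseed)
    cols <- seq_len(n_columns)
    profile <- site_class_profile(
      n_columns,
      conserved_cols = cols[seq_len(n_conserved)],
      sdp_cols = cols[n_conserved + seq_len(n_sdp)],
      sdp_residue_groups = sdp_residue_groups,
      substitution_rate = substitution_rate
    )
    ev <- evolve_family(tree, profile, seed = fseed)
    model <- accumulation_model(start_year, end_year, growth_rate,
                                n_final = nrow(ev$family),
                                discovery_bias = discovery_bias)
    fam <- assign_dates(ev$family, model, seed = fseed)
    if (redundancy_fraction > 0) {
      fam <- with_seed(fseed + 500L, {
        n_clone <- round(redundancy_fraction * nrow(fam))
        if (n_clone > 0) {
          src <- sample.int(nrow(fam), n_clone)
          clones <- fam[src, , drop = FALSE]
          clones$seq_id <- paste0(clones$seq_id, "_r")
          neutral <- profile$neutral_cols
          nmut <- max(1L, round(0.02 * n_columns))
          for (j in seq_len(n_clone)) {
            ch <- strsplit(clones$residues[j], "")[[1]]
            at <- sample(neutral, nmut)
            ch[at] <- sample(AA20, nmut, replace = TRUE)
            clones$residues[j] <- paste(ch, collapse = "")
            clones$year[j] <- as.integer(min(end_year, clones$year[j] + sample.int(3L, 1L)))
          }
          fam <- rbind(fam, clones)
          fam <- fam[order(fam$year, fam$seq_id), , drop = FALSE]
          rownames(fam) <- NULL
        }
        fam
      })
    }
    n_bind <- ceiling(n_conserved / 2)
    binding_cols <- profile$conserved_cols[seq_len(n_bind)]
    near_cols <- c(profile$conserved_cols[-seq_len(n_bind)], profile$sdp_cols)
    st <- synth_structure(n_columns, binding_cols, near_cols,
                          seed = fseed, pocket_radius = pocket_radius)
    ev$truth$binding_cols <- binding_cols
    ev$truth$near_cols <- near_cols
    fams[[f]] <- fam; truths[[f]] <- ev$truth; structs[[f]] <- st
  }
  names(fams) <- names(truths) <- names(structs) <- ids
  structure(list(families = fams, truth = truths, structures = structs,
                 params = as.list(environment())[c(
                   "n_families", "seed", "n_subfamilies", "seqs_per_subfamily",
                   "within_depth", "between_depth", "n_columns", "n_conserved",
                   "n_sdp", "substitution_rate", "sdp_residue_groups",
                   "start_year", "end_year", "growth_rate", "discovery_bias",
                   "redundancy_fraction", "pocket_radius")]),
            class = "sdp_dataset")
}

#' @export
print.sdp_dataset <- function(x, ...) {
  cat(sprintf("sdp_dataset: %d families, %d columns each\n",
              length(x$families), x$params$n_columns))
  cat(sprintf("  %d subfamilies x %d sequences, timeline %d-%d\n",
              x$params$n_subfamilies, x$params$seqs_per_subfamily,
              x$params$start_year, x$params$end_year))
  invisible(x)
}
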