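# Tree construction and root-to-leaf level partitions shared by the ET-like
# and TEA-O-like methods.

#' Build a tree and its cut levels from an alignment
#'
#' Estimates a neighbor-joining tree from the distance `1 - pairwise
#' identity`, midpoint-roots it, and derives the hierarchy of leaf partitions
#' obtained by cutting the tree at its internal nodes in order of increasing
#' distance from the root (ties broken by traversal order, parents first):
#' level 1 is the single group of all leaves, level l splits the shallowest
#' l-1 internal nodes, and the deepest level has one leaf per group.
#'
#' @param msa alignment with at least 3 sequences.
#' @return an object of class `tree_levels`: the rooted [ape::phylo] tree,
#'   the split order, and `membership`, an L x N integer matrix whose row l
#'   assigns every sequence (columns, named) to its level-l group.
#' @export
build_tree <- function(msa) {
  m <- as_msa(msa)
  n <- nrow(m)
  if (n < 3L) stop_invalid("need at least 3 sequences to build a tree")
  D <- 1 - identity_matrix(m)
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0  # NJ can emit tiny negatives
  tr <- phangorn::midpoint(tr)
  tree_levels(tr, seq_ids = rownames(m))
}

#' Level partitions of a rooted tree
#'
#' @param tree a rooted [ape::phylo].
#' @param seq_ids optional ordering of sequence ids for the membership
#'   columns (defaults to the tree's tip labels).
#' @return a `tree_levels` object (see [build_tree()]).
#' @export
tree_levels <- function(tree, seq_ids = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(seq_ids)) seq_ids <- tree$tip.label
  if (!setequal(seq_ids, tree$tip.label))
    stop_invalid("tree tips and sequence ids disagree")
  depth <- ape::node.depth.edgelength(tree)
  eo <- stats::reorder(tree, "cladewise")
  # preorder rank guarantees parents precede children when depths tie
  pre <- integer(ntip + tree$Nnode)
  pre[ntip + 1L] <- 0L
  pre[eo$edge[, 2L]] <- seq_len(nrow(eo$edge))
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  split_order <- internal[order(depth[internal], pre[internal])]

  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- vector("list", ntip + tree$Nnode)
  for (i in rev(seq_len(nrow(eo$edge)))) {
    ch <- eo$edge[i, 2L]
    if (is.null(tips_under[[ch]]) && ch <= ntip) tips_under[[ch]] <- ch
  }
  # accumulate tip sets bottom-up (edges in reverse cladewise order)
  for (i in rev(seq_len(nrow(eo$edge)))) {
    par <- eo$edge[i, 1L]; ch <- eo$edge[i, 2L]
    tips_under[[par]] <- c(tips_under[[par]], tips_under[[ch]])
  }

  L <- ntip
  membership <- matrix(1L, nrow = L, ncol = ntip,
                       dimnames = list(NULL, tree$tip.label))
  grp <- rep(1L, ntip)
  next_id <- 1L
  for (l in 2:L) {
    node <- split_order[l - 1L]
    for (ch in children[[as.character(node)]][-1L]) {
      next_id <- next_id + 1L
      grp[unlist(tips_under[ch])] <- next_id
    }
    membership[l, ] <- grp
  }
  membership <- membership[, seq_ids, drop = FALSE]
  structure(list(tree = tree, split_order = split_order,
                 membership = membership, n_leaves = ntip),
            class = "tree_levels")
}

#' @export
print.tree_levels <- function(x, ...) {
  cat(sprintf("tree_levels: %d leaves, %d cut levels\n",
              x$n_leaves, nrow(x$membership)))
  invisible(x)
}

#' Leaf partition at one level
#'
#' @param tl a `tree_levels` object.
#' @param level level index (1 = all leaves in one group).
#' @return list of character vectors of sequence ids, one per group.
#' @export
level_partition <- function(tl, level) {
  g <- tl$membership[level, ]
  unname(split(colnames(tl$membership), g))
}
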