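# Bipartition machinery shared by the tree-comparison code (RF distances,
# gene concordance factors, bootstrap support mapping, clade recovery).
# A split is stored canonically as the sorted tip set on the side NOT
# containing the anchor label (the lexicographically smallest leaf), pasted
# with "\r"; this makes splits orientation-free and hashable.

# tip sets below each edge, as a list indexed by edge row
edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- i
  # postorder: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(k) tree$tip.label[desc[[tree$edge[k, 2]]]])
}

canonical_split <- function(tips_below, all_tips, anchor = NULL) {
  if (is.null(anchor)) anchor <- min(all_tips)
  side <- if (anchor %in% tips_below) setdiff(all_tips, tips_below) else tips_below
  paste(sort(side), collapse = "\r")
}

#' Non-trivial splits (bipartitions) of an unrooted tree
#'
#' @param tree A `phylo` object (rooted trees are read as unrooted).
#' @return Character vector of canonical split keys, one per internal branch
#'   that separates at least 2 tips from at least 2 tips.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  sets <- edge_tip_sets(tree)
  sz <- lengths(sets)
  keep <- sz >= 2 & sz <= n - 2
  keys <- vapply(sets[keep], canonical_split, character(1), all_tips = tips)
  unique(keys)
}

# split keys for internal edges, in tree$edge row order (NA for trivial),
# on the (possibly rooted) input tree as-is
edge_split_keys <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  sets <- edge_tip_sets(tree)
  sz <- lengths(sets)
  out <- rep(NA_character_, nrow(tree$edge))
  keep <- sz >= 2 & sz <= n - 2
  out[keep] <- vapply(sets[keep], canonical_split, character(1), all_tips = tips)
  out
}

split_from_tips <- function(tips_in_clade, all_tips) {
  canonical_split(tips_in_clade, all_tips)
}
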