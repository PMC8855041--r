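#' Read trees from a Newick file
#'
#' One tree per line. Internal node labels, when numeric, are interpreted as
#' branch support values for the subtending branch (the dominant convention
#' of tree software).
#'
#' @param path Newick file path.
#' @return A list of `phylo` objects (always a list, even for one tree).
#' @export
read_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(t) { class(t) <- "phylo"; t })
}

#' Write trees to a Newick file
#' @param trees A `phylo` or list of `phylo` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(t) ape::write.tree(t, digits = 12), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Harmonize a set of trees to a common pruned, rooted form
#'
#' Drops the given tips from every tree, reroots each tree on the pendant
#' edge of `root_on`, and checks that the resulting leaf sets are identical.
#' Degree-2 nodes created by pruning are suppressed with branch lengths
#' summed (as done by `ape::drop.tip`).
#'
#' @param trees List of `phylo` objects.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @param root_on Outgroup tip label present in every tree.
#' @return List of rooted `phylo` objects sharing one leaf set.
#' @export
harmonize_trees <- function(trees, drop = character(0), root_on) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(root_on) == 1L)
  out <- lapply(trees, function(t) {
    if (!root_on %in% t$tip.label)
      stop("missing outgroup: '", root_on, "' absent from a tree")
    drop_here <- intersect(drop, t$tip.label)
    if (length(drop_here) >= length(t$tip.label) - 2L)
      stop("drop list leaves fewer than 3 tips")
    if (length(drop_here)) t <- ape::drop.tip(t, drop_here)
    t <- ape::root(t, outgroup = root_on, resolve.root = TRUE)
    t
  })
  sets <- lapply(out, function(t) sort(t$tip.label))
  if (length(unique(vapply(sets, paste, character(1), collapse = "\r"))) != 1L)
    stop("harmonized trees do not share a common leaf set; extend 'drop'")
  out
}

#' Build a keyed collection of species trees
#'
#' A `tree_collection` maps (dataset, method) pairs to trees, mirroring the
#' dataset-by-method design of a multi-analysis species-tree comparison.
#'
#' @param trees List of `phylo` objects.
#' @param dataset Character vector of dataset labels (recycled against
#'   `method`).
#' @param method Character vector of method labels.
#' @return A `tree_collection`: a named list of trees with a `key` attribute
#'   (data frame with columns dataset, method).
#' @export
tree_collection <- function(trees, dataset, method) {
  key <- data.frame(dataset = dataset, method = method,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(key) == length(trees))
  nm <- paste(key$dataset, key$method, sep = "_")
  if (anyDuplicated(nm)) stop("duplicate (dataset, method) keys")
  names(trees) <- nm
  structure(trees, class = "tree_collection", key = key)
}

#' @export
print.tree_collection <- function(x, ...) {
  key <- attr(x, "key")
  cat(sprintf("<tree_collection> %d trees: %d dataset(s) x %d method(s)\n",
              length(x), length(unique(key$dataset)),
              length(unique(key$method))))
  invisible(x)
}

#' @export
`[.tree_collection` <- function(x, i, ...) {
  key <- attr(x, "key")
  y <- unclass(x)[i]
  idx <- seq_along(x)
  names(idx) <- names(x)
  structure(y, class = "tree_collection", key = key[idx[names(y)], , drop = FALSE])
}
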