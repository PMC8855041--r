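#' Robinson-Foulds distance between two unrooted trees
#'
#' Size of the symmetric difference between the non-trivial bipartition
#' sets; multifurcating trees simply contribute fewer bipartitions.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets.
#' @param normalized Divide by `2 (n - 3)` (the maximum for binary trees)?
#' @return Count (or fraction when `normalized`).
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ; harmonize the trees first")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) d / (2 * (length(t1$tip.label) - 3)) else d
}

#' Kendall-Colijn vector of a rooted tree
#'
#' For each unordered tip pair (in lexicographic label order) the entry is
#' `(1 - lambda) * m + lambda * l`, where `m` counts edges from the root to
#' the pair's most recent common ancestor and `l` is the branch-length sum
#' on that path; the vector ends with one entry per tip,
#' `(1 - lambda) * 1 + lambda * pendant_length`. `lambda = 0` captures pure
#' topology, `lambda = 1` pure branch lengths.
#'
#' @param t Rooted `phylo`.
#' @param lambda Mixing parameter in `[0, 1]`.
#' @return Numeric vector of length `choose(n, 2) + n`.
#' @export
kc_vector <- function(t, lambda = 0) {
  if (!ape::is.rooted(t)) stop("Kendall-Colijn requires a rooted tree")
  stopifnot(lambda >= 0, lambda <= 1)
  ord <- order(t$tip.label)
  tips <- seq_along(t$tip.label)[ord]
  n <- length(tips)
  ntot <- n + t$Nnode
  root <- n + 1L
  # edge-count and length depth of every node from the root
  dE <- rep(0, ntot); dL <- rep(0, ntot)
  eo <- ape::reorder.phylo(t, "postorder")
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    dE[ch] <- dE[p] + 1
    dL[ch] <- dL[p] + if (lambda > 0) eo$edge.length[k] else 0
  }
  M <- ape::mrca(t)
  pair <- utils::combn(n, 2)
  i <- tips[pair[1, ]]; j <- tips[pair[2, ]]
  a <- M[cbind(i, j)]
  pair_part <- (1 - lambda) * dE[a] + lambda * dL[a]
  pend_len <- if (lambda > 0) {
    pe <- match(tips, t$edge[, 2])
    t$edge.length[pe]
  } else rep(0, n)
  tip_part <- (1 - lambda) * 1 + lambda * pend_len
  c(pair_part, tip_part)
}

#' Kendall-Colijn distance between two rooted trees
#'
#' Euclidean norm of the difference of the two [kc_vector]s (same
#' lexicographic pair ordering).
#'
#' @param t1,t2 Rooted `phylo` objects with identical leaf sets.
#' @param lambda Mixing parameter in `[0, 1]`.
#' @return Nonnegative real.
#' @export
kc_distance <- function(t1, t2, lambda = 0) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ; harmonize the trees first")
  sqrt(sum((kc_vector(t1, lambda) - kc_vector(t2, lambda))^2))
}

#' Pairwise tree distance matrix
#'
#' @param trees A [tree_collection] or list of `phylo` with a shared leaf
#'   set.
#' @param metric `"RF"` (unrooted) or `"KC"` (rooted).
#' @param lambda KC mixing parameter.
#' @return Symmetric matrix of class `tree_dist` with a `"metric"`
#'   attribute.
#' @export
tree_distance_matrix <- function(trees, metric = c("RF", "KC"), lambda = 0) {
  metric <- match.arg(metric)
  n <- length(trees)
  D <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  if (metric == "KC") {
    vs <- lapply(trees, kc_vector, lambda = lambda)
    # order must match across trees: kc_vector sorts by label already
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sqrt(sum((vs[[i]] - vs[[j]])^2))
  } else {
    ss <- lapply(trees, tree_splits)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- length(setdiff(ss[[i]], ss[[j]])) +
        length(setdiff(ss[[j]], ss[[i]]))
  }
  structure(D, class = c("tree_dist", "matrix"),
            metric = metric, lambda = if (metric == "KC") lambda else NA)
}

#' Principal coordinate analysis of a tree distance matrix
#'
#' Classical scaling: double-centre `-D^2 / 2`, eigendecompose, and keep up
#' to `k` axes with positive eigenvalues (coordinates are eigenvectors
#' scaled by the square root of their eigenvalue). Negative eigenvalues are
#' dropped and reported.
#'
#' @param D A [tree_distance_matrix] result (or any symmetric distance
#'   matrix).
#' @param k Number of axes requested.
#' @return An `ordination`: list with `coords` (trees x axes), `eig`
#'   (positive eigenvalues kept), `var_explained`, `n_negative`.
#' @export
pcoa <- function(D, k = 3) {
  stopifnot(k >= 1)
  n <- nrow(D)
  cs <- stats::cmdscale(stats::as.dist(D), k = min(k, n - 1), eig = TRUE)
  pos <- cs$eig[cs$eig > 1e-10]
  kk <- min(k, length(pos))
  if (kk < k)
    warning("only ", kk, " positive-eigenvalue axes available")
  if (kk == 0) {
    # degenerate configuration (all distances zero): everything at origin
    coords <- matrix(0, n, min(k, n - 1),
                     dimnames = list(rownames(D), NULL))
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
    return(structure(list(coords = coords, eig = numeric(0),
                          var_explained = numeric(0),
                          n_negative = sum(cs$eig < -1e-10),
                          metric = attr(D, "metric")),
                     class = "ordination"))
  }
  coords <- cs$points[, seq_len(kk), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(kk))
  structure(list(coords = coords, eig = pos[seq_len(kk)],
                 var_explained = pos[seq_len(kk)] / sum(pos),
                 n_negative = sum(cs$eig < -1e-10),
                 metric = attr(D, "metric")),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d trees, %d axes (%s); var explained: %s\n",
              nrow(x$coords), ncol(x$coords),
              if (is.null(x$metric)) "?" else x$metric,
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' Detect groves (clusters of similar topologies) in an ordination
#'
#' Ward-linkage hierarchical clustering on the leading principal-coordinate
#' axes, cut into `k_groups` groups.
#'
#' @param ord An [pcoa] ordination.
#' @param n_axes Number of leading axes used (capped at those available).
#' @param k_groups Number of groves.
#' @return Integer vector of grove labels named by tree.
#' @export
find_groves <- function(ord, n_axes = 3, k_groups = 2) {
  stopifnot(k_groups >= 1)
  X <- ord$coords[, seq_len(min(n_axes, ncol(ord$coords))), drop = FALSE]
  if (k_groups > nrow(X)) stop("k_groups exceeds the number of trees")
  if (k_groups == nrow(X)) {
    out <- seq_len(nrow(X)); names(out) <- rownames(X); return(out)
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  stats::cutree(hc, k = k_groups)
}

#' Scatter plot of a tree-landscape ordination
#'
#' @param ord An [pcoa] ordination.
#' @param axes Length-2 integer vector of axes to draw.
#' @param groves Optional grove labels for colouring.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, the plotted coordinates.
#' @export
plot_landscape <- function(ord, axes = c(1, 2), groves = NULL, ...) {
  X <- ord$coords
  stopifnot(max(axes) <= ncol(X))
  col <- if (is.null(groves)) "black" else as.integer(groves) + 1L
  graphics::plot(X[, axes[1]], X[, axes[2]], col = col, pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1],
                                100 * ord$var_explained[axes[1]]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2],
                                100 * ord$var_explained[axes[2]]), ...)
  graphics::text(X[, axes[1]], X[, axes[2]], labels = rownames(X),
                 pos = 3, cex = 0.6)
  invisible(X[, axes])
}
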