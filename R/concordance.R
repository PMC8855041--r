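#' Gene concordance factor per branch
#'
#' For each internal branch of the reference tree with bipartition `A | B`,
#' a gene tree is decisive when its leaf set intersects both sides in at
#' least two taxa, and concordant when it contains the bipartition
#' restricted to its own leaves. `gCF = 100 * concordant / decisive`
#' (`NA` when no gene tree is decisive).
#'
#' @param reference `phylo` (treated as unrooted).
#' @param gene_trees Non-empty list of `phylo`.
#' @return Data frame of class `branch_concordance`: one row per internal
#'   branch with columns `split` (canonical key), `clade_size`,
#'   `decisive`, `concordant`, `gcf`.
#' @export
gcf <- function(reference, gene_trees) {
  if (length(gene_trees) == 0) stop("no gene trees")
  ref <- ape::unroot(reference)
  taxa <- ref$tip.label
  keys <- edge_split_keys(ref)
  rows <- which(!is.na(keys))
  # pre-extract gene-tree split sets and leaf sets
  g_leaves <- lapply(gene_trees, `[[`, "tip.label")
  g_splits <- lapply(gene_trees, tree_splits)
  out <- data.frame(split = keys[rows],
                    clade_size = NA_integer_,
                    decisive = 0L, concordant = 0L, gcf = NA_real_)
  sets <- edge_tip_sets(ref)
  for (r in seq_along(rows)) {
    k <- rows[r]
    A <- sets[[k]]
    B <- setdiff(taxa, A)
    out$clade_size[r] <- min(length(A), length(B))
    dec <- 0L; conc <- 0L
    for (gi in seq_along(gene_trees)) {
      L <- g_leaves[[gi]]
      A2 <- intersect(A, L); B2 <- intersect(B, L)
      if (length(A2) < 2 || length(B2) < 2) next
      dec <- dec + 1L
      # gene leaves = A2 U B2, so the restricted bipartition is present iff
      # some gene split side equals A2 (or B2) exactly
      if (gene_has_split(g_splits[[gi]], L, A2, B2))
        conc <- conc + 1L
    }
    out$decisive[r] <- dec
    out$concordant[r] <- conc
    out$gcf[r] <- if (dec > 0) 100 * conc / dec else NA_real_
  }
  class(out) <- c("branch_concordance", "data.frame")
  out
}

# does a gene tree (split keys over leaf set L) contain a split that,
# restricted to A2 U B2, equals A2 | B2?
gene_has_split <- function(gkeys, L, A2, B2) {
  for (key in gkeys) {
    side <- strsplit(key, "\r", fixed = TRUE)[[1]]
    a_in <- A2 %in% side
    b_in <- B2 %in% side
    if ((all(a_in) && !any(b_in)) || (!any(a_in) && all(b_in)))
      return(TRUE)
  }
  FALSE
}

#' Site concordance factor per branch
#'
#' For each internal branch, quartets are sampled by drawing one taxon
#' uniformly from each of the four subtrees adjacent to the branch. For a
#' quartet `{a, a' | b, b'}` a site is decisive when all four taxa carry a
#' called base and the pattern supports exactly one of the three pairings
#' (two equal states on one side differing from two equal states on the
#' other); the quartet's concordance is the fraction of its decisive sites
#' supporting the branch's own pairing. `sCF` is 100 times the mean over
#' sampled quartets with at least one decisive site. When fewer than `q`
#' distinct quartets exist around a branch, all are used exhaustively.
#' Under pure noise each pairing is equally likely, so sCF has a floor
#' near 33%.
#'
#' @param reference `phylo` (treated as unrooted; must be resolved at
#'   scored branches).
#' @param supermatrix [locus_aln] containing all reference leaves.
#' @param q Quartets sampled per branch.
#' @param seed Optional seed (recorded in the output attributes).
#' @return Data frame of class `branch_concordance` with columns `split`,
#'   `quartets`, `decisive_sites` (mean per quartet), `scf`.
#' @export
scf <- function(reference, supermatrix, q = 100L, seed = NULL) {
  stopifnot(q >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- ape::unroot(reference)
  taxa <- ref$tip.label
  if (!all(taxa %in% rownames(supermatrix)))
    stop("reference leaves missing from supermatrix")
  m <- unclass(supermatrix)[taxa, , drop = FALSE]
  called <- is_called(m)
  keys <- edge_split_keys(ref)
  rows <- which(!is.na(keys))
  groups <- branch_adjacent_groups(ref)
  out <- data.frame(split = keys[rows], quartets = 0L,
                    decisive_sites = NA_real_, scf = NA_real_)
  for (r in seq_along(rows)) {
    k <- rows[r]
    gr <- groups[[k]]
    if (is.null(gr) || any(lengths(gr) == 0)) next
    n_distinct <- prod(lengths(gr))
    qq <- min(q, n_distinct)
    if (n_distinct <= q) {
      combs <- expand.grid(gr[[1]], gr[[2]], gr[[3]], gr[[4]],
                           stringsAsFactors = FALSE)
      quarts <- as.matrix(combs)
    } else {
      quarts <- cbind(sample(gr[[1]], qq, replace = TRUE),
                      sample(gr[[2]], qq, replace = TRUE),
                      sample(gr[[3]], qq, replace = TRUE),
                      sample(gr[[4]], qq, replace = TRUE))
    }
    cf <- numeric(0); dsites <- numeric(0)
    for (i in seq_len(nrow(quarts))) {
      a <- m[quarts[i, 1], ]; a2 <- m[quarts[i, 2], ]
      b <- m[quarts[i, 3], ]; b2 <- m[quarts[i, 4], ]
      ok <- called[quarts[i, 1], ] & called[quarts[i, 2], ] &
        called[quarts[i, 3], ] & called[quarts[i, 4], ]
      s1 <- ok & a == a2 & b == b2 & a != b      # branch's own pairing
      s2 <- ok & a == b & a2 == b2 & a != a2
      s3 <- ok & a == b2 & a2 == b & a != a2
      dec <- (s1 & !s2 & !s3) | (s2 & !s1 & !s3) | (s3 & !s1 & !s2)
      nd <- sum(dec)
      if (nd > 0) {
        cf <- c(cf, sum(s1 & dec) / nd)
        dsites <- c(dsites, nd)
      }
    }
    out$quartets[r] <- nrow(quarts)
    if (length(cf)) {
      out$scf[r] <- 100 * mean(cf)
      out$decisive_sites[r] <- mean(dsites)
    }
  }
  class(out) <- c("branch_concordance", "data.frame")
  attr(out, "q") <- q
  attr(out, "seed") <- seed
  out
}

# for each edge of an unrooted tree: the four tip groups adjacent to it
# (two per endpoint); NULL for pendant edges or unresolved endpoints with
# fewer than two other neighbours
branch_adjacent_groups <- function(tr) {
  ntip <- length(tr$tip.label)
  sets <- edge_tip_sets(tr)
  taxa <- tr$tip.label
  kids_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  parent_edge <- match(seq_len(ntip + tr$Nnode), tr$edge[, 2])
  out <- vector("list", nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2]
    if (ch <= ntip) next
    # child side: subtrees hanging from ch (other than edge k)
    ch_edges <- kids_of[[as.character(ch)]]
    below <- lapply(ch_edges, function(e) sets[[e]])
    # parent side: sibling subtrees at the parent plus the rest of the tree
    p <- tr$edge[k, 1]
    sib_edges <- setdiff(kids_of[[as.character(p)]], k)
    above <- lapply(sib_edges, function(e) sets[[e]])
    rest <- setdiff(taxa, unique(c(unlist(below), unlist(above))))
    if (length(rest)) above <- c(above, list(rest))
    if (length(below) < 2 || length(above) < 2) {
      # unresolved endpoint: merge smallest groups so four remain
      next
    }
    # with more than two groups on a side, merge extras into the two largest
    below <- two_groups(below)
    above <- two_groups(above)
    out[[k]] <- list(below[[1]], below[[2]], above[[1]], above[[2]])
  }
  out
}

two_groups <- function(gr) {
  if (length(gr) == 2) return(gr)
  ord <- order(lengths(gr), decreasing = TRUE)
  g1 <- gr[[ord[1]]]
  g2 <- unlist(gr[ord[-1]])
  list(g1, g2)
}

#' Classify a support or concordance value into low/moderate/high bands
#'
#' Bands follow common reporting practice: gene concordance factors are
#' low below 30, high at 80 or above; posterior probabilities are low
#' below 0.75, high at 0.9 or above; bootstrap percentages are low below
#' 75, high at 90 or above.
#'
#' @param value Numeric value (vectorised).
#' @param kind `"gcf"`, `"support_pp"`, or `"support_bs"`.
#' @return Character vector: `"low"`, `"moderate"`, `"high"`.
#' @export
classify_scores <- function(value, kind = c("gcf", "support_pp", "support_bs")) {
  kind <- match.arg(kind)
  rng <- switch(kind, gcf = c(0, 100), support_pp = c(0, 1),
                support_bs = c(0, 100))
  if (any(value < rng[1] | value > rng[2], na.rm = TRUE))
    stop("value out of range for kind '", kind, "'")
  cuts <- switch(kind, gcf = c(30, 80), support_pp = c(0.75, 0.9),
                 support_bs = c(75, 90))
  ifelse(value < cuts[1], "low",
         ifelse(value < cuts[2], "moderate", "high"))
}

#' Convert a gene concordance factor to a concordant gene-tree count
#'
#' The count of single-locus trees behind a reported gCF percentage:
#' `round(gcf_pct / 100 * n_trees)`.
#'
#' @param gcf_pct gCF in percent.
#' @param n_trees Number of decisive gene trees.
#' @return Integer count.
#' @export
cf_concordant_count <- function(gcf_pct, n_trees) {
  as.integer(round(gcf_pct / 100 * n_trees))
}

#' Clade recovery across a tree collection
#'
#' A clade is recovered in a tree when its tips present in that tree form a
#' clade (a bipartition side on the unrooted tree, or the full side of a
#' pendant-adjacent split). `NA` is returned when fewer than two clade tips
#' are present, or when the clade is absent only because the relevant node
#' is unresolved: the clade's split is compatible with every split the tree
#' does contain (a polytomy could hide it). `not_recovered` means the tree
#' actively conflicts with the clade.
#'
#' @param trees A [tree_collection] or list of `phylo`.
#' @param clades Named list of tip-label character vectors (>= 2 tips each).
#' @return Character matrix (clade x tree) over
#'   `{"recovered", "not_recovered", NA}`.
#' @export
clade_recovery <- function(trees, clades) {
  stopifnot(all(lengths(clades) >= 2), !is.null(names(clades)))
  out <- matrix(NA_character_, length(clades), length(trees),
                dimnames = list(names(clades), names(trees)))
  for (j in seq_along(trees)) {
    tr <- trees[[j]]
    taxa <- tr$tip.label
    splits <- tree_splits(tr)
    for (i in seq_along(clades)) {
      tips <- clades[[i]]
      unknown <- setdiff(tips, taxa)
      if (length(unknown) == length(tips)) next
      present <- intersect(tips, taxa)
      if (length(present) < 2) next
      if (length(present) > length(taxa) - 2) {
        out[i, j] <- "recovered"  # trivially a clade on an unrooted tree
        next
      }
      key <- canonical_split(present, taxa)
      if (key %in% splits) {
        out[i, j] <- "recovered"
      } else {
        conflict <- any(!vapply(splits, function(s) {
          side <- strsplit(s, "\r", fixed = TRUE)[[1]]
          splits_compatible(present, side, taxa)
        }, logical(1)))
        out[i, j] <- if (conflict) "not_recovered" else NA_character_
      }
    }
  }
  out
}

# two splits (as tip sets over the same taxa) are compatible iff one of
# the four pairwise intersections of sides is empty
splits_compatible <- function(A, B, taxa) {
  ia <- taxa %in% A; ib <- taxa %in% B
  !any(ia & ib) || !any(ia & !ib) || !any(!ia & ib) || !any(!ia & !ib)
}

#' Long-format concordance-factor table across a tree collection
#'
#' One row per clade and tree: gene and site concordance factors at the
#' clade's branch (when recovered), plus the recovery status — the
#' machinery behind per-dataset CF heatmaps.
#'
#' @param trees A [tree_collection].
#' @param clades Named list of tip-label vectors.
#' @param gene_trees_by_dataset Named list (dataset -> list of gene trees).
#' @param supermatrix_by_dataset Named list (dataset -> [locus_aln]).
#' @param q Quartets per branch for sCF.
#' @param seed Optional seed for sCF sampling.
#' @return Data frame: clade, dataset, method, recovery, gcf, scf.
#' @export
cf_heatmap_table <- function(trees, clades, gene_trees_by_dataset,
                             supermatrix_by_dataset, q = 100L, seed = NULL) {
  key <- attr(trees, "key")
  rec <- clade_recovery(trees, clades)
  rows <- list()
  for (j in seq_along(trees)) {
    tr <- trees[[j]]
    ds <- key$dataset[j]
    gt <- gene_trees_by_dataset[[ds]]
    sm <- supermatrix_by_dataset[[ds]]
    g_tab <- if (!is.null(gt)) gcf(tr, gt) else NULL
    s_tab <- if (!is.null(sm)) scf(tr, sm, q = q, seed = seed) else NULL
    taxa <- ape::unroot(tr)$tip.label
    for (i in seq_along(clades)) {
      status <- rec[i, j]
      gv <- NA_real_; sv <- NA_real_
      if (identical(status, "recovered")) {
        present <- intersect(clades[[i]], taxa)
        if (length(present) >= 2 && length(present) <= length(taxa) - 2) {
          keyspl <- canonical_split(present, taxa)
          if (!is.null(g_tab)) {
            hit <- match(keyspl, g_tab$split)
            if (!is.na(hit)) gv <- g_tab$gcf[hit]
          }
          if (!is.null(s_tab)) {
            hit <- match(keyspl, s_tab$split)
            if (!is.na(hit)) sv <- s_tab$scf[hit]
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        clade = names(clades)[i], dataset = ds, method = key$method[j],
        recovery = status, gcf = gv, scf = sv)
    }
  }
  do.call(rbind, rows)
}

#' Read clade definitions from CSV
#'
#' Expected columns: `clade` (name) and `tips` (comma-separated labels).
#'
#' @param path CSV file path.
#' @return Named list of tip-label vectors.
#' @export
read_clades <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("clade", "tips") %in% names(df)))
  out <- lapply(df$tips, function(s) trimws(strsplit(s, ",")[[1]]))
  names(out) <- df$clade
  if (anyDuplicated(names(out))) stop("duplicate clade names")
  out
}

#' Plot a concordance-factor heatmap
#'
#' Renders the long table from [cf_heatmap_table] for one dataset as a
#' clade-by-method heatmap (requires the pheatmap package).
#'
#' @param tab Output of [cf_heatmap_table].
#' @param dataset Dataset label to plot.
#' @param what `"gcf"` or `"scf"`.
#' @param ... Passed to [pheatmap::pheatmap].
#' @return The pheatmap object, invisibly.
#' @export
plot_cf_heatmap <- function(tab, dataset, what = c("gcf", "scf"), ...) {
  what <- match.arg(what)
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for heatmap rendering")
  sub <- tab[tab$dataset == dataset, ]
  M <- tapply(sub[[what]], list(sub$clade, sub$method), mean)
  ph <- pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                           main = paste(dataset, toupper(what)), ...)
  invisible(ph)
}
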