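# Quartet machinery. The induced topology of a quartet {a,b,c,d} in a tree
# follows from the four-point condition on topological (edge-count) path
# distances: the pairing with the strictly smallest sum of within-pair
# distances is the induced split; ties (multifurcations) are unresolved.

# topological distance matrix between tips, ordered by `taxa`
tip_path_counts <- function(tree, taxa) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- ape::dist.nodes(t2)[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D[taxa, taxa]
}

# all C(n,4) quartets over 1..n as an index matrix (columns a<b<c<d)
quartet_index <- function(n) {
  t(utils::combn(n, 4))
}

# codes: 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved
quartet_codes <- function(tree, taxa, qi = quartet_index(length(taxa))) {
  D <- tip_path_counts(tree, taxa)
  d_ab <- D[cbind(qi[, 1], qi[, 2])] + D[cbind(qi[, 3], qi[, 4])]
  d_ac <- D[cbind(qi[, 1], qi[, 3])] + D[cbind(qi[, 2], qi[, 4])]
  d_ad <- D[cbind(qi[, 1], qi[, 4])] + D[cbind(qi[, 2], qi[, 3])]
  M <- cbind(d_ab, d_ac, d_ad)
  mn <- pmin(d_ab, d_ac, d_ad)
  n_min <- (d_ab == mn) + (d_ac == mn) + (d_ad == mn)
  code <- max.col(-M, ties.method = "first")
  code[n_min != 1L] <- 0L
  code
}

#' Quartet score of a species tree against gene trees
#'
#' The number of (gene tree, 4-leaf subset) combinations whose induced
#' quartet topology in the gene tree is resolved and matches the species
#' tree. This is the objective maximised by quartet-based coalescent
#' species-tree methods; it is statistically consistent under the
#' multispecies coalescent.
#'
#' @param species_tree `phylo` whose leaf set contains every gene-tree leaf.
#' @param gene_trees List of `phylo` objects.
#' @return Integer score.
#' @export
quartet_score <- function(species_tree, gene_trees) {
  taxa <- sort(species_tree$tip.label)
  qi <- quartet_index(length(taxa))
  sp_codes <- quartet_codes(species_tree, taxa, qi)
  score <- 0L
  for (g in gene_trees) {
    gt_taxa <- g$tip.label
    if (all(taxa %in% gt_taxa)) {
      gc <- quartet_codes(g, taxa, qi)
      score <- score + sum(gc != 0L & gc == sp_codes)
    } else {
      keep <- which(apply(matrix(taxa[qi] %in% gt_taxa, nrow(qi)), 1, all))
      if (!length(keep)) next
      sub <- sort(intersect(taxa, gt_taxa))
      qi_sub <- quartet_index(length(sub))
      gc <- quartet_codes(g, sub, qi_sub)
      # align sub-quartets with full quartets
      key_sub <- apply(matrix(sub[qi_sub], nrow(qi_sub)), 1, paste, collapse = "\r")
      key_full <- apply(matrix(taxa[qi], nrow(qi)), 1, paste, collapse = "\r")
      gc_full <- gc[match(key_full[keep], key_sub)]
      score <- score + sum(gc_full != 0L & gc_full == sp_codes[keep],
                           na.rm = TRUE)
    }
  }
  score
}

# quartet-code matrix (quartets x genes) for a fixed taxon order
gene_code_matrix <- function(gene_trees, taxa, qi) {
  key_full <- NULL
  out <- vapply(gene_trees, function(g) {
    if (all(taxa %in% g$tip.label)) quartet_codes(g, taxa, qi)
    else {
      out <- rep(NA_integer_, nrow(qi))
      sub <- sort(intersect(taxa, g$tip.label))
      if (length(sub) >= 4) {
        qi_sub <- quartet_index(length(sub))
        gc <- quartet_codes(g, sub, qi_sub)
        key_sub <- apply(matrix(sub[qi_sub], nrow(qi_sub)), 1, paste,
                         collapse = "\r")
        if (is.null(key_full))
          key_full <<- apply(matrix(taxa[qi], nrow(qi)), 1, paste,
                             collapse = "\r")
        out <- gc[match(key_full, key_sub)]
      }
      out
    }
  }, integer(nrow(qi)))
  matrix(out, nrow = nrow(qi))
}

score_against_codes <- function(tree, taxa, qi, gcodes) {
  sp <- quartet_codes(tree, taxa, qi)
  sum(gcodes == sp & gcodes != 0L, na.rm = TRUE)
}

#' Species tree by quartet-score maximisation (coalescent estimator)
#'
#' Exact mode enumerates all unrooted binary topologies (feasible up to 8
#' taxa) and returns the quartet-score argmax, breaking ties by the
#' lexicographically smallest Newick string. Heuristic mode starts from a
#' neighbor-joining tree on average topological gene-tree distances and
#' hill-climbs over nearest-neighbor interchanges to a local optimum.
#' Internal branches are annotated with normalised quartet support: the
#' share of the dominant resolution among the three, over resolved
#' gene-tree quartets that span the branch (stored in `node.label` as
#' percentages; this is not ASTRAL's local posterior probability).
#'
#' @param gene_trees List of `phylo` (>= 2).
#' @param mode `"auto"` (exact up to 8 taxa), `"exact"`, or `"heuristic"`.
#' @return Unrooted `phylo` with `node.label` support annotation and
#'   attributes `"quartet_score"` and `"mode"`.
#' @export
msc_tree <- function(gene_trees, mode = c("auto", "exact", "heuristic"),
                     start = NULL) {
  mode <- match.arg(mode)
  if (length(gene_trees) < 2) stop("need at least 2 gene trees")
  taxa <- sort(Reduce(union, lapply(gene_trees, `[[`, "tip.label")))
  n <- length(taxa)
  if (n < 4) stop("need at least 4 taxa")
  if (mode == "auto") mode <- if (n <= 8) "exact" else "heuristic"
  qi <- quartet_index(n)
  gcodes <- gene_code_matrix(gene_trees, taxa, qi)
  if (all(gcodes == 0L | is.na(gcodes)))
    stop("degenerate input: no informative gene trees")

  if (mode == "exact") {
    cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    scores <- vapply(cands, score_against_codes, numeric(1),
                     taxa = taxa, qi = qi, gcodes = gcodes)
    best <- which(scores == max(scores))
    if (length(best) > 1) {
      nwk <- vapply(cands[best], function(t) ape::write.tree(t), character(1))
      best <- best[order(nwk)[1]]
    }
    tr <- cands[[best]]
    sc <- max(scores)
  } else {
    if (!is.null(start) && setequal(start$tip.label, taxa)) {
      tr <- ape::unroot(start)
      tr$node.label <- NULL
    } else {
      # start tree: NJ on mean topological distances across gene trees
      Dsum <- matrix(0, n, n, dimnames = list(taxa, taxa))
      Dn <- matrix(0, n, n)
      for (g in gene_trees) {
        sub <- intersect(taxa, g$tip.label)
        Dg <- tip_path_counts(g, sub)
        Dsum[sub, sub] <- Dsum[sub, sub] + Dg
        Dn[match(sub, taxa), match(sub, taxa)] <-
          Dn[match(sub, taxa), match(sub, taxa)] + 1
      }
      Dn[Dn == 0] <- 1
      tr <- nj_tree(Dsum / Dn)
      tr <- ape::unroot(tr)
    }
    sc <- score_against_codes(tr, taxa, qi, gcodes)
    repeat {
      nbrs <- phangorn::nni(tr)
      nsc <- vapply(nbrs, score_against_codes, numeric(1),
                    taxa = taxa, qi = qi, gcodes = gcodes)
      if (max(nsc) <= sc) break
      tr <- nbrs[[which.max(nsc)]]
      sc <- max(nsc)
    }
  }
  tr$edge.length <- NULL
  tr <- annotate_quartet_support(tr, taxa, qi, gcodes)
  attr(tr, "quartet_score") <- sc
  attr(tr, "mode") <- mode
  tr
}

# normalised quartet support per internal branch: among gene-tree quartets
# with one pair of taxa on each side of the branch, the share following the
# branch's own resolution
annotate_quartet_support <- function(tr, taxa, qi, gcodes) {
  keys <- edge_split_keys(tr)
  sp_codes <- quartet_codes(tr, taxa, qi)
  ntip <- length(tr$tip.label)
  node_lab <- rep(NA_character_, tr$Nnode)
  qtaxa <- matrix(taxa[qi], nrow(qi))
  for (k in which(!is.na(keys))) {
    side <- strsplit(keys[k], "\r", fixed = TRUE)[[1]]
    inA <- matrix(qtaxa %in% side, nrow(qi))
    nA <- rowSums(inA)
    span <- nA == 2L & sp_codes != 0L
    if (!any(span)) next
    gc <- gcodes[span, , drop = FALSE]
    sp <- sp_codes[span]
    conc <- sum(gc == sp & gc != 0L, na.rm = TRUE)
    tot <- sum(gc != 0L, na.rm = TRUE)
    node <- tr$edge[k, 2] - ntip
    node_lab[node] <- if (tot > 0) sprintf("%.1f", 100 * conc / tot) else ""
  }
  tr$node.label <- ifelse(is.na(node_lab), "", node_lab)
  tr
}

#' Concatenated (supermatrix) species tree
#'
#' Assembles the supermatrix, infers the topology by neighbor joining on
#' supermatrix ML distances, re-optimises branch lengths by maximum
#' likelihood, and attaches site-resampling bootstrap support (percent of
#' replicate NJ trees containing each branch; sites are resampled within
#' loci so partition sizes are preserved). In the partitioned variant every
#' locus gets its own rate scalar multiplying the shared branch lengths,
#' optimised jointly with the lengths.
#'
#' @param loci List of [locus_aln] (taxon sets may differ per locus).
#' @param partitioned Use per-locus rate scalars?
#' @param model A [substitution_model].
#' @param bootstrap Number of bootstrap replicates (0 to skip).
#' @param seed Optional seed for the bootstrap.
#' @param optimize Re-optimise branch lengths by ML? (`FALSE` keeps NJ
#'   lengths; useful for large supermatrices.)
#' @return `phylo` with `node.label` bootstrap support; attributes
#'   `"loglik"`, `"rates"` (partitioned only), `"supermatrix"`.
#' @export
concatenated_tree <- function(loci, partitioned = TRUE,
                              model = substitution_model("JC69"),
                              bootstrap = 100L, seed = NULL,
                              optimize = TRUE) {
  stopifnot(length(loci) >= 1)
  sm <- concat_supermatrix(loci)
  taxa <- rownames(sm)
  if (length(taxa) < 3) stop("unbuildable supermatrix: fewer than 3 taxa")
  D <- ml_distance_matrix(sm, model)
  main <- nj_tree(D)
  rates <- NULL
  if (optimize) {
    main <- optimize_branch_lengths(main, sm, model)
    if (partitioned && length(loci) > 1) {
      fit <- fit_partition_rates(main, sm, model)
      main <- fit$tree
      rates <- fit$rates
    }
  }
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    part <- attr(sm, "partitions")
    reps <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      idx <- unlist(lapply(seq_len(nrow(part)), function(k) {
        rng <- part$start[k]:part$end[k]
        sample(rng, length(rng), replace = TRUE)
      }))
      smb <- sm[, idx]
      reps[[b]] <- nj_tree(ml_distance_matrix(smb, model))
    }
    main <- attach_split_support(main, reps)
  }
  attr(main, "rates") <- rates
  attr(main, "supermatrix") <- sm
  main
}

# joint optimisation of shared branch lengths and per-locus rate scalars:
# alternate scalar fits (bounded 1-D searches on each locus) with a
# rescaling of the shared lengths to keep mean rate 1
fit_partition_rates <- function(tree, sm, model, rounds = 2) {
  part <- attr(sm, "partitions")
  nl <- nrow(part)
  rates <- rep(1, nl)
  pats <- lapply(seq_len(nl), function(k) {
    loc <- sm[, part$start[k]:part$end[k]]
    keep <- rowSums(is_called(unclass(loc))) > 0
    compress_patterns(loc[keep, ])
  })
  lik_locus <- function(k, r) {
    t2 <- ape::keep.tip(tree, pats[[k]]$taxa)
    t2$edge.length <- t2$edge.length * r
    sum(pruning_loglik_patterns(t2, pats[[k]], model) * pats[[k]]$weight)
  }
  for (it in seq_len(rounds)) {
    for (k in seq_len(nl)) {
      opt <- stats::optimize(function(r) -lik_locus(k, r), c(0.02, 50))
      rates[k] <- opt$minimum
    }
    # identifiability: mean log-rate 0, absorbed into shared lengths
    g <- exp(mean(log(rates)))
    rates <- rates / g
    tree$edge.length <- tree$edge.length * g
  }
  ll <- sum(vapply(seq_len(nl), function(k) lik_locus(k, rates[k]), numeric(1)))
  attr(tree, "loglik") <- ll
  names(rates) <- part$locus_id
  list(tree = tree, rates = rates)
}

# map split frequencies from replicate trees onto the main tree node labels
attach_split_support <- function(main, replicate_trees) {
  keys <- edge_split_keys(ape::unroot(main))
  tab <- table(unlist(lapply(replicate_trees, tree_splits)))
  ntip <- length(main$tip.label)
  un <- ape::unroot(main)
  lab <- rep("", un$Nnode)
  for (k in which(!is.na(keys))) {
    node <- un$edge[k, 2] - ntip
    cnt <- if (keys[k] %in% names(tab)) tab[[keys[k]]] else 0
    lab[node] <- sprintf("%d", round(100 * cnt / length(replicate_trees)))
  }
  un$node.label <- lab
  un
}

#' Bootstrap support for the quartet-score species tree
#'
#' `flavor = "gene_site"` resamples loci with replacement and sites within
#' each sampled locus, rebuilds gene trees, and re-estimates the species
#' tree per replicate (the classic two-level gene bootstrap).
#' `flavor = "site_only"` is the fast analog: only sites are resampled
#' within each locus. Supports on the main tree are the percentage of
#' replicate trees containing each branch; a greedy majority consensus of
#' the replicates is attached as attribute `"consensus"`.
#'
#' @param loci List of [locus_aln] used to (re)build gene trees.
#' @param replicates Bootstrap replicate count.
#' @param flavor `"gene_site"` or `"site_only"`.
#' @param seed Optional seed.
#' @param model A [substitution_model] for gene-tree distances.
#' @param mode Passed to [msc_tree].
#' @return The main `msc_tree` with bootstrap `node.label` supports and
#'   attributes `"consensus"` and `"replicates"`.
#' @export
msc_bootstrap <- function(loci, replicates = 100L,
                          flavor = c("gene_site", "site_only"),
                          seed = NULL, model = substitution_model("JC69"),
                          mode = "auto") {
  flavor <- match.arg(flavor)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  gts <- infer_gene_trees(loci, model)
  main <- msc_tree(gts, mode = mode)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    pick <- if (flavor == "gene_site")
      sample(seq_along(loci), length(loci), replace = TRUE)
    else seq_along(loci)
    gtb <- vector("list", length(pick))
    for (i in seq_along(pick)) {
      aln <- loci[[pick[i]]]
      idx <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      res <- infer_gene_trees(list(aln[, idx]), model)
      gtb[[i]] <- if (length(res)) res[[1]] else NULL
    }
    gtb <- gtb[!vapply(gtb, is.null, logical(1))]
    reps[[b]] <- msc_tree(gtb, mode = mode, start = main)
  }
  main <- attach_split_support(main, reps)
  attr(main, "consensus") <- greedy_consensus(reps)
  attr(main, "replicates") <- replicates
  main
}

#' Infer gene trees by neighbor joining on ML distances
#'
#' Taxa with no called site in a locus are pruned first; loci retaining
#' fewer than 4 taxa are dropped from the output.
#'
#' @param loci List of [locus_aln].
#' @param model A [substitution_model].
#' @return List of unrooted `phylo` gene trees (NULLs removed).
#' @export
infer_gene_trees <- function(loci, model = substitution_model("JC69")) {
  out <- lapply(loci, function(aln) {
    keep <- rowSums(is_called(unclass(aln))) >= 1
    if (sum(keep) < 4) return(NULL)
    aln <- aln[keep, ]
    nj_tree(ml_distance_matrix(aln, model))
  })
  out[!vapply(out, is.null, logical(1))]
}

# greedy majority-rule-extended consensus: splits by decreasing frequency,
# added when compatible with those already accepted
greedy_consensus <- function(trees) {
  taxa <- sort(trees[[1]]$tip.label)
  tab <- sort(table(unlist(lapply(trees, tree_splits))), decreasing = TRUE)
  accepted <- list()
  compatible <- function(a, b) {
    ia <- taxa %in% a; ib <- taxa %in% b
    !any(ia & ib) || !any(ia & !ib) || !any(!ia & ib) || !any(!ia & !ib)
  }
  for (key in names(tab)) {
    side <- strsplit(key, "\r", fixed = TRUE)[[1]]
    if (all(vapply(accepted, compatible, logical(1), b = side)) ||
        !length(accepted))
      accepted[[length(accepted) + 1]] <- side
  }
  splits_to_tree(accepted, taxa)
}

# build an unrooted tree realising a compatible split set
splits_to_tree <- function(splits, taxa) {
  # start from a star tree and successively resolve each split
  tr <- ape::read.tree(text = paste0("(", paste(taxa, collapse = ","), ");"))
  for (side in splits) {
    if (length(side) < 2 || length(side) > length(taxa) - 2) next
    tr2 <- tryCatch(resolve_split(tr, side), error = function(e) NULL)
    if (!is.null(tr2)) tr <- tr2
  }
  tr
}

resolve_split <- function(tr, side) {
  ntip <- length(tr$tip.label)
  sets <- edge_tip_sets(tr)
  # the split's tips must currently attach to a common node
  tips <- match(side, tr$tip.label)
  # find node whose children include exactly the subtrees covering `side`
  kids_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  for (v in names(kids_of)) {
    ke <- kids_of[[v]]
    cover <- vapply(ke, function(k) all(sets[[k]] %in% side), logical(1))
    covered <- unlist(sets[ke[cover]])
    if (setequal(covered, side) && sum(cover) >= 2 &&
        sum(cover) < length(ke)) {
      # insert a new node gathering the covering child edges
      return(group_edges(tr, as.integer(v), ke[cover]))
    }
  }
  stop("split not realisable")
}

group_edges <- function(tr, v, edge_rows) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  new <- nn + 1L
  edge <- tr$edge
  # children being grouped now hang from `new`; `new` hangs from v
  edge[edge_rows, 1] <- new
  edge <- rbind(edge, c(v, new))
  # renumber: internal nodes must stay > ntip; new node appended is fine
  tr$edge <- edge
  tr$Nnode <- tr$Nnode + 1L
  if (!is.null(tr$edge.length)) tr$edge.length <- c(tr$edge.length, 0)
  # canonicalise numbering through write/read
  tr$node.label <- NULL
  ape::read.tree(text = ape::write.tree(tr))
}
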