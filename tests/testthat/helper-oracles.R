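# Fixtures and independent brute-force oracles used across the suite.

rtree_labeled <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
  tr
}

random_locus <- function(n_taxa = 5, len = 40, seed = NULL, tag = "CDS") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * len, replace = TRUE),
              n_taxa, dimnames = list(sprintf("t%02d", 1:n_taxa), NULL))
  locus_aln(m, locus_id = paste0("rand", seed), class_tag = tag)
}

# exhaustive likelihood oracle: sum over all internal-state assignments
# (JC69 only), usable for trees with <= 5 leaves
oracle_site_loglik <- function(tree, aln) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  n_int <- tr$Nnode
  jc_p <- function(t) {
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    diff <- 0.25 - 0.25 * exp(-4 * t / 3)
    matrix(diff, 4, 4) + diag(rep(same - diff, 4))
  }
  P_list <- lapply(tr$edge.length, jc_p)
  nt <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  out <- numeric(ncol(aln))
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  m <- unclass(aln)[tr$tip.label, , drop = FALSE]
  for (s in seq_len(ncol(aln))) {
    tipstate <- nt[m[, s]]           # NA for gap/N
    tot <- 0
    for (gi in seq_len(nrow(grid))) {
      assign_int <- grid[gi, ]
      state_of <- function(v) if (v <= ntip) tipstate[v]
        else assign_int[v - ntip]
      pr <- 0.25                     # root frequency
      okprod <- pr
      for (k in seq_len(nrow(tr$edge))) {
        p <- state_of(tr$edge[k, 1]); ch <- state_of(tr$edge[k, 2])
        if (is.na(ch)) next          # missing tip: marginalised (sums to 1)
        if (is.na(p)) stop("internal state NA")
        okprod <- okprod * P_list[[k]][p, ch]
      }
      tot <- tot + okprod
    }
    out[s] <- log(tot)
  }
  out
}

# brute-force quartet score: extract each 4-taxon subtree with ape and
# compare unrooted topologies directly
oracle_quartet_score <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  quads <- utils::combn(sort(taxa), 4, simplify = FALSE)
  same_topo <- function(a, b) {
    ape::dist.topo(ape::unroot(a), ape::unroot(b)) == 0
  }
  score <- 0L
  for (g in gene_trees) {
    for (q in quads) {
      if (!all(q %in% g$tip.label)) next
      sq <- ape::unroot(ape::keep.tip(species_tree, q))
      gq <- ape::unroot(ape::keep.tip(g, q))
      if (gq$Nnode < 2 || sq$Nnode < 2) next  # unresolved quartet
      if (same_topo(sq, gq)) score <- score + 1L
    }
  }
  score
}

default_clades_for_test <- function(tree) {
  phyloconcord:::default_clades(tree, root_on = sort(tree$tip.label)[1])
}

# brute-force gCF: decisiveness and concordance checked by restricting the
# gene tree with ape and testing monophyly after rooting on the other side
oracle_gcf <- function(reference, gene_trees) {
  ref <- ape::unroot(reference)
  taxa <- ref$tip.label
  ntip <- length(taxa)
  res <- list()
  # clades below each internal edge, via ape's bipartition extraction
  bp <- ape::prop.part(ref)
  labs <- attr(bp, "labels")
  parts <- lapply(bp, function(i) labs[i])
  parts <- Filter(function(A) length(A) >= 2 && length(A) <= ntip - 2, parts)
  for (A in parts) {
    B <- setdiff(taxa, A)
    dec <- 0L; conc <- 0L
    for (g in gene_trees) {
      A2 <- intersect(A, g$tip.label); B2 <- intersect(B, g$tip.label)
      if (length(A2) < 2 || length(B2) < 2) next
      dec <- dec + 1L
      sub <- ape::keep.tip(g, c(A2, B2))
      rooted <- ape::root(sub, outgroup = B2[1], resolve.root = TRUE)
      if (ape::is.monophyletic(rooted, A2)) conc <- conc + 1L
    }
    res[[length(res) + 1]] <- data.frame(
      clade = paste(sort(A), collapse = ","), decisive = dec,
      concordant = conc, gcf = if (dec > 0) 100 * conc / dec else NA_real_)
  }
  do.call(rbind, res)
}
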