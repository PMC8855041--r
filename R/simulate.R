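#' Simulate a species tree (pure-birth shape, coalescent-unit lengths)
#'
#' Generates a rooted, binary, ultrametric tree by a Yule (pure-birth)
#' process with exponential waiting times, then multiplies internal branch
#' lengths by `ils_scale`. Branch lengths are interpreted as coalescent
#' units by the multispecies-coalescent simulator: shrinking internal
#' branches (small `ils_scale`) raises incomplete lineage sorting.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Optional integer seed (deterministic output given seed).
#' @param birth_rate Speciation rate of the Yule process.
#' @param ils_scale Multiplier applied to internal branch lengths.
#' @param labels Optional tip labels; default `t01, t02, ...`.
#' @return A rooted binary `phylo` with strictly positive branch lengths.
#' @export
sim_species_tree <- function(n_taxa, seed = NULL, birth_rate = 1,
                             ils_scale = 1, labels = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels))
    labels <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))

  # forward-time pure birth: the root splits at time 0; each subsequent
  # split waits Exp(k * birth_rate) and hits a uniformly chosen lineage
  n_nodes <- n_taxa + (n_taxa - 1L)
  root <- n_taxa + 1L
  parent <- integer(0); child <- integer(0)
  node_time <- numeric(n_nodes)
  node_time[root] <- 0
  next_int <- root + 1L
  t_now <- 0
  par_of <- c(root, root)            # parent node of each open lineage
  k <- 2L
  while (k < n_taxa) {
    t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
    i <- sample.int(k, 1L)
    v <- next_int; next_int <- next_int + 1L
    node_time[v] <- t_now
    parent <- c(parent, par_of[i]); child <- c(child, v)
    par_of <- c(par_of[-i], v, v)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1, rate = birth_rate * k)
  ord <- sample.int(k)               # random assignment of tips to lineages
  for (j in seq_len(k)) {
    tip <- ord[j]
    parent <- c(parent, par_of[j]); child <- c(child, tip)
    node_time[tip] <- t_end
  }
  edge <- cbind(parent, child)
  len <- node_time[child] - node_time[parent]
  internal <- child > n_taxa
  len[internal] <- len[internal] * ils_scale
  tr <- list(edge = edge, edge.length = as.numeric(len),
             tip.label = labels, Nnode = n_taxa - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per species. Within each species-tree
#' branch of length `t` (coalescent units), lineage pairs coalesce at rate 1
#' per pair with exponential waiting times; lineages remaining at the top of
#' a branch enter the parent branch; all remaining lineages coalesce above
#' the root. With `linked = TRUE` a single genealogy is drawn and repeated
#' for all loci (uniparentally inherited, non-recombining plastid emulation).
#'
#' @param species_tree Rooted `phylo` with coalescent-unit branch lengths.
#' @param n_loci Number of gene trees.
#' @param ils_scale Extra multiplier on internal species-tree branches.
#' @param linked If `TRUE`, all loci share one drawn genealogy.
#' @param seed Optional integer seed.
#' @return List of rooted `phylo` gene trees (coalescent-unit lengths).
#' @export
sim_gene_trees_msc <- function(species_tree, n_loci, ils_scale = 1,
                               linked = FALSE, seed = NULL) {
  if (!ape::is.rooted(species_tree))
    stop("species_tree must be rooted")
  if (!is.null(seed)) set.seed(seed)
  st <- species_tree
  if (ils_scale != 1) {
    internal <- st$edge[, 2] > length(st$tip.label)
    st$edge.length[internal] <- st$edge.length[internal] * ils_scale
  }
  n_draw <- if (linked) 1L else n_loci
  out <- vector("list", n_draw)
  for (i in seq_len(n_draw)) out[[i]] <- msc_one_locus(st)
  if (linked) out <- rep(out, n_loci)
  out
}

# single MSC genealogy on a rooted species tree
msc_one_locus <- function(st) {
  ntip <- length(st$tip.label)
  nn <- ntip + st$Nnode
  root <- ntip + 1L
  kids <- split(st$edge[, 2], st$edge[, 1])
  elen <- numeric(nn)
  elen[st$edge[, 2]] <- st$edge.length

  # gene-tree bookkeeping: nodes numbered as created; tips 1..ntip
  g_parent <- integer(0); g_child <- integer(0); g_len <- numeric(0)
  next_g <- ntip + 1L
  # pending branch length per live gene lineage
  coalesce_in <- function(lin, pend, duration) {
    t_cur <- 0
    while (length(lin) >= 2L) {
      k <- length(lin)
      w <- stats::rexp(1, rate = k * (k - 1) / 2)
      if (t_cur + w > duration) break
      t_cur <- t_cur + w
      pend <- pend + w
      pair <- sample.int(k, 2L)
      v <- next_g; next_g <<- next_g + 1L
      g_parent <<- c(g_parent, v, v)
      g_child <<- c(g_child, lin[pair])
      g_len <<- c(g_len, pend[pair])
      lin <- c(lin[-pair], v)
      pend <- c(pend[-pair], 0)
    }
    if (is.finite(duration)) pend <- pend + (duration - t_cur)
    list(lin = lin, pend = pend)
  }

  # postorder over species nodes: lineages arriving at top of each branch
  po <- unique(ape::reorder.phylo(st, "postorder")$edge[, 1])
  at_node <- vector("list", nn)
  pend_at <- vector("list", nn)
  for (i in seq_len(ntip)) { at_node[[i]] <- i; pend_at[[i]] <- 0 }
  # process every non-root branch bottom-up: species nodes in postorder give
  # children processed before parents
  order_nodes <- c(seq_len(ntip), po[po != root])
  # simpler: iterate species nodes by decreasing depth
  depth <- node_depths_edges(st)
  for (v in order(depth[seq_len(nn)], decreasing = TRUE)) {
    if (v == root) next
    if (v > ntip) {
      lin <- unlist(lapply(kids[[as.character(v)]], function(ch) at_node[[ch]]))
      pend <- unlist(lapply(kids[[as.character(v)]], function(ch) pend_at[[ch]]))
    } else {
      lin <- at_node[[v]]; pend <- pend_at[[v]]
    }
    res <- coalesce_in(lin, pend, elen[v])
    at_node[[v]] <- res$lin; pend_at[[v]] <- res$pend
  }
  lin <- unlist(lapply(kids[[as.character(root)]], function(ch) at_node[[ch]]))
  pend <- unlist(lapply(kids[[as.character(root)]], function(ch) pend_at[[ch]]))
  res <- coalesce_in(lin, pend, Inf)

  n_gnode <- next_g - ntip - 1L
  # renumber gene nodes to ape convention: root = ntip+1
  # our creation order is bottom-up; the last created node is the root
  old <- seq.int(ntip + 1L, next_g - 1L)
  new <- c(ntip + 1L, seq.int(ntip + 2L, length.out = n_gnode - 1L))
  map <- integer(next_g - 1L)
  map[seq_len(ntip)] <- seq_len(ntip)
  map[rev(old)] <- new   # last created -> root id
  tr <- list(edge = cbind(map[g_parent], map[g_child]),
             edge.length = g_len,
             tip.label = st$tip.label,
             Nnode = n_gnode)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# edge-count depth of every node from the root (root = 0)
node_depths_edges <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  d <- rep(NA_real_, nn)
  root <- length(tree$tip.label) + 1L
  d[root] <- 0
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in rev(seq_len(nrow(eo))))
    d[eo[k, 2]] <- d[eo[k, 1]] + 1
  d
}

#' Simulate a nucleotide alignment on a gene tree
#'
#' Sites evolve independently root-to-tips under the substitution model,
#' with branch lengths multiplied by `rate` to convert to expected
#' substitutions per site. Missing data is then injected: whole-taxon
#' dropout first (emulating failed locus capture), then random cells, until
#' the realized missing fraction is within 2 percentage points of target.
#'
#' @param gene_tree Rooted `phylo`.
#' @param length Number of sites.
#' @param model A [substitution_model].
#' @param rate Multiplier converting branch lengths to substitutions/site.
#' @param missing_fraction Target fraction of masked cells, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param locus_id,class_tag Passed to [locus_aln].
#' @return A [locus_aln].
#' @export
sim_alignment <- function(gene_tree, length, model = substitution_model("JC69"),
                          rate = 1, missing_fraction = 0, seed = NULL,
                          locus_id = "sim", class_tag = "CDS") {
  if (missing_fraction >= 1) stop("missing_fraction must be < 1")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")  # preorder-friendly
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  root <- ntip + 1L
  states <- matrix(0L, nrow = nn, ncol = length)
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$freq)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    P <- model_pmatrix(model, tr$edge.length[k] * rate)
    ps <- states[p, ]
    cs <- integer(length)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[ch, ] <- cs
  }
  nt <- c("A", "C", "G", "T")
  mat <- matrix(nt[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
                dimnames = list(tr$tip.label, NULL))
  mat <- mask_missing(mat, missing_fraction)
  locus_aln(mat, locus_id = locus_id, class_tag = class_tag)
}

# whole-taxon dropout first, then random cells, hitting the target exactly
mask_missing <- function(mat, target) {
  if (target <= 0) return(mat)
  ntax <- nrow(mat); nsite <- ncol(mat)
  total <- ntax * nsite
  want <- round(target * total)
  n_drop <- min(floor(target * ntax / 2), max(ntax - 4L, 0L))
  if (n_drop > 0) {
    drop <- sample.int(ntax, n_drop)
    mat[drop, ] <- "-"
  }
  have <- sum(mat == "-")
  need <- want - have
  if (need > 0) {
    free <- which(mat != "-")
    pick <- sample(free, min(need, length(free)))
    mat[pick] <- "N"
  }
  mat
}

#' Simulation configuration for the study-structure generator
#'
#' Defaults emulate the locus structure of a three-class target-capture
#' dataset: exon-like loci (many, short, moderate signal, light
#' missingness), intron-like loci (longer, high signal, heavier
#' missingness), and plastid-like loci (few, low signal, very heavy
#' missingness, all sharing one genealogy). Full scale uses 306/239/44
#' loci; desk scale (the default) uses 30/24/8.
#'
#' @param n_taxa Number of species.
#' @param seed Integer seed for the whole dataset build.
#' @param scale `"desk"` or `"full"` locus counts.
#' @param ils_scale Multiplier on internal species-tree branches.
#' @param classes Optional list overriding per-class settings; each class is
#'   a list with `n_loci`, `mean_len`, `min_len`, `max_len`, `rate`,
#'   `missing`, `linked`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 12, seed = 1, scale = c("desk", "full"),
                       ils_scale = 1, classes = NULL) {
  scale <- match.arg(scale)
  full <- scale == "full"
  default <- list(
    CDS = list(n_loci = if (full) 306L else 30L, mean_len = 590,
               min_len = 59, max_len = 2713, rate = 0.02,
               missing = 0.161, linked = FALSE),
    INT = list(n_loci = if (full) 239L else 24L, mean_len = 1375,
               min_len = 243, max_len = 47434, rate = 0.068,
               missing = 0.346, linked = FALSE),
    PL  = list(n_loci = if (full) 44L else 8L, mean_len = 1116,
               min_len = 183, max_len = 5613, rate = 0.016,
               missing = 0.775, linked = TRUE))
  if (!is.null(classes))
    for (nm in names(classes))
      default[[nm]] <- utils::modifyList(default[[nm]], classes[[nm]])
  for (cl in default) {
    if (cl$n_loci <= 0) stop("n_loci must be positive")
    if (cl$missing >= 1) stop("missing fraction must be < 1")
  }
  if (ils_scale <= 0) stop("ils_scale must be positive")
  structure(list(n_taxa = n_taxa, seed = seed, scale = scale,
                 ils_scale = ils_scale, classes = default,
                 model = substitution_model("JC69")),
            class = "sim_config")
}

#' Build a synthetic multi-class locus set (plus its true species tree)
#'
#' Simulates a species tree, per-class MSC gene trees (the plastid-like
#' class shares a single genealogy), and per-locus alignments whose counts,
#' lengths, per-class rates and missing-data levels follow the configured
#' targets. Locus lengths are drawn from a lognormal matched to the class
#' mean and truncated to the class range.
#'
#' @param config A [sim_config].
#' @return A `locus_set`: list with `loci` (list of [locus_aln]),
#'   `gene_trees` (true genealogies, same order), `species_tree`,
#'   `config`.
#' @export
build_study_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  sp <- sim_species_tree(config$n_taxa, ils_scale = config$ils_scale)
  loci <- list(); gts <- list()
  for (cl_name in names(config$classes)) {
    cl <- config$classes[[cl_name]]
    g <- sim_gene_trees_msc(sp, cl$n_loci, linked = cl$linked)
    sdlog <- 0.55
    lens <- round(stats::rlnorm(cl$n_loci,
                                meanlog = log(cl$mean_len) - sdlog^2 / 2,
                                sdlog = sdlog))
    lens <- pmin(pmax(lens, cl$min_len), cl$max_len)
    for (i in seq_len(cl$n_loci)) {
      id <- sprintf("%s_%03d", cl_name, i)
      aln <- sim_alignment(g[[i]], lens[i], model = config$model,
                           rate = cl$rate, missing_fraction = cl$missing,
                           locus_id = id, class_tag = cl_name)
      loci[[id]] <- aln
      gts[[id]] <- g[[i]]
    }
  }
  structure(list(loci = loci, gene_trees = gts, species_tree = sp,
                 config = config),
            class = "locus_set")
}

#' Write a locus set to disk
#'
#' Per-locus FASTA files, a partition table (`partitions.csv`: locus_id,
#' class, length), the true species tree and gene trees as Newick, and the
#' configuration as YAML (when the yaml package is available).
#'
#' @param ds A [build_study_dataset] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus_set <- function(ds, dir) {
  dir.create(file.path(dir, "loci"), showWarnings = FALSE, recursive = TRUE)
  for (id in names(ds$loci))
    write_alignment(ds$loci[[id]], file.path(dir, "loci",
                                             paste0(id, ".fasta")))
  utils::write.csv(data.frame(
    locus_id = names(ds$loci),
    class = vapply(ds$loci, function(l) attr(l, "class_tag"), character(1)),
    length = vapply(ds$loci, ncol, integer(1)), row.names = NULL),
    file.path(dir, "partitions.csv"), row.names = FALSE)
  write_trees(ds$species_tree, file.path(dir, "true_species_tree.nwk"))
  write_trees(ds$gene_trees, file.path(dir, "true_gene_trees.nwk"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- ds$config
    yaml::write_yaml(list(n_taxa = cfg$n_taxa, seed = cfg$seed,
                          scale = cfg$scale, ils_scale = cfg$ils_scale,
                          classes = cfg$classes),
                     file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file with fields `n_taxa`, `seed`, `scale`,
#'   `ils_scale`, `classes` (as written by [write_locus_set]).
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  y <- yaml::read_yaml(path)
  y$classes <- lapply(y$classes, function(cl) {
    cl$n_loci <- as.integer(cl$n_loci)
    cl
  })
  sim_config(n_taxa = y$n_taxa, seed = y$seed, scale = y$scale,
             ils_scale = y$ils_scale, classes = y$classes)
}

#' @export
print.locus_set <- function(x, ...) {
  tab <- table(vapply(x$loci, function(l) attr(l, "class_tag"), character(1)))
  cat("<locus_set>", length(x$loci), "loci (",
      paste(names(tab), as.integer(tab), collapse = ", "), ") on",
      length(x$species_tree$tip.label), "taxa\n")
  invisible(x)
}
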