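test_that("quartet score counts concordant resolved quartets", {
  ab_cd <- ape::read.tree(text = "((A,B),(C,D));")
  ac_bd <- ape::read.tree(text = "((A,C),(B,D));")
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(quartet_score(ab_cd, list(ab_cd, ab_cd, ac_bd)), 2L)
  expect_equal(quartet_score(ab_cd, list(star)), 0L)
  tr6 <- rtree_labeled(6, seed = 31)
  expect_equal(quartet_score(tr6, list(tr6, tr6, tr6)), 3 * choose(6, 4))
})

test_that("quartet score equals the brute-force oracle on random fixtures", {
  for (s in 1:4) {
    sp <- rtree_labeled(6, seed = 200 + s)
    gts <- lapply(1:5, function(i) rtree_labeled(6, seed = 300 + 10 * s + i))
    expect_equal(quartet_score(sp, gts), oracle_quartet_score(sp, gts))
  }
  # gene trees with missing taxa
  sp <- rtree_labeled(7, seed = 88)
  gts <- lapply(1:4, function(i) {
    g <- rtree_labeled(7, seed = 400 + i)
    ape::drop.tip(g, sample(g$tip.label, 2))
  })
  expect_equal(quartet_score(sp, gts), oracle_quartet_score(sp, gts))
})

test_that("exact-mode quartet species tree is the enumeration argmax", {
  set.seed(41)
  sp <- sim_species_tree(6, seed = 41)
  gts <- sim_gene_trees_msc(sp, 25, seed = 42)
  est <- msc_tree(gts, mode = "exact")
  # oracle: score every enumerated topology directly
  cands <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = sort(sp$tip.label))
  scores <- vapply(cands, function(t) quartet_score(t, gts), integer(1))
  expect_equal(attr(est, "quartet_score"), max(scores))
  expect_equal(quartet_score(est, gts), max(scores))
})

test_that("identical input gene trees are returned with full support", {
  g <- rtree_labeled(6, seed = 43)
  est <- msc_tree(list(g, g, g), mode = "exact")
  expect_equal(ape::dist.topo(est, ape::unroot(g)), 0, ignore_attr = TRUE)
  sup <- suppressWarnings(as.numeric(est$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("heuristic mode never scores below its start tree", {
  set.seed(44)
  sp <- sim_species_tree(10, seed = 44, ils_scale = 0.3)
  gts <- sim_gene_trees_msc(sp, 30, seed = 45)
  est <- msc_tree(gts, mode = "heuristic")
  start <- msc_tree(gts, mode = "heuristic", start = ape::unroot(sp))
  expect_gte(attr(est, "quartet_score"), 0)
  # hill-climbing from the truth can only match or beat the truth's score
  expect_gte(attr(start, "quartet_score"),
             quartet_score(ape::unroot(sp), gts))
})

test_that("concatenated trees behave on degenerate and clean inputs", {
  set.seed(46)
  sp <- sim_species_tree(6, seed = 46)
  # one shared genealogy and equal rates: scalars should recover near 1
  gts <- sim_gene_trees_msc(sp, 4, linked = TRUE, seed = 47)
  loci <- lapply(seq_along(gts), function(i)
    sim_alignment(gts[[i]], 1000, rate = 0.05, seed = 50 + i,
                  locus_id = paste0("L", i)))
  # one locus: partitioned and unpartitioned coincide topologically
  cpa1 <- concatenated_tree(loci[1], partitioned = TRUE, bootstrap = 0)
  cun1 <- concatenated_tree(loci[1], partitioned = FALSE, bootstrap = 0)
  expect_equal(ape::dist.topo(cpa1, cun1), 0, ignore_attr = TRUE)
  # equal-rate loci: partition rate scalars near 1
  cpa <- suppressWarnings(
    concatenated_tree(loci, partitioned = TRUE, bootstrap = 20, seed = 9))
  expect_true(all(attr(cpa, "rates") > 0.8 & attr(cpa, "rates") < 1.2))
  # strong-signal branches: bootstrap support 100
  sup <- suppressWarnings(as.numeric(cpa$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("MSC bootstrap supports are percentages and clean data maxes out", {
  set.seed(48)
  # discordance-free: one genealogy for all loci, strong signal
  sp <- sim_species_tree(6, seed = 48)
  gts <- sim_gene_trees_msc(sp, 6, linked = TRUE, seed = 49)
  loci <- lapply(seq_along(gts), function(i)
    sim_alignment(gts[[i]], 800, rate = 0.08, seed = 60 + i,
                  locus_id = paste0("L", i)))
  bt <- msc_bootstrap(loci, replicates = 20, flavor = "site_only",
                      seed = 50, mode = "heuristic")
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(mean(sup == 100) >= 0.5)
  expect_s3_class(attr(bt, "consensus"), "phylo")
})

test_that("stronger lineage sorting lowers mean internal support", {
  score_support <- function(ils, seed) {
    sp <- sim_species_tree(7, seed = seed, ils_scale = ils)
    gts <- sim_gene_trees_msc(sp, 20, seed = seed + 1)
    loci <- lapply(seq_along(gts), function(i)
      sim_alignment(gts[[i]], 300, rate = 0.05, seed = seed + 10 + i,
                    locus_id = paste0("L", i)))
    bt <- msc_bootstrap(loci, replicates = 15, flavor = "site_only",
                        seed = seed + 99, mode = "heuristic")
    sup <- suppressWarnings(as.numeric(bt$node.label))
    mean(sup, na.rm = TRUE)
  }
  lo_ils <- score_support(3, 71)    # long internals: little discordance
  hi_ils <- score_support(0.05, 71) # short internals: strong discordance
  expect_gt(lo_ils, hi_ils)
})
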