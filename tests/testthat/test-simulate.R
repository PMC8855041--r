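test_that("species-tree simulation is binary, ultrametric and seeded", {
  tr <- sim_species_tree(3, seed = 1)
  expect_equal(tr$Nnode, 2L)
  expect_error(sim_species_tree(2), "n_taxa")
  a <- sim_species_tree(9, seed = 42)
  b <- sim_species_tree(9, seed = 42)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  big <- sim_species_tree(20, seed = 1)
  expect_true(ape::is.ultrametric(big, tol = 1e-8))
  expect_true(all(big$edge.length > 0))
  expect_true(ape::is.binary(big))
})

test_that("MSC gene trees follow the coalescent limits", {
  sp_long <- ape::read.tree(text = "((A:50,B:50):50,C:100);")
  g <- sim_gene_trees_msc(sp_long, 200, seed = 5)
  concord <- mean(vapply(g, function(t) {
    d <- tip_path_counts(t, c("A", "B", "C"))
    d["A", "B"] < d["A", "C"] & d["A", "B"] < d["B", "C"]
  }, logical(1)))
  expect_gte(concord, 0.99)
  # zero-length internal branch: each triplet near 1/3
  sp0 <- ape::read.tree(text = "((A:1,B:1):0.000001,C:1);")
  g0 <- sim_gene_trees_msc(sp0, 3000, seed = 6)
  topo <- vapply(g0, function(t) {
    d <- tip_path_counts(t, c("A", "B", "C"))
    which.min(c(d["A", "B"], d["A", "C"], d["B", "C"]))
  }, integer(1))
  freq <- tabulate(topo, 3) / length(topo)
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))
  expect_error(sim_gene_trees_msc(ape::unroot(ape::rtree(5)), 2), "rooted")
})

test_that("triplet concordance matches the closed-form coalescent law", {
  for (t_int in c(0.5, 1, 2)) {
    sp <- ape::read.tree(text = sprintf("((A:1,B:1):%f,C:2);", t_int))
    g <- sim_gene_trees_msc(sp, 4000, seed = round(100 * t_int))
    conc <- mean(vapply(g, function(t) {
      d <- tip_path_counts(t, c("A", "B", "C"))
      d["A", "B"] < d["A", "C"] & d["A", "B"] < d["B", "C"]
    }, logical(1)))
    p <- 1 - (2 / 3) * exp(-t_int)
    expect_lt(abs(conc - p), 3 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("linked loci share one genealogy", {
  sp <- sim_species_tree(8, seed = 2)
  g <- sim_gene_trees_msc(sp, 10, linked = TRUE, seed = 3)
  d0 <- vapply(g[-1], function(t) ape::dist.topo(ape::unroot(t),
                                                 ape::unroot(g[[1]])),
               numeric(1))
  expect_true(all(d0 == 0))
})

test_that("sequence simulation matches the JC expected p-distance", {
  t2 <- ape::read.tree(text = "(A:0.05,B:0.05);")
  a <- sim_alignment(t2, 100000, rate = 1, seed = 8)
  p <- mean(a["A", ] != a["B", ])
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("zero rate gives identical sequences; missing mask hits target", {
  tr <- sim_species_tree(6, seed = 4)
  a <- sim_alignment(tr, 300, rate = 0, seed = 5)
  expect_equal(length(unique(apply(unclass(a), 1, paste, collapse = ""))), 1L)
  b <- sim_alignment(tr, 2000, rate = 0.05, missing_fraction = 0.346,
                     seed = 6)
  expect_true(abs(missing_fraction(b) - 0.346) <= 0.02)
  expect_error(sim_alignment(tr, 100, missing_fraction = 1), "missing")
})

test_that("study dataset builder respects counts, scale and determinism", {
  cfg <- sim_config(n_taxa = 8, seed = 9, scale = "desk",
                    classes = list(CDS = list(n_loci = 6L, mean_len = 120),
                                   INT = list(n_loci = 5L, mean_len = 150),
                                   PL = list(n_loci = 3L, mean_len = 130)))
  ds <- build_study_dataset(cfg)
  tags <- vapply(ds$loci, function(l) attr(l, "class_tag"), character(1))
  expect_equal(as.vector(table(tags)[c("CDS", "INT", "PL")]), c(6L, 5L, 3L))
  ds2 <- build_study_dataset(cfg)
  expect_identical(lapply(ds$loci, unclass), lapply(ds2$loci, unclass))
  expect_identical(ape::write.tree(ds$species_tree),
                   ape::write.tree(ds2$species_tree))
  # linked plastid class: all gene trees topologically identical
  pl_gts <- ds$gene_trees[tags == "PL"]
  expect_true(all(vapply(pl_gts[-1], function(t)
    ape::dist.topo(ape::unroot(t), ape::unroot(pl_gts[[1]])) == 0,
    logical(1))))
  # full-scale counts follow the configured study structure
  full <- sim_config(scale = "full")
  expect_equal(vapply(full$classes, `[[`, integer(1), "n_loci"),
               c(CDS = 306L, INT = 239L, PL = 44L))
})

test_that("locus sets and configurations round-trip through disk", {
  cfg <- sim_config(n_taxa = 6, seed = 13, scale = "desk",
                    classes = list(CDS = list(n_loci = 2L, mean_len = 80),
                                   INT = list(n_loci = 2L, mean_len = 80),
                                   PL = list(n_loci = 2L, mean_len = 80)))
  ds <- build_study_dataset(cfg)
  dir <- withr::local_tempdir()
  write_locus_set(ds, dir)
  expect_true(file.exists(file.path(dir, "partitions.csv")))
  back <- read_alignments(file.path(dir, "loci",
                                    paste0(names(ds$loci)[1], ".fasta")),
                          class_tag = "CDS")[[1]]
  expect_equal(unclass(back), unclass(ds$loci[[1]]), ignore_attr = TRUE)
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$classes, cfg$classes)
  expect_identical(
    ape::write.tree(build_study_dataset(cfg2)$species_tree),
    ape::write.tree(ds$species_tree))
})

test_that("informative-site fraction rises with the rate multiplier", {
  sp <- sim_species_tree(10, seed = 10)
  g <- sim_gene_trees_msc(sp, 1, seed = 11)[[1]]
  pis <- vapply(c(0.005, 0.03, 0.15), function(r) {
    a <- sim_alignment(g, 2000, rate = r, seed = 12)
    count_pis(a) / 2000
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
})
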