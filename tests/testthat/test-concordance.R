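test_that("gene concordance factor follows the decisive/concordant counts", {
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  alt <- ape::read.tree(text = "((A,C),(B,D));")
  tab <- gcf(ref, list(ref, ref, ref, alt))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$decisive, 4L)
  expect_equal(tab$concordant, 3L)
  expect_equal(tab$gcf, 75)
  # gene tree with taxa from one side only is not decisive
  one_side <- ape::read.tree(text = "((A,B),E);")
  ref5 <- ape::read.tree(text = "(((A,B),E),(C,D));")
  tab5 <- gcf(ref5, list(one_side))
  ab_row <- tab5[tab5$clade_size == 2 & grepl("C", tab5$split), ]
  expect_equal(gcf(ref, list(one_side))$decisive, 0L)
  expect_error(gcf(ref, list()), "no gene trees")
})

test_that("gCF equals the brute-force restriction oracle", {
  for (s in 1:3) {
    ref <- rtree_labeled(7, seed = 500 + s)
    gts <- lapply(1:8, function(i) {
      g <- rtree_labeled(7, seed = 600 + 10 * s + i)
      if (i %% 3 == 0) g <- ape::drop.tip(g, g$tip.label[1:2])
      g
    })
    mine <- gcf(ref, gts)
    oracle <- oracle_gcf(ref, gts)
    # align by clade tip set
    mine_key <- vapply(strsplit(mine$split, "\r", fixed = TRUE),
                       function(x) paste(sort(x), collapse = ","),
                       character(1))
    taxa <- ref$tip.label
    oracle_key <- vapply(strsplit(oracle$clade, ","), function(x) {
      side <- if (min(taxa) %in% x) sort(setdiff(taxa, x)) else sort(x)
      paste(side, collapse = ",")
    }, character(1))
    m <- match(mine_key, oracle_key)
    expect_false(anyNA(m))
    expect_equal(mine$decisive, oracle$decisive[m])
    expect_equal(mine$concordant, oracle$concordant[m])
  }
})

test_that("all-identical gene trees give gCF 100 on every branch", {
  ref <- rtree_labeled(10, seed = 51)
  tab <- gcf(ref, rep(list(ref), 20))
  expect_true(all(tab$gcf == 100))
})

test_that("site concordance factor scores a single quartet correctly", {
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- locus_aln(rbind(A = c(rep("A", 8), rep("A", 2), rep("C", 5)),
                         B = c(rep("A", 8), rep("G", 2), rep("C", 5)),
                         C = c(rep("T", 8), rep("A", 2), rep("C", 5)),
                         D = c(rep("T", 8), rep("G", 2), rep("C", 5))),
                   "x", "CDS")
  tab <- scf(ref, aln, q = 50, seed = 1)
  expect_equal(tab$scf, 80)
  expect_equal(tab$quartets, 1L)  # only one distinct quartet exists
})

test_that("strong clean signal pushes sCF high; exhaustive mode is stable", {
  # fixed tree whose internal branches all carry real signal, at a rate low
  # enough that homoplasy stays rare
  sp <- ape::read.tree(text = paste0("(((A:.05,B:.05):.3,(C:.05,D:.05):.3)",
                                     ":.3,((E:.05,F:.05):.3,(G:.05,H:.05)",
                                     ":.3):.3);"))
  aln <- sim_alignment(sp, 3000, rate = 0.3, seed = 53)
  tab <- scf(sp, aln, q = 100, seed = 2)
  expect_true(all(tab$scf > 80, na.rm = TRUE))
  # q larger than the number of distinct quartets => deterministic
  t1 <- scf(sp, aln, q = 10000, seed = 3)
  t2 <- scf(sp, aln, q = 10000, seed = 4)
  expect_equal(t1$scf, t2$scf)
})

test_that("score classification uses the printed band edges", {
  expect_equal(classify_scores(c(80, 79.9, 29.9, 30), "gcf"),
               c("high", "moderate", "low", "moderate"))
  expect_equal(classify_scores(c(0.9, 0.89, 0.749), "support_pp"),
               c("high", "moderate", "low"))
  expect_equal(classify_scores(c(74.9, 75, 90), "support_bs"),
               c("low", "moderate", "high"))
  expect_error(classify_scores(1.2, "support_pp"), "range")
})

test_that("gCF-to-count conversion reproduces the printed worked example", {
  expect_equal(cf_concordant_count(37.4, 306), 114L)
  expect_equal(cf_concordant_count(100, 50), 50L)
  expect_equal(cf_concordant_count(0, 50), 0L)
})

test_that("clade recovery distinguishes recovered, absent and unresolved", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  clades <- list(ab = c("A", "B"), ax = c("A", "X"), de = c("D", "E"),
                 ac = c("A", "C"))
  rec <- clade_recovery(list(good = tr, star = star), clades)
  expect_equal(rec["ab", "good"], "recovered")
  expect_equal(rec["de", "good"], "recovered")
  expect_equal(rec["ac", "good"], "not_recovered")
  expect_true(is.na(rec["ax", "good"]))   # X absent
  expect_true(is.na(rec["ab", "star"]))   # unresolved node
})

test_that("CF long table has one row per clade and tree with NA propagation", {
  set.seed(54)
  sp <- sim_species_tree(7, seed = 54, ils_scale = 5)
  gts <- sim_gene_trees_msc(sp, 8, seed = 55)
  aln <- sim_alignment(sp, 1000, rate = 0.05, seed = 56)
  trees <- tree_collection(list(ape::unroot(sp), ape::unroot(sp)),
                           dataset = c("d1", "d1"), method = c("m1", "m2"))
  clades <- default_clades_for_test(sp)
  tab <- cf_heatmap_table(trees, clades,
                          gene_trees_by_dataset = list(d1 = gts),
                          supermatrix_by_dataset = list(d1 = aln),
                          q = 30, seed = 5)
  expect_equal(nrow(tab), length(clades) * length(trees))
  expect_true(all(tab$recovery[!is.na(tab$recovery)] %in%
                    c("recovered", "not_recovered")))
  expect_true(all(is.na(tab$gcf[tab$recovery != "recovered"])))
})

test_that("clade definitions round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("clade,tips", "c1,\"A, B\"", "c2,\"C,D,E\""), f)
  cl <- read_clades(f)
  expect_equal(cl$c1, c("A", "B"))
  expect_equal(cl$c2, c("C", "D", "E"))
})
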