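test_that("JC distance matches the closed form and inverts the p-map", {
  a <- c(rep("A", 90), rep("C", 10))
  b <- c(rep("A", 90), rep("G", 10))
  expect_equal(ml_distance(a, a), 0)
  expect_equal(ml_distance(a, b), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-9)
  expect_equal(ml_distance(a, b), 0.107326, tolerance = 1e-5)
  # saturated pair
  sat_a <- c(rep("A", 2), rep("C", 8)); sat_b <- c(rep("A", 2), rep("G", 8))
  expect_equal(ml_distance(sat_a, sat_b), Inf)
  expect_error(ml_distance(rep("-", 4), rep("A", 4)), "shared")
  # d(p(d')) = d' across the domain
  for (d in c(0.01, 0.1, 0.5, 1)) {
    p <- 0.75 * (1 - exp(-4 * d / 3))
    expect_equal(-0.75 * log(1 - 4 * p / 3), d, tolerance = 1e-9)
  }
})

test_that("vectorised distance matrix agrees with the pairwise routine", {
  a <- random_locus(6, 200, seed = 21)
  m <- unclass(a)
  m[sample(length(m), 100)] <- "N"
  a <- locus_aln(m, "m", "CDS")
  D <- ml_distance_matrix(a)
  mx <- -Inf
  for (i in 1:5) for (j in (i + 1):6) {
    d <- ml_distance(a[i, ], a[j, ])
    if (is.finite(d)) {
      expect_equal(D[i, j], d, tolerance = 1e-12)
      mx <- max(mx, d)
    }
  }
  # saturated pairs are imputed as largest finite distance + 1, flagged
  for (i in 1:5) for (j in (i + 1):6)
    if (is.infinite(ml_distance(a[i, ], a[j, ])))
      expect_equal(D[i, j], mx + 1, tolerance = 1e-12)
  expect_true(attr(D, "imputed"))
})

test_that("neighbor joining recovers additive distances exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
  expect_equal(sum(nj$edge.length), sum(ape::unroot(tr)$edge.length),
               tolerance = 1e-9)
  # taxon-order invariance
  perm <- sample(rownames(D))
  nj2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(nj, nj2), 0, ignore_attr = TRUE)
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("pruning likelihood matches the exhaustive state-sum oracle", {
  for (s in 1:4) {
    tr <- rtree_labeled(sample(4:5, 1), seed = s)
    aln <- random_locus(length(tr$tip.label), 6, seed = 100 + s)
    rownames(aln) <- tr$tip.label
    m <- unclass(aln)
    m[1, 2] <- "N"  # exercise missing-data marginalisation
    aln <- locus_aln(m, "o", "CDS")
    expect_equal(site_loglik(tr, aln), oracle_site_loglik(tr, aln),
                 tolerance = 1e-9)
  }
})

test_that("likelihood limits, additivity and rerooting invariance hold", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- locus_aln(matrix("A", 4, 1, dimnames = list(LETTERS[1:4], NULL)),
                   "one", "CDS")
  expect_equal(site_loglik(tr, aln), log(0.25), tolerance = 1e-12)
  tr2 <- rtree_labeled(6, seed = 9)
  aln2 <- random_locus(6, 40, seed = 10)
  rownames(aln2) <- tr2$tip.label
  sl <- site_loglik(tr2, aln2)
  expect_equal(sum(sl), sum(site_loglik(tr2, aln2)))
  rerooted <- ape::root(tr2, outgroup = tr2$tip.label[1],
                        resolve.root = TRUE)
  expect_equal(sum(site_loglik(rerooted, aln2)), sum(sl), tolerance = 1e-8)
  # cross-check against an independent likelihood implementation
  fit <- phangorn::pml(tr2, phangorn::phyDat(unclass(aln2), type = "DNA"),
                       model = "JC")
  expect_equal(sum(sl), fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimisation is consistent and idempotent", {
  # two sequences: optimised length equals the ML pairwise distance
  t2 <- ape::read.tree(text = "(A:0.05,B:0.05);")
  aln <- sim_alignment(t2, 4000, rate = 1, seed = 11)
  d <- ml_distance(aln["A", ], aln["B", ])
  o <- optimize_branch_lengths(ape::read.tree(text = "(A:0.2,B:0.2);"), aln)
  expect_equal(sum(o$edge.length), d, tolerance = 1e-4)
  # long alignment on a known tree: recovered lengths within 10%
  truth <- ape::read.tree(text = "((A:0.08,B:0.12):0.06,(C:0.1,D:0.15):0.09);")
  big <- sim_alignment(truth, 10000, rate = 1, seed = 12)
  fit <- suppressWarnings(optimize_branch_lengths(truth, big))
  expect_true(all(abs(fit$edge.length - truth$edge.length) <
                    pmax(0.1 * truth$edge.length, 0.01)))
  # re-optimising an optimum changes the likelihood by < 1e-6
  again <- suppressWarnings(optimize_branch_lengths(fit, big))
  expect_lt(abs(attr(again, "loglik") - attr(fit, "loglik")), 1e-4)
})
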