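test_that("gap-threshold trimming applies the stated column rule", {
  # 5 sequences; columns with 5, 4, 3 gaps: only the all-gap column falls
  m <- rbind(s1 = c("-", "-", "-", "A"), s2 = c("-", "-", "A", "A"),
             s3 = c("-", "-", "A", "A"), s4 = c("-", "A", "A", "A"),
             s5 = c("-", "A", "A", "A"))
  a <- locus_aln(m, "t", "CDS")
  tr <- trim_gapped_columns(a, gt = 0.2)
  expect_equal(ncol(tr), 3L)
  # gap-free alignment is untouched
  clean <- random_locus(5, 20, seed = 3)
  expect_equal(unclass(trim_gapped_columns(clean)), unclass(clean),
               ignore_attr = TRUE)
  # idempotence
  expect_equal(unclass(trim_gapped_columns(tr, 0.2)), unclass(tr),
               ignore_attr = TRUE)
  expect_error(trim_gapped_columns(a, gt = 0), "gt")
})

test_that("Bowker symmetry statistic, df and p-value follow the definition", {
  # n_AG = 10, n_GA = 0 only
  si <- c(rep("A", 10), rep("C", 5))
  sj <- c(rep("G", 10), rep("C", 5))
  tst <- bowker_symmetry_test(si, sj)
  expect_equal(tst$statistic, 10)
  expect_equal(tst$df, 1L)
  expect_equal(tst$p.value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(tst$p.value, 0.001565, tolerance = 1e-3)
  # symmetric counts and identical sequences: statistic 0, p 1
  sym_i <- c("A", "G", "C", "T"); sym_j <- c("G", "A", "T", "C")
  expect_equal(bowker_symmetry_test(sym_i, sym_j)$statistic, 0)
  expect_equal(bowker_symmetry_test(sym_i, sym_j)$p.value, 1)
  same <- random_locus(2, 50, seed = 4)
  tst2 <- bowker_symmetry_test(same[1, ], same[1, ])
  expect_equal(tst2$statistic, 0)
  expect_equal(tst2$p.value, 1)
  expect_error(bowker_symmetry_test(rep("-", 5), rep("A", 5)), "shared")
})

test_that("symmetry filter removes asymmetric loci and honours alpha", {
  asym <- locus_aln(rbind(a = c(rep("A", 40), rep("C", 60)),
                          b = c(rep("G", 40), rep("C", 60))), "bad", "CDS")
  ok <- sim_alignment(ape::read.tree(text = "(A:0.05,B:0.05);"), 200,
                      rate = 1, seed = 5, locus_id = "ok")
  res <- filter_loci_symtest(list(bad = asym, ok = ok), alpha = 0.05)
  expect_equal(res$report$removed, c(TRUE, FALSE))
  expect_length(res$kept, 1)
  # alpha = 0 removes nothing
  res0 <- filter_loci_symtest(list(bad = asym), alpha = 0)
  expect_length(res0$removed, 0)
  # untestable loci are kept and flagged
  tiny <- locus_aln(rbind(a = rep("A", 10), b = rep("A", 10)), "tiny", "CDS")
  rest <- filter_loci_symtest(list(tiny), min_overlap = 50)
  expect_false(rest$report$testable[1])
  expect_length(rest$kept, 1)
})

test_that("symmetry-test type-I error is near nominal under a null model", {
  # sequences diverged under JC (stationary, reversible): expect ~5%
  set.seed(77)
  n_rep <- 400
  rej <- logical(n_rep)
  t2 <- ape::read.tree(text = "(A:0.15,B:0.15);")
  for (r in seq_len(n_rep)) {
    a <- sim_alignment(t2, 400, rate = 1)
    p <- bowker_symmetry_test(a["A", ], a["B", ])$p.value
    rej[r] <- p < 0.05
  }
  # binomial 99% envelope around 0.05
  half <- 2.58 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), half + 0.01)
})

test_that("parsimony-informative sites follow the 2x2 definition", {
  a <- locus_aln(rbind(w = c("A", "A", "A"), x = c("A", "C", "A"),
                       y = c("T", "G", "C"), z = c("T", "T", "C")),
                 "p", "CDS")
  expect_equal(count_pis(a), 2L)
  inv <- locus_aln(matrix("A", 4, 10,
                          dimnames = list(letters[1:4], NULL)), "i", "CDS")
  expect_equal(count_pis(inv), 0L)
  # singleton state does not count
  edge <- locus_aln(rbind(a = "A", b = "A", c = "T", d = "-"), "e", "CDS")
  expect_equal(count_pis(edge), 0L)
  # invariance under row and column permutation
  r <- random_locus(6, 50, seed = 6)
  perm <- locus_aln(unclass(r)[sample(6), sample(50)], "perm", "CDS")
  expect_equal(count_pis(perm), count_pis(r))
})

test_that("dataset summary arithmetic and composition are correct", {
  l1 <- random_locus(4, 100, seed = 7)
  l2 <- random_locus(4, 200, seed = 8)
  s <- summarize_dataset(list(l1, l2), "mix")
  expect_equal(s$total_length, 300)
  expect_equal(s$min_len, 100)
  expect_equal(s$max_len, 200)
  expect_equal(s$mean_len, 150)
  expect_equal(s$at_pct + s$gc_pct, 100, tolerance = 0.1)
  expect_equal(s$pis_pct, 100 * s$pis / s$total_length)
  allA <- locus_aln(matrix("A", 3, 10,
                           dimnames = list(letters[1:3], NULL)), "a", "CDS")
  sa <- summarize_dataset(list(allA), "A")
  expect_equal(sa$gc_pct, 0)
  expect_equal(sa$at_pct, 100)
  expect_equal(sa$missing_pct, 0)
})
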