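#' Remove heavily gapped alignment columns
#'
#' Retains exactly the columns whose fraction of non-gap characters is at
#' least `gt` — i.e. removes columns gapped in more than `1 - gt` of the
#' sequences (the classic gap-threshold trim). Only `-` counts as a gap
#' here; `N` is missing for the statistics but is a residue for trimming.
#'
#' @param aln A [locus_aln].
#' @param gt Minimum fraction of non-gap characters per retained column,
#'   in `(0, 1]`.
#' @return The trimmed [locus_aln] (column order preserved).
#' @export
trim_gapped_columns <- function(aln, gt = 0.2) {
  stopifnot(gt > 0, gt <= 1)
  if (ncol(aln) == 0 || nrow(aln) == 0) stop("empty alignment")
  nongap <- colMeans(unclass(aln) != "-")
  keep <- nongap >= gt
  if (!any(keep))
    keep[1] <- TRUE  # never emit a zero-length alignment
  aln[, keep]
}

#' Matched-pairs (Bowker) test of symmetry for two aligned sequences
#'
#' Tests whether the joint substitution pattern between two sequences is
#' symmetric, i.e. whether the divergence process could be stationary and
#' reversible. With `n_xy` the number of sites showing state `x` in one
#' sequence and `y` in the other, the statistic is
#' `sum over x < y of (n_xy - n_yx)^2 / (n_xy + n_yx)` over pairs with a
#' nonzero denominator, chi-squared with one degree of freedom per such
#' pair under the null.
#'
#' @param seq_i,seq_j Character vectors (aligned rows).
#' @return List with `statistic`, `df`, `p.value` (`df = 0` gives p = 1).
#' @export
bowker_symmetry_test <- function(seq_i, seq_j) {
  ok <- is_called(seq_i) & is_called(seq_j)
  if (!any(ok)) stop("undefined test: no shared called sites")
  a <- factor(seq_i[ok], levels = c("A", "C", "G", "T"))
  b <- factor(seq_j[ok], levels = c("A", "C", "G", "T"))
  n <- table(a, b)
  num <- (n - t(n))^2
  den <- n + t(n)
  use <- upper.tri(n) & den > 0
  stat <- sum(num[use] / den[use])
  df <- sum(use)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

#' Filter loci by the matched-pairs symmetry test
#'
#' For each locus, Bowker tests are run over all taxon pairs sharing at
#' least `min_overlap` called sites; the locus-level p-value is that of the
#' pair with the largest test statistic (no multiple-testing correction,
#' mirroring the max-pair heuristic of alignment-screening tools). Loci
#' with `p < alpha` are removed; loci with no testable pair are kept and
#' flagged.
#'
#' @param loci List of [locus_aln] objects.
#' @param alpha Rejection level (default 0.05).
#' @param min_overlap Minimum shared called sites per tested pair.
#' @return List with `kept`, `removed` (both lists of loci) and `report`
#'   (data frame: locus_id, class, statistic, df, p, testable, removed).
#' @export
filter_loci_symtest <- function(loci, alpha = 0.05, min_overlap = 50L) {
  rows <- vector("list", length(loci))
  removed <- logical(length(loci))
  for (k in seq_along(loci)) {
    aln <- loci[[k]]
    called <- is_called(unclass(aln))
    best <- NULL
    n <- nrow(aln)
    if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sum(called[i, ] & called[j, ]) < min_overlap) next
      tst <- bowker_symmetry_test(aln[i, ], aln[j, ])
      if (is.null(best) || tst$statistic > best$statistic) best <- tst
    }
    testable <- !is.null(best)
    p <- if (testable) best$p.value else NA_real_
    removed[k] <- testable && p < alpha
    rows[[k]] <- data.frame(
      locus_id = attr(aln, "locus_id"),
      class = attr(aln, "class_tag"),
      statistic = if (testable) best$statistic else NA_real_,
      df = if (testable) best$df else NA_integer_,
      p = p, testable = testable, removed = removed[k])
  }
  list(kept = loci[!removed], removed = loci[removed],
       report = do.call(rbind, rows))
}

#' Count parsimony-informative sites
#'
#' A column is parsimony informative when it shows at least two distinct
#' called states, each present in at least two sequences; gaps and `N` are
#' ignored.
#'
#' @param aln A [locus_aln].
#' @return Integer count.
#' @export
count_pis <- function(aln) {
  if (ncol(aln) == 0) stop("empty alignment")
  m <- unclass(aln)
  pis_col <- function(col) {
    col <- col[is_called(col)]
    if (length(col) < 4) return(FALSE)
    tab <- table(col)
    sum(tab >= 2) >= 2
  }
  sum(apply(m, 2, pis_col))
}

#' Per-dataset alignment summary
#'
#' Emits the usual multi-locus summary columns: total concatenated length,
#' parsimony-informative sites (count and percent), AT and GC content over
#' called bases, locus-length range and mean, and the overall missing-data
#' percentage (gap or `N` cells).
#'
#' @param loci List of [locus_aln] objects (>= 1).
#' @param dataset Label for the summary row.
#' @return One-row data frame of class `summary_table`.
#' @export
summarize_dataset <- function(loci, dataset = "dataset") {
  stopifnot(length(loci) >= 1)
  lens <- vapply(loci, ncol, integer(1))
  pis <- sum(vapply(loci, count_pis, numeric(1)))
  cells <- vapply(loci, function(l) length(unclass(l)), numeric(1))
  miss <- vapply(loci, function(l) sum(l == "-" | l == "N"), numeric(1))
  at <- sum(vapply(loci, function(l) sum(l == "A" | l == "T"), numeric(1)))
  gc <- sum(vapply(loci, function(l) sum(l == "G" | l == "C"), numeric(1)))
  out <- data.frame(
    dataset = dataset,
    n_loci = length(loci),
    total_length = sum(lens),
    pis = pis,
    pis_pct = 100 * pis / sum(lens),
    at_pct = 100 * at / (at + gc),
    gc_pct = 100 * gc / (at + gc),
    min_len = min(lens),
    max_len = max(lens),
    mean_len = mean(lens),
    missing_pct = 100 * sum(miss) / sum(cells))
  class(out) <- c("summary_table", "data.frame")
  out
}
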