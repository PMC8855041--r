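#' RELL resampling of a per-site log-likelihood matrix
#'
#' Resampling estimated log-likelihood: per replicate, `round(scale * n)`
#' sites are drawn with replacement (the same draw shared by all trees) and
#' each tree's replicate log-likelihood is the sum of its per-site values
#' over the draw. Identical per-site columns are collapsed internally and
#' the draw is made multinomially over the collapsed columns, which is
#' distributionally identical and much faster.
#'
#' @param L Numeric matrix, trees x sites, of per-site log-likelihoods.
#' @param B Number of replicates.
#' @param scale Resampling scale (1 = ordinary bootstrap).
#' @param seed Optional seed.
#' @return Matrix, trees x B, of replicate total log-likelihoods.
#' @export
rell_resample <- function(L, B, scale = 1, seed = NULL) {
  if (length(L) == 0) stop("empty site log-likelihood matrix")
  stopifnot(scale > 0, B >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(L)
  m <- max(1L, round(scale * n))
  # collapse identical columns
  key <- apply(round(L, 12), 2, paste, collapse = ",")
  fk <- factor(key, levels = unique(key))
  first <- !duplicated(fk)
  Lc <- L[, first, drop = FALSE]
  w <- as.numeric(table(fk))
  counts <- stats::rmultinom(B, size = m, prob = w / n)
  R <- Lc %*% counts
  rownames(R) <- rownames(L)
  R
}

#' Test configuration for RELL topology tests
#'
#' @param B RELL replicate count (>= 100).
#' @param scales Resampling scales for the multiscale (AU) fit; must
#'   include 1.
#' @param alpha Rejection level.
#' @param seed Optional seed.
#' @return A `test_config` list.
#' @export
test_config <- function(B = 10000L, scales = seq(0.5, 1.4, by = 0.1),
                        alpha = 0.05, seed = NULL) {
  stopifnot(B >= 100, any(abs(scales - 1) < 1e-9), alpha > 0, alpha < 1)
  structure(list(B = as.integer(B), scales = scales, alpha = alpha,
                 seed = seed), class = "test_config")
}

#' Shimodaira-Hasegawa test from per-site log-likelihoods
#'
#' For each tree `t`, `delta_t` is the log-likelihood gap to the best tree.
#' RELL replicates at scale 1 are centred per tree (replicate value minus
#' that tree's replicate mean), and the null gap for replicate `b` is
#' `max_s R[s, b] - R[t, b]`; the p-value is the fraction of replicates
#' whose null gap reaches `delta_t`. The best tree always receives p = 1.
#'
#' @param L Numeric matrix, trees x sites.
#' @param cfg A [test_config].
#' @return Numeric p-value per tree (named as `rownames(L)`).
#' @export
sh_test <- function(L, cfg = test_config()) {
  if (nrow(L) < 2) {
    p <- rep(1, nrow(L)); names(p) <- rownames(L); return(p)
  }
  tot <- rowSums(L)
  delta <- max(tot) - tot
  R <- rell_resample(L, cfg$B, scale = 1, seed = cfg$seed)
  Rc <- R - rowMeans(R)
  Dmat <- matrix(apply(Rc, 2, max), nrow(L), cfg$B, byrow = TRUE) - Rc
  p <- vapply(seq_len(nrow(L)), function(t) mean(Dmat[t, ] >= delta[t]),
              numeric(1))
  names(p) <- rownames(L)
  p
}

#' Approximately-unbiased test from per-site log-likelihoods
#'
#' Multiscale RELL: at each scale `r` the bootstrap proportion `BP(t, r)`
#' is the fraction of replicates in which tree `t` attains the maximum
#' (ties split equally). The normal quantiles `z = qnorm(1 - BP)` are
#' fitted by weighted least squares to `d * sqrt(r) + c / sqrt(r)`
#' (weights from the binomial variance of BP), giving
#' `p_AU = 1 - pnorm(d - c)`. BP values of 0 or 1 are clipped to
#' `1/(2B)` and `1 - 1/(2B)`; a tree degenerate at every scale gets p = 0
#' or 1 directly (flagged in the `"degenerate"` attribute).
#'
#' @param L Numeric matrix, trees x sites.
#' @param cfg A [test_config] (needs >= 2 scales).
#' @return Numeric p-value per tree; attribute `"degenerate"` marks trees
#'   whose BP was clipped at every scale.
#' @export
au_test <- function(L, cfg = test_config()) {
  stopifnot(nrow(L) >= 2, length(cfg$scales) >= 2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nt <- nrow(L)
  BP <- matrix(0, nt, length(cfg$scales))
  for (si in seq_along(cfg$scales)) {
    R <- rell_resample(L, cfg$B, scale = cfg$scales[si])
    mx <- apply(R, 2, max)
    isamax <- sweep(R, 2, mx, `>=`)
    share <- sweep(isamax, 2, colSums(isamax), `/`)
    BP[, si] <- rowSums(share) / cfg$B
  }
  lo <- 1 / (2 * cfg$B); hi <- 1 - lo
  clipped <- BP <= lo | BP >= hi
  BPc <- pmin(pmax(BP, lo), hi)
  degenerate <- apply(clipped, 1, all)
  p <- numeric(nt)
  sq <- sqrt(cfg$scales)
  for (t in seq_len(nt)) {
    if (degenerate[t]) {
      p[t] <- if (mean(BP[t, ]) > 0.5) 1 else 0
      next
    }
    z <- stats::qnorm(1 - BPc[t, ])
    w <- (stats::dnorm(z)^2 * cfg$B) / (BPc[t, ] * (1 - BPc[t, ]))
    X <- cbind(sq, 1 / sq)
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("AU curve fit failed for tree ", t, "; SH p substituted")
      p[t] <- sh_test(L, cfg)[t]
    } else {
      d <- fit$coefficients[1]; cc <- fit$coefficients[2]
      p[t] <- 1 - stats::pnorm(d - cc)
    }
  }
  names(p) <- rownames(L)
  attr(p, "degenerate") <- degenerate
  p
}

#' Compare candidate species trees against a fixed reference tree
#'
#' Branch lengths of the fixed tree and every candidate are optimised by
#' maximum likelihood on the evaluation alignment (candidates are pruned
#' to the alignment's taxa beforehand with [harmonize_trees] if needed);
#' the per-site log-likelihood matrix then feeds the SH and AU tests.
#' Identical topologies share one optimisation (they are indistinguishable
#' given the fixed alignment).
#'
#' @param fixed `phylo` reference tree.
#' @param candidates [tree_collection] or list of `phylo` with the same
#'   leaf set as `fixed`.
#' @param eval_alignment [locus_aln] supermatrix covering all leaves.
#' @param cfg A [test_config].
#' @param model A [substitution_model].
#' @return A `toptest_report` data frame: dataset, tree, lnL, delta,
#'   p_SH, SH, p_AU, AU (`+` accepted / `-` rejected at `cfg$alpha`).
#' @export
compare_to_fixed <- function(fixed, candidates, eval_alignment,
                             cfg = test_config(),
                             model = substitution_model("JC69")) {
  key <- attr(candidates, "key")
  cand <- if (inherits(candidates, "tree_collection"))
    unclass(candidates) else candidates
  all_trees <- c(list(fixed = fixed), cand)
  # drop supports; unify leaf sets check
  taxa <- sort(fixed$tip.label)
  for (t in all_trees)
    if (!setequal(t$tip.label, taxa))
      stop("candidate leaf set differs from fixed tree; harmonize first")
  # one optimisation per distinct unrooted topology
  hashes <- vapply(all_trees, function(t)
    paste(sort(tree_splits(t)), collapse = ";"), character(1))
  Lrows <- vector("list", length(all_trees))
  cache <- list()
  for (i in seq_along(all_trees)) {
    h <- hashes[i]
    if (is.null(cache[[h]])) {
      tr <- ape::unroot(all_trees[[i]])
      tr$node.label <- NULL
      opt <- optimize_branch_lengths(tr, eval_alignment, model)
      cache[[h]] <- attr(opt, "site_loglik")
    }
    Lrows[[i]] <- cache[[h]]
  }
  L <- do.call(rbind, Lrows)
  rownames(L) <- names(all_trees)
  p_sh <- sh_test(L, cfg)
  p_au <- au_test(L, cfg)
  tot <- rowSums(L)
  idx <- seq_along(all_trees)[-1]
  out <- data.frame(
    dataset = if (!is.null(key)) key$dataset else NA_character_,
    tree = if (!is.null(key)) key$method else names(cand),
    lnL = tot[idx],
    delta = max(tot) - tot[idx],
    p_SH = p_sh[idx],
    SH = ifelse(p_sh[idx] < cfg$alpha, "-", "+"),
    p_AU = p_au[idx],
    AU = ifelse(p_au[idx] < cfg$alpha, "-", "+"),
    row.names = NULL)
  attr(out, "fixed") <- c(lnL = tot[1], p_SH = p_sh[1], p_AU = p_au[1])
  attr(out, "site_loglik") <- L
  class(out) <- c("toptest_report", "data.frame")
  out
}
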