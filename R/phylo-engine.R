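#' Nucleotide substitution model
#'
#' JC69 (equal rates, equal frequencies) or HKY85 (transition/transversion
#' ratio `kappa`, arbitrary stationary frequencies). Both are time
#' reversible; transition probabilities are computed from the spectral
#' decomposition of the rate matrix, normalised so branch lengths are
#' expected substitutions per site.
#'
#' @param model `"JC69"` or `"HKY85"`.
#' @param kappa Transition/transversion rate ratio (HKY85 only).
#' @param freq Stationary base frequencies (A, C, G, T), summing to 1.
#' @return A `substitution_model` list with the eigendecomposition cached.
#' @export
substitution_model <- function(model = c("JC69", "HKY85"), kappa = 2,
                               freq = rep(0.25, 4)) {
  model <- match.arg(model)
  stopifnot(length(freq) == 4, all(freq > 0),
            abs(sum(freq) - 1) < 1e-12, kappa > 0)
  if (model == "JC69") freq <- rep(0.25, 4)
  # rate matrix, order A C G T; transitions: A<->G, C<->T
  k <- if (model == "JC69") 1 else kappa
  R <- matrix(1, 4, 4)
  R[1, 3] <- R[3, 1] <- k
  R[2, 4] <- R[4, 2] <- k
  Q <- R * rep(freq, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  # symmetrise for a stable eigendecomposition: S = D^1/2 Q D^-1/2
  d <- sqrt(freq)
  S <- diag(d) %*% Q %*% diag(1 / d)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(model = model, kappa = kappa, freq = freq, Q = Q,
                 eval = es$values,
                 U = diag(1 / d) %*% es$vectors,
                 Uinv = t(es$vectors) %*% diag(d)),
            class = "substitution_model")
}

# transition probability matrix P(t) = exp(Qt)
model_pmatrix <- function(model, t) {
  if (t <= 0) return(diag(4))
  P <- model$U %*% (exp(model$eval * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Maximum-likelihood pairwise distance
#'
#' JC69 uses the closed form `d = -(3/4) log(1 - (4/3) p)` with `p` the
#' mismatch fraction over shared called sites; `p >= 0.75` returns `Inf`.
#' HKY85 maximises the two-sequence likelihood numerically.
#'
#' @param seq_i,seq_j Character vectors (aligned rows).
#' @param model A [substitution_model].
#' @return Distance in expected substitutions per site (possibly `Inf`).
#' @export
ml_distance <- function(seq_i, seq_j, model = substitution_model("JC69")) {
  ok <- is_called(seq_i) & is_called(seq_j)
  n <- sum(ok)
  if (n == 0) stop("undefined distance: no shared called sites")
  if (model$model == "JC69") {
    p <- sum(seq_i[ok] != seq_j[ok]) / n
    if (p >= 0.75) return(Inf)
    return(-0.75 * log(1 - 4 * p / 3))
  }
  nt <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  a <- nt[seq_i[ok]]; b <- nt[seq_j[ok]]
  counts <- table(factor(a, levels = 1:4), factor(b, levels = 1:4))
  nll <- function(d) {
    P <- model_pmatrix(model, d)
    L <- log(pmax(model$freq * P, 1e-300))
    -sum(counts * L)
  }
  if (all(a == b)) return(0)
  opt <- stats::optimize(nll, c(1e-8, 20))
  if (nll(20 - 1e-6) < opt$objective) return(Inf)
  opt$minimum
}

#' Pairwise ML distance matrix for an alignment
#'
#' Infinite distances (saturated pairs) are imputed as the largest finite
#' distance plus 1 and flagged via the `"imputed"` attribute.
#'
#' @param aln A [locus_aln].
#' @param model A [substitution_model].
#' @param min_overlap Pairs sharing fewer called sites than this are treated
#'   as saturated.
#' @return A symmetric matrix with zero diagonal.
#' @export
ml_distance_matrix <- function(aln, model = substitution_model("JC69"),
                               min_overlap = 1L) {
  n <- nrow(aln)
  m <- unclass(aln)
  called <- is_called(m)
  if (model$model == "JC69") {
    # vectorised: shared called sites and matches via crossproducts
    C <- matrix(as.numeric(called), n)
    shared <- tcrossprod(C)
    eq <- matrix(0, n, n)
    for (s in c("A", "C", "G", "T")) {
      I <- matrix(as.numeric(m == s), n)
      eq <- eq + tcrossprod(I)
    }
    p <- ifelse(shared > 0, (shared - eq) / shared, NA)
    D <- matrix(Inf, n, n, dimnames = list(rownames(aln), rownames(aln)))
    ok <- !is.na(p) & p < 0.75 & shared >= min_overlap
    D[ok] <- -0.75 * log1p(-4 * p[ok] / 3)
    diag(D) <- 0
  } else {
    D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- called[i, ] & called[j, ]
      if (sum(ok) < min_overlap) d <- Inf
      else d <- ml_distance(aln[i, ], aln[j, ], model)
      D[i, j] <- D[j, i] <- d
    }
  }
  imputed <- which(is.infinite(D), arr.ind = TRUE)
  if (nrow(imputed)) {
    mx <- max(D[is.finite(D)], 0)
    D[is.infinite(D)] <- mx + 1
  }
  attr(D, "imputed") <- nrow(imputed) > 0
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj]); negative estimated branch lengths
#' are clamped to zero.
#'
#' @param D Symmetric distance matrix with zero diagonal; `Inf` entries are
#'   imputed as in [ml_distance_matrix].
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(is.infinite(D))) {
    mx <- max(D[is.finite(D)], 0)
    D[is.infinite(D)] <- mx + 1
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# alignment -> compressed site patterns
# returns list(index: per-tip state 1..4 / 5=missing matrix [tips x patterns],
#              weight: pattern multiplicities, map: site -> pattern)
compress_patterns <- function(aln, taxa = rownames(aln)) {
  m <- unclass(aln)[taxa, , drop = FALSE]
  code <- matrix(5L, nrow(m), ncol(m))
  nt <- c("A", "C", "G", "T")
  for (s in 1:4) code[m == nt[s]] <- s
  key <- apply(code, 2, paste, collapse = ",")
  fk <- factor(key, levels = unique(key))
  map <- as.integer(fk)
  first <- !duplicated(map)
  list(states = code[, first, drop = FALSE],
       weight = as.numeric(table(fk)),
       map = map, taxa = taxa)
}

# Felsenstein pruning on compressed patterns.
# Returns per-pattern log-likelihood vector.
pruning_loglik_patterns <- function(tree, pat, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P_ <- ncol(pat$states)
  tipidx <- match(tree$tip.label, pat$taxa)
  if (anyNA(tipidx)) stop("tree leaf missing from alignment")
  eo <- ape::reorder.phylo(tree, "postorder")
  edges <- eo$edge
  elens <- eo$edge.length
  partial <- vector("list", nn)
  for (i in seq_len(ntip)) {
    st <- pat$states[tipidx[i], ]
    M <- matrix(0, 4, P_)
    miss <- st == 5L
    if (any(miss)) M[, miss] <- 1
    obs <- which(!miss)
    if (length(obs)) M[cbind(st[obs], obs)] <- 1
    partial[[i]] <- M
  }
  scale_log <- numeric(P_)
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    P <- model_pmatrix(model, elens[k])
    contrib <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- contrib
    else {
      partial[[p]] <- partial[[p]] * contrib
      mx <- apply(partial[[p]], 2, max)
      low <- mx < 1e-250 & mx > 0
      if (any(low)) {
        partial[[p]][, low] <- partial[[p]][, low] / rep(mx[low], each = 4)
        scale_log[low] <- scale_log[low] + log(mx[low])
      }
    }
  }
  root <- ntip + 1L
  lik <- colSums(model$freq * partial[[root]])
  log(pmax(lik, 1e-300)) + scale_log
}

#' Per-site log-likelihood of a tree given an alignment
#'
#' Felsenstein pruning over compressed site patterns; gaps and `N`
#' contribute partial likelihood 1 over all states; stationary frequencies
#' are used at the root (valid at any rooting for reversible models).
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param aln A [locus_aln] containing every tree leaf.
#' @param model A [substitution_model].
#' @return Numeric vector of per-site log-likelihoods (length `ncol(aln)`).
#' @export
site_loglik <- function(tree, aln, model = substitution_model("JC69")) {
  pat <- compress_patterns(aln, taxa = rownames(aln))
  lp <- pruning_loglik_patterns(tree, pat, model)
  lp[pat$map]
}

# down (tip-ward) partials for every node, plus per-node message matrices
# m[[edge]] = P(t_e) %*% D[child(e)]; no scaling (fine at desk problem sizes
# where per-site likelihoods stay far from the double-precision floor)
tree_partials <- function(tree, pat, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P_ <- ncol(pat$states)
  tipidx <- match(tree$tip.label, pat$taxa)
  if (anyNA(tipidx)) stop("tree leaf missing from alignment")
  eo <- ape::reorder.phylo(tree, "postorder")
  edges <- eo$edge; elens <- eo$edge.length
  D <- vector("list", nn)
  for (i in seq_len(ntip)) {
    st <- pat$states[tipidx[i], ]
    M <- matrix(0, 4, P_)
    miss <- st == 5L
    if (any(miss)) M[, miss] <- 1
    obs <- which(!miss)
    if (length(obs)) M[cbind(st[obs], obs)] <- 1
    D[[i]] <- M
  }
  msg <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    msg[[k]] <- model_pmatrix(model, elens[k]) %*% D[[ch]]
    D[[p]] <- if (is.null(D[[p]])) msg[[k]] else D[[p]] * msg[[k]]
  }
  # up partials: U[root] = freq; child via leave-one-out product of sibling
  # messages times the parent's own up partial
  U <- vector("list", nn)
  root <- ntip + 1L
  U[[root]] <- matrix(model$freq, 4, P_)
  kids_rows <- split(seq_len(nrow(edges)), edges[, 1])
  Uedge <- vector("list", nrow(edges))
  for (k in rev(seq_len(nrow(edges)))) {   # preorder: parents first
    p <- edges[k, 1]; ch <- edges[k, 2]
    sibs <- setdiff(kids_rows[[as.character(p)]], k)
    acc <- U[[p]]
    for (s in sibs) acc <- acc * msg[[s]]
    Uedge[[k]] <- acc
    if (ch > ntip)
      U[[ch]] <- crossprod(model_pmatrix(model, elens[k]), acc)
  }
  list(D = D, U = U, Uedge = Uedge, edges = edges, elens = elens)
}

#' Optimize branch lengths on a fixed topology
#'
#' Sweeps of edge-wise optimisation: per sweep, tip-ward and root-ward
#' partial likelihoods are computed once, then every branch is optimised by
#' a bounded scalar search on `[0, max_len]` using only its two incident
#' partials; the joint update is accepted when it improves the total
#' log-likelihood (otherwise that sweep falls back to strictly cyclic
#' per-branch updates). Sweeping stops when the total improves by less
#' than `tol` or `max_sweeps` is reached.
#'
#' @param topology `phylo`; existing branch lengths are used as the start
#'   (missing lengths start at 0.05).
#' @param aln A [locus_aln].
#' @param model A [substitution_model].
#' @param max_len Upper bound per branch (substitutions/site).
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_sweeps Sweep cap; non-convergence sets the `"converged"`
#'   attribute to `FALSE` with a warning.
#' @return The tree with MLE branch lengths; attributes `"loglik"` (total),
#'   `"site_loglik"` (per-site vector) and `"converged"`.
#' @export
optimize_branch_lengths <- function(topology, aln,
                                    model = substitution_model("JC69"),
                                    max_len = 10, tol = 1e-6,
                                    max_sweeps = 20) {
  if (ncol(aln) < 1) stop("empty alignment")
  tr <- topology
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(0.05, nrow(tr$edge))
  tr$edge.length[!is.finite(tr$edge.length) | tr$edge.length < 0] <- 0.05
  tr$edge.length[tr$edge.length > max_len] <- max_len
  pat <- compress_patterns(aln, taxa = rownames(aln))
  total <- function(t) sum(pruning_loglik_patterns(t, pat, model) * pat$weight)
  cur <- total(tr)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    sweep_start <- cur
    prt <- tree_partials(tr, pat, model)
    new_len <- prt$elens
    for (k in seq_len(nrow(prt$edges))) {
      Dc <- prt$D[[prt$edges[k, 2]]]
      Ue <- prt$Uedge[[k]]
      f <- function(x)
        -sum(pat$weight *
               log(pmax(colSums(Ue * (model_pmatrix(model, x) %*% Dc)),
                        1e-300)))
      opt <- stats::optimize(f, c(0, max_len), tol = 1e-6)
      if (opt$objective < f(prt$elens[k])) new_len[k] <- opt$minimum
    }
    # map postorder edge order back onto tr$edge rows
    key_tr <- paste(tr$edge[, 1], tr$edge[, 2])
    key_po <- paste(prt$edges[, 1], prt$edges[, 2])
    rowmap <- match(key_po, key_tr)
    old_len <- tr$edge.length[rowmap]
    accepted <- FALSE
    # the independent per-edge optima can jointly overshoot when branch
    # lengths are strongly correlated (e.g. heavy missing data); damp the
    # step until the total likelihood improves
    for (alpha in c(1, 0.5, 0.25, 0.125)) {
      cand <- tr
      cand$edge.length[rowmap] <- old_len + alpha * (new_len - old_len)
      cand_ll <- total(cand)
      if (cand_ll > cur) {
        tr <- cand; cur <- cand_ll; accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # last resort: accept the single best improving edge, if any
      best_ll <- cur; best_tr <- NULL
      for (k in seq_along(rowmap)) {
        if (new_len[k] == old_len[k]) next
        cand <- tr
        cand$edge.length[rowmap[k]] <- new_len[k]
        ll <- total(cand)
        if (ll > best_ll) { best_ll <- ll; best_tr <- cand }
      }
      if (is.null(best_tr)) { converged <- TRUE; break }
      tr <- best_tr; cur <- best_ll
    }
    if (cur - sweep_start < tol) { converged <- TRUE; break }
  }
  if (!converged && max_sweeps > 1)
    warning("branch-length optimisation hit the sweep cap")
  lp <- pruning_loglik_patterns(tr, pat, model)
  attr(tr, "site_loglik") <- lp[pat$map]
  attr(tr, "loglik") <- sum(lp * pat$weight)
  attr(tr, "converged") <- converged
  tr
}
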