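# Phylogenetic signal: Blomberg's K for continuous traits (K ~ 1 under
# Brownian motion, K << 1 for labile/convergent traits) and the Fritz-Purvis
# D statistic for binary traits (D ~ 0 under threshold-Brownian evolution,
# D ~ 1 under phylogenetic randomness, D < 0 for extreme clumping).

# ratio MSE0/MSE for one or many trait vectors (columns of Y), given the
# inverse Brownian covariance of the tree. Vectorized so 999 permutations are
# a single matrix product.
k_ratio <- function(Y, Cinv) {
  Y <- as.matrix(Y)
  CY <- Cinv %*% Y
  denom <- sum(Cinv)
  ahat <- colSums(CY) / denom               # phylogenetically corrected mean
  R <- sweep(Y, 2L, ahat)
  mse0 <- colSums(R * R)
  mse <- colSums(R * (Cinv %*% R))
  mse0 / mse
}

#' Blomberg's K with permutation test
#'
#' `K = (MSE0/MSE)_obs / (MSE0/MSE)_expected`, where MSE0 is the mean squared
#' error about the phylogenetically corrected mean, MSE the generalized
#' least-squares error under the tree's Brownian covariance C, and the
#' Brownian-motion expectation is the closed form
#' `(tr(C) - n / sum(C^-1)) / (n - 1)` — exact, no simulation. The p-value
#' shuffles trait values across tips and recomputes the ratio; K itself is
#' invariant to affine transformation of the trait.
#'
#' @param tree phylo object with branch lengths.
#' @param trait numeric vector named by tip labels (or in tip order).
#' @param n_perm permutation replicates (default 999).
#' @param seed integer seed.
#' @return a one-row data.frame: trait, statistic ("K"), value, p, n_species,
#'   n_reps, seed.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  validate_phylogeny(tree)
  y <- align_trait(tree, trait)
  if (stats::sd(y) == 0) stopf("constant trait: K undefined")
  C <- ape::vcv(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stopf(paste("singular Brownian covariance (duplicate tips at zero",
                "distance?); merge or jitter zero-length tips")))
  n <- length(y)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  obs <- k_ratio(y, Cinv)
  K <- unname(obs / expected)
  p <- NA_real_
  if (n_perm > 0) {
    perms <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) sample(y), y))
    ratios <- k_ratio(perms, Cinv)
    p <- (sum(ratios >= obs) + 1) / (n_perm + 1)
  }
  data.frame(trait = trait_label(trait), statistic = "K", value = K, p = p,
             n_species = n, n_reps = n_perm,
             seed = if (is.null(seed)) NA_integer_ else seed)
}

# match a (possibly named) per-tip vector to tip order
align_trait <- function(tree, trait) {
  tips <- tree$tip.label
  if (!is.null(names(trait))) {
    miss <- setdiff(tips, names(trait))
    if (length(miss)) stopf("trait missing for tips: %s",
                            paste(utils::head(miss, 5L), collapse = ", "))
    trait <- trait[tips]
  } else if (length(trait) != length(tips)) {
    stopf("unnamed trait of length %d for %d tips", length(trait), length(tips))
  }
  if (anyNA(trait)) stopf("missing trait values")
  as.numeric(trait)
}

trait_label <- function(trait) {
  lb <- attr(trait, "label")
  if (is.null(lb)) "trait" else lb
}

# Fritz-Purvis d for a matrix of binary traits (columns): sum over edges of
# |change| in nodal values, nodal values estimated bottom-up as unweighted
# daughter means (postorder guarantees children are final before use).
fp_d_many <- function(tree, X) {
  X <- as.matrix(X)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  V <- matrix(0, nn, ncol(X))
  V[seq_len(n), ] <- X
  ksum <- matrix(0, nn, ncol(X))
  kn <- integer(nn)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    # child value is final by postorder; if child is internal, compute it now
    if (child > n && kn[child] > 0L) V[child, ] <- ksum[child, ] / kn[child]
    ksum[par, ] <- ksum[par, ] + V[child, ]
    kn[par] <- kn[par] + 1L
  }
  root <- po$edge[nrow(po$edge), 1L]
  V[root, ] <- ksum[root, ] / kn[root]
  # second pass: V is now final for all nodes; d = sum over edges |parent - child|
  colSums(abs(V[po$edge[, 1L], , drop = FALSE] - V[po$edge[, 2L], , drop = FALSE]))
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' The observed sum of sister-clade state differences `d_obs` (nodal values
#' estimated as unweighted daughter means) is scaled between two
#' prevalence-preserving references: random shuffles of the trait (`d_r`) and
#' threshold-Brownian evolution (`d_b`, a Brownian liability thresholded at
#' the empirical prevalence quantile per replicate):
#' `D = (d_obs - mean d_b) / (mean d_r - mean d_b)`. D is invariant to
#' swapping the 0/1 labels.
#'
#' @param tree phylo object.
#' @param trait 0/1 vector named by tip labels (or in tip order); both states
#'   must be present.
#' @param n_sim simulation replicates per reference (default 1000).
#' @param seed integer seed.
#' @return one-row data.frame: trait, statistic ("D"), value, p_random
#'   (P(d_r <= d_obs): small = more conserved than random), p_brownian
#'   (P(d_b <= d_obs)), n_species, n_reps, seed.
#' @export
fritz_purvis_d <- function(tree, trait, n_sim = 1000, seed = NULL) {
  validate_phylogeny(tree)
  x <- align_trait(tree, trait)
  if (!all(x %in% c(0, 1))) stopf("trait must be 0/1")
  k <- sum(x)
  n <- length(x)
  if (k == 0 || k == n) stopf("invariant binary trait: D undefined")
  if (k == 1 || k == n - 1) warnf("single-tip prevalence: D is unstable")
  d_obs <- fp_d_many(tree, matrix(x, ncol = 1L))
  M <- edge_tip_incidence(tree)              # edges x tips root-path incidence
  sd_edge <- sqrt(tree$edge.length)
  # d is invariant under set complement, so threshold at the minority-state
  # count: makes the reference streams (and hence D) exactly invariant to
  # swapping the 0/1 labels
  k_eff <- min(k, n - k)
  res <- with_seed(seed, {
    shuf <- vapply(seq_len(n_sim), function(i) sample(x), x)
    incr <- matrix(stats::rnorm(nrow(M) * n_sim, sd = sd_edge), nrow(M), n_sim)
    liab <- crossprod(M, incr)               # tips x n_sim Brownian liabilities
    thr <- apply(liab, 2L, function(l) l >= sort(l, decreasing = TRUE)[k_eff]) * 1
    list(d_r = fp_d_many(tree, shuf), d_b = fp_d_many(tree, thr))
  })
  mr <- mean(res$d_r); mb <- mean(res$d_b)
  D <- unname((d_obs - mb) / (mr - mb))
  data.frame(trait = trait_label(trait), statistic = "D", value = D,
             p_random = (sum(res$d_r <= d_obs) + 1) / (n_sim + 1),
             p_brownian = (sum(res$d_b <= d_obs) + 1) / (n_sim + 1),
             n_species = n, n_reps = n_sim,
             seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Batch phylogenetic-signal tests over a trait table
#'
#' Runs [blomberg_k()] on continuous columns and [fritz_purvis_d()] on binary
#' columns, one row per trait (the shape of a signal summary table).
#'
#' @param tree phylo object.
#' @param traits a [trait_table()].
#' @param n_perm,n_sim replicate counts for K and D.
#' @param seed master seed, split per trait.
#' @return data.frame: trait, type, statistic, value, p, p_random, p_brownian.
#' @export
signal_table <- function(tree, traits, n_perm = 999, n_sim = 1000, seed = NULL) {
  types <- trait_types(traits)
  out <- NULL
  for (j in seq_along(traits)) {
    nm <- names(traits)[j]
    x <- stats::setNames(traits[[j]], rownames(traits))
    attr(x, "label") <- nm
    sj <- if (is.null(seed)) NULL else split_seed(seed, nm)
    row <- if (types[j] == "continuous") {
      r <- blomberg_k(tree, x, n_perm = n_perm, seed = sj)
      data.frame(trait = nm, type = "continuous", statistic = "K",
                 value = r$value, p = r$p, p_random = NA_real_,
                 p_brownian = NA_real_)
    } else {
      r <- fritz_purvis_d(tree, x, n_sim = n_sim, seed = sj)
      data.frame(trait = nm, type = "binary", statistic = "D",
                 value = r$value, p = NA_real_, p_random = r$p_random,
                 p_brownian = r$p_brownian)
    }
    out <- rbind(out, row)
  }
  out
}
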