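# Per-site diversity indices on a site x species incidence matrix:
# species richness, Faith's PD (and its functional-dendrogram analogue FD),
# mean pairwise distance (MPD/MFD), and index intercorrelation.

#' Construct and validate a site x species incidence matrix
#'
#' @param x matrix or data.frame with sites in rows, species in columns,
#'   entries 0/1. A `site` column is used for row names if present.
#' @return an integer 0/1 matrix with dimnames.
#' @export
community_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("site" %in% names(x)) {
      rownames(x) <- x$site
      x$site <- NULL
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stopf("incidence matrix must be numeric")
  if (anyNA(x) || !all(x %in% c(0, 1))) stopf("incidence entries must be 0/1")
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (is.null(colnames(x))) stopf("species (column) labels required")
  if (anyDuplicated(colnames(x))) stopf("duplicated species labels")
  if (anyDuplicated(rownames(x))) stopf("duplicated site labels")
  storage.mode(x) <- "integer"
  x
}

#' Read / write a community CSV (sites in rows, species in columns)
#' @param file path to CSV with a `site` column.
#' @return incidence matrix.
#' @export
read_community_csv <- function(file) {
  community_matrix(utils::read.csv(file, check.names = FALSE))
}

#' @rdname read_community_csv
#' @param cm incidence matrix.
#' @export
write_community_csv <- function(cm, file) {
  utils::write.csv(cbind(site = rownames(cm), as.data.frame(cm)), file,
                   row.names = FALSE)
  invisible(file)
}

#' Species richness per site
#' @param cm incidence matrix.
#' @return named integer vector of row sums.
#' @export
species_richness <- function(cm) {
  cm <- community_matrix(cm)
  rowSums(cm)
}

# edges x tips incidence: M[e, t] = 1 iff tip t descends through edge e.
# Shared by PD and by branch-wise Brownian simulation.
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of <- integer(nn)                    # edge whose child is node k
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  M <- matrix(0L, nrow(tree$edge), n)
  for (t in seq_len(n)) {
    k <- t
    while (k != root) {
      M[edge_of[k], t] <- 1L
      k <- parent[k]
    }
  }
  dimnames(M) <- list(NULL, tree$tip.label)
  M
}

#' Faith's phylogenetic diversity (or dendrogram FD) per site
#'
#' PD of a site is the sum of branch lengths of the smallest subtree spanning
#' the species present. With `include_root = TRUE` (default) the path from
#' that subtree up to the root is counted, so single-species sites get their
#' tip's root-path length rather than zero. Passing the functional dendrogram
#' from [upgma()] instead of the phylogeny yields dendrogram-based FD.
#'
#' @param tree phylo object (phylogeny or functional dendrogram).
#' @param cm incidence matrix; species must all be tree tips.
#' @param include_root count branches above the site's MRCA up to the root.
#' @return named numeric vector of per-site PD values (0 for empty sites, with
#'   a warning).
#' @export
branch_length_diversity <- function(tree, cm, include_root = TRUE) {
  validate_phylogeny(tree)
  cm <- community_matrix(cm)
  missing <- setdiff(colnames(cm), tree$tip.label)
  if (length(missing))
    stopf("species not in tree: %s", paste(missing, collapse = ", "))
  M <- edge_tip_incidence(tree)[, colnames(cm), drop = FALSE]
  below <- M %*% t(cm)                      # edges x sites: present tips below edge
  sr <- rowSums(cm)
  # without the root path, an edge belongs to the spanning subtree iff it
  # separates present species (some below, some not); singletons then get 0
  keep <- if (include_root) below >= 1
          else sweep(below, 2L, sr, function(b, s) b >= 1 & b < s)
  pd <- as.numeric(crossprod(keep, tree$edge.length))
  names(pd) <- rownames(cm)
  if (any(sr == 0)) {
    warnf("%d empty site(s); PD reported as 0", sum(sr == 0))
    pd[sr == 0] <- 0
  }
  pd
}

#' Mean pairwise distance per site (MPD / MFD)
#'
#' Unweighted mean of `d(i, j)` over all unordered pairs of species present at
#' a site. Sites with fewer than two species are undefined and reported as
#' `NA` with a warning, so a batch over many sites never aborts.
#'
#' @param d symmetric distance matrix over species (patristic for MPD, Gower
#'   or cophenetic for MFD).
#' @param cm incidence matrix.
#' @return named numeric vector.
#' @export
mean_pairwise_distance <- function(d, cm) {
  validate_dissimilarity(d, tol = 1e-6)
  cm <- community_matrix(cm)
  missing <- setdiff(colnames(cm), rownames(d))
  if (length(missing))
    stopf("species not in distance matrix: %s", paste(missing, collapse = ", "))
  d <- d[colnames(cm), colnames(cm)]
  sr <- rowSums(cm)
  res <- vapply(seq_len(nrow(cm)), function(i) {
    idx <- which(cm[i, ] == 1L)
    if (length(idx) < 2L) return(NA_real_)
    sum(d[idx, idx]) / (length(idx) * (length(idx) - 1L))
  }, 0)
  names(res) <- rownames(cm)
  if (any(sr < 2L)) warnf("%d site(s) with SR < 2; MPD undefined (NA)", sum(sr < 2L))
  res
}

#' Assemble the per-site diversity table
#'
#' @param tree phylogeny; `dend` functional dendrogram; `d_phy`, `d_fun`
#'   optional precomputed distance matrices (patristic / cophenetic are used
#'   when `NULL`); `cm` incidence matrix; `include_root` as in
#'   [branch_length_diversity()].
#' @return data.frame with columns site, SR, PD, FD, MPD, MFD.
#' @export
diversity_table <- function(tree, dend, cm, d_phy = NULL, d_fun = NULL,
                            include_root = TRUE) {
  cm <- community_matrix(cm)
  if (is.null(d_phy)) d_phy <- patristic_matrix(tree)
  if (is.null(d_fun)) d_fun <- cophenetic_matrix(dend)
  data.frame(site = rownames(cm),
             SR = as.integer(species_richness(cm)),
             PD = branch_length_diversity(tree, cm, include_root),
             FD = branch_length_diversity(dend, cm, include_root),
             MPD = mean_pairwise_distance(d_phy, cm),
             MFD = mean_pairwise_distance(d_fun, cm),
             row.names = NULL)
}

#' Pairwise Pearson correlations among diversity indices
#'
#' @param dt data.frame of per-site indices (e.g. from [diversity_table()]).
#' @param columns which columns to correlate (default SR, PD, FD).
#' @return data.frame with index pair, Pearson r, and two-sided p-value;
#'   zero-variance columns yield `NA` with a warning.
#' @export
index_correlations <- function(dt, columns = c("SR", "PD", "FD")) {
  miss <- setdiff(columns, names(dt))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(dt) < 3L) stopf("need >= 3 sites")
  out <- NULL
  for (a in seq_along(columns)) for (b in seq_along(columns)) {
    if (b <= a) next
    x <- dt[[columns[a]]]; y <- dt[[columns[b]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("zero variance in %s or %s; correlation undefined",
            columns[a], columns[b])
      row <- data.frame(index1 = columns[a], index2 = columns[b],
                        r = NA_real_, p = NA_real_)
    } else {
      ct <- stats::cor.test(x, y)
      row <- data.frame(index1 = columns[a], index2 = columns[b],
                        r = unname(ct$estimate), p = ct$p.value)
    }
    out <- rbind(out, row)
  }
  out
}
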