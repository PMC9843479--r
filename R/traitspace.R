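# Mixed-type trait tables, Gower dissimilarity, and the UPGMA functional
# dendrogram on which dendrogram-based functional diversity is computed.

#' Construct and validate a species x trait table
#'
#' Columns are tagged `"continuous"` or `"binary"`. Binary columns must contain
#' only 0/1; no missing values are tolerated (validation errors rather than
#' silently dropping — trait imputation is an upstream decision).
#'
#' @param data data.frame of trait values with species as row names (or a
#'   `species` column).
#' @param types character vector, one of `"continuous"`/`"binary"` per column.
#' @param log_continuous if `TRUE`, log-transform continuous columns (all
#'   values must be positive). Off by default.
#' @return a `trait_table`: data.frame with a `types` attribute.
#' @export
trait_table <- function(data, types, log_continuous = FALSE) {
  data <- as.data.frame(data)
  if ("species" %in% names(data)) {
    rownames(data) <- data$species
    data$species <- NULL
  }
  sp <- rownames(data)
  if (is.null(sp) || any(!nzchar(sp))) stopf("species labels required")
  if (anyDuplicated(sp)) stopf("duplicated species in trait table")
  if (nrow(data) < 2L) stopf("need >= 2 species")
  if (length(types) != ncol(data))
    stopf("types length (%d) != number of columns (%d)", length(types), ncol(data))
  types <- match.arg(types, c("continuous", "binary"), several.ok = TRUE)
  for (j in seq_along(data)) {
    x <- data[[j]]
    if (!is.numeric(x)) stopf("column '%s' is not numeric", names(data)[j])
    if (anyNA(x)) stopf("missing values in column '%s'", names(data)[j])
    if (types[j] == "binary" && !all(x %in% c(0, 1)))
      stopf("binary column '%s' contains values outside {0,1}", names(data)[j])
    if (types[j] == "continuous" && log_continuous) {
      if (any(x <= 0)) stopf("log transform needs positive values in '%s'",
                             names(data)[j])
      data[[j]] <- log(x)
    }
  }
  structure(data, types = types, class = c("trait_table", "data.frame"))
}

trait_types <- function(traits) {
  t <- attr(traits, "types")
  if (is.null(t)) stopf("not a trait_table (missing column types)")
  t
}

#' Read / write a typed trait-table CSV
#'
#' The on-disk format carries a `species` column and a first data row named
#' `type` giving each column's type (`continuous`|`binary`).
#'
#' @param file path to CSV.
#' @return a `trait_table`.
#' @export
read_trait_csv <- function(file) {
  raw <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(raw)) stopf("trait CSV needs a 'species' column")
  trow <- which(raw$species == "type")
  if (length(trow) != 1L) stopf("trait CSV needs one 'type' row")
  types <- as.character(raw[trow, setdiff(names(raw), "species")])
  vals <- raw[-trow, , drop = FALSE]
  sp <- vals$species
  vals$species <- NULL
  vals[] <- lapply(vals, as.numeric)
  rownames(vals) <- sp
  trait_table(vals, types)
}

#' @rdname read_trait_csv
#' @param traits a `trait_table`.
#' @export
write_trait_csv <- function(traits, file) {
  types <- trait_types(traits)
  out <- rbind(as.data.frame(as.list(stats::setNames(types, names(traits)))),
               as.data.frame(lapply(traits, as.character)))
  out <- cbind(species = c("type", rownames(traits)), out)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Gower dissimilarity for mixed continuous/binary traits
#'
#' `d(i,j) = sum_k w_k * delta_k(i,j) / sum_k w_k`, with
#' `delta_k = |x_ik - x_jk| / range_k` for continuous columns and simple
#' mismatch (0/0 agreement counts as agreement) for binary columns. Every
#' column gets equal weight by default — one weight per indicator column, so a
#' categorical family with many indicators weighs more than a single
#' continuous trait; `weights = "group"` instead downweights columns by a
#' `groups` factor so each family totals weight 1.
#'
#' @param traits a `trait_table`.
#' @param weights numeric per-column weights, or `"equal"` (default) or
#'   `"group"`.
#' @param groups factor/character of column group labels (required for
#'   `weights = "group"`).
#' @return symmetric dissimilarity matrix in \[0, 1\] with species labels.
#' @export
gower_matrix <- function(traits, weights = "equal", groups = NULL) {
  types <- trait_types(traits)
  X <- as.matrix(as.data.frame(traits))
  p <- ncol(X)
  if (identical(weights, "equal")) {
    w <- rep(1, p)
  } else if (identical(weights, "group")) {
    if (is.null(groups) || length(groups) != p)
      stopf("weights='group' needs a per-column `groups` vector")
    w <- 1 / as.numeric(table(groups)[as.character(groups)])
  } else {
    w <- as.numeric(weights)
    if (length(w) != p || any(!is.finite(w)) || any(w < 0) || sum(w) == 0)
      stopf("invalid weight vector")
  }
  n <- nrow(X)
  acc <- matrix(0, n, n)
  for (k in seq_len(p)) {
    x <- X[, k]
    if (types[k] == "continuous") {
      rg <- diff(range(x))
      if (rg == 0) stopf("zero-range continuous column '%s'", colnames(X)[k])
      dk <- abs(outer(x, x, "-")) / rg
    } else {
      dk <- outer(x, x, "!=") * 1
    }
    acc <- acc + w[k] * dk
  }
  d <- acc / sum(w)
  dimnames(d) <- list(rownames(X), rownames(X))
  validate_dissimilarity(d)
  d
}

#' Validate a dissimilarity matrix
#' @param d square numeric matrix.
#' @param tol symmetry tolerance.
#' @return `d` invisibly.
#' @export
validate_dissimilarity <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("not a square matrix")
  if (any(!is.finite(d))) stopf("non-finite dissimilarities")
  if (any(d < 0)) stopf("negative dissimilarities")
  if (max(abs(d - t(d))) > tol) stopf("dissimilarity matrix not symmetric")
  if (any(abs(diag(d)) > tol)) stopf("nonzero diagonal")
  invisible(d)
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Standard unweighted pair-group average linkage: the closest pair of
#' clusters is merged at height d/2 (so the cophenetic tip-to-tip distance on
#' the output equals the merge dissimilarity), and distances to the merged
#' cluster are size-weighted arithmetic means. Ties are broken by the lowest
#' (row, column) index pair in current label order — this affects topology on
#' tied data and is therefore fixed, not left to the platform.
#'
#' @param d symmetric dissimilarity matrix with labels, n >= 2.
#' @return an ultrametric phylo object (the functional dendrogram), with the
#'   merge record kept in `attr(, "hclust")`.
#' @export
upgma <- function(d) {
  validate_dissimilarity(d)
  n <- nrow(d)
  if (n < 2L) stopf("need >= 2 items")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  D <- d
  size <- rep(1L, n)
  id <- -seq_len(n)                       # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- seq_len(n)
  for (s in seq_len(n - 1L)) {
    m <- length(active)
    sub <- D[active, active, drop = FALSE]
    sub[upper.tri(sub, diag = TRUE)] <- Inf
    # lowest (row, col) pair among minima: column-major which() on the
    # transposed mask scans rows first; enforce ordering explicitly
    hit <- which(sub == min(sub), arr.ind = TRUE)
    hit <- hit[order(hit[, 2L], hit[, 1L]), , drop = FALSE]  # (i<j): col=j index? rows>cols in lower tri
    i <- active[hit[1L, 2L]]; j <- active[hit[1L, 1L]]       # i < j in label order
    height[s] <- D[i, j]     # hclust records the merge dissimilarity;
                             # as.phylo halves it into node height d/2
    merge[s, ] <- c(id[i], id[j])
    # size-weighted average distance to the merged cluster, stored at slot i
    rest <- setdiff(active, c(i, j))
    if (length(rest)) {
      newd <- (size[i] * D[i, rest] + size[j] * D[j, rest]) / (size[i] + size[j])
      D[i, rest] <- newd; D[rest, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    active <- setdiff(active, j)
  }
  if (any(diff(height) < -1e-12)) stopf("height inversion (should not happen for UPGMA)")
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge), labels = labs,
                       method = "average", call = match.call(),
                       dist.method = "user"),
                  class = "hclust")
  tr <- ape::as.phylo(hc)   # branch lengths give tip depth = height (merge d/2)
  validate_phylogeny(tr)
  attr(tr, "hclust") <- hc
  tr
}

# leaf ordering for an hclust merge matrix (left-to-right traversal)
hclust_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' Cophenetic distances of a dendrogram
#' @param dend a phylo dendrogram (e.g. from [upgma()]).
#' @return symmetric matrix of tip-to-tip cophenetic distances.
#' @export
cophenetic_matrix <- function(dend) patristic_matrix(dend)
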