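# Phylogeny input/output and queries. Trees are ape "phylo" objects throughout;
# this module adds validation (unique tips, non-negative finite branch lengths)
# on every entry point, since downstream metrics silently misbehave on bad trees.

#' Validate a phylogeny
#'
#' Checks the invariants every downstream computation relies on: a single root,
#' unique non-empty tip labels, and finite branch lengths >= 0 (zero-length
#' branches are allowed, e.g. after pruning; negative lengths are rejected).
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  tips <- tree$tip.label
  if (any(is.na(tips)) || any(!nzchar(tips))) stopf("empty tip labels")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup))
    stopf("duplicate tip labels: %s", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  bl <- tree$edge.length
  if (any(!is.finite(bl))) stopf("non-finite branch lengths")
  if (any(bl < 0)) stopf("negative branch lengths")
  # single root: exactly one node that never appears as a child
  kids <- tree$edge[, 2L]
  parents <- tree$edge[, 1L]
  roots <- setdiff(unique(parents), kids)
  if (length(roots) != 1L) stopf("tree must have a single root")
  invisible(tree)
}

#' Parse a Newick string into a phylogeny
#'
#' Accepts quoted labels, scientific-notation branch lengths and bracketed
#' comments (the birdtree.org dialect). Malformed parentheses are reported with
#' the character offset of the first imbalance.
#'
#' @param text a single Newick string (terminating `;` optional).
#' @return a validated [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("\\[[^]]*\\]", "", text)  # drop [&...] comments
  # balance check with offset, ignoring quoted sections
  chars <- strsplit(stripped, "")[[1]]
  depth <- 0L; inq <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inq <- !inq
    else if (!inq && ch == "(") depth <- depth + 1L
    else if (!inq && ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("unbalanced ')' at character %d", i)
    }
  }
  if (depth != 0L) stopf("unclosed '(' (%d open) at end of string", depth)
  if (!grepl(";\\s*$", stripped)) stripped <- paste0(stripped, ";")
  tree <- tryCatch(ape::read.tree(text = stripped),
                   error = function(e) stopf("Newick parse error: %s",
                                             conditionMessage(e)))
  if (is.null(tree)) stopf("Newick parse error: no tree found")
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)  # unquote labels
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny as a Newick string or file
#'
#' @param tree a phylo object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree)
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a sample of trees sharing one tip set
#'
#' Reads multi-line Newick files or NEXUS trees blocks (the format of posterior
#' tree samples). All members must share the same tip-label set.
#'
#' @param file path to a Newick (one tree per line) or NEXUS file.
#' @return a `multiPhylo` object.
#' @export
read_tree_sample <- function(file) {
  first <- toupper(trimws(readLines(file, n = 1L)))
  trees <- if (startsWith(first, "#NEXUS")) ape::read.nexus(file)
           else ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  if (length(trees) == 0L) stopf("no trees in %s", file)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_phylogeny(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stopf("tree %d has a different tip set", i)
  }
  trees
}

#' Total branch length of a tree
#' @param tree a phylo object.
#' @return sum of all branch lengths (plus root edge if present).
#' @export
total_branch_length <- function(tree) {
  sum(tree$edge.length) + if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Prune a phylogeny to a species set
#'
#' Returns the induced subtree on `species`: unbranched internal nodes are
#' suppressed with their branch lengths summed, and the branch-length path from
#' the subtree to the original root is preserved in `$root.edge`.
#'
#' @param tree a phylo object.
#' @param species character vector of tip labels to keep (non-empty).
#' @return a phylo object on `species`.
#' @export
prune_to <- function(tree, species) {
  validate_phylogeny(tree)
  if (length(species) < 1L) stopf("`species` must contain at least one label")
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stopf("species not in tree: %s", paste(unknown, collapse = ", "))
  species <- unique(species)
  if (length(species) == length(tree$tip.label)) return(tree)
  if (length(species) == 1L) {
    # degenerate single-tip tree: root edge carries the full root path
    depth <- ape::node.depth.edgelength(tree)[match(species, tree$tip.label)]
    return(structure(list(edge = matrix(c(2L, 1L), 1L), tip.label = species,
                          edge.length = 0, Nnode = 1L, root.edge = depth),
                     class = "phylo"))
  }
  out <- ape::keep.tip(tree, species)
  # path from the induced subtree's root (the MRCA) up to the original root
  mrca <- ape::getMRCA(tree, species)
  depth <- ape::node.depth.edgelength(tree)[mrca]
  if (depth > 0) out$root.edge <- depth
  out
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree a phylo object.
#' @return symmetric matrix with zero diagonal, rows/cols in `tip.label` order.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

# sorted-label keys of the clades (tip bipartitions) of a tree
clade_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  vapply(pp, function(i) paste(sort(tree$tip.label[i]), collapse = "\r"), "")
}

# per-node heights: distance from each node down to its deepest descendant tip
# (time-from-present on ultrametric trees); internal nodes only, named by key
node_heights <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)          # distance from root
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)                      # clades for nodes n+1 .. n+Nnode
  h <- vapply(seq_along(pp), function(j) {
    max(nd[pp[[j]]]) - nd[n + j]
  }, 0)
  names(h) <- clade_keys(tree)
  h
}

#' Maximum clade credibility tree with mean node heights
#'
#' Selects, among the sample members only (never building a consensus
#' topology), the tree maximizing the product of clade credibilities, where a
#' clade's credibility is the frequency of its tip bipartition in the sample.
#' Node heights of the selected tree are replaced by the mean height of the
#' matching clade across the trees containing it, and branch lengths rebuilt
#' from those heights (negative lengths clamped to zero with a warning).
#' Intended for ultrametric posterior samples.
#'
#' @param sample a `multiPhylo` (or list of phylo) with a shared tip set.
#' @param heights height summary; only `"mean"` is supported.
#' @return a phylo object.
#' @export
mcc_tree <- function(sample, heights = "mean") {
  heights <- match.arg(heights)
  if (inherits(sample, "phylo")) sample <- list(sample)
  N <- length(sample)
  if (N == 0L) stopf("empty tree sample")
  ref <- sort(sample[[1]]$tip.label)
  keys <- vector("list", N)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  hsum <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(N)) {
    tr <- sample[[i]]
    validate_phylogeny(tr)
    if (!identical(sort(tr$tip.label), ref)) stopf("tree %d tip set differs", i)
    k <- clade_keys(tr)
    keys[[i]] <- k
    h <- node_heights(tr)
    for (j in seq_along(k)) {
      key <- k[j]
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      hsum[[key]] <- (if (is.null(hsum[[key]])) 0 else hsum[[key]]) + h[j]
    }
  }
  score <- vapply(keys, function(k)
    sum(log(vapply(k, function(key) counts[[key]], 0L) / N)), 0)
  best <- which.max(score)                        # first member wins ties
  tree <- sample[[best]]
  # annotate: mean height per clade across trees containing it
  k <- keys[[best]]
  hmean <- vapply(k, function(key) hsum[[key]] / counts[[key]], 0)
  n <- length(tree$tip.label)
  hall <- c(rep(0, n), hmean)                     # tips at height 0
  len <- hall[tree$edge[, 1L]] - hall[tree$edge[, 2L]]
  if (any(len < -1e-8))
    warnf("%d negative branch lengths after mean-height annotation; clamped to 0",
          sum(len < -1e-8))
  tree$edge.length <- pmax(len, 0)
  attr(tree, "log_clade_credibility") <- score[best]
  tree
}

#' Log clade-credibility score of each sample member
#'
#' @param sample a `multiPhylo` with shared tip set.
#' @return numeric vector of per-tree log products of clade credibilities.
#' @export
clade_credibility_scores <- function(sample) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  N <- length(sample)
  if (N == 0L) stopf("empty tree sample")
  keys <- lapply(sample, clade_keys)
  tab <- table(unlist(keys))
  vapply(keys, function(k) sum(log(as.numeric(tab[k]) / N)), 0)
}
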