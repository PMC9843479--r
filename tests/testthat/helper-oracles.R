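# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (edge-incidence tricks, vectorized nulls) so that agreement is a
# real check, not a tautology.

# patristic distances by Floyd-Warshall on the tree graph
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  D <- matrix(Inf, nn, nn)
  diag(D) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    D[a, b] <- D[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) for (j in seq_len(nn))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  out <- D[seq_len(n), seq_len(n)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Faith PD by explicit root-path edge union
oracle_pd <- function(tree, species, include_root = TRUE) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_edges <- function(tip) {
    k <- match(tip, tree$tip.label)
    es <- integer(0)
    while (k != root) {
      es <- c(es, which(tree$edge[, 2] == k))
      k <- parent[k]
    }
    es
  }
  paths <- lapply(species, path_edges)
  edges <- unique(unlist(paths))
  if (!include_root) {
    shared <- Reduce(intersect, paths)       # root-to-MRCA edges
    edges <- setdiff(edges, shared)
  }
  sum(tree$edge.length[edges])
}

# Gower by double loop over pairs and columns
oracle_gower <- function(df, types) {
  n <- nrow(df)
  out <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  rg <- vapply(seq_along(df), function(k) diff(range(df[[k]])), 0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_along(df)) {
      s <- s + if (types[k] == "continuous")
        abs(df[i, k] - df[j, k]) / rg[k]
      else as.numeric(df[i, k] != df[j, k])
    }
    out[i, j] <- s / length(df)
  }
  out
}

# cophenetic matrix recomputed from an hclust merge record
oracle_cophenetic_hclust <- function(hc) {
  n <- length(hc$labels)
  members <- lapply(seq_len(n), identity)
  out <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  clusters <- list()
  for (s in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) -k else clusters[[k]]
    a <- get(hc$merge[s, 1]); b <- get(hc$merge[s, 2])
    out[a, b] <- out[b, a] <- hc$height[s]
    clusters[[s]] <- c(a, b)
  }
  out
}

# d-sep basis set by naive enumeration over all unordered node pairs
oracle_basis_set <- function(edges_mat, parents, topo) {
  adj <- paste(edges_mat[, 1], edges_mat[, 2])
  claims <- list()
  nodes <- topo
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (b <= a) next
    u <- nodes[a]; v <- nodes[b]
    if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
    claims[[length(claims) + 1]] <-
      list(x = u, y = v,
           conditioning = setdiff(union(parents[[u]], parents[[v]]), c(u, v)))
  }
  claims
}

# random DAG over k nodes: edges only from lower to higher index
random_dag <- function(k, p = 0.4) {
  em <- NULL
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k))
    if (stats::runif(1) < p) em <- rbind(em, c(paste0("v", a), paste0("v", b)))
  em
}

# tiny random tree via the package Yule generator with random branch scaling;
# topology/lengths are exercised through independent oracles
random_small_tree <- function(n, seed) {
  tr <- simulate_yule_tree(n, birth_rate = 1, seed = seed)
  tr$edge.length <- tr$edge.length * stats::runif(length(tr$edge.length), 0.5, 2)
  tr
}
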