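# Piecewise structural equation modelling: one linear model per endogenous
# node, d-separation tests of the implied conditional independencies, and
# Fisher's C combining the claim p-values into a global goodness-of-fit test.

#' Build a path model (DAG) from edge declarations
#'
#' Edges are `"parent -> child"` strings (one per element or newline-separated
#' in a single string), or a two-column matrix/data.frame of (parent, child).
#'
#' @param edges edge declarations.
#' @return a `path_model`: list with `nodes`, `edges` (2-col matrix),
#'   `parents` (named list), `order` (topological).
#' @export
path_model <- function(edges) {
  if (is.character(edges) && is.null(dim(edges))) {
    lines <- trimws(unlist(strsplit(edges, "\n")))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- regmatches(lines, regexec("^(\\S+)\\s*->\\s*(\\S+)$", lines))
    bad <- lines[vapply(parts, length, 0L) != 3L]
    if (length(bad)) stopf("cannot parse edge(s): %s", paste(bad, collapse = "; "))
    em <- t(vapply(parts, function(p) p[2:3], character(2L)))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stopf("edges must have 2 columns (parent, child)")
  }
  colnames(em) <- c("parent", "child")
  if (any(em[, 1L] == em[, 2L])) stopf("self-loop edge")
  if (anyDuplicated(paste(em[, 1L], em[, 2L]))) stopf("duplicated edge")
  nodes <- unique(c(em))
  parents <- lapply(stats::setNames(nodes, nodes),
                    function(v) unname(em[em[, 2L] == v, 1L]))
  # Kahn topological sort; leftover nodes mean a cycle
  ord <- character(0)
  indeg <- vapply(parents, length, 0L)
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(v)
      all(parents[[v]] %in% ord), TRUE)]
    if (!length(free))
      stopf("graph is cyclic (involving: %s)", paste(remaining, collapse = ", "))
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
  }
  structure(list(nodes = nodes, edges = em, parents = parents, order = ord),
            class = "path_model")
}

#' d-separation basis set of a DAG
#'
#' One claim per non-adjacent pair of nodes: the pair is claimed independent
#' conditional on the union of both nodes' parents. The response of the test
#' is the node later in topological order (so the claim is testable as a
#' partial regression coefficient).
#'
#' @param model a [path_model()].
#' @return list of claims, each `list(x, y, conditioning)` with `y` the
#'   response; empty for a complete DAG.
#' @export
dsep_basis_set <- function(model) {
  stopifnot(inherits(model, "path_model"))
  nodes <- model$order
  adj <- paste(model$edges[, 1L], model$edges[, 2L])
  claims <- list()
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (b <= a) next
    u <- nodes[a]; v <- nodes[b]           # v later in topological order
    if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
    cond <- setdiff(union(model$parents[[u]], model$parents[[v]]), c(u, v))
    claims[[length(claims) + 1L]] <- list(x = u, y = v, conditioning = cond)
  }
  claims
}

#' Fit a piecewise SEM
#'
#' Each endogenous node is regressed on its parents by least squares on
#' z-scored variables (standardized path coefficients; a node with a single
#' parent gets the Pearson correlation as its coefficient). Each basis-set
#' claim is tested by the two-sided p-value of the conditioned partial
#' coefficient, and Fisher's `C = -2 sum ln p_i` is referred to a chi-square
#' with `2k` degrees of freedom; the model is conventionally accepted when
#' the global p exceeds .05.
#'
#' @param model a [path_model()].
#' @param data data.frame containing every model variable (site covariates,
#'   diversity indices, SES columns, ...).
#' @return a `sem_fit` list: `paths` (response, predictor, coef, se, p),
#'   `claims` (x, y, conditioning, p), `C`, `df`, `p`, `n`.
#' @export
fit_piecewise_sem <- function(model, data) {
  stopifnot(inherits(model, "path_model"))
  miss <- setdiff(model$nodes, names(data))
  if (length(miss)) stopf("variables missing from data: %s",
                          paste(miss, collapse = ", "))
  Z <- as.data.frame(lapply(data[model$nodes], function(col)
    zscore(as.numeric(col), "model variable")))
  n <- nrow(Z)
  endo <- model$nodes[vapply(model$nodes, function(v)
    length(model$parents[[v]]) > 0L, TRUE)]
  maxp <- max(vapply(endo, function(v) length(model$parents[[v]]), 0L))
  if (n <= maxp + 1L) stopf("n too small for the largest component model")
  paths <- NULL
  for (v in endo) {
    pa <- model$parents[[v]]
    fml <- stats::reformulate(pa, response = v)
    fit <- stats::lm(fml, data = Z)
    sm <- summary(fit)$coefficients
    if (anyNA(stats::coef(fit)))
      stopf("singular component fit for response '%s'", v)
    paths <- rbind(paths, data.frame(
      response = v, predictor = pa, coef = unname(sm[pa, 1L]),
      se = unname(sm[pa, 2L]), p = unname(sm[pa, 4L]), row.names = NULL))
  }
  claims <- dsep_basis_set(model)
  claim_df <- NULL
  for (cl in claims) {
    fml <- stats::reformulate(c(cl$x, cl$conditioning), response = cl$y)
    fit <- stats::lm(fml, data = Z)
    sm <- summary(fit)$coefficients
    claim_df <- rbind(claim_df, data.frame(
      x = cl$x, y = cl$y,
      conditioning = paste(cl$conditioning, collapse = "+"),
      p = unname(sm[cl$x, 4L]), row.names = NULL))
  }
  if (is.null(claim_df)) {
    C <- 0; df <- 0L; p <- 1
  } else {
    C <- -2 * sum(log(claim_df$p))
    df <- 2L * nrow(claim_df)
    p <- stats::pchisq(C, df, lower.tail = FALSE)
  }
  structure(list(paths = paths, claims = claim_df, C = C, df = df, p = p,
                 n = n), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Piecewise SEM (n =", x$n, ")\n")
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.4f (%s)\n", x$C, x$df, x$p,
              if (x$p > 0.05) "model accepted" else "model rejected"))
  cat("Paths:\n")
  print(x$paths, digits = 3)
  invisible(x)
}

#' Default habitat-to-diversity path model
#'
#' A stand-in DAG in the spirit of habitat-driven bird-diversity analyses:
#' nine exogenous habitat factors with direct edges to the response, plus an
#' indirect route `Altitude.HD -> Plant.ric -> response` (altitudinal
#' heterogeneity acting on diversity through plant richness). Fully
#' user-overridable: it is a plausible default, not a claim about any
#' particular study's topology.
#'
#' @param response name of the response variable (e.g. `"SR"`).
#' @return a [path_model()].
#' @export
default_sem_model <- function(response = "SR") {
  exo <- c("longitude", "latitude", "Area", "MAP", "ASH", "AT",
           "Altitude.min", "Altitude.HD", "Plant.ric")
  edges <- c("Altitude.HD -> Plant.ric",
             paste(exo, "->", response))
  path_model(edges)
}
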