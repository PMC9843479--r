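# Synthetic studies with the statistical structure the pipeline assumes:
# a Yule species pool, Brownian continuous and threshold-Brownian binary
# traits, incidence matrices assembled at random or under environmental
# filtering / competition, and site covariates with tunable spatially
# autocorrelated responses. Every generator is a pure function of its seed.

#' Simulate a Yule (pure-birth) tree
#'
#' Lineages split at rate `birth_rate` per lineage (exponential waiting
#' times); after the n-th tip appears an extra `Exp(n * birth_rate)` interval
#' is simulated so the tree is observed between the n-th and (n+1)-th birth.
#' Output is ultrametric; with the root split at time 0 the expected tree
#' height is `sum_{k=2..n} 1/(k * birth_rate)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed.
#' @return an ultrametric phylo object with tips `s1..sn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  with_seed(seed, {
    # waits[k] = Exp(k * birth_rate) interval while k lineages are extant;
    # the stem (waits[1]) is dropped, so the root split defines time 0 and
    # the k-lineage stage for k >= 2 contributes waits[k] to tree height
    waits <- stats::rexp(n_tips, rate = birth_rate * seq_len(n_tips))
    n_node <- n_tips - 1L
    split_times <- if (n_node >= 2L) c(0, cumsum(waits[2:n_node])) else 0
    Tend <- split_times[n_node] + waits[n_tips]
    edge <- matrix(0L, 2L * n_tips - 2L, 2L)
    elen <- numeric(nrow(edge))
    nextnode <- n_tips + 2L
    # active lineage = (node it hangs from, start time); root node = n_tips+1
    act_par <- c(n_tips + 1L, n_tips + 1L)
    act_t0 <- c(0, 0)
    e <- 0L
    tip <- 0L
    for (s in seq_len(n_node - 1L)) {
      i <- sample.int(length(act_par), 1L)
      tsplit <- split_times[s + 1L]
      node <- nextnode; nextnode <- nextnode + 1L
      e <- e + 1L
      edge[e, ] <- c(act_par[i], node)
      elen[e] <- tsplit - act_t0[i]
      act_par <- c(act_par[-i], node, node)
      act_t0 <- c(act_t0[-i], tsplit, tsplit)
    }
    for (i in seq_along(act_par)) {
      tip <- tip + 1L
      e <- e + 1L
      edge[e, ] <- c(act_par[i], tip)
      elen[e] <- Tend - act_t0[i]
    }
    tr <- structure(list(edge = edge, edge.length = elen, Nnode = n_node,
                         tip.label = paste0("s", seq_len(n_tips))),
                    class = "phylo")
    tr <- ape::reorder.phylo(tr, "cladewise")
    validate_phylogeny(tr)
    tr
  })
}

#' Simulate traits on a tree
#'
#' Continuous traits evolve by Brownian motion (variance `sigma2` per unit
#' branch length, root state 0). Binary traits threshold an independent
#' Brownian liability at its median, giving prevalence 0.5 by construction —
#' the threshold model under which the D statistic is calibrated to 0.
#'
#' @param tree phylo object.
#' @param n_continuous,n_binary numbers of trait columns.
#' @param sigma2 Brownian rate.
#' @param seed integer seed.
#' @return a [trait_table()] with columns `cont1.. / bin1..`.
#' @export
simulate_traits <- function(tree, n_continuous = 6, n_binary = 20,
                            sigma2 = 1, seed = NULL) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  ntr <- n_continuous + n_binary
  stopifnot(ntr >= 1)
  M <- edge_tip_incidence(tree)
  sd_edge <- sqrt(sigma2 * tree$edge.length)
  X <- with_seed(seed, {
    incr <- matrix(stats::rnorm(nrow(M) * ntr, sd = sd_edge), nrow(M), ntr)
    crossprod(M, incr)                      # tips x traits
  })
  out <- as.data.frame(X)
  names(out) <- c(if (n_continuous) paste0("cont", seq_len(n_continuous)),
                  if (n_binary) paste0("bin", seq_len(n_binary)))
  types <- rep(c("continuous", "binary"), c(n_continuous, n_binary))
  for (j in seq_len(n_binary)) {
    col <- n_continuous + j
    out[[col]] <- as.numeric(out[[col]] > stats::median(out[[col]]))
  }
  rownames(out) <- tree$tip.label
  trait_table(out, types)
}

#' Assemble site x species communities under a known process
#'
#' * `random`: each site draws SR species uniformly from the pool.
#' * `filtering`: a site-specific focal species is drawn; other species are
#'   sampled with probability decaying exponentially in their patristic
#'   distance from the focal (`exp(-strength * d / mean(d))`), producing
#'   phylogenetically clustered sites as `strength` grows.
#' * `competition`: species are added one at a time, rejecting candidates
#'   whose distance to any current member falls below `strength` times the
#'   pool's mean nearest-neighbour patristic distance (0 = no exclusion),
#'   producing over-dispersed sites. The nearest-neighbour scale makes
#'   strength dimensionless and keeps moderate values feasible: strength 1
#'   excludes roughly sister-pair co-occurrence, larger values push members
#'   apart by whole clades.
#'
#' @param tree pool phylogeny.
#' @param n_sites number of sites.
#' @param richness_range inclusive SR range sampled uniformly per site.
#' @param process assembly process.
#' @param strength process intensity (>= 0): exponential decay rate in units
#'   of mean pairwise distance (filtering) or exclusion radius in units of
#'   mean nearest-neighbour distance (competition).
#' @param seed integer seed.
#' @param d optional precomputed patristic matrix.
#' @return incidence matrix with a `truth` attribute recording the process,
#'   strength, per-site richness and focal species.
#' @export
assemble_communities <- function(tree, n_sites = 37, richness_range = c(30, 91),
                                 process = c("random", "filtering", "competition"),
                                 strength = 0, seed = NULL, d = NULL) {
  process <- match.arg(process)
  validate_phylogeny(tree)
  pool <- tree$tip.label
  n <- length(pool)
  if (max(richness_range) > n) stopf("richness exceeds pool size")
  if (strength < 0) stopf("strength must be >= 0")
  if (is.null(d)) d <- patristic_matrix(tree)
  dbar <- mean(d[upper.tri(d)])
  dnn <- mean(apply(d + diag(Inf, n), 1L, min))   # mean nearest-neighbour dist
  thr <- if (process == "competition") strength * dnn else 0
  with_seed(seed, {
    sr <- sample(seq(richness_range[1L], richness_range[2L]), n_sites,
                 replace = TRUE)
    cm <- matrix(0L, n_sites, n, dimnames = list(paste0("site", seq_len(n_sites)),
                                                 pool))
    focal <- rep(NA_character_, n_sites)
    for (i in seq_len(n_sites)) {
      k <- sr[i]
      if (process == "random" || strength == 0) {
        idx <- sample.int(n, k)
      } else if (process == "filtering") {
        f <- sample.int(n, 1L)
        focal[i] <- pool[f]
        w <- exp(-strength * d[f, ] / dbar)
        idx <- sample.int(n, k, prob = w)
      } else {
        # greedy rejection can dead-end even when a valid set exists, so a
        # failed site is restarted from a fresh first member
        idx <- NULL
        for (restart in seq_len(50L)) {
          idx <- sample.int(n, 1L)
          tries <- 0L
          while (length(idx) < k && tries <= 200L * k) {
            cand <- sample.int(n, 1L)
            tries <- tries + 1L
            if (cand %in% idx) next
            if (min(d[cand, idx]) >= thr) idx <- c(idx, cand)
          }
          if (length(idx) == k) break
        }
        if (length(idx) < k)
          stopf(paste("competition threshold infeasible for richness %d;",
                      "lower `strength`"), k)
      }
      cm[i, idx] <- 1L
    }
    attr(cm, "truth") <- list(process = process, strength = strength,
                              richness = sr, focal = focal,
                              threshold = unname(thr), seed = seed)
    cm
  })
}

#' Simulate a site table with spatially autocorrelated responses
#'
#' Coordinates are uniform in a plateau-like bounding box; the 12 habitat
#' covariates are drawn on plausible scales with the altitude identity
#' `Altitude.HD = Altitude.max - Altitude.min` holding exactly. The response
#' is `sum_j beta_j z(x_j) + u` with spatial-error noise
#' `u = lambda W u + eps` on row-standardized weights of the generated
#' coordinates, so SAR recovery can be scored against known truth. The
#' default weights are k = 8 nearest neighbours: neighbourhood weights carry
#' identifiable local spatial structure, whereas dense inverse-distance
#' weights on uniform points are close to a global mean shift and leave
#' lambda weakly identified.
#'
#' @param n_sites number of sites.
#' @param effect_spec named numeric vector of true standardized effects on
#'   covariate columns (default: Plant.ric 0.5).
#' @param lambda_spatial spatial-error coefficient, |lambda| < 1.
#' @param noise_sd innovation sd (default 1).
#' @param seed integer seed.
#' @param lon_range,lat_range coordinate bounding box (decimal degrees).
#' @param weights_style,knn_k weights used for the spatial-error process.
#' @return data.frame of site, coordinates, the 12 covariates and a
#'   `response` column; attribute `truth` records beta, lambda, noise_sd and
#'   the weights used.
#' @export
simulate_site_table <- function(n_sites = 37,
                                effect_spec = c(Plant.ric = 0.5),
                                lambda_spatial = 0, noise_sd = 1, seed = NULL,
                                lon_range = c(103, 109),
                                lat_range = c(22, 28),
                                weights_style = c("knn", "inverse_distance"),
                                knn_k = 8) {
  weights_style <- match.arg(weights_style)
  if (abs(lambda_spatial) >= 1) stopf("|lambda_spatial| must be < 1")
  with_seed(seed, {
    lon <- stats::runif(n_sites, lon_range[1L], lon_range[2L])
    lat <- stats::runif(n_sites, lat_range[1L], lat_range[2L])
    alt_min <- stats::runif(n_sites, 300, 2200)
    alt_hd <- stats::rlnorm(n_sites, log(600), 0.6)
    st <- data.frame(
      site = paste0("site", seq_len(n_sites)),
      longitude = lon, latitude = lat,
      Area = stats::rlnorm(n_sites, log(150), 1),          # km^2
      Plant.ric = round(stats::rlnorm(n_sites, log(1500), 0.5)),
      MAT = stats::rnorm(n_sites, 15, 3),                  # deg C
      MAP = stats::rnorm(n_sites, 1100, 200),              # mm
      ASH = stats::rnorm(n_sites, 1400, 250),              # h
      AT = stats::rnorm(n_sites, 4500, 800),               # deg C
      Altitude.min = alt_min,
      Altitude.max = alt_min + alt_hd,
      Altitude.mean = alt_min + alt_hd * stats::runif(n_sites, 0.3, 0.7),
      Altitude.HD = alt_hd)
    bad <- setdiff(names(effect_spec), names(st))
    if (length(bad)) stopf("unknown covariates in effect_spec: %s",
                           paste(bad, collapse = ", "))
    D <- great_circle_distances(lon, lat)
    W <- build_weights(D, weights_style, k = min(knn_k, n_sites - 1L),
                       row_standardize = TRUE)
    eps <- stats::rnorm(n_sites, sd = noise_sd)
    u <- as.numeric(solve(diag(n_sites) - lambda_spatial * W$W, eps))
    xb <- rep(0, n_sites)
    for (v in names(effect_spec)) xb <- xb + effect_spec[[v]] * zscore(st[[v]], v)
    st$response <- xb + u
    attr(st, "truth") <- list(beta = effect_spec, lambda = lambda_spatial,
                              noise_sd = noise_sd, seed = seed, weights = W)
    st
  })
}

#' Generate a complete synthetic study bundle
#'
#' Defaults mirror a 37-site, 164-species study with site richness 30-91.
#' All four inputs share consistent labels and pass downstream validation.
#'
#' @param n_species pool size; `n_sites` sites; `richness_range` per-site SR.
#' @param process,strength community assembly (see [assemble_communities()]).
#' @param lambda_spatial,effect_spec site-table generation (see
#'   [simulate_site_table()]).
#' @param seed master seed, split per stage.
#' @return list: `tree`, `traits`, `communities`, `sites`, `truth`.
#' @export
simulate_study <- function(n_species = 164, n_sites = 37,
                           richness_range = c(30, 91),
                           process = "random", strength = 0,
                           effect_spec = c(Plant.ric = 0.5),
                           lambda_spatial = 0, seed = 1) {
  tree <- simulate_yule_tree(n_species, birth_rate = 1,
                             seed = split_seed(seed, "tree"))
  traits <- simulate_traits(tree, seed = split_seed(seed, "traits"))
  cm <- assemble_communities(tree, n_sites, richness_range, process, strength,
                             seed = split_seed(seed, "communities"))
  sites <- simulate_site_table(n_sites, effect_spec, lambda_spatial,
                               seed = split_seed(seed, "sites"))
  sites$site <- rownames(cm)
  list(tree = tree, traits = traits, communities = cm, sites = sites,
       truth = list(assembly = attr(cm, "truth"),
                    spatial = attr(sites, "truth"), seed = seed))
}

#' Write a study bundle to disk
#'
#' Emits `tree.nwk`, `traits.csv`, `communities.csv`, `sites.csv` and
#' `truth.json` under `dir`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write_trait_csv(study$traits, file.path(dir, "traits.csv"))
  write_community_csv(study$communities, file.path(dir, "communities.csv"))
  utils::write.csv(study$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  truth <- study$truth
  truth$spatial$weights <- NULL              # matrices don't belong in JSON
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
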