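# Config-driven end-to-end runner: reads a study bundle (tree(s), traits,
# communities, sites), runs diversity -> structure -> signal -> regression ->
# SEM, and writes one CSV per stage plus a JSON run manifest. All randomness
# descends from one master seed, split deterministically per stage.

#' Run configuration
#'
#' @param tree path to a Newick file (one or more trees; a multi-tree sample
#'   is summarized to its maximum clade credibility tree first).
#' @param traits,communities,sites paths to the CSV inputs.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_reps,scheme,sign_convention null-model settings (see
#'   [null_config()]).
#' @param weights_style `"invdist"` or `"knn"`; `knn_k` neighbours for knn.
#' @param sem_edges character vector of `"parent -> child"` lines, or `NULL`
#'   to skip the SEM stage.
#' @param include_root PD/FD root-path convention.
#' @return a `run_config` list.
#' @export
run_config <- function(tree, traits, communities, sites, out_dir,
                       seed = 1, n_reps = 999,
                       scheme = "taxa_labels", sign_convention = "ses",
                       weights_style = c("invdist", "knn"), knn_k = 4,
                       sem_edges = NULL, include_root = TRUE) {
  cfg <- list(tree = tree, traits = traits, communities = communities,
              sites = sites, out_dir = out_dir, seed = seed, n_reps = n_reps,
              scheme = scheme, sign_convention = sign_convention,
              weights_style = match.arg(weights_style), knn_k = knn_k,
              sem_edges = sem_edges, include_root = include_root)
  for (f in c("tree", "traits", "communities", "sites"))
    if (!file.exists(cfg[[f]])) stopf("input file for '%s' not found: %s", f,
                                      cfg[[f]])
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#' @param file JSON path with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  j$sem_edges <- if (is.null(j$sem_edges)) NULL else as.character(j$sem_edges)
  do.call(run_config, j)
}

# consolidated label cross-checks before any computation
preflight <- function(tree, traits, cm, sites) {
  errs <- character(0)
  sp_cm <- colnames(cm)
  m <- setdiff(sp_cm, tree$tip.label)
  if (length(m)) errs <- c(errs, sprintf("species in communities but not in tree: %s",
                                         paste(m, collapse = ", ")))
  m <- setdiff(sp_cm, rownames(traits))
  if (length(m)) errs <- c(errs, sprintf("species in communities but not in traits: %s",
                                         paste(m, collapse = ", ")))
  m <- setdiff(rownames(cm), sites$site)
  if (length(m)) errs <- c(errs, sprintf("site(s) in communities but not in sites table: %s",
                                         paste(m, collapse = ", ")))
  need <- c("site", "longitude", "latitude")
  m <- setdiff(need, names(sites))
  if (length(m)) errs <- c(errs, sprintf("sites table missing column(s): %s",
                                         paste(m, collapse = ", ")))
  if (length(errs)) stopf("pre-flight failed:\n- %s", paste(errs, collapse = "\n- "))
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) tree input, with MCC summarization when several trees are
#' supplied; (2) per-site diversity (SR, PD, FD, MPD, MFD); (3) SESmpd/SESmfd
#' against the configured null; (4) phylogenetic signal of every trait;
#' (5) bivariate OLS + Moran + SAR grid over all site covariates; (6)
#' piecewise SEM if a DAG is configured; (7) index correlations. Each stage
#' writes a CSV under `out_dir`; a `manifest.json` echoes the config and
#' per-stage seeds. Reruns with the same config are byte-identical.
#'
#' @param cfg a [run_config()] (or path to a JSON config).
#' @return invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  trees <- read_tree_sample(cfg$tree)
  tree <- if (length(trees) > 1L) mcc_tree(trees) else trees[[1L]]
  traits <- read_trait_csv(cfg$traits)
  cm <- read_community_csv(cfg$communities)
  sites <- utils::read.csv(cfg$sites, check.names = FALSE)
  preflight(tree, traits, cm, sites)
  sites <- sites[match(rownames(cm), sites$site), , drop = FALSE]
  tree <- prune_to(tree, colnames(cm))
  traits <- trait_table(as.data.frame(traits)[colnames(cm), , drop = FALSE],
                        trait_types(traits))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(cfg$out_dir, f)
  wcsv <- function(df, f) utils::write.csv(df, outp(f), row.names = FALSE)

  d_phy <- patristic_matrix(tree)
  gower <- gower_matrix(traits)
  dend <- upgma(gower)
  d_fun <- cophenetic_matrix(dend)

  div <- diversity_table(tree, dend, cm, d_phy, d_fun, cfg$include_root)
  wcsv(div, "diversity.csv")

  mk_null <- function(stage) null_config(cfg$n_reps, cfg$scheme,
                                         seed = split_seed(cfg$seed, stage),
                                         sign_convention = cfg$sign_convention)
  struct <- rbind(ses(d_phy, cm, mk_null("ses_mpd"), metric = "mpd"),
                  ses(d_fun, cm, mk_null("ses_mfd"), metric = "mfd"))
  wcsv(struct, "structure.csv")

  signals <- signal_table(tree, traits, seed = split_seed(cfg$seed, "signal"))
  wcsv(signals, "signals.csv")

  D <- great_circle_distances(sites)
  W <- if (cfg$weights_style == "invdist")
    build_weights(D, "inverse_distance")
  else build_weights(D, "knn", k = cfg$knn_k)
  predictors <- sites[, setdiff(names(sites), "site"), drop = FALSE]
  responses <- data.frame(SR = div$SR, PD = div$PD, FD = div$FD,
                          MPD = div$MPD, MFD = div$MFD,
                          SESmpd = struct$ses[struct$metric == "mpd"],
                          SESmfd = struct$ses[struct$metric == "mfd"])
  tab1 <- regression_table(responses, predictors, W)
  wcsv(tab1, "table1.csv")

  corr <- index_correlations(div)
  wcsv(corr, "correlations.csv")

  sem_fit <- NULL
  if (!is.null(cfg$sem_edges)) {
    model <- path_model(cfg$sem_edges)
    sem_data <- cbind(predictors, responses)
    sem_fit <- fit_piecewise_sem(model, sem_data)
    wcsv(sem_fit$paths, "sem.csv")
    wcsv(data.frame(C = sem_fit$C, df = sem_fit$df, p = sem_fit$p,
                    n = sem_fit$n), "sem_global.csv")
  }

  manifest <- list(
    package = "commstruct",
    version = as.character(utils::packageVersion("commstruct")),
    r_version = R.version.string,
    config = unclass(cfg),
    stage_seeds = list(ses_mpd = split_seed(cfg$seed, "ses_mpd"),
                       ses_mfd = split_seed(cfg$seed, "ses_mfd"),
                       signal = split_seed(cfg$seed, "signal")),
    n_trees_input = length(trees))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(tree = tree, diversity = div, structure = struct,
                 signals = signals, table1 = tab1, correlations = corr,
                 sem = sem_fit, weights = W))
}
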