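test_that("simulate_yule_tree produces valid ultrametric trees", {
  t2 <- simulate_yule_tree(2, seed = 81)
  expect_equal(length(t2$tip.label), 2)
  expect_true(ape::is.ultrametric(t2, tol = 1e-8))

  tr <- simulate_yule_tree(50, seed = 82)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(write_newick(simulate_yule_tree(50, seed = 82)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_yule_tree(50, seed = 83)),
                         write_newick(tr)))
})

test_that("yule tree height matches the pure-birth expectation", {
  # E[height] = sum_{k=2..n} 1/(b k); 400 sims at n = 15, b = 2
  n <- 15; b <- 2
  hts <- vapply(1:400, function(r) {
    tr <- simulate_yule_tree(n, birth_rate = b, seed = 8000 + r)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  expected <- sum(1 / (b * (2:n)))
  se <- sd(hts) / sqrt(length(hts))
  expect_lt(abs(mean(hts) - expected), 4 * se)
})

test_that("simulate_traits has Brownian covariance structure", {
  tr <- simulate_yule_tree(25, seed = 84)
  # shared path length from root = covariance of tip values under BM
  n <- 25
  depths <- ape::node.depth.edgelength(tr)[1:n]
  dmat <- patristic_matrix(tr)[tr$tip.label, tr$tip.label]
  shared <- outer(depths, depths, "+") / 2 - dmat / 2   # (d_i + d_j - d_ij)/2
  X <- vapply(1:300, function(r)
    setNames(simulate_traits(tr, 1, 0, sigma2 = 1, seed = 8400 + r)[[1]],
             paste0("s", 1:n)),
    numeric(n))
  emp <- tcrossprod(X) / ncol(X)      # E[x x'] with root state 0
  pair <- upper.tri(shared)
  fit <- lm(emp[pair] ~ shared[pair])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)

  tt <- simulate_traits(tr, 2, 4, seed = 85)
  expect_equal(attr(tt, "types"), rep(c("continuous", "binary"), c(2, 4)))
  # median threshold: prevalence 0.5 (n even rounds to n/2 +- 1)
  prev <- colMeans(as.data.frame(tt)[, 3:6])
  expect_true(all(abs(prev - 0.5) <= 1 / 25))
  expect_identical(as.data.frame(simulate_traits(tr, 2, 4, seed = 85)),
                   as.data.frame(tt))
})

test_that("assemble_communities respects richness and process contracts", {
  tr <- simulate_yule_tree(40, seed = 86)
  d <- patristic_matrix(tr)
  cm <- assemble_communities(tr, 8, c(5, 12), "random", seed = 87, d = d)
  expect_true(all(rowSums(cm) >= 5 & rowSums(cm) <= 12))
  expect_equal(colnames(cm), tr$tip.label)
  expect_identical(assemble_communities(tr, 8, c(5, 12), "random", seed = 87,
                                        d = d), cm)

  truth <- attr(cm, "truth")
  expect_equal(truth$process, "random")
  expect_equal(truth$richness, unname(rowSums(cm)))

  # strength 0: filtering and competition coincide with random
  cf0 <- assemble_communities(tr, 8, c(5, 12), "filtering", 0, seed = 87, d = d)
  expect_true(all(cf0 == cm))

  # infeasible competition errors with advice
  expect_error(assemble_communities(tr, 2, c(35, 38), "competition",
                                    strength = 5, seed = 88, d = d),
               "lower `strength`")
})

test_that("filtering clusters and competition disperses (small-scale check)", {
  tr <- simulate_yule_tree(80, seed = 89)
  d <- patristic_matrix(tr)
  cfg <- null_config(199, seed = 90)
  s_f <- ses(d, assemble_communities(tr, 10, c(10, 25), "filtering", 10,
                                     seed = 91, d = d), cfg)
  s_c <- ses(d, assemble_communities(tr, 10, c(10, 25), "competition", 2,
                                     seed = 92, d = d), cfg)
  expect_lt(mean(s_f$ses), -0.5)
  expect_gt(mean(s_c$ses), 0.5)
})

test_that("simulate_site_table constructs consistent covariates and truth", {
  st <- simulate_site_table(20, lambda_spatial = 0.4, seed = 93)
  expect_equal(st$Altitude.HD, st$Altitude.max - st$Altitude.min,
               tolerance = 1e-12)
  expect_true(all(st$Altitude.mean >= st$Altitude.min &
                    st$Altitude.mean <= st$Altitude.max))
  truth <- attr(st, "truth")
  expect_equal(truth$lambda, 0.4)
  expect_s3_class(truth$weights, "spatial_weights")
  expect_identical(simulate_site_table(20, lambda_spatial = 0.4, seed = 93)$response,
                   st$response)
  expect_error(simulate_site_table(10, lambda_spatial = 1.2), "< 1")
  expect_error(simulate_site_table(10, effect_spec = c(Nope = 1), seed = 1),
               "unknown covariates")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_yule_tree(10, seed = 1))
  invisible(simulate_traits(simulate_yule_tree(5, seed = 2), 1, 1, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("simulate_study emits an internally consistent bundle", {
  study <- simulate_study(n_species = 30, n_sites = 6, richness_range = c(4, 10),
                          seed = 94)
  expect_setequal(colnames(study$communities), study$tree$tip.label)
  expect_setequal(rownames(study$traits), study$tree$tip.label)
  expect_equal(study$sites$site, rownames(study$communities))

  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_setequal(list.files(dir), c("tree.nwk", "traits.csv", "communities.csv",
                                     "sites.csv", "truth.json"))
  cm2 <- read_community_csv(file.path(dir, "communities.csv"))
  expect_true(all(cm2 == study$communities))
  expect_equal(dimnames(cm2), dimnames(study$communities))
})
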