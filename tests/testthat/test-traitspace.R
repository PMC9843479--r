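test_that("trait_table validates structure and types", {
  df <- data.frame(mass = c(10, 20, 30), diet = c(0, 1, 1),
                   row.names = c("a", "b", "c"))
  tt <- trait_table(df, c("continuous", "binary"))
  expect_s3_class(tt, "trait_table")

  expect_error(trait_table(df[1, , drop = FALSE], c("continuous", "binary")),
               ">= 2 species")
  df_bad <- df; df_bad$diet[1] <- 2
  expect_error(trait_table(df_bad, c("continuous", "binary")), "outside")
  df_na <- df; df_na$mass[2] <- NA
  expect_error(trait_table(df_na, c("continuous", "binary")), "missing")
})

test_that("gower_matrix matches hand-computed values", {
  df <- data.frame(x = c(0, 10), b = c(0, 1), row.names = c("s1", "s2"))
  g <- gower_matrix(trait_table(df, c("continuous", "binary")))
  expect_equal(g["s1", "s2"], 1)          # maximal difference in both columns

  df3 <- data.frame(x = c(0, 5, 10), b = c(0, 1, 1),
                    row.names = c("s1", "s2", "s3"))
  g3 <- gower_matrix(trait_table(df3, c("continuous", "binary")))
  expect_equal(g3["s1", "s2"], (0.5 + 1) / 2)
  expect_equal(g3["s1", "s3"], 1)
  expect_equal(g3["s2", "s3"], (0.5 + 0) / 2)

  # identical rows at distance zero
  df_eq <- data.frame(x = c(1, 1, 9), b = c(1, 1, 0),
                      row.names = c("s1", "s2", "s3"))
  g_eq <- gower_matrix(trait_table(df_eq, c("continuous", "binary")))
  expect_equal(g_eq["s1", "s2"], 0)
})

test_that("gower_matrix agrees with cluster::daisy and the loop oracle", {
  skip_if_not_installed("cluster")
  set.seed(3)
  for (rep in 1:5) {
    df <- data.frame(a = rnorm(7), b = runif(7, 10, 20),
                     c = rbinom(7, 1, 0.5), d = rbinom(7, 1, 0.4))
    if (diff(range(df$c)) == 0) df$c[1] <- 1 - df$c[1]
    if (diff(range(df$d)) == 0) df$d[1] <- 1 - df$d[1]
    rownames(df) <- paste0("sp", 1:7)
    types <- c("continuous", "continuous", "binary", "binary")
    g <- gower_matrix(trait_table(df, types))
    expect_equal(g, as.matrix(cluster::daisy(df, metric = "gower")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(g, oracle_gower(df, types), tolerance = 1e-12)
  }
})

test_that("gower_matrix invariances and error cases", {
  set.seed(4)
  df <- data.frame(a = rnorm(6), b = rbinom(6, 1, 0.5),
                   row.names = paste0("sp", 1:6))
  df$b[1] <- 1 - df$b[1]
  types <- c("continuous", "binary")
  g <- gower_matrix(trait_table(df, types))

  # affine rescaling of a continuous column cancels in the range normalization
  df2 <- df; df2$a <- 100 + 7 * df$a
  expect_equal(gower_matrix(trait_table(df2, types)), g, tolerance = 1e-12)

  # permuting species permutes but does not change the matrix
  perm <- sample(6)
  g_p <- gower_matrix(trait_table(df[perm, ], types))
  expect_equal(g_p[rownames(g), colnames(g)], g, tolerance = 1e-12)

  df_const <- df; df_const$a <- 1
  expect_error(gower_matrix(trait_table(df_const, types)), "zero-range")
})

test_that("group weights downweight indicator families", {
  df <- data.frame(m = c(0, 1, 0.5), d1 = c(0, 1, 1), d2 = c(1, 0, 1),
                   row.names = paste0("s", 1:3))
  tt <- trait_table(df, c("continuous", "binary", "binary"))
  g <- gower_matrix(tt, weights = "group", groups = c("m", "diet", "diet"))
  # d(s1,s2): continuous 1 (w 1) + two mismatches (w 0.5 each) over total w 2
  expect_equal(g["s1", "s2"], (1 + 0.5 + 0.5) / 2)
})

test_that("upgma reproduces hand-computed merges", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  u2 <- upgma(d2)
  expect_equal(max(ape::node.depth.edgelength(u2)), 0.4)

  d3 <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  u3 <- upgma(d3)
  cp <- cophenetic_matrix(u3)
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.7)          # 2 * mean(0.6, 0.8) / 2
  expect_equal(attr(u3, "hclust")$height, c(0.2, 0.7))
})

test_that("upgma output is ultrametric with monotone heights and matches oracles", {
  set.seed(5)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    x <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(x)); dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    u <- upgma(d)
    hc <- attr(u, "hclust")
    expect_true(all(diff(hc$height) >= -1e-12))
    depths <- ape::node.depth.edgelength(u)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
    # cophenetic distances recomputed independently from the merge record
    expect_equal(cophenetic_matrix(u)[hc$labels, hc$labels],
                 oracle_cophenetic_hclust(hc), tolerance = 1e-10)
    # stats::hclust average linkage agrees on tie-free data
    expect_equal(sort(hc$height),
                 sort(stats::hclust(as.dist(d), "average")$height),
                 tolerance = 1e-10)
  }
})

test_that("upgma rejects invalid input and breaks ties by lowest index", {
  d_bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(d_bad), "symmetric")
  d_neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(d_neg), "negative")

  # all-tied 3-point matrix: A,B merge first by the documented tie-break
  d_tie <- matrix(0.5, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(d_tie) <- 0
  hc <- attr(upgma(d_tie), "hclust")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))   # leaves 1 and 2
})

test_that("trait CSV round-trips with column types", {
  tt <- trait_table(data.frame(m = c(1.5, 2.5), d = c(0, 1),
                               row.names = c("a", "b")),
                    c("continuous", "binary"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trait_csv(tt, f)
  tt2 <- read_trait_csv(f)
  expect_equal(as.data.frame(tt2), as.data.frame(tt))
  expect_equal(attr(tt2, "types"), attr(tt, "types"))
})
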