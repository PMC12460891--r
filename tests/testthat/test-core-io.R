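test_that("expression matrix read/write round-trips and rejects bad input", {
  x <- matrix(c(1.5, 0, 3, 2, 7, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- expression_matrix(x, "protein", "linear")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  m2 <- read_expression_matrix(path, "protein")
  expect_identical(dim(m2$values), dim(m$values))
  expect_equal(m2$values, m$values)
  expect_identical(rownames(m2$values), rownames(m$values))

  # identity read-back of a hand-written well-formed file
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "p1\t1\t2", "p2\t3\t4", "p3\t5\t6"), f)
  m3 <- read_expression_matrix(f, "protein")
  expect_equal(unname(m3$values), matrix(c(1, 3, 5, 2, 4, 6), 3))

  # duplicate feature ids -> format error
  writeLines(c("feature_id\ts1", "p1\t1", "p1\t2"), f)
  expect_error(read_expression_matrix(f, "protein"), "duplicate")

  # negative value -> format error
  writeLines(c("feature_id\ts1", "p1\t-3"), f)
  expect_error(read_expression_matrix(f, "protein"), "negative")

  # non-numeric cell -> format error; missing cells become 0
  writeLines(c("feature_id\ts1\ts2", "p1\tx\t2"), f)
  expect_error(read_expression_matrix(f, "protein"), "non-numeric")
  writeLines(c("feature_id\ts1\ts2", "p1\tNA\t2", "p2\t4\t"), f)
  m4 <- read_expression_matrix(f, "protein")
  expect_equal(unname(m4$values), matrix(c(0, 4, 2, 0), 2))

  expect_error(expression_matrix(matrix(1, 1, 1), "protein"),
               "feature ids")
})

test_that("log2_transform maps values as log2(x + pseudocount)", {
  x <- matrix(c(1, 0, 7, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- expression_matrix(x, "protein", "linear")
  lt <- log2_transform(m, 1)
  expect_equal(unname(lt$values), matrix(c(1, 0, 3, 2), 2))
  expect_identical(lt$scale, "log2")
  expect_error(log2_transform(m, 0), "pseudocount")
  expect_error(log2_transform(lt), "already")
  # no zeros: pseudocount 0 allowed
  m2 <- expression_matrix(x + 1, "protein", "linear")
  expect_equal(unname(log2_transform(m2, 0)$values[1, 1]), 1)
})

test_that("stage_mean_profiles averages replicates per stage group", {
  d <- make_design(3)
  v <- matrix(10, 2, nrow(d))
  # feature 1, LD E57 replicates 2,4,6 (pooled with SD E57 at 10s)
  idx <- which(d$region == "LD" & d$stage == "E57")
  v[1, idx] <- c(2, 4, 6)
  m <- make_matrix(v, d)
  pooled <- stage_mean_profiles(m, d, pool_regions = TRUE)
  expect_equal(ncol(pooled$values), 6)
  expect_equal(unname(pooled$values[1, "E57"]), mean(c(2, 4, 6, 10, 10, 10)))
  split <- stage_mean_profiles(m, d, pool_regions = FALSE)
  expect_equal(ncol(split$values), 12)
  expect_equal(unname(split$values[1, "LD_E57"]), 4)
  # constant replicates give a constant profile
  expect_true(all(split$values[2, ] == 10))
})

test_that("stage correlations are symmetric with unit diagonal and match the
           textbook Pearson formula", {
  d <- make_region_design(c("E57", "E73", "E90"), replicates = 2)
  # 3 features; stage means (1,2,4) and (2,3,9) live in two disjoint features?
  # Build so stage profiles across features are exactly those vectors.
  v <- rbind(c(1, 1, 2, 2, 4, 4),
             c(2, 2, 3, 3, 9, 9),
             c(5, 5, 1, 1, 3, 3))
  m <- make_matrix(v, d)
  lm2 <- m; lm2$scale <- "log2"  # values already treated as log2 for the test
  sc <- stage_correlations(lm2, d)
  expect_equal(sc$r, t(sc$r))
  expect_equal(unname(diag(sc$r)), rep(1, 3))
  # hand-computed sum-formula Pearson between stage columns E57 and E73:
  # x = (1,2,5), y = (2,3,1) across features
  x <- c(1, 2, 5); y <- c(2, 3, 1); n <- 3
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(unname(sc$r["E57", "E73"]), r_oracle, tolerance = 1e-12)
  # perfect anticorrelation
  v2 <- rbind(c(1, 1, 3, 3), c(2, 2, 2, 2) + c(0, 0, 0, 0), c(3, 3, 1, 1))
  d2 <- make_region_design(c("E57", "E73"), replicates = 2)
  m2 <- make_matrix(rbind(c(1, 1, 3, 3), c(2, 2, 2, 2), c(3, 3, 1, 1)), d2)
  m2$scale <- "log2"
  # feature 2 is constant and must be excluded; remaining profiles are
  # (1,3) vs (3,1) -> r = -1
  sc2 <- stage_correlations(m2, d2)
  expect_equal(unname(sc2$r["E57", "E73"]), -1)
  # feature reordering leaves the matrix unchanged
  m3 <- m
  m3$values <- m3$values[c(3, 1, 2), ]
  m3$scale <- "log2"
  expect_equal(stage_correlations(m3, d)$r, sc$r)
})

test_that("PCA matches a covariance eigensolve and fixes signs", {
  set.seed(42)
  x <- matrix(rnorm(5 * 4, sd = 2), 5, 4,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  m <- expression_matrix(abs(x), "protein", "linear")
  m$values <- x; m$scale <- "log2"
  res <- run_pca(m, 3)
  # oracle: eigendecomposition of the sample covariance of samples x features
  xs <- scale(t(x), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xs))
  expect_equal(unname(res$explained_all)[1:3],
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(unname(res$scores[, j])),
                 abs(unname(xs %*% ev$vectors[, j])[, 1]), tolerance = 1e-9)
    # sign convention: top-|loading| feature has positive loading
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  expect_equal(sum(res$explained_all), 1, tolerance = 1e-12)

  # two samples span one axis
  m2 <- m; m2$values <- x[, 1:2]
  expect_equal(unname(run_pca(m2, 1)$explained_fraction), 1)

  # duplicated samples get identical scores
  xd <- cbind(x, x); colnames(xd) <- paste0("s", 1:8)
  md <- m; md$values <- xd
  rd <- run_pca(md, 2)
  expect_equal(unname(rd$scores[1:4, ]), unname(rd$scores[5:8, ]),
               tolerance = 1e-9)

  # sample reordering leaves scores invariant (up to order)
  mp <- m; mp$values <- x[, c(3, 1, 4, 2)]
  rp <- run_pca(mp, 2)
  expect_equal(unname(rp$scores[match(paste0("s", 1:4), rownames(rp$scores)), ]),
               unname(res$scores[, 1:2]), tolerance = 1e-9)

  expect_error(run_pca(expression_matrix(
    matrix(1, 3, 3, dimnames = list(letters[1:3], letters[4:6])),
    "protein", "linear") |> log2_transform(), 2), "variance|constant")
})

test_that("study design validation enforces the stage vocabulary and unique
           triples", {
  d <- make_design(2)
  expect_s3_class(d, "StudyDesign")
  bad <- as.data.frame(d)
  bad$stage <- as.character(bad$stage)
  bad$stage[1] <- "E999"
  expect_error(study_design(bad), "unknown stage")
  dup <- as.data.frame(make_design(2))
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(study_design(dup), "duplicate sample")
  tri <- as.data.frame(make_design(2))
  tri$replicate[2] <- tri$replicate[1]
  expect_error(study_design(tri), "triples")
})
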