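test_that("standardize_profiles z-scores rows and excludes flat features", {
  v <- rbind(c(1, 2, 3), c(5, 5, 5), c(2, 4, 6))
  rownames(v) <- c("a", "flat", "c")
  colnames(v) <- c("E57", "E73", "E90")
  m <- expression_matrix(v, "protein", "linear")
  z <- standardize_profiles(m)
  expect_equal(rownames(z$values), c("a", "c"))
  expect_equal(attr(z, "excluded"), "flat")
  expect_equal(unname(z$values["a", ]), (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(unname(rowMeans(z$values)), c(0, 0))
  expect_equal(unname(apply(z$values, 1, sd)), c(1, 1))
  # idempotence
  z2 <- standardize_profiles(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
})

test_that("fuzzy c-means degenerate and symmetric cases behave as forced", {
  x <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), NULL))
  m1 <- fuzzy_cmeans(x, c = 1, seed = 1)
  expect_equal(unname(m1$membership[, 1]), rep(1, 4))
  expect_equal(unname(m1$centers[1, ]), colMeans(x))

  # a point equidistant from two symmetric centers gets membership (1/2, 1/2)
  xs <- rbind(a = c(-1, 0), b = c(1, 0), mid = c(0, 0))
  ms <- fuzzy_cmeans(xs, c = 2, m = 2, seed = 1,
                     init = rbind(c(-1, 0), c(1, 0)), max_iter = 1)
  expect_equal(unname(ms$membership["mid", ]), c(0.5, 0.5))
  # points coinciding with a center take membership 1 there
  expect_equal(max(ms$membership["a", ]), 1)
})

test_that("one fuzzy c-means update step reproduces the hand-computed
           membership formula", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(x) <- paste0("p", 1:4)
  init <- rbind(c(0, 0.5), c(10, 0.5))
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1, init = init, max_iter = 1)
  # hand oracle: u_ij = 1 / sum_k (d_ij^2 / d_ik^2) for m = 2
  d2 <- rbind(c(0.25, 100.25), c(0.25, 100.25),
              c(100.25, 0.25), c(100.25, 0.25))
  u_oracle <- d2
  for (i in 1:4) for (j in 1:2) {
    u_oracle[i, j] <- 1 / sum((d2[i, j] / d2[i, ]))
  }
  expect_equal(unname(fit$membership), unname(u_oracle), tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 4), tolerance = 1e-9)
})

test_that("the objective is non-increasing and memberships stay normalized
           across seeds", {
  set.seed(5)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(paste0("f", 1:60), NULL))
  for (s in c(1, 7, 23)) {
    fit <- fuzzy_cmeans(x, c = 3, m = 2, seed = s)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
    expect_equal(unname(rowSums(fit$membership)), rep(1, 60),
                 tolerance = 1e-9)
    expect_true(all(is.finite(fit$centers)))
  }
  # determinism given the seed
  f1 <- fuzzy_cmeans(x, c = 3, seed = 11)
  f2 <- fuzzy_cmeans(x, c = 3, seed = 11)
  expect_identical(f1$membership, f2$membership)
  expect_error(fuzzy_cmeans(x, c = 60, seed = 1), "smaller")
  expect_error(fuzzy_cmeans(x * NA, c = 2, seed = 1), "finite")
})

test_that("hard labels approach k-means labels as the fuzzifier nears 1 on
           well-separated clusters", {
  set.seed(9)
  centers <- rbind(c(0, 0, 0), c(10, 10, 10), c(-10, 5, 0))
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(180, sd = 0.3), 60)
  rownames(x) <- paste0("f", 1:60)
  fcm <- fuzzy_cmeans(x, c = 3, m = 1.05, seed = 2, init = centers)
  km <- with(list(), {set.seed(2); stats::kmeans(x, centers = centers)})
  hard <- apply(fcm$membership, 1, which.max)
  expect_equal(unname(hard), unname(km$cluster))
})

test_that("fuzzy c-means agrees with an independent implementation on a fixed
           initialization", {
  skip_if_not_installed("e1071")
  set.seed(31)
  mu <- rbind(c(0, 0, 0, 0, 0), c(4, 4, 0, -4, -4), c(-4, 0, 4, 0, -4))
  x <- mu[rep(1:3, each = 30), ] + matrix(rnorm(90 * 5, sd = 0.5), 90)
  rownames(x) <- paste0("f", 1:90)
  init <- mu + 0.1
  ours <- fuzzy_cmeans(x, c = 3, m = 2, seed = 1, init = init,
                       tol = 1e-12, max_iter = 500)
  ref <- e1071::cmeans(x, centers = init, m = 2, iter.max = 500,
                       method = "cmeans")
  ord <- apply(omnifiber:::sqdist(ours$centers, ref$centers), 1, which.min)
  expect_equal(unname(ours$centers), unname(ref$centers[ord, ]),
               tolerance = 1e-4)
  expect_equal(unname(ours$membership), unname(ref$membership[, ord]),
               tolerance = 1e-3)
})

test_that("tendency assignment uses argmax with canonical relabeling", {
  u <- rbind(c(0.9, 0.05, 0.03, 0.02),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.1, 0.2, 0.3, 0.4))
  rownames(u) <- c("a", "b", "c")
  centers <- rbind(c(-1, 0, 1), c(1, 0, -1), c(0, 1, 0), c(-1, 1, 2))
  model <- structure(list(centers = centers, membership = u, fuzzifier_m = 2,
                          objective = 0, n_iter = 1, seed = 1),
                     class = "FcmModel")
  # canonical order by (peak stage, last value): rows 2 (peak 1, -1),
  # 3 (peak 2, 0), 1 (peak 3, 1), 4 (peak 3, 2) -> permutation (2,3,1,4)
  ass <- assign_tendencies(model)
  expect_equal(ass$tendency[ass$feature_id == "a"], 3)  # old cluster 1
  expect_equal(ass$tendency[ass$feature_id == "b"], 1)  # tie -> lowest index
  expect_equal(ass$max_membership[ass$feature_id == "a"], 0.9)
  # min_membership gate
  ass2 <- assign_tendencies(model, min_membership = 0.3)
  expect_true(is.na(ass2$tendency[ass2$feature_id == "b"]))
  # relabeling is a permutation: counts preserved (tie-free memberships)
  u3 <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
              c(0.1, 0.1, 0.1, 0.7), c(0.6, 0.2, 0.1, 0.1))
  rownames(u3) <- paste0("g", 1:4)
  model3 <- structure(list(centers = centers, membership = u3,
                           fuzzifier_m = 2, objective = 0, n_iter = 1,
                           seed = 1), class = "FcmModel")
  ass3 <- assign_tendencies(model3)
  expect_equal(sort(as.integer(table(ass3$tendency))),
               sort(as.integer(table(apply(u3, 1, which.max)))))
})

test_that("cross-region composition counts shared and unique members", {
  ld <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                   tendency = c(1, 1, 1, 2, NA))
  sd_ <- data.frame(feature_id = c("a", "b", "f", "d", "g"),
                    tendency = c(1, 1, 1, 2, 2))
  ov <- compare_regions(ld, sd_)
  t1 <- ov[ov$tendency == 1, ]
  expect_equal(t1$n_shared, 2)
  expect_equal(t1$n_ld_only, 1)
  expect_equal(t1$n_sd_only, 1)
  expect_equal(t1$frac_different, 0.5)
  # identical assignments -> frac_different 0
  same <- compare_regions(ld, ld)
  expect_true(all(same$frac_different == 0))
  # disjoint universes -> frac_different 1
  dis <- compare_regions(ld, within(ld, feature_id <- paste0("x", feature_id)))
  expect_true(all(dis$frac_different == 1))
  # planted 3 shared + 1 + 1 unique -> 0.4
  a <- data.frame(feature_id = c("s1", "s2", "s3", "u1"), tendency = 1)
  b <- data.frame(feature_id = c("s1", "s2", "s3", "u2"), tendency = 1)
  expect_equal(compare_regions(a, b)$frac_different, 0.4)
})

test_that("planted archetypes are recovered from a full study", {
  cfg <- simulation_config(n_genes = 400, trend_fraction = 1, dap_fraction = 0,
                           presence_fraction = 0, concordance_fraction = 0,
                           detection_limit = 0, seed = 404)
  st <- generate_study(cfg)
  ass <- region_tendencies(st$protein, st$design, "LD", c = 4, seed = 7)
  ari <- trend_agreement(
    setNames(st$truth$trend$archetype, st$truth$trend$gene_id), ass)
  expect_gte(ari, 0.9)
})
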