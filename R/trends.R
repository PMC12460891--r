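#' @title Temporal trend clustering
#' @description Soft clustering of per-region stage-mean profiles into
#'   tendencies by fuzzy c-means (the Mfuzz-style algorithm), hard assignment
#'   with canonical relabeling, and cross-region composition comparison.
#' @name trends
NULL

#' Z-score profiles across stages
#'
#' Per-feature standardization (mean 0, sd 1 across the stage columns), the
#' conventional preprocessing before fuzzy c-means so clusters reflect shape,
#' not level. Features with zero temporal variance are excluded and reported.
#'
#' @param m An [expression_matrix()] of stage-mean profiles (>= 2 columns).
#' @return The standardized matrix; excluded feature ids in
#'   `attr(, "excluded")`.
#' @export
standardize_profiles <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- m$values
  if (ncol(x) < 2) stop("need >= 2 stages to standardize", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- m
  out$values <- z
  attr(out, "excluded") <- rownames(x)[!keep]
  out
}

# Squared Euclidean distances between rows of x and rows of centers.
sqdist <- function(x, centers) {
  n <- nrow(x); c <- nrow(centers)
  d2 <- matrix(0, n, c)
  for (j in seq_len(c)) {
    d2[, j] <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
  }
  d2
}

# Memberships from squared distances; exact-zero distance gives membership 1
# at that center (split if several coincide).
fcm_memberships <- function(d2, m) {
  pow <- 1 / (m - 1)
  u <- 1 / (d2^pow)
  zero <- d2 == 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ][zero[hit, , drop = FALSE]] <- 1
  }
  u / rowSums(u)
}

# k-means++-style seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  idx <- integer(c)
  idx[1] <- sample.int(n, 1)
  if (c > 1) {
    for (j in 2:c) {
      d2 <- sqdist(x, x[idx[seq_len(j - 1)], , drop = FALSE])
      nearest <- apply(d2, 1, min)
      if (all(nearest == 0)) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = nearest / sum(nearest))
      }
    }
  }
  x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering
#'
#' Classic alternating optimization of the fuzzy c-means objective
#' `J = sum_ij u_ij^m ||x_i - v_j||^2`: memberships
#' `u_ij = 1 / sum_k (||x_i - v_j|| / ||x_i - v_k||)^(2/(m-1))`, centers
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the objective
#' change drops below `tol` or `max_iter` is reached. Deterministic given
#' `seed` (k-means++-style center seeding). A point at exactly zero distance
#' from a center takes membership 1 there.
#'
#' @param x Numeric matrix, features x timepoints (standardized profiles).
#' @param c Number of clusters (>= 1, < number of features).
#' @param m Fuzzifier (> 1); default 2.
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param max_iter Iteration cap (default 300).
#' @param seed RNG seed for initialization (required for reproducibility).
#' @param init Optional c x T matrix of initial centers (overrides seeding).
#' @return An `FcmModel`: `centers` (c x T), `membership` (features x c, rows
#'   sum to 1), `fuzzifier_m`, `objective`, `objective_trace`, `n_iter`,
#'   `seed`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, tol = 1e-6, max_iter = 300,
                         seed = 1L, init = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix",
                                            call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in `x`", call. = FALSE)
  if (c < 1) stop("c must be >= 1", call. = FALSE)
  if (c >= nrow(x) && c > 1) stop("c must be smaller than the number of features",
                                  call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)

  if (c == 1) {
    centers <- matrix(colMeans(x), 1, ncol(x))
    colnames(centers) <- colnames(x)
    u <- matrix(1, nrow(x), 1, dimnames = list(rownames(x), NULL))
    obj <- sum(sqdist(x, centers))
    return(structure(list(centers = centers, membership = u, fuzzifier_m = m,
                          objective = obj, objective_trace = obj, n_iter = 0L,
                          seed = seed),
                     class = "FcmModel"))
  }

  centers <- if (is.null(init)) {
    with_seed(seed, kmeanspp_init(x, c))
  } else {
    stopifnot(nrow(init) == c, ncol(init) == ncol(x))
    init
  }

  trace <- numeric(0)
  obj_prev <- Inf
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- sqdist(x, centers)
    u <- fcm_memberships(d2, m)
    obj <- sum(u^m * d2)
    trace <- c(trace, obj)
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    if (abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }
  rownames(u) <- rownames(x)
  colnames(centers) <- colnames(x)
  structure(list(centers = centers, membership = u, fuzzifier_m = m,
                 objective = trace[length(trace)], objective_trace = trace,
                 n_iter = length(trace), seed = seed),
            class = "FcmModel")
}

# Canonical cluster order: by stage index of the center's maximum, then by
# the center value at the final stage. Makes "Tendency k" comparable across
# runs and regions.
canonical_order <- function(centers) {
  peak <- apply(centers, 1, which.max)
  last <- centers[, ncol(centers)]
  order(peak, last)
}

#' Hard tendency labels from a fuzzy model
#'
#' Argmax membership per feature (ties to the lowest cluster index), with
#' clusters relabeled canonically by center shape so tendency numbers are
#' stable across runs. Features whose maximum membership falls below
#' `min_membership` are labeled `NA` (unassigned).
#'
#' @param model An [fuzzy_cmeans()] fit.
#' @param min_membership Minimum membership for a hard label (default 0).
#' @return Data frame `feature_id`, `tendency` (1..c or NA), `max_membership`;
#'   relabeled centers in `attr(, "centers")`.
#' @export
assign_tendencies <- function(model, min_membership = 0) {
  stopifnot(inherits(model, "FcmModel"))
  ord <- canonical_order(model$centers)
  u <- model$membership[, ord, drop = FALSE]
  centers <- model$centers[ord, , drop = FALSE]
  hard <- apply(u, 1, which.max)  # which.max breaks ties by lowest index
  maxu <- u[cbind(seq_len(nrow(u)), hard)]
  hard[maxu < min_membership] <- NA
  out <- data.frame(feature_id = rownames(u), tendency = hard,
                    max_membership = maxu, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- centers
  out
}

#' Cluster one region's temporal profiles into tendencies
#'
#' Convenience wrapper: stage means for one region, log2 transform if needed,
#' per-feature standardization, fuzzy c-means, canonical hard labels.
#'
#' @param m Linear- or log2-scale protein [expression_matrix()].
#' @param d Matching [study_design()].
#' @param region Region to cluster.
#' @param c Number of tendencies (default 4).
#' @param m_fuzz Fuzzifier (default 2).
#' @param seed RNG seed.
#' @param min_membership Passed to [assign_tendencies()].
#' @return The [assign_tendencies()] table with `region` column; the fitted
#'   model in `attr(, "model")`, excluded zero-variance features in
#'   `attr(, "excluded")`.
#' @export
region_tendencies <- function(m, d, region, c = 4, m_fuzz = 2, seed = 1L,
                              min_membership = 0) {
  if (m$scale == "linear") m <- log2_transform(m)
  prof <- stage_mean_profiles(m, d, region = region)
  z <- standardize_profiles(prof)
  model <- fuzzy_cmeans(z$values, c = c, m = m_fuzz, seed = seed)
  ass <- assign_tendencies(model, min_membership = min_membership)
  ass$region <- region
  attr(ass, "model") <- model
  attr(ass, "excluded") <- attr(z, "excluded")
  ass
}

#' Cross-region tendency composition
#'
#' For each tendency, how many features are shared between the two regions'
#' assignments and how many are unique to one region;
#' `frac_different = (n_ld_only + n_sd_only) / total`.
#'
#' @param ld,sd [assign_tendencies()] tables for the two regions.
#' @return Data frame with one row per tendency: `tendency`, `n_shared`,
#'   `n_ld_only`, `n_sd_only`, `frac_different`.
#' @export
compare_regions <- function(ld, sd) {
  tend <- sort(unique(c(ld$tendency, sd$tendency)))
  tend <- tend[!is.na(tend)]
  rows <- lapply(tend, function(t) {
    a <- ld$feature_id[!is.na(ld$tendency) & ld$tendency == t]
    b <- sd$feature_id[!is.na(sd$tendency) & sd$tendency == t]
    shared <- length(intersect(a, b))
    ld_only <- length(setdiff(a, b))
    sd_only <- length(setdiff(b, a))
    tot <- shared + ld_only + sd_only
    data.frame(tendency = t, n_shared = shared, n_ld_only = ld_only,
               n_sd_only = sd_only,
               frac_different = if (tot > 0) (ld_only + sd_only) / tot else NA_real_)
  })
  do.call(rbind, rows)
}
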