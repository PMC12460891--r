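#' @title Cross-dataset harmonization
#' @description Location-scale batch adjustment with protected covariates,
#'   per-feature Z-scoring, and profile clustering for cross-species ortholog
#'   expression comparison.
#' @name harmonization
NULL

#' Read a long-format ortholog expression table
#'
#' Tab-separated columns `gene_group`, `dataset`, `sample`, `value` (single-
#' copy ortholog groups only; one-to-many orthology must be resolved
#' upstream). Pivoted to a gene_group x sample matrix; rows with any missing
#' sample are dropped and counted.
#'
#' @param path File path.
#' @return List: `values` (matrix), `meta` (data frame `sample`, `dataset`),
#'   `n_dropped` (incomplete rows removed).
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_group", "dataset", "sample", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  samples <- unique(df$sample)
  genes <- unique(df$gene_group)
  x <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  x[cbind(match(df$gene_group, genes), match(df$sample, samples))] <- df$value
  complete <- stats::complete.cases(x)
  meta <- unique(df[, c("sample", "dataset")])
  meta <- meta[match(samples, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  list(values = x[complete, , drop = FALSE], meta = meta,
       n_dropped = sum(!complete))
}

#' Location-scale batch adjustment with protected covariates
#'
#' Per feature, fits `value = covariate effects + batch shift` by least
#' squares, removes the (sample-size-weighted, centered) batch shifts, and
#' rescales per-batch residuals to the pooled residual scale. Covariate
#' effects are retained untouched. This is a plain location-scale adjustment:
#' it deliberately omits the empirical-Bayes shrinkage of ComBat-style
#' methods, trading a little small-sample stability for a directly testable
#' contract (equalized batch moments, exactly preserved covariate contrasts in
#' the noiseless limit).
#'
#' @param x Numeric matrix, features x samples, log-scale values.
#' @param batch Factor/character of batch labels, one per sample.
#' @param covariates Optional data frame of protected covariates (one row per
#'   sample).
#' @return The adjusted matrix (same dimensions).
#' @export
batch_adjust <- function(x, batch, covariates = NULL) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  batch <- factor(batch)
  if (length(batch) != ncol(x)) stop("one batch label per sample", call. = FALSE)
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("each batch needs >= 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "), call. = FALSE)
  }
  if (nlevels(batch) == 1) return(x)

  C <- if (is.null(covariates)) {
    matrix(1, ncol(x), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  B <- stats::model.matrix(~ 0 + batch)
  Bc <- B[, -1, drop = FALSE]  # reference-coded batch shifts
  X <- cbind(C, Bc)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("batch is confounded with covariates; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  beta <- qr.coef(qx, t(x))                    # p x features
  fitted <- X %*% beta                          # samples x features
  resid <- t(x) - fitted

  # Per-sample batch shift (reference batch = 0), centered by batch size so
  # the grand mean is untouched.
  gamma <- rbind(0, beta[seq(ncol(C) + 1, ncol(X)), , drop = FALSE])
  shift <- gamma[as.integer(batch), , drop = FALSE]       # samples x features
  gbar <- colSums(shift) / ncol(x)
  shift_centered <- sweep(shift, 2, gbar)

  # Rescale residuals batch-wise to the pooled scale.
  scaled <- resid
  lev <- levels(batch)
  var_b <- vapply(lev, function(b) {
    rb <- resid[batch == b, , drop = FALSE]
    apply(rb, 2, stats::var)
  }, numeric(ncol(resid)))                      # features x batches
  if (is.null(dim(var_b))) var_b <- matrix(var_b, ncol = length(lev))
  w <- as.numeric(nb[lev] - 1)
  pooled_sd <- sqrt(as.numeric(var_b %*% w) / sum(w))
  for (b in lev) {
    idx <- batch == b
    sb <- sqrt(var_b[, lev == b])
    fac <- ifelse(sb > 0, pooled_sd / sb, 1)
    scaled[idx, ] <- sweep(resid[idx, , drop = FALSE], 2, fac, `*`)
  }

  t(fitted - shift_centered + scaled)
}

#' Z-score matrix rows
#'
#' Per-feature standardization to mean 0, sd 1 across samples; zero-variance
#' rows are dropped and counted in `attr(, "n_dropped")`.
#'
#' @param x Numeric matrix, features x samples.
#' @return The standardized matrix.
#' @export
zscore_rows <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sdv[keep]
  attr(z, "n_dropped") <- sum(!keep)
  z
}

#' Cluster standardized expression profiles
#'
#' Hard k-means clustering (fixed seed, multiple starts) of concatenated
#' profiles; cluster labels are C1..Ck ordered by decreasing cluster size.
#' Optionally reports per-cluster mean trajectories split by a column grouping
#' (e.g. species).
#'
#' @param x Standardized matrix (rows = features, e.g. ortholog groups).
#' @param k Number of clusters (< number of rows).
#' @param seed RNG seed.
#' @param col_groups Optional factor over columns (e.g. species/dataset) for
#'   split mean curves.
#' @param method `"kmeans"` (default) or `"fcm"` (reuses [fuzzy_cmeans()] with
#'   hard argmax labels).
#' @return List: `labels` (named C1..Ck factor per row), `centers` (k x
#'   columns mean curves), `group_means` (list per cluster of per-group mean
#'   curves, when `col_groups` given), `sizes`.
#' @export
cluster_profiles <- function(x, k, seed = 1L, col_groups = NULL,
                             method = c("kmeans", "fcm")) {
  method <- match.arg(method)
  if (k >= nrow(x)) stop("k must be smaller than the number of rows",
                         call. = FALSE)
  if (method == "kmeans") {
    fit <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 50,
                                         iter.max = 100))
    raw <- fit$cluster
  } else {
    model <- fuzzy_cmeans(x, c = k, seed = seed)
    raw <- apply(model$membership, 1, which.max)
  }
  # Stable label order: decreasing cluster size, ties by first occurrence.
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_len(k), names(sizes)[ord])
  lab <- relabel[as.character(raw)]
  labels <- factor(paste0("C", lab), levels = paste0("C", seq_len(k)))
  names(labels) <- rownames(x)
  centers <- t(vapply(seq_len(k), function(j) {
    colMeans(x[lab == j, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(centers) <- levels(labels)
  colnames(centers) <- colnames(x)
  group_means <- NULL
  if (!is.null(col_groups)) {
    col_groups <- factor(col_groups)
    group_means <- lapply(seq_len(k), function(j) {
      xi <- x[lab == j, , drop = FALSE]
      sapply(levels(col_groups), function(g) {
        colMeans(xi[, col_groups == g, drop = FALSE])
      }, simplify = FALSE)
    })
    names(group_means) <- levels(labels)
  }
  list(labels = labels, centers = centers, group_means = group_means,
       sizes = as.integer(table(labels)))
}
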