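#' @title Expression matrices and the study design
#' @description Core containers shared by every stage of the pipeline: a
#'   features x samples abundance matrix tagged by modality and scale, and the
#'   sample design binding each column to muscle region, developmental stage
#'   and replicate.
#' @name core-io
NULL

#' Ordered developmental stages of the porcine muscle design
#'
#' Embryonic days 57/73/90 and postnatal days 1/28/120, in developmental
#' order. All stage handling validates against (or orders by) this vocabulary
#' unless a design supplies its own ordered stage set.
#'
#' @export
MUSCLE_STAGES <- c("E57", "E73", "E90", "P1", "P28", "P120")

#' Muscle regions of the two-region design
#'
#' LD = longissimus dorsi (fast-twitch dominant), SD = semitendinosus
#' (slow-twitch enriched).
#'
#' @export
MUSCLE_REGIONS <- c("LD", "SD")

#' Construct an expression matrix
#'
#' @param values Numeric matrix, features x samples, with feature ids as
#'   rownames and sample ids as colnames. Nonnegative when `scale = "linear"`.
#'   For protein LFQ data a value of 0 means "not detected".
#' @param modality `"protein"` (LFQ intensity) or `"transcript"` (TPM).
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `modality`, `scale`.
#' @export
expression_matrix <- function(values, modality = c("protein", "transcript"),
                              scale = c("linear", "log2")) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale abundances must be nonnegative", call. = FALSE)
  }
  structure(list(values = values, modality = modality, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s, %s scale]\n",
              nrow(x$values), ncol(x$values), x$modality, x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Validate a study design table
#'
#' @param df Data frame with columns `sample_id`, `region`, `stage`,
#'   `replicate`.
#' @param stages Ordered stage vocabulary; defaults to [MUSCLE_STAGES].
#' @param regions Allowed regions; defaults to [MUSCLE_REGIONS].
#' @return The validated design (class `StudyDesign`/`data.frame`) with
#'   `stage` as an ordered factor and `region` as a factor.
#' @export
study_design <- function(df, stages = MUSCLE_STAGES, regions = MUSCLE_REGIONS) {
  need <- c("sample_id", "region", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  bad <- setdiff(unique(as.character(df$region)), regions)
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$stage)), stages)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$region <- factor(as.character(df$region), levels = regions)
  df$stage <- factor(as.character(df$stage), levels = stages, ordered = TRUE)
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1)) stop("replicate must be >= 1", call. = FALSE)
  key <- paste(df$region, df$stage, df$replicate)
  if (anyDuplicated(key)) {
    stop("(region, stage, replicate) triples must be unique", call. = FALSE)
  }
  class(df) <- c("StudyDesign", "data.frame")
  df
}

#' Read a tab-separated study design file
#'
#' @inheritParams read_expression_matrix
#' @inheritParams study_design
#' @return A validated [study_design()] table.
#' @export
read_study_design <- function(path, stages = MUSCLE_STAGES,
                              regions = MUSCLE_REGIONS) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  study_design(df, stages = stages, regions = regions)
}

# Check every matrix column is covered by the design; returns design rows
# reordered to the matrix's samples.
match_design <- function(m, d) {
  idx <- match(sample_ids(m), d$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from design: ",
         paste(sample_ids(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d[idx, , drop = FALSE]
}

#' Read a features x samples abundance matrix
#'
#' Tab-separated, first column = feature id, header row = sample ids. Missing
#' cells (empty or `NA`) are stored as 0: for protein LFQ this encodes
#' "not detected"; TPM matrices conventionally carry explicit zeros already.
#' Leading lines starting with `#` (provenance headers) are skipped.
#'
#' @param path File path.
#' @param modality `"protein"` or `"transcript"`.
#' @return A linear-scale [expression_matrix()].
#' @export
read_expression_matrix <- function(path, modality = c("protein", "transcript")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("matrix file needs a feature column and >= 1 sample",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path, call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- is.na(conv) & !(is.na(v) | v %in% c("", "NA"))
      if (any(bad)) {
        stop("non-numeric cell(s) in column ", names(vals)[j], call. = FALSE)
      }
      v <- conv
    }
    vals[[j]] <- v
  }
  x <- as.matrix(vals)
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("negative abundance value(s) in ", path, call. = FALSE)
  rownames(x) <- ids
  expression_matrix(x, modality = modality, scale = "linear")
}

#' Write an expression matrix with a provenance header
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param command Free-text provenance note recorded in the `#` header line.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, command = "write") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  header <- sprintf("# omnifiber %s %s %s",
                    as.character(utils::packageVersion("omnifiber")),
                    command,
                    substr(paste(format(digest_lite(m$values)), collapse = ""), 1, 8))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("feature_id", colnames(m$values)), collapse = "\t"), con)
  utils::write.table(
    data.frame(feature_id = rownames(m$values), m$values, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Cheap content hash (sum-based) for provenance lines; not cryptographic.
digest_lite <- function(x) {
  v <- as.numeric(x)
  s <- sum(v * seq_along(v) %% 97, na.rm = TRUE)
  sprintf("%08x", as.integer(abs(s) %% 2^31))
}

#' Log2-transform a linear-scale matrix
#'
#' Each abundance x becomes log2(x + pseudocount); protein zeros
#' ("not detected") map to log2(pseudocount), which is 0 at the default
#' pseudocount of 1 so absence stays at the floor of the log scale.
#'
#' @param m Linear-scale [expression_matrix()].
#' @param pseudocount Nonnegative offset added before the log (default 1).
#' @return The log2-scale matrix; modality preserved.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
  if (pseudocount == 0 && any(m$values == 0)) {
    stop("pseudocount 0 with zero abundances present", call. = FALSE)
  }
  out <- m
  out$values <- log2(m$values + pseudocount)
  out$scale <- "log2"
  out
}

#' Average replicates into stage (or region x stage) profiles
#'
#' @param m An [expression_matrix()] on either scale.
#' @param d Matching [study_design()].
#' @param pool_regions If `TRUE` (default), one column per stage averaging
#'   across both regions; if `FALSE`, one column per region x stage named
#'   `REGION_STAGE`.
#' @param region Optional single region to restrict to (implies per-stage
#'   columns for that region only).
#' @return An [expression_matrix()] of stage-mean profiles on `m`'s scale.
#' @export
stage_mean_profiles <- function(m, d, pool_regions = TRUE, region = NULL) {
  d <- match_design(m, d)
  if (!is.null(region)) {
    keep <- d$region == region
    if (!any(keep)) stop("no samples in region ", region, call. = FALSE)
    m$values <- m$values[, keep, drop = FALSE]
    d <- d[keep, , drop = FALSE]
    pool_regions <- TRUE
  }
  grp <- if (pool_regions) {
    factor(as.character(d$stage), levels = levels(d$stage))
  } else {
    interaction(d$region, d$stage, sep = "_", lex.order = TRUE)
  }
  counts <- table(grp)
  if (any(counts == 0)) {
    stop("stage group(s) with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  present <- levels(grp)
  cols <- lapply(present, function(g) {
    rowMeans(m$values[, grp == g, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- present
  rownames(out) <- feature_ids(m)
  res <- m
  res$values <- out
  res
}

#' Pearson correlations between stage-mean profiles
#'
#' Computes the stage x stage Pearson correlation matrix over per-feature
#' stage-mean profiles (region-pooled by default, the convention of reporting
#' one 6 x 6 matrix for the whole design; pass `pool_regions = FALSE` upstream via
#' [stage_mean_profiles()] for a per-region variant). Features constant across
#' all stage means are excluded.
#'
#' @param m Log2-scale [expression_matrix()].
#' @param d Matching [study_design()].
#' @param pool_regions Passed to [stage_mean_profiles()].
#' @return A list of class `StageCorrelationMatrix`: `stages` and symmetric
#'   matrix `r` with unit diagonal.
#' @export
stage_correlations <- function(m, d, pool_regions = TRUE) {
  if (m$scale != "log2") stop("stage correlations expect a log2-scale matrix",
                              call. = FALSE)
  prof <- stage_mean_profiles(m, d, pool_regions = pool_regions)
  x <- prof$values
  keep <- apply(x, 1, function(v) max(v) > min(v))
  if (sum(keep) < 2) stop("fewer than 2 features with temporal variance",
                          call. = FALSE)
  r <- stats::cor(x[keep, , drop = FALSE], method = "pearson")
  diag(r) <- 1
  structure(list(stages = colnames(x), r = r), class = "StageCorrelationMatrix")
}

#' Principal component analysis of samples
#'
#' Samples are projected onto the principal axes of the feature-centered data
#' (SVD via [stats::prcomp]); features are centered but not unit-scaled by
#' default, the usual convention for abundance PCA. The sign of each component
#' is fixed so that its largest-magnitude feature loading is positive, making
#' scores reproducible across platforms.
#'
#' @param m Log2-scale [expression_matrix()].
#' @param n_components Number of components to keep.
#' @param scale_features Unit-scale features before the SVD (default `FALSE`).
#' @return A list of class `PcaResult`: `scores` (samples x components),
#'   `explained_fraction`, `loadings`.
#' @export
run_pca <- function(m, n_components = 2, scale_features = FALSE) {
  if (m$scale != "log2") stop("PCA expects a log2-scale matrix", call. = FALSE)
  x <- t(m$values)  # samples x features
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("constant matrix: no variance for PCA", call. = FALSE)
  if (scale_features) x <- x[, sds > 0, drop = FALSE]
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(features, samples)", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_features)
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, explained_fraction = expl[seq_len(k)],
                 explained_all = expl, loadings = load),
            class = "PcaResult")
}
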