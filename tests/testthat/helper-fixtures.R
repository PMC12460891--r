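# Shared fixture builders: small designs and matrices constructed in code.

# Full 2-region x 6-stage x n-replicate design.
make_design <- function(replicates = 3) {
  df <- expand.grid(replicate = seq_len(replicates), stage = MUSCLE_STAGES,
                    region = MUSCLE_REGIONS, stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_%s_R%d", df$region, df$stage, df$replicate)
  study_design(df[, c("sample_id", "region", "stage", "replicate")])
}

# Matrix with given per-(region,stage) replicate rows; values: features x
# (region x stage x rep) filled from a feature x stage-mean spec + noise 0.
make_matrix <- function(values, design, modality = "protein") {
  stopifnot(ncol(values) == nrow(design))
  colnames(values) <- design$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  }
  expression_matrix(values, modality = modality, scale = "linear")
}

# One-region design over arbitrary stages (for presence / trend fixtures).
make_region_design <- function(stages, replicates = 3, region = "LD") {
  df <- expand.grid(replicate = seq_len(replicates), stage = stages,
                    stringsAsFactors = FALSE)
  df$region <- region
  df$sample_id <- sprintf("%s_%s_R%d", df$region, df$stage, df$replicate)
  study_design(df[, c("sample_id", "region", "stage", "replicate")],
               stages = stages)
}

# Brute-force BH step-up: q_(i) = min_{j>=i} p_(j) * n / j, mapped back to
# input order. Independent of stats::p.adjust.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Brute-force hypergeometric upper tail by direct summation of the pmf.
hyper_bruteforce <- function(k, K, n, N) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# 20-feature hand-built fixture over one region and two adjacent transitions;
# expected calls enumerated by hand in the comments.
presence_fixture <- function() {
  stages <- c("P1", "P28", "P120")
  d <- make_region_design(stages, replicates = 3, region = "SD")
  rows <- list()
  # f01-f07: planted gains at P1->P28 (all zero, then all positive)
  for (i in 1:7) rows[[i]] <- c(0, 0, 0, 5 + i, 6 + i, 7 + i, 9, 9, 9)
  # f08: detected before -> not increasing under all_replicates
  rows[[8]] <- c(1, 0, 0, 5, 6, 7, 8, 8, 8)
  # f09: still absent -> nothing
  rows[[9]] <- c(0, 0, 0, 0, 0, 0, 0, 0, 0)
  # f10: partial detection after -> not increasing under all_replicates,
  # increasing under mean_based (mean 0 -> mean > 0)
  rows[[10]] <- c(0, 0, 0, 4, 0, 0, 0, 0, 0)
  # f11-f13: losses at P28->P120 (present, then all zero)
  for (i in 11:13) rows[[i]] <- c(2, 2, 2, 5, 6, 7, 0, 0, 0)
  # f14: decreases in abundance but never absent -> no absence-rule call
  rows[[14]] <- c(9, 9, 9, 5, 6, 7, 4, 5, 6)
  # f15: loss at P1->P28
  rows[[15]] <- c(5, 6, 7, 0, 0, 0, 0, 0, 0)
  # f16-f20: constant detected
  for (i in 16:20) rows[[i]] <- rep(3, 9)
  v <- do.call(rbind, rows)
  rownames(v) <- sprintf("f%02d", 1:20)
  list(m = make_matrix(v, d), d = d)
}

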