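#' @title Differential abundance/expression calling
#' @description Two-group t testing on log2 abundances, BH correction, and the
#'   named threshold policies used for region DAPs, stage DAPs and DEGs.
#' @name differential
NULL

#' Define a differential calling policy
#'
#' A call is `(fc_linear >= fc_high or fc_linear <= fc_low, or no FC gate) and
#' (chosen p-type < alpha)`. Fold-change boundaries are inclusive; the p cutoff
#' is strict.
#'
#' @param name Policy label stamped into results.
#' @param fc_low,fc_high Linear fold-change gates (`fc_low < 1 < fc_high`), or
#'   both `NA` for no fold-change gate.
#' @param use_adjusted_p Gate on BH-adjusted q instead of raw p.
#' @param alpha Significance cutoff (strict `<`).
#' @return A `CallingPolicy` list.
#' @export
calling_policy <- function(name, fc_low, fc_high, use_adjusted_p, alpha = 0.05) {
  has_gate <- !(is.na(fc_low) && is.na(fc_high))
  if (has_gate && !(fc_low < 1 && fc_high > 1)) {
    stop("need fc_low < 1 < fc_high", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(name = name, fc_low = fc_low, fc_high = fc_high,
                 has_fc_gate = has_gate,
                 use_adjusted_p = isTRUE(use_adjusted_p), alpha = alpha),
            class = "CallingPolicy")
}

#' Built-in calling policies
#'
#' * `region_dap`: FC >= 1.2 or <= 0.833, raw p < 0.05 (lenient, for the
#'   subtle between-region contrasts);
#' * `stage_dap`: no FC gate, BH-adjusted p < 0.05;
#' * `stage_deg`: |log2FC| >= 1 (FC gates 2 and 0.5), BH-adjusted p < 0.05;
#' * `region_deg`: |log2FC| >= 1, raw p < 0.05.
#'
#' @param name One of the policy names above.
#' @return A [calling_policy()].
#' @export
builtin_policy <- function(name = c("region_dap", "stage_dap", "stage_deg",
                                    "region_deg")) {
  name <- match.arg(name)
  switch(name,
    region_dap = calling_policy("region_dap", 0.833, 1.2, FALSE, 0.05),
    stage_dap  = calling_policy("stage_dap", NA, NA, TRUE, 0.05),
    stage_deg  = calling_policy("stage_deg", 0.5, 2, TRUE, 0.05),
    region_deg = calling_policy("region_deg", 0.5, 2, FALSE, 0.05))
}

#' Two-sided two-group t test on log2 values
#'
#' @param a,b Numeric vectors on the log2 scale; NAs dropped.
#' @param variant `"student"` (pooled variance, the default) or `"welch"`.
#' @return List with `log2fc` (= mean(a) - mean(b)), `p_value`, `degenerate`
#'   (TRUE when both groups have zero variance but unequal means, forcing
#'   p = 0).
#' @export
two_group_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient replication: need >= 2 usable values per group",
         call. = FALSE)
  }
  lfc <- mean(a) - mean(b)
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (lfc == 0) {
      p <- 1
    } else {
      p <- 0
      degenerate <- TRUE
    }
  } else {
    p <- stats::t.test(a, b, var.equal = (variant == "student"))$p.value
  }
  list(log2fc = lfc, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted values, each >= its input and <= 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Specify a two-group contrast
#'
#' @param axis `"region_within_stage"` (LD vs SD at one stage) or
#'   `"stage_pair_within_region"` (two stages within one region).
#' @param region_a,stage_a,region_b,stage_b Group selectors.
#' @return A `ContrastSpec` list with a readable `label`.
#' @export
contrast_spec <- function(axis = c("region_within_stage",
                                   "stage_pair_within_region"),
                          region_a, stage_a, region_b, stage_b) {
  axis <- match.arg(axis)
  if (identical(c(region_a, stage_a), c(region_b, stage_b))) {
    stop("contrast groups must differ", call. = FALSE)
  }
  label <- sprintf("%s_%s.vs.%s_%s", region_a, stage_a, region_b, stage_b)
  structure(list(axis = axis,
                 a = list(region = region_a, stage = stage_a),
                 b = list(region = region_b, stage = stage_b),
                 label = label),
            class = "ContrastSpec")
}

select_samples <- function(d, sel) {
  idx <- d$region == sel$region & d$stage == sel$stage
  if (!any(idx)) {
    stop("contrast selector resolves to no samples: ",
         sel$region, "/", sel$stage, call. = FALSE)
  }
  d$sample_id[idx]
}

#' Run one contrast under a calling policy
#'
#' Fold change is the ratio of linear-scale group means; the t test runs on
#' log2(x + pseudocount). For protein matrices zeros are "not detected" and
#' are treated as missing: features with fewer than 2 detected replicates in
#' either group are skipped (reported in the `skipped` attribute), not
#' imputed. BH q-values are computed over the features tested in this
#' contrast.
#'
#' @param m Linear-scale [expression_matrix()].
#' @param d Matching [study_design()].
#' @param contrast A [contrast_spec()].
#' @param policy A [calling_policy()].
#' @param variant t-test variant, see [two_group_test()].
#' @param pseudocount Offset used for the log2 test values.
#' @return Data frame with one row per tested feature: `feature_id`,
#'   `contrast`, `fc_linear`, `log2fc`, `p_value`, `q_value`, `n_a`, `n_b`,
#'   `called`, `policy`; skipped feature ids in `attr(, "skipped")`.
#' @export
call_contrast <- function(m, d, contrast, policy,
                          variant = c("student", "welch"), pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(contrast, "ContrastSpec"),
            inherits(policy, "CallingPolicy"))
  if (m$scale != "linear") {
    stop("call_contrast expects a linear-scale matrix", call. = FALSE)
  }
  variant <- match.arg(variant)
  d <- match_design(m, d)
  ids_a <- select_samples(d, contrast$a)
  ids_b <- select_samples(d, contrast$b)
  xa <- m$values[, ids_a, drop = FALSE]
  xb <- m$values[, ids_b, drop = FALSE]
  if (m$modality == "protein") {
    xa[xa == 0] <- NA
    xb[xb == 0] <- NA
  }
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ok <- na >= 2 & nb >= 2
  skipped <- feature_ids(m)[!ok]

  xa <- xa[ok, , drop = FALSE]
  xb <- xb[ok, , drop = FALSE]
  mean_a <- rowMeans(xa, na.rm = TRUE)
  mean_b <- rowMeans(xb, na.rm = TRUE)
  fc <- mean_a / mean_b
  la <- log2(xa + pseudocount)
  lb <- log2(xb + pseudocount)
  p <- vapply(seq_len(nrow(la)), function(i) {
    two_group_test(la[i, ], lb[i, ], variant = variant)$p_value
  }, numeric(1))
  q <- bh_adjust(p)

  pass_fc <- if (policy$has_fc_gate) {
    fc >= policy$fc_high | fc <= policy$fc_low
  } else rep(TRUE, length(fc))
  pval <- if (policy$use_adjusted_p) q else p
  called <- pass_fc & pval < policy$alpha

  res <- data.frame(
    feature_id = rownames(xa),
    contrast = contrast$label,
    fc_linear = fc,
    log2fc = log2(fc),
    p_value = p,
    q_value = q,
    n_a = na[ok],
    n_b = nb[ok],
    called = called,
    policy = policy$name,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "skipped") <- skipped
  res
}

#' Enumerate stage-pair contrasts within each region
#'
#' @param d A [study_design()].
#' @param scope `"adjacent"` (5 transitions per region) or `"all_pairs"`
#'   (15 pairs per region).
#' @return List of [contrast_spec()]s, ordered region-major then earlier stage
#'   first; each contrast's group a is the earlier stage.
#' @export
enumerate_stage_contrasts <- function(d, scope = c("adjacent", "all_pairs")) {
  scope <- match.arg(scope)
  stages <- levels(d$stage)[levels(d$stage) %in% as.character(d$stage)]
  regions <- levels(d$region)[levels(d$region) %in% as.character(d$region)]
  out <- list()
  for (r in regions) {
    if (scope == "adjacent") {
      pairs <- lapply(seq_len(length(stages) - 1),
                      function(i) c(stages[i], stages[i + 1]))
    } else {
      pairs <- list()
      for (i in seq_len(length(stages) - 1)) {
        for (j in seq(i + 1, length(stages))) {
          pairs[[length(pairs) + 1]] <- c(stages[i], stages[j])
        }
      }
    }
    for (p in pairs) {
      out[[length(out) + 1]] <- contrast_spec(
        "stage_pair_within_region", r, p[1], r, p[2])
    }
  }
  out
}

#' Enumerate region contrasts (LD vs SD) at each stage
#'
#' @param d A [study_design()].
#' @return List of [contrast_spec()]s, one per stage, first region vs second.
#' @export
enumerate_region_contrasts <- function(d) {
  stages <- levels(d$stage)[levels(d$stage) %in% as.character(d$stage)]
  regions <- levels(d$region)[levels(d$region) %in% as.character(d$region)]
  if (length(regions) != 2) stop("need exactly 2 regions", call. = FALSE)
  lapply(stages, function(s) {
    contrast_spec("region_within_stage", regions[1], s, regions[2], s)
  })
}

#' Summarize called sets across contrasts
#'
#' Intersection structure of the per-contrast called-feature sets: pairwise
#' intersection counts, exact membership-pattern (UpSet) counts, and each
#' set's share of the total calls (set size / sum of set sizes, so shares sum
#' to 1).
#'
#' @param called_sets Named list of character vectors (called feature ids per
#'   contrast or stage group).
#' @return List with `sizes`, `union_size`, `pairwise` (matrix), `patterns`
#'   (data frame of membership pattern counts), `shares`.
#' @export
summarize_dap_sets <- function(called_sets) {
  if (length(called_sets) < 1) stop("need >= 1 called set", call. = FALSE)
  if (is.null(names(called_sets))) {
    names(called_sets) <- paste0("set", seq_along(called_sets))
  }
  sets <- lapply(called_sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  pat <- apply(member, 1, paste, collapse = "")
  patterns <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(patterns) <- c("pattern", "count")
  sizes <- vapply(sets, length, integer(1))
  total <- sum(sizes)
  shares <- if (total > 0) sizes / total else sizes * 0
  list(sizes = sizes, union_size = length(univ), pairwise = pairwise,
       patterns = patterns, shares = shares)
}
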