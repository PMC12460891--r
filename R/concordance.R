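#' @title Six-type RNA-protein concordance
#' @description Paired RNA/protein log2 fold changes for a contrast and the
#'   six-type classification of their magnitude/direction agreement
#'   (nine-quadrant analysis).
#' @name concordance
NULL

#' Classify paired fold changes into the six concordance types
#'
#' With `R = |rna_log2fc| >= t`, `P = |prot_log2fc| >= t`, and `S` = direction
#' agreement (a zero fold change agrees with either sign), the default
#' `precedence_v1` rule is:
#' \itemize{
#'   \item Type 1: neither changed (`!R & !P`) — minimal alteration at both
#'     levels;
#'   \item Type 6: both changed, same direction (`R & P & S`);
#'   \item Type 5: both changed, opposite direction (`R & P & !S`);
#'   \item Type 4: exactly one changed, directions agree;
#'   \item Type 2: only protein changed, directions disagree;
#'   \item Type 3: only RNA changed, directions disagree.
#' }
#' Taken literally, the six category definitions overlap ("either" in the Type 4 wording
#' intersects Types 2/3/6); this precedence resolves the overlap with
#' both-above cases taking priority and sign agreement splitting the one-above
#' cases. The rule is exhaustive and mutually exclusive on all of R^2.
#'
#' @param rna_log2fc,prot_log2fc Finite numeric vectors (recycled to common
#'   length).
#' @param t Log2 threshold for "changed" (default 1, i.e. |FC| >= 2; boundary
#'   inclusive).
#' @param rule_variant Classification strategy; only `"precedence_v1"` is
#'   currently defined.
#' @return Integer vector of types 1..6.
#' @export
classify_six_types <- function(rna_log2fc, prot_log2fc, t = 1,
                               rule_variant = "precedence_v1") {
  rule_variant <- match.arg(rule_variant, "precedence_v1")
  if (t <= 0) stop("threshold t must be > 0", call. = FALSE)
  n <- max(length(rna_log2fc), length(prot_log2fc))
  r <- rep_len(as.numeric(rna_log2fc), n)
  p <- rep_len(as.numeric(prot_log2fc), n)
  if (!all(is.finite(r)) || !all(is.finite(p))) {
    stop("fold changes must be finite", call. = FALSE)
  }
  R <- abs(r) >= t
  P <- abs(p) >= t
  S <- sign(r) == 0 | sign(p) == 0 | sign(r) == sign(p)
  type <- integer(n)
  type[!R & !P] <- 1L
  type[R & P & S] <- 6L
  type[R & P & !S] <- 5L
  one <- xor(R, P)
  type[one & S] <- 4L
  type[one & !S & P] <- 2L
  type[one & !S & R] <- 3L
  type
}

#' Paired RNA/protein log2 fold changes for a contrast
#'
#' Fold changes are computed identically in both modalities as the log2 ratio
#' of linear group means (`log2((mean_a + pseudocount)/(mean_b + pseudocount))`).
#' The default pseudocount is 0 so reported fold changes align exactly with the
#' linear |FC| gates; genes with a zero group mean in either modality are then
#' excluded (use `pseudocount = 1` to retain them). Genes detected in only one
#' modality are excluded and counted.
#'
#' @param rna Linear-scale transcript [expression_matrix()].
#' @param prot Linear-scale protein [expression_matrix()].
#' @param d [study_design()] covering both matrices' samples.
#' @param contrast A [contrast_spec()].
#' @param id_map Data frame mapping `gene_id` to `protein_id`; defaults to the
#'   identity map over shared feature ids.
#' @param pseudocount Offset added to group means before the ratio (default 0).
#' @return Data frame `gene_id`, `rna_log2fc`, `prot_log2fc`; counts of
#'   excluded genes in `attr(, "excluded")`.
#' @export
paired_fold_changes <- function(rna, prot, d, contrast, id_map = NULL,
                                pseudocount = 0) {
  stopifnot(inherits(rna, "ExpressionMatrix"), inherits(prot, "ExpressionMatrix"))
  if (rna$scale != "linear" || prot$scale != "linear") {
    stop("paired fold changes expect linear-scale matrices", call. = FALSE)
  }
  if (is.null(id_map)) {
    shared <- intersect(feature_ids(rna), feature_ids(prot))
    id_map <- data.frame(gene_id = shared, protein_id = shared,
                         stringsAsFactors = FALSE)
  }
  if (!nrow(id_map)) stop("empty gene-protein id mapping", call. = FALSE)
  in_rna <- id_map$gene_id %in% feature_ids(rna)
  in_prot <- id_map$protein_id %in% feature_ids(prot)
  keep <- in_rna & in_prot
  n_one_sided <- sum(xor(in_rna, in_prot))
  map <- id_map[keep, , drop = FALSE]

  group_means <- function(m, ids) {
    dd <- match_design(m, d)
    a <- rowMeans(m$values[ids, select_samples(dd, contrast$a), drop = FALSE])
    b <- rowMeans(m$values[ids, select_samples(dd, contrast$b), drop = FALSE])
    list(a = a, b = b)
  }
  gr <- group_means(rna, map$gene_id)
  gp <- group_means(prot, map$protein_id)
  ok <- rep(TRUE, nrow(map))
  if (pseudocount == 0) {
    ok <- gr$a > 0 & gr$b > 0 & gp$a > 0 & gp$b > 0
  }
  out <- data.frame(
    gene_id = map$gene_id[ok],
    rna_log2fc = log2((gr$a[ok] + pseudocount) / (gr$b[ok] + pseudocount)),
    prot_log2fc = log2((gp$a[ok] + pseudocount) / (gp$b[ok] + pseudocount)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- c(one_modality = n_one_sided,
                             zero_mean = sum(!ok))
  out
}

#' Classify a contrast's genes and record the result
#'
#' @inheritParams paired_fold_changes
#' @param t Log2 threshold passed to [classify_six_types()].
#' @param rule_variant Passed to [classify_six_types()].
#' @param label Label for the contrast/stage stored with each record.
#' @return Data frame `gene_id`, `stage_or_contrast`, `rna_log2fc`,
#'   `prot_log2fc`, `type`, `rule_variant`.
#' @export
concordance_records <- function(rna, prot, d, contrast, id_map = NULL, t = 1,
                                rule_variant = "precedence_v1",
                                label = contrast$label, pseudocount = 0) {
  fc <- paired_fold_changes(rna, prot, d, contrast, id_map,
                            pseudocount = pseudocount)
  fc$type <- classify_six_types(fc$rna_log2fc, fc$prot_log2fc, t = t,
                                rule_variant = rule_variant)
  fc$stage_or_contrast <- label
  fc$rule_variant <- rule_variant
  fc[, c("gene_id", "stage_or_contrast", "rna_log2fc", "prot_log2fc",
         "type", "rule_variant")]
}

#' Per-group type proportions
#'
#' @param records A [concordance_records()] table (possibly several contrasts
#'   row-bound).
#' @param by Column to group by (default `"stage_or_contrast"`).
#' @return Data frame with one row per group: the group label, counts
#'   `n1..n6`, proportions `p1..p6` (summing to 1 per group), and `n_total`.
#' @export
type_proportions <- function(records, by = "stage_or_contrast") {
  if (!nrow(records)) stop("no concordance records", call. = FALSE)
  groups <- split(records, records[[by]])
  rows <- lapply(names(groups), function(g) {
    tab <- tabulate(groups[[g]]$type, nbins = 6)
    n <- sum(tab)
    cbind(data.frame(group = g, n_total = n),
          stats::setNames(as.data.frame(t(tab)), paste0("n", 1:6)),
          stats::setNames(as.data.frame(t(tab / n)), paste0("p", 1:6)))
  })
  do.call(rbind, rows)
}
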