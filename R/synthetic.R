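#' @title Synthetic paired-omics study generator
#' @description Generates a paired protein (LFQ) / transcript (TPM) study over
#'   the 2-region x 6-stage x 3-replicate design with planted, machine-readable
#'   truth: differential region effects, presence gain/loss events (via
#'   detection-limit censoring), four temporal trend archetypes, a six-type
#'   concordance mixture, and enriched annotation terms. Every pipeline stage
#'   is testable against the returned truth tables.
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults emulate the study design: log-normal abundance noise (sd 0.3 on
#' the log2 scale, a typical replicate CV for label-free MS), three biological
#' replicates, protein non-detection by censoring linear LFQ below
#' `detection_limit`, and planted effect classes partitioning the gene set.
#'
#' @param n_genes Number of genes (default 2000).
#' @param regions,stages,replicates Design (defaults: LD/SD, the six
#'   developmental stages, 3).
#' @param noise_sd_log2 Replicate noise sd on log2 scale (default 0.3).
#' @param detection_limit Linear LFQ threshold below which protein values are
#'   zeroed (default 2^14; set 0 to disable censoring).
#' @param baseline_log2_mean,baseline_log2_sd Protein baseline log2 abundance
#'   distribution (defaults 18, 2).
#' @param rna_baseline_log2_mean,rna_baseline_log2_sd Transcript baseline
#'   log2 TPM distribution (defaults 4, 1.5).
#' @param dap_fraction Fraction of genes with a planted region effect
#'   (default 0.10).
#' @param dap_effect Planted |log2FC| for DAP genes (default 1.5).
#' @param dap_stage Stage at which the region effect applies; `NULL` (default)
#'   draws one stage per gene.
#' @param presence_fraction Fraction with planted presence gain/loss events
#'   (default 0.05; half gains, half losses).
#' @param trend_fraction Fraction following one of four temporal archetypes
#'   (default 0.20): decline from E90, peak around birth, trough around birth,
#'   monotone rise.
#' @param trend_amplitude Log2 amplitude scaling the archetype shapes
#'   (default 2).
#' @param concordance_fraction Fraction with planted paired RNA/protein region
#'   fold changes (default 0.25).
#' @param concordance_mix Type 1..6 mixture fractions (default
#'   0.60/0.15/0.15/0.04/0.03/0.03, apportioned deterministically).
#' @param concordance_margin Interior margin (log2) kept from the type
#'   boundaries so planted types are recoverable under noise (default 0.25).
#' @param concordance_max Maximum planted |log2FC| (default 4).
#' @param n_terms,n_enriched_terms Annotation terms: total random terms and
#'   planted enriched terms anchored to trend-archetype gene sets (defaults
#'   40, 5).
#' @param term_size_range Term sizes drawn uniformly in this range
#'   (default c(10, 60)).
#' @param enriched_purity Fraction of an enriched term's members drawn from
#'   its anchor class (default 0.8).
#' @param seed Mandatory RNG seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              regions = MUSCLE_REGIONS,
                              stages = MUSCLE_STAGES,
                              replicates = 3,
                              noise_sd_log2 = 0.3,
                              detection_limit = 2^14,
                              baseline_log2_mean = 18,
                              baseline_log2_sd = 2,
                              rna_baseline_log2_mean = 4,
                              rna_baseline_log2_sd = 1.5,
                              dap_fraction = 0.10,
                              dap_effect = 1.5,
                              dap_stage = NULL,
                              presence_fraction = 0.05,
                              trend_fraction = 0.20,
                              trend_amplitude = 2,
                              concordance_fraction = 0.25,
                              concordance_mix = c(0.60, 0.15, 0.15,
                                                  0.04, 0.03, 0.03),
                              concordance_margin = 0.25,
                              concordance_max = 4,
                              n_terms = 40,
                              n_enriched_terms = 5,
                              term_size_range = c(10, 60),
                              enriched_purity = 0.8,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (replicates < 2) stop("need >= 2 replicates", call. = FALSE)
  fr <- c(dap = dap_fraction, presence = presence_fraction,
          trend = trend_fraction, concordance = concordance_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("planted-class fractions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  if (abs(sum(concordance_mix) - 1) > 1e-9 || length(concordance_mix) != 6) {
    stop("concordance_mix must be 6 fractions summing to 1", call. = FALSE)
  }
  if (concordance_margin <= 0 || concordance_margin >= 1) {
    stop("concordance_margin must be in (0, 1)", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$fr <- fr
  structure(cfg, class = "SimulationConfig")
}

# Four archetype shapes defined on six stages; linearly interpolated for other
# stage counts. Rows: decline-from-E90, birth-peak, birth-trough, rise.
trend_shapes <- function(n_stages) {
  base <- rbind(
    c( 1.2,  1.2,  1.2,  0.2, -0.8, -1.8),
    c(-1.2, -0.2,  0.8,  1.6,  0.6, -0.6),
    c( 1.2,  0.6, -0.4, -1.6, -0.6,  0.4),
    c(-1.8, -1.2, -0.4,  0.4,  1.2,  1.8))
  if (n_stages == 6) return(base)
  t0 <- seq(0, 1, length.out = 6)
  t1 <- seq(0, 1, length.out = n_stages)
  t(apply(base, 1, function(s) stats::approx(t0, s, t1)$y))
}

#' Draw paired fold changes from a concordance type's interior region
#'
#' Samples (rna_log2fc, prot_log2fc) uniformly from the region of the plane
#' belonging to `type`, staying `margin` log2 units away from every decision
#' boundary (threshold and sign) so the planted type is recoverable.
#'
#' @param type Integer vector of types 1..6.
#' @param t Log2 threshold (default 1).
#' @param margin Interior margin (default 0.25).
#' @param max_fc Maximum |log2FC| (default 4).
#' @return Data frame `rna_log2fc`, `prot_log2fc`, `type`.
#' @export
draw_concordance_pairs <- function(type, t = 1, margin = 0.25, max_fc = 4) {
  n <- length(type)
  lo <- function(n, sgn = NULL) {
    mag <- stats::runif(n, margin, t - margin)
    s <- if (is.null(sgn)) sample(c(-1, 1), n, replace = TRUE) else sgn
    s * mag
  }
  hi <- function(n, sgn = NULL) {
    mag <- stats::runif(n, t + margin, max_fc)
    s <- if (is.null(sgn)) sample(c(-1, 1), n, replace = TRUE) else sgn
    s * mag
  }
  rna <- numeric(n)
  prot <- numeric(n)
  for (ty in 1:6) {
    idx <- which(type == ty)
    m <- length(idx)
    if (!m) next
    s <- sample(c(-1, 1), m, replace = TRUE)
    if (ty == 1) {                    # both sub-threshold
      rna[idx] <- lo(m); prot[idx] <- lo(m)
    } else if (ty == 2) {             # protein changed, directions disagree
      prot[idx] <- hi(m, s); rna[idx] <- lo(m, -s)
    } else if (ty == 3) {             # RNA changed, directions disagree
      rna[idx] <- hi(m, s); prot[idx] <- lo(m, -s)
    } else if (ty == 4) {             # exactly one changed, directions agree
      which_prot <- stats::runif(m) < 0.5
      prot[idx[which_prot]] <- hi(sum(which_prot), s[which_prot])
      rna[idx[which_prot]] <- lo(sum(which_prot), s[which_prot])
      rna[idx[!which_prot]] <- hi(sum(!which_prot), s[!which_prot])
      prot[idx[!which_prot]] <- lo(sum(!which_prot), s[!which_prot])
    } else if (ty == 5) {             # both changed, opposite direction
      rna[idx] <- hi(m, s); prot[idx] <- hi(m, -s)
    } else {                          # both changed, same direction
      rna[idx] <- hi(m, s); prot[idx] <- hi(m, s)
    }
  }
  data.frame(rna_log2fc = rna, prot_log2fc = prot, type = type)
}

#' Generate a paired protein/RNA study with planted truth
#'
#' Baseline log2 abundances per gene are normal; planted class effects are
#' added on the log2 scale; replicate noise is normal on log2; protein linear
#' values below the detection limit are zeroed (RNA is never censored). The
#' same config + seed is bit-reproducible.
#'
#' @param cfg A [simulation_config()].
#' @return List: `protein`, `rna` ([expression_matrix()]s), `design`
#'   ([study_design()]), `ann` ([annotation_map()]), `truth` (list of tables:
#'   `classes`, `dap`, `presence`, `trend`, `concordance`, `terms`).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seeds <- split_seed(cfg$seed, 8)
  G <- cfg$n_genes
  S <- length(cfg$stages)
  R <- length(cfg$regions)
  genes <- sprintf("g%04d", seq_len(G))

  # -- class partition (deterministic counts, contiguous blocks) -------------
  counts <- apportion_counts(G, cfg$fr)
  names(counts) <- names(cfg$fr)
  cls <- rep("null", G)
  pos <- 1
  for (nm in names(counts)) {
    if (counts[nm] > 0) {
      cls[seq(pos, pos + counts[nm] - 1)] <- nm
      pos <- pos + counts[nm]
    }
  }
  classes <- data.frame(gene_id = genes, class = cls, stringsAsFactors = FALSE)

  # -- design ----------------------------------------------------------------
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        stage = cfg$stages, region = cfg$regions,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_R%d", design$region, design$stage,
                              design$replicate)
  design <- study_design(design[, c("sample_id", "region", "stage", "replicate")],
                         stages = cfg$stages, regions = cfg$regions)

  # -- per-gene true log2 means per (region, stage) ---------------------------
  base_p <- with_seed(seeds[1], stats::rnorm(G, cfg$baseline_log2_mean,
                                             cfg$baseline_log2_sd))
  base_r <- with_seed(seeds[2], stats::rnorm(G, cfg$rna_baseline_log2_mean,
                                             cfg$rna_baseline_log2_sd))
  # mu arrays: gene x region x stage
  mu_p <- array(rep(base_p, R * S), dim = c(G, R, S),
                dimnames = list(genes, cfg$regions, cfg$stages))
  mu_r <- array(rep(base_r, R * S), dim = c(G, R, S),
                dimnames = list(genes, cfg$regions, cfg$stages))

  truth <- list(classes = classes)

  # DAP genes: region effect at one stage (LD +e/2, SD -e/2)
  idx <- which(cls == "dap")
  if (length(idx)) {
    dap_tab <- with_seed(seeds[3], {
      stg <- if (is.null(cfg$dap_stage)) {
        sample(cfg$stages, length(idx), replace = TRUE)
      } else rep(cfg$dap_stage, length(idx))
      eff <- sample(c(-1, 1), length(idx), replace = TRUE) * cfg$dap_effect
      data.frame(gene_id = genes[idx], stage = stg, true_log2fc = eff,
                 stringsAsFactors = FALSE)
    })
    for (i in seq_along(idx)) {
      s <- match(dap_tab$stage[i], cfg$stages)
      mu_p[idx[i], 1, s] <- mu_p[idx[i], 1, s] + dap_tab$true_log2fc[i] / 2
      mu_p[idx[i], 2, s] <- mu_p[idx[i], 2, s] - dap_tab$true_log2fc[i] / 2
    }
    truth$dap <- dap_tab
  } else truth$dap <- data.frame(gene_id = character(0), stage = character(0),
                                 true_log2fc = numeric(0))

  # Presence genes: absence below the detection limit before (gain) or after
  # (loss) a transition, in one region; high and safely detectable otherwise.
  idx <- which(cls == "presence")
  if (length(idx) && cfg$detection_limit > 0) {
    lo_level <- log2(cfg$detection_limit) - 6
    hi_level <- log2(cfg$detection_limit) + 4
    pres_tab <- with_seed(seeds[4], {
      data.frame(
        gene_id = genes[idx],
        region = sample(cfg$regions, length(idx), replace = TRUE),
        transition = sample(S - 1, length(idx), replace = TRUE),
        direction = rep(c("increasing", "decreasing"),
                        length.out = length(idx)),
        stringsAsFactors = FALSE)
    })
    for (i in seq_along(idx)) {
      g <- idx[i]
      r <- match(pres_tab$region[i], cfg$regions)
      tr <- pres_tab$transition[i]
      mu_p[g, , ] <- hi_level
      mu_r[g, , ] <- base_r[g]
      if (pres_tab$direction[i] == "increasing") {
        mu_p[g, r, seq_len(tr)] <- lo_level
      } else {
        mu_p[g, r, seq(tr + 1, S)] <- lo_level
      }
    }
    pres_tab$from_stage <- cfg$stages[pres_tab$transition]
    pres_tab$to_stage <- cfg$stages[pres_tab$transition + 1]
    truth$presence <- pres_tab
  } else {
    truth$presence <- data.frame(gene_id = character(0), region = character(0),
                                 transition = integer(0),
                                 direction = character(0),
                                 from_stage = character(0),
                                 to_stage = character(0))
  }

  # Trend genes: archetype stage offsets in both regions (protein).
  idx <- which(cls == "trend")
  if (length(idx)) {
    shapes <- trend_shapes(S) * cfg$trend_amplitude
    arch <- rep_len(1:4, length(idx))
    for (i in seq_along(idx)) {
      for (r in seq_len(R)) {
        mu_p[idx[i], r, ] <- mu_p[idx[i], r, ] + shapes[arch[i], ]
      }
    }
    truth$trend <- data.frame(gene_id = genes[idx], archetype = arch,
                              stringsAsFactors = FALSE)
  } else {
    truth$trend <- data.frame(gene_id = character(0), archetype = integer(0))
  }

  # Concordance genes: paired region fold changes constant across stages.
  idx <- which(cls == "concordance")
  if (length(idx)) {
    ty_counts <- apportion_counts(length(idx), cfg$concordance_mix)
    ty <- rep(1:6, times = ty_counts)
    pairs <- with_seed(seeds[5],
      draw_concordance_pairs(ty, t = 1, margin = cfg$concordance_margin,
                             max_fc = cfg$concordance_max))
    for (i in seq_along(idx)) {
      g <- idx[i]
      mu_r[g, 1, ] <- mu_r[g, 1, ] + pairs$rna_log2fc[i] / 2
      mu_r[g, 2, ] <- mu_r[g, 2, ] - pairs$rna_log2fc[i] / 2
      mu_p[g, 1, ] <- mu_p[g, 1, ] + pairs$prot_log2fc[i] / 2
      mu_p[g, 2, ] <- mu_p[g, 2, ] - pairs$prot_log2fc[i] / 2
    }
    truth$concordance <- cbind(data.frame(gene_id = genes[idx],
                                          stringsAsFactors = FALSE), pairs)
  } else {
    truth$concordance <- data.frame(gene_id = character(0),
                                    rna_log2fc = numeric(0),
                                    prot_log2fc = numeric(0), type = integer(0))
  }

  # Annotation map: random background terms + enriched terms anchored to
  # trend-archetype gene sets.
  ann_truth <- with_seed(seeds[6], {
    terms <- list()
    flags <- logical(0)
    anchors <- character(0)
    sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                    cfg$n_terms, replace = TRUE)
    for (j in seq_len(cfg$n_terms)) {
      terms[[sprintf("T%03d", j)]] <- sample(genes, sizes[j])
      flags <- c(flags, FALSE)
      anchors <- c(anchors, NA_character_)
    }
    if (cfg$n_enriched_terms > 0 && nrow(truth$trend) > 0) {
      for (j in seq_len(cfg$n_enriched_terms)) {
        arch_j <- ((j - 1) %% 4) + 1
        pool <- truth$trend$gene_id[truth$trend$archetype == arch_j]
        size <- min(sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                           1), length(pool) * 2)
        n_anchor <- min(round(cfg$enriched_purity * size), length(pool))
        members <- c(sample(pool, n_anchor),
                     sample(setdiff(genes, pool), size - n_anchor))
        terms[[sprintf("E%03d", j)]] <- members
        flags <- c(flags, TRUE)
        anchors <- c(anchors, sprintf("archetype%d", arch_j))
      }
    }
    list(map = annotation_map(terms),
         table = data.frame(term_id = names(terms), enriched = flags,
                            anchor = anchors, stringsAsFactors = FALSE))
  })
  truth$terms <- ann_truth$table

  # -- sample matrices --------------------------------------------------------
  ridx <- match(as.character(design$region), cfg$regions)
  sidx <- match(as.character(design$stage), cfg$stages)
  mean_p <- vapply(seq_len(nrow(design)),
                   function(j) mu_p[, ridx[j], sidx[j]], numeric(G))
  mean_r <- vapply(seq_len(nrow(design)),
                   function(j) mu_r[, ridx[j], sidx[j]], numeric(G))
  noise_p <- with_seed(seeds[7],
    matrix(stats::rnorm(G * nrow(design), 0, cfg$noise_sd_log2), G))
  noise_r <- with_seed(seeds[8],
    matrix(stats::rnorm(G * nrow(design), 0, cfg$noise_sd_log2), G))
  prot <- 2^(mean_p + noise_p)
  prot[prot < cfg$detection_limit] <- 0
  rna <- 2^(mean_r + noise_r)
  dimnames(prot) <- dimnames(rna) <- list(genes, design$sample_id)

  list(protein = expression_matrix(prot, "protein", "linear"),
       rna = expression_matrix(rna, "transcript", "linear"),
       design = design,
       ann = ann_truth$map,
       truth = truth)
}

#' DAP recovery against planted truth
#'
#' @param truth_dap The generator's `truth$dap` table.
#' @param records A [call_contrast()] result for a region contrast at `stage`.
#' @param stage The stage of the contrast.
#' @return List: `sensitivity` (planted genes at this stage that were called),
#'   `observed_fdr` (called genes not planted at this stage), `n_planted`,
#'   `n_called`.
#' @export
dap_recovery <- function(truth_dap, records, stage) {
  planted <- truth_dap$gene_id[truth_dap$stage == stage]
  called <- records$feature_id[records$called]
  tp <- length(intersect(planted, called))
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       observed_fdr = if (length(called)) 1 - tp / length(called) else 0,
       n_planted = length(planted), n_called = length(called))
}

#' Agreement between planted and recovered cluster labels
#'
#' Adjusted Rand index over the shared, labeled features (permutation
#' invariant, so canonical relabeling does not matter).
#'
#' @param truth_labels Named vector or data frame (`gene_id`, label column).
#' @param assignments An [assign_tendencies()] table (or any data frame with
#'   `feature_id` and `tendency`).
#' @return The adjusted Rand index.
#' @export
trend_agreement <- function(truth_labels, assignments) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stop("trend_agreement needs the mclust package", call. = FALSE)
  }
  if (is.data.frame(truth_labels)) {
    lab <- stats::setNames(truth_labels[[2]], truth_labels[[1]])
  } else lab <- truth_labels
  ass <- assignments[!is.na(assignments$tendency), ]
  shared <- intersect(names(lab), ass$feature_id)
  if (!length(shared)) stop("no shared features between truth and assignments",
                            call. = FALSE)
  mclust::adjustedRandIndex(lab[shared],
                            ass$tendency[match(shared, ass$feature_id)])
}

#' Confusion matrix of planted vs recovered concordance types
#'
#' @param truth_conc The generator's `truth$concordance` table.
#' @param records A [concordance_records()] table.
#' @return List: `confusion` (6x6, planted rows x recovered columns),
#'   `accuracy`, `proportion_error` (max absolute error between planted and
#'   recovered type proportions).
#' @export
concordance_confusion <- function(truth_conc, records) {
  shared <- intersect(truth_conc$gene_id, records$gene_id)
  tt <- factor(truth_conc$type[match(shared, truth_conc$gene_id)], levels = 1:6)
  rt <- factor(records$type[match(shared, records$gene_id)], levels = 1:6)
  conf <- table(planted = tt, recovered = rt)
  pp <- as.numeric(table(tt)) / length(tt)
  pr <- as.numeric(table(rt)) / length(rt)
  list(confusion = conf, accuracy = sum(diag(conf)) / length(shared),
       proportion_error = max(abs(pp - pr)))
}

#' Hit rate of planted enriched terms
#'
#' @param truth_terms The generator's `truth$terms` table.
#' @param result An [enrich()] result.
#' @param top_n Terms (by p) considered hits (default: number of planted
#'   enriched terms).
#' @return Fraction of planted enriched terms among the top `top_n`.
#' @export
enrichment_hit_rate <- function(truth_terms, result,
                                top_n = sum(truth_terms$enriched)) {
  planted <- truth_terms$term_id[truth_terms$enriched]
  if (!length(planted)) return(NA_real_)
  top <- utils::head(result$term_id, top_n)
  length(intersect(planted, top)) / length(planted)
}

#' Evaluate pipeline outputs against planted truth
#'
#' Computes whichever recovery metrics the supplied results allow: DAP
#' sensitivity/observed FDR, trend label agreement (ARI), concordance
#' confusion, enrichment top-term hit rate.
#'
#' @param truth The generator's `truth` list.
#' @param results Named list; recognized elements: `dap` (list with `records`
#'   and `stage`), `trend` (list with `assignments` per region, compared to
#'   planted archetypes), `concordance` ([concordance_records()] table),
#'   `enrichment` (list with `result`, optional `top_n`).
#' @return Named list of metric objects.
#' @export
evaluate_recovery <- function(truth, results) {
  out <- list()
  if (!is.null(results$dap)) {
    out$dap <- dap_recovery(truth$dap, results$dap$records, results$dap$stage)
  }
  if (!is.null(results$trend)) {
    lab <- stats::setNames(truth$trend$archetype, truth$trend$gene_id)
    out$trend <- lapply(results$trend, function(a) trend_agreement(lab, a))
  }
  if (!is.null(results$concordance)) {
    out$concordance <- concordance_confusion(truth$concordance,
                                             results$concordance)
  }
  if (!is.null(results$enrichment)) {
    out$enrichment <- do.call(enrichment_hit_rate,
                              c(list(truth$terms), results$enrichment))
  }
  out
}
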