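test_that("the generator is deterministic and respects its config", {
  cfg <- simulation_config(n_genes = 120, seed = 42)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$rna$values, b$rna$values)
  expect_identical(a$truth, b$truth)

  # class counts follow the fractions deterministically
  tab <- table(a$truth$classes$class)
  expect_equal(unname(tab["dap"]), 12)          # 0.10 * 120
  expect_equal(unname(tab["presence"]), 6)      # 0.05 * 120
  expect_equal(unname(tab["trend"]), 24)        # 0.20 * 120
  expect_equal(unname(tab["concordance"]), 30)  # 0.25 * 120

  # zero planted DAPs when the fraction is 0
  cfg0 <- simulation_config(n_genes = 100, dap_fraction = 0, seed = 1)
  st0 <- generate_study(cfg0)
  expect_equal(nrow(st0$truth$dap), 0)

  # infeasible fractions rejected before sampling
  expect_error(simulation_config(dap_fraction = 0.7, concordance_fraction = 0.5,
                                 seed = 1), "sum to <= 1")
  expect_error(simulation_config(seed = 1, replicates = 1), ">= 2")
  expect_error(simulation_config(n_genes = 10), "mandatory")

  # RNA is never censored; protein zeros only below the detection limit
  expect_true(all(st0$rna$values > 0))
  nz <- a$protein$values[a$protein$values > 0]
  expect_true(all(nz >= cfg$detection_limit))
})

test_that("protein zero-rate rises monotonically with the detection limit", {
  rates <- vapply(c(0, 2^12, 2^14, 2^16, 2^18), function(dl) {
    cfg <- simulation_config(n_genes = 150, detection_limit = dl, seed = 5)
    mean(generate_study(cfg)$protein$values == 0)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
})

test_that("planted region effects average to their nominal log2 size", {
  # law-of-large-numbers check: 1000 planted genes, no censoring
  cfg <- simulation_config(n_genes = 1000, dap_fraction = 1, dap_effect = 1.5,
                           dap_stage = "P28", presence_fraction = 0,
                           trend_fraction = 0, concordance_fraction = 0,
                           detection_limit = 0, seed = 77)
  st <- generate_study(cfg)
  d <- st$design
  ld <- d$sample_id[d$region == "LD" & d$stage == "P28"]
  sd_ <- d$sample_id[d$region == "SD" & d$stage == "P28"]
  lfc <- rowMeans(log2(st$protein$values[, ld])) -
    rowMeans(log2(st$protein$values[, sd_]))
  est <- abs(lfc[st$truth$dap$gene_id])
  expect_lt(abs(mean(est) - 1.5), 0.05)
  # signs match the planted truth
  expect_equal(unname(sign(lfc[st$truth$dap$gene_id])),
               sign(st$truth$dap$true_log2fc))
})

test_that("planted presence events are recovered by the presence scan", {
  cfg <- simulation_config(n_genes = 200, presence_fraction = 0.2,
                           dap_fraction = 0, trend_fraction = 0,
                           concordance_fraction = 0,
                           baseline_log2_mean = 22,  # far above the limit:
                           baseline_log2_sd = 1,     # no accidental zeros
                           seed = 9)
  st <- generate_study(cfg)
  tr <- st$truth$presence
  hits <- 0
  for (i in seq_len(nrow(tr))) {
    f <- if (tr$direction[i] == "increasing") find_increasing else find_decreasing
    got <- f(st$protein, st$design, tr$region[i],
             c(tr$from_stage[i], tr$to_stage[i]))
    hits <- hits + (tr$gene_id[i] %in% got$feature_id)
  }
  expect_equal(hits, nrow(tr))
})

test_that("recovery metrics return identity results on an oracle pass-through", {
  cfg <- simulation_config(n_genes = 300, dap_fraction = 0.5,
                           dap_stage = "P28", presence_fraction = 0,
                           trend_fraction = 0, concordance_fraction = 0.4,
                           detection_limit = 0, seed = 3)
  st <- generate_study(cfg)
  # oracle DAP records: called exactly the planted set
  genes <- rownames(st$protein$values)
  rec <- data.frame(feature_id = genes, contrast = "LD_P28.vs.SD_P28",
                    called = genes %in% st$truth$dap$gene_id)
  r <- dap_recovery(st$truth$dap, rec, "P28")
  expect_equal(r$sensitivity, 1)
  expect_equal(r$observed_fdr, 0)

  # oracle concordance records: recovered = planted
  tc <- st$truth$concordance
  recs <- data.frame(gene_id = tc$gene_id, stage_or_contrast = "oracle",
                     rna_log2fc = tc$rna_log2fc, prot_log2fc = tc$prot_log2fc,
                     type = tc$type, rule_variant = "precedence_v1")
  cc <- concordance_confusion(tc, recs)
  expect_equal(cc$accuracy, 1)
  expect_equal(cc$proportion_error, 0)

  # random calls at rate alpha under a pure null -> observed FDR ~ 1
  null_truth <- st$truth$dap[0, ]
  set.seed(6)
  rec_null <- data.frame(feature_id = genes, contrast = "x",
                         called = runif(length(genes)) < 0.05)
  rn <- dap_recovery(null_truth, rec_null, "P28")
  expect_equal(rn$observed_fdr, 1)

  # noiseless limit: trend agreement is exactly 1
  cfg0 <- simulation_config(n_genes = 200, trend_fraction = 1,
                            dap_fraction = 0, presence_fraction = 0,
                            concordance_fraction = 0, noise_sd_log2 = 1e-4,
                            detection_limit = 0, seed = 31)
  st0 <- generate_study(cfg0)
  ass <- region_tendencies(st0$protein, st0$design, "LD", c = 4, seed = 2)
  ari <- trend_agreement(setNames(st0$truth$trend$archetype,
                                  st0$truth$trend$gene_id), ass)
  expect_equal(ari, 1)
})

test_that("planted enriched terms rank above background terms", {
  cfg <- simulation_config(n_genes = 500, trend_fraction = 0.4,
                           dap_fraction = 0, presence_fraction = 0,
                           concordance_fraction = 0, detection_limit = 0,
                           n_terms = 30, n_enriched_terms = 4, seed = 21)
  st <- generate_study(cfg)
  # foreground = planted archetype-1 genes; its anchored term must lead
  fg <- st$truth$trend$gene_id[st$truth$trend$archetype == 1]
  res <- enrich(fg, rownames(st$protein$values), st$ann)
  anchored <- st$truth$terms$term_id[
    st$truth$terms$enriched &
      st$truth$terms$anchor == "archetype1" &
      !is.na(st$truth$terms$anchor)]
  expect_true(all(anchored %in% res$term_id[seq_along(anchored)]))
  expect_equal(enrichment_hit_rate(st$truth$terms[
    st$truth$terms$enriched %in% TRUE &
      st$truth$terms$anchor %in% "archetype1" |
      !st$truth$terms$enriched, ], res, top_n = length(anchored)), 1)
})
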