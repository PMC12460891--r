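#!/usr/bin/env Rscript
# Global proteome summaries: stage-stage Pearson correlations of stage-mean
# log2 profiles and sample PCA.

source("analysis/00_config.R")

st <- load_study()
lp <- log2_transform(st$protein)

sc <- stage_correlations(lp, st$design)
write_tsv(data.frame(stage = sc$stages, round(sc$r, 4)),
          results_path("stage_correlations.tsv"))
adj <- vapply(seq_len(5), function(i) sc$r[i, i + 1], numeric(1))
cat(sprintf("adjacent-stage correlations: %s (max %.2f at %s-%s)\n",
            paste(round(adj, 2), collapse = ", "), max(adj),
            sc$stages[which.max(adj)], sc$stages[which.max(adj) + 1]))

pca <- run_pca(lp, n_components = 2)
scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     st$design[match(rownames(pca$scores),
                                     st$design$sample_id),
                               c("region", "stage")])
write_tsv(scores, results_path("pca_scores.tsv"))
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
            100 * pca$explained_fraction[1], 100 * pca$explained_fraction[2]))
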