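#!/usr/bin/env Rscript
# Six-type RNA-protein concordance per stage (LD vs SD fold changes in both
# modalities) and the per-stage type proportions.

source("analysis/00_config.R")

st <- load_study()

recs <- do.call(rbind, lapply(enumerate_region_contrasts(st$design),
                              function(ct) {
  concordance_records(st$rna, st$protein, st$design, ct,
                      label = as.character(ct$a$stage))
}))
write_tsv(recs, results_path("concordance_records.tsv"))

props <- type_proportions(recs)
props <- props[match(MUSCLE_STAGES, props$group), ]
write_tsv(props, results_path("concordance_proportions.tsv"))
cat("six-type proportions per stage (%):\n")
print(cbind(stage = props$group, round(props[, paste0("p", 1:6)] * 100, 1)))

# confusion against planted types at one representative stage
cc <- concordance_confusion(st$truth$concordance,
                            recs[recs$stage_or_contrast == "P28", ])
cat(sprintf("type accuracy vs planted truth at P28: %.3f\n", cc$accuracy))
print(cc$confusion)
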