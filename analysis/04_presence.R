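#!/usr/bin/env Rscript
# Presence/absence dynamics: proteins appearing or disappearing between
# adjacent stages (LFQ 0 <-> detected), per region.

source("analysis/00_config.R")

st <- load_study()

counts <- count_presence_changes(st$protein, st$design,
                                 policy = "all_replicates")
write_tsv(counts, results_path("presence_counts.tsv"))
write_tsv(attr(counts, "changes"), results_path("presence_changes.tsv"))
print(counts)

# recovery of planted gain/loss events
tr <- st$truth$presence
if (nrow(tr)) {
  chg <- attr(counts, "changes")
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(chg$feature_id == tr$gene_id[i] & chg$region == tr$region[i] &
          chg$from_stage == tr$from_stage[i] &
          chg$direction == tr$direction[i])
  }, logical(1))
  cat(sprintf("planted events recovered: %d / %d\n", sum(hit), nrow(tr)))
}
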