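# Shared configuration for the analysis drivers: one synthetic study stands in
# for the deposited matrices so the whole workflow runs offline and against
# known planted truth. All drivers regenerate it deterministically from this
# config, so they can run independently and in any order.

library(omnifiber)

STUDY_SEED <- 17L
RESULTS_DIR <- "results"

study_config <- function() {
  simulation_config(n_genes = 2000, seed = STUDY_SEED)
}

load_study <- function() generate_study(study_config())

results_path <- function(...) {
  dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
  file.path(RESULTS_DIR, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
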