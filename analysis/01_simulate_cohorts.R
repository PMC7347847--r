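#!/usr/bin/env Rscript
# Generate the synthetic discovery (19 DA / 28 AA / 108 GBM) and validation
# (14 DA / 24 AA / 75 GBM) cohorts used throughout the analysis: 27
# profile-seeded differential genes over a 500-gene background, 0.5 log2
# units of noise, two cohorts-of-origin with injected location/scale batch
# effects. Writes the TSV exchange files plus the ground truth.

suppressPackageStartupMessages(library(gliopanel))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

make <- function(n_per_group, seed, prefix) {
  sim <- simulate_study(simulation_spec(
    n_per_group = n_per_group, n_background_genes = 500,
    probes_per_gene = 1:3, noise_sd = 0.5,
    n_batches = 2, batch_shift_sd = 0.8, batch_scale_sd = 0.1,
    seed = seed))
  write_study(sim$study,
              file.path(out, paste0(prefix, "_matrix.tsv")),
              file.path(out, paste0(prefix, "_annotation.tsv")),
              file.path(out, paste0(prefix, "_metadata.tsv")))
  truth <- data.frame(gene = rownames(sim$truth$gene_means),
                      sim$truth$gene_means, check.names = FALSE)
  write.table(truth, file.path(out, paste0(prefix, "_truth_means.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(prefix, ": ", nrow(sim$study$matrix), " probes x ",
          ncol(sim$study$matrix), " samples, 2 batches")
  invisible(sim)
}

make(c(DA = 19, AA = 28, GBM = 108), seed = 20260925L, "discovery")
make(c(DA = 14, AA = 24, GBM = 75), seed = 20260926L, "validation")
message("cohorts written under ", out)
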