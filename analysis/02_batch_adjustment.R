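#!/usr/bin/env Rscript
# Remove the injected cohort effects from the discovery study with the
# empirical-Bayes location/scale adjustment and record how the batch share
# of the first principal component drops. Writes the adjusted matrix and a
# before/after PCA score table.

suppressPackageStartupMessages(library(gliopanel))
dat <- "results/data"
study <- read_study(file.path(dat, "discovery_matrix.tsv"),
                    file.path(dat, "discovery_annotation.tsv"),
                    file.path(dat, "discovery_metadata.tsv"))

adj <- combat_adjust(study)
write_study(adj$study,
            file.path(dat, "discovery_adjusted.tsv"),
            file.path(dat, "discovery_annotation.tsv"),
            file.path(dat, "discovery_metadata.tsv"))

batch_r2 <- function(st) {
  pc1 <- pca_scores(st, 1L)[, 1L]
  summary(lm(pc1 ~ st$batch))$r.squared
}
before <- batch_r2(study)
after <- batch_r2(adj$study)
scores <- data.frame(
  sample_id = study$sample_ids, group = study$group, batch = study$batch,
  pc1_before = pca_scores(study, 2L)[, 1L],
  pc2_before = pca_scores(study, 2L)[, 2L],
  pc1_after = pca_scores(adj$study, 2L)[, 1L],
  pc2_after = pca_scores(adj$study, 2L)[, 2L]
)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("batch share of PC1: %.3f before, %.3f after adjustment",
                before, after))
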