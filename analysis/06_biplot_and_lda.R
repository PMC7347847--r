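#!/usr/bin/env Rscript
# Canonical (MANOVA) biplot of the discovery cohort on the panel probes —
# group means, sample scores and gene structure correlations on the two
# canonical axes — followed by LDA transfer: train on discovery, classify
# the independent validation cohort, report the confusion matrix.

suppressPackageStartupMessages(library(gliopanel))
dat <- "results/data"
disc <- read_study(file.path(dat, "discovery_adjusted.tsv"),
                   file.path(dat, "discovery_annotation.tsv"),
                   file.path(dat, "discovery_metadata.tsv"))
valid <- read_study(file.path(dat, "validation_matrix.tsv"),
                    file.path(dat, "validation_annotation.tsv"),
                    file.path(dat, "validation_metadata.tsv"))
valid <- combat_adjust(valid)$study
panel <- read_panel("results/panel.tsv")

probes <- intersect(unlist(panel$probes), valid$probe_ids)
disc_p <- subset_probes(disc, probes)
valid_p <- subset_probes(valid, probes)

bp <- fit_canonical_biplot(disc_p)
message(sprintf("canonical axes: eigenvalues %.1f / %.1f",
                bp$eigenvalues[1L], bp$eigenvalues[2L]))
message("group coordinates (axis 1, axis 2):")
print(round(bp$group_coordinates, 2))
a1 <- sort(abs(bp$variable_coordinates[, 1L]), decreasing = TRUE)
message("most discriminatory probes on axis 1: ",
        paste(names(head(a1, 8L)), collapse = ", "))
for (nm in c("samples", "groups", "variables")) {
  obj <- switch(nm, samples = bp$sample_coordinates,
                groups = bp$group_coordinates,
                variables = bp$variable_coordinates)
  write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
              sprintf("results/biplot_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
vproj <- project_samples(bp, valid_p)
write.table(data.frame(id = rownames(vproj), vproj, check.names = FALSE),
            "results/biplot_validation_projection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

model <- fit_lda(disc_p)
report <- classify(model, valid_p)
message("validation confusion matrix (transfer mode):")
print(report$confusion)
message(sprintf("accuracy: %.1f%% (%d/%d)", 100 * report$accuracy,
                sum(diag(report$confusion)), sum(report$confusion)))
write.table(as.data.frame(report$confusion), "results/lda_confusion.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
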