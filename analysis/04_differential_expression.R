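#!/usr/bin/env Rscript
# Pairwise moderated-t comparisons (DA vs GBM, AA vs GBM, DA vs AA) on the
# leverage-selected probes, BH correction within each comparison, and panel
# collapse at FC >= 4. Writes the record table, the per-comparison counts,
# and the gene panel.

suppressPackageStartupMessages(library(gliopanel))
dat <- "results/data"
study <- read_study(file.path(dat, "discovery_adjusted.tsv"),
                    file.path(dat, "discovery_annotation.tsv"),
                    file.path(dat, "discovery_metadata.tsv"))
sel <- readLines("results/selected_probes.txt")
study <- subset_probes(study, sel)

pairs <- list(c("DA", "GBM"), c("AA", "GBM"), c("DA", "AA"))
records <- do.call(rbind, lapply(pairs, function(p) {
  pairwise_test(study, p[1L], p[2L], moderated = TRUE)
}))
write.table(records, "results/diffexpr_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cs <- comparison_summary(records, alpha = 0.05, fc_min = 1)
write.table(cs$counts, "results/comparison_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("significant probes (adjusted p < 0.05) per comparison:")
print(cs$counts)
message("shared significant probes: ",
        paste(names(cs$intersections), cs$intersections,
              sep = " = ", collapse = "; "))

panel <- select_panel(records, alpha = 0.05, fc_min = 4)
write_panel(panel, "results/panel.tsv")
truth <- panel_profile()$gene
message(sprintf("panel: %d genes at FC >= 4 (%d of the %d planted)",
                length(panel$genes), sum(panel$genes %in% truth),
                length(truth)))
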