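#!/usr/bin/env Rscript
# Consensus NMF of the panel-gene submatrix over K in 2:4 with cophenetic
# rank selection; reports the recommended number of clusters, the agreement
# of the K = 2 partition with the GBM vs DA+AA split, and the gene
# contribution rankings of each cluster.

suppressPackageStartupMessages(library(gliopanel))
dat <- "results/data"
study <- read_study(file.path(dat, "discovery_adjusted.tsv"),
                    file.path(dat, "discovery_annotation.tsv"),
                    file.path(dat, "discovery_metadata.tsv"))
panel <- read_panel("results/panel.tsv")
ps <- subset_probes(study, unlist(panel$probes))

cc <- consensus_cluster(ps$matrix, k_range = 2:4, n_restarts = 30L,
                        seed = 20260925L)
write.table(data.frame(k = cc$k_range, cophenetic = unname(cc$cophenetic)),
            "results/cophenetic.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("cophenetic correlation by rank:")
print(round(cc$cophenetic, 4))
message("recommended K: ", cc$recommended_k)

two_class <- ifelse(study$group == "GBM", 1L, 2L)
acc <- match_labels(cc$per_k$k2$cluster_labels, two_class)$accuracy
message(sprintf("K = 2 partition vs GBM/lower-grade split: %.1f%% agreement",
                100 * acc))

fit <- nmf_factorize(ps$matrix, k = cc$recommended_k, seed = 20260925L)
ranks <- gene_contributions(fit)
labs <- assign_clusters(fit)
lower_cluster <- unname(labs[which(study$group == "DA")[1L]])
top <- function(v, n = 10L) paste(head(v, n), collapse = ", ")
message("top contributions, DA+AA cluster: ", top(ranks[[lower_cluster]]))
message("top contributions, GBM cluster:   ",
        top(ranks[[setdiff(seq_len(fit$k), lower_cluster)[1L]]]))
wdf <- data.frame(probe_id = rownames(fit$W), fit$W, check.names = FALSE)
write.table(wdf, "results/nmf_contributions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = names(labs), cluster = labs,
                       group = study$group),
            "results/nmf_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
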