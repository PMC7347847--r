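# Small fixtures built in code; no files on disk.

# A tiny 3-probe x 4-sample study.
toy_study <- function() {
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                2, 2, 2, 2), nrow = 3, byrow = TRUE)
  expression_study(
    m, gene_symbols = c("G1", "G1", "G2"),
    group = c("DA", "DA", "GBM", "GBM"),
    batch = c("B1", "B1", "B2", "B2"),
    probe_ids = c("p1", "p2", "p3"),
    sample_ids = c("s1", "s2", "s3", "s4")
  )
}

# Write a study as the three-file TSV trio into a temp dir; returns paths.
write_toy_tsvs <- function(study, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                metadata = file.path(dir, "metadata.tsv"))
  write_study(study, paths$matrix, paths$annotation, paths$metadata)
  paths
}

# Independent step-up BH oracle: explicit double loop over sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Noiseless profile-seeded discovery simulation (small background).
noiseless_spec <- function(n_bg = 50, seed = 1L) {
  simulation_spec(n_per_group = c(DA = 19, AA = 28, GBM = 108),
                  n_background_genes = n_bg, probes_per_gene = 1,
                  noise_sd = 0, seed = seed)
}
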