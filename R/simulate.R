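#' Reference group-mean profile of the 27-gene discriminatory panel
#'
#' Mean log2 expression of the 27 genes that discriminate the three
#' histopathological subtypes of diffuse astrocytic glioma (DA, diffuse
#' astrocytoma; AA, anaplastic astrocytoma; GBM, glioblastoma). These means
#' seed the synthetic cohorts: the first nine genes are overexpressed in
#' lower-grade tumors, the remaining eighteen in GBM.
#'
#' @return A data.frame with columns `gene`, `DA`, `AA`, `GBM` (27 rows).
#' @export
panel_profile <- function() {
  df <- data.frame(
    gene = c("GABRG2", "CNTN3", "GABRB2", "SPX", "DPP10", "FSTL5", "SH3GL2",
             "SFRP2", "ETNPPL", "SHOX2", "IBSP", "IGF2BP3", "LOX", "HS3ST3B1",
             "XIST", "PTX3", "POSTN", "TOP2A", "VEGFA", "COL3A1", "NNMT",
             "COL1A2", "COL1A1", "PDPN", "CHI3L1", "IGFBP3", "ANXA1"),
    DA = c(7.72, 7.75, 7.90, 8.07, 8.09, 8.27, 9.75, 9.87, 10.31, 4.83, 5.04,
           5.25, 5.37, 5.49, 5.50, 6.29, 6.46, 6.49, 6.94, 7.00, 7.25, 7.44,
           7.47, 7.89, 8.65, 8.73, 9.09),
    AA = c(7.30, 7.64, 7.79, 7.77, 7.86, 7.06, 9.16, 8.50, 9.84, 5.82, 5.22,
           6.06, 5.65, 5.98, 8.33, 6.26, 6.61, 7.44, 7.26, 7.20, 7.31, 7.80,
           7.45, 7.98, 9.31, 9.43, 9.65),
    GBM = c(5.62, 5.49, 5.84, 5.84, 6.07, 5.53, 7.47, 7.15, 7.19, 7.23, 7.20,
            7.66, 7.48, 7.81, 7.64, 8.57, 9.10, 8.64, 9.13, 9.64, 9.65, 9.97,
            9.80, 9.91, 11.86, 10.81, 11.12),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$gene
  df
}

#' Specification of a synthetic multi-cohort expression study
#'
#' Defaults mirror the discovery-cohort design the workflow targets: three
#' unbalanced groups (19 DA / 28 AA / 108 GBM), differential genes seeded
#' from [panel_profile()] against a non-differential background centred at a
#' global mean of 7 log2 units, homoscedastic Gaussian noise of 0.5 log2
#' units, and optional per-batch location/scale distortions.
#'
#' @param n_per_group Named integer vector of samples per group.
#' @param n_background_genes Number of non-differential background genes.
#' @param probes_per_gene Integer vector of candidate probes-per-gene counts;
#'   each gene draws its probe count uniformly from these.
#' @param de_profile Data.frame of per-gene group means (columns `gene` plus
#'   one column per group); default [panel_profile()].
#' @param background_mean Global mean of background genes (log2 units).
#' @param noise_sd Gaussian noise standard deviation in log2 units; may be 0.
#' @param heteroscedastic If `TRUE`, per-gene noise variances are drawn from
#'   a scaled inverse-chi-square distribution `het_df * het_scale^2 /
#'   chisq(het_df)` instead of being constant, to exercise variance
#'   shrinkage.
#' @param het_df,het_scale Degrees of freedom and scale of that distribution.
#' @param n_batches Number of cohorts.
#' @param batch_shift_sd,batch_scale_sd Standard deviations of the per-batch
#'   per-gene additive shifts (log2 units) and of the log multiplicative
#'   scales; both 0 by default (no batch effects).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_per_group = c(DA = 19, AA = 28, GBM = 108),
                            n_background_genes = 500,
                            probes_per_gene = 1:3,
                            de_profile = panel_profile(),
                            background_mean = 7,
                            noise_sd = 0.5,
                            heteroscedastic = FALSE,
                            het_df = 8, het_scale = 0.5,
                            n_batches = 1,
                            batch_shift_sd = 0,
                            batch_scale_sd = 0,
                            seed = 1L) {
  if (any(n_per_group <= 0) || n_background_genes < 0 || n_batches < 1) {
    stop("counts must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(n_per_group))) stop("n_per_group must be named by group")
  groups <- names(n_per_group)
  if (!all(groups %in% colnames(de_profile))) {
    stop("de_profile must have one column of means per group")
  }
  structure(
    list(n_per_group = n_per_group, n_background_genes = n_background_genes,
         probes_per_gene = probes_per_gene, de_profile = de_profile,
         background_mean = background_mean, noise_sd = noise_sd,
         heteroscedastic = heteroscedastic, het_df = het_df,
         het_scale = het_scale, n_batches = n_batches,
         batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a three-group expression study with known ground truth
#'
#' Each probe's value is its gene's group mean (background genes share one
#' global mean, identical across groups) plus a per-batch additive shift,
#' plus scale-modulated Gaussian noise:
#' `x = mu[gene, group] + gamma[batch, gene] + delta[batch, gene] * eps`,
#' `eps ~ N(0, sd_gene^2)`. Batches are assigned round-robin within each
#' group so group and batch are roughly balanced.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `study` (an [expression_study()]) and `truth`
#'   (de_genes with their group means, batch parameters, sample labels).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)
  group <- rep(groups, times = spec$n_per_group)
  n <- length(group)
  sample_ids <- sprintf("S%03d", seq_len(n))
  # round-robin batch assignment within group: batches span all groups
  batch <- unlist(lapply(spec$n_per_group, function(k) {
    rep_len(paste0("B", seq_len(spec$n_batches)), k)
  }), use.names = FALSE)

  de <- spec$de_profile
  n_bg <- spec$n_background_genes
  gene_names <- c(de$gene, if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)))
  n_genes <- length(gene_names)
  gene_means <- rbind(
    as.matrix(de[, groups, drop = FALSE]),
    matrix(spec$background_mean, nrow = n_bg, ncol = length(groups),
           dimnames = list(NULL, groups))
  )
  rownames(gene_means) <- gene_names

  ppg <- if (length(spec$probes_per_gene) == 1L) {
    rep(spec$probes_per_gene, n_genes)
  } else {
    sample(spec$probes_per_gene, n_genes, replace = TRUE)
  }
  probe_gene <- rep(seq_len(n_genes), times = ppg)
  probe_ids <- unlist(lapply(seq_len(n_genes), function(g) {
    sprintf("%s_p%d", gene_names[g], seq_len(ppg[g]))
  }), use.names = FALSE)
  n_probes <- length(probe_ids)

  gene_sd <- if (spec$heteroscedastic) {
    sqrt(spec$het_df * spec$het_scale^2 / stats::rchisq(n_genes, spec$het_df))
  } else {
    rep(spec$noise_sd, n_genes)
  }

  batches <- paste0("B", seq_len(spec$n_batches))
  gamma <- matrix(0, spec$n_batches, n_genes, dimnames = list(batches, gene_names))
  delta <- matrix(1, spec$n_batches, n_genes, dimnames = list(batches, gene_names))
  if (spec$n_batches > 1 && (spec$batch_shift_sd > 0 || spec$batch_scale_sd > 0)) {
    gamma[] <- stats::rnorm(length(gamma), 0, spec$batch_shift_sd)
    delta[] <- exp(stats::rnorm(length(delta), 0, spec$batch_scale_sd))
  }

  mu <- gene_means[probe_gene, match(group, groups), drop = FALSE]
  bi <- match(batch, batches)
  gam <- t(gamma)[probe_gene, bi, drop = FALSE]
  del <- t(delta)[probe_gene, bi, drop = FALSE]
  eps <- matrix(stats::rnorm(n_probes * n, 0, gene_sd[probe_gene]),
                nrow = n_probes, ncol = n)
  x <- mu + gam + del * eps
  dimnames(x) <- list(probe_ids, sample_ids)

  study <- expression_study(
    matrix = x, gene_symbols = gene_names[probe_gene],
    group = factor(group, levels = groups), batch = batch,
    probe_ids = probe_ids, sample_ids = sample_ids
  )
  truth <- list(
    de_genes = de$gene,
    gene_means = gene_means,
    gene_sd = stats::setNames(gene_sd, gene_names),
    batch_shift = gamma,
    batch_scale = delta,
    group = stats::setNames(study$group, sample_ids),
    batch = stats::setNames(study$batch, sample_ids)
  )
  list(study = study, truth = truth)
}

#' Inject per-batch location/scale distortions into a study
#'
#' Applies, per gene and batch, an additive shift and a multiplicative scale
#' around the gene's grand mean: `x' = gamma + m + delta * (x - m)` with `m`
#' the per-probe grand mean. This is precisely the family of distortions the
#' empirical-Bayes batch adjustment models and removes.
#'
#' @param study An [expression_study()].
#' @param shift Named numeric vector (or batch x probe matrix) of additive
#'   shifts per batch.
#' @param scale Named numeric vector (or batch x probe matrix) of
#'   multiplicative scales per batch; default 1.
#' @return A list with `study` (the distorted study) and `params` (the
#'   expanded batch x probe shift and scale grids).
#' @export
inject_batch_effects <- function(study, shift, scale = NULL) {
  stopifnot(inherits(study, "expression_study"))
  batches <- levels(study$batch)
  J <- nrow(study$matrix)
  expand <- function(x, fill) {
    if (is.null(x)) {
      matrix(fill, length(batches), J, dimnames = list(batches, study$probe_ids))
    } else if (is.matrix(x)) {
      if (!setequal(rownames(x), batches)) stop("batch label absent from spec")
      x[batches, , drop = FALSE]
    } else {
      if (!all(batches %in% names(x))) stop("batch label absent from spec")
      matrix(x[batches], length(batches), J,
             dimnames = list(batches, study$probe_ids))
    }
  }
  gamma <- expand(shift, 0)
  delta <- expand(scale, 1)
  m <- rowMeans(study$matrix)
  bi <- match(study$batch, batches)
  x <- study$matrix
  for (b in seq_along(batches)) {
    cols <- bi == b
    if (!any(cols)) next
    x[, cols] <- gamma[b, ] + m + delta[b, ] * (x[, cols] - m)
  }
  out <- study
  out$matrix <- x
  list(study = out, params = list(shift = gamma, scale = delta))
}
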