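#' Pairwise two-group differential expression per probe
#'
#' For every probe, a two-sample t-test with pooled variance between two
#' sample groups. With `moderated = TRUE` (the default) the per-probe
#' variance is replaced by the empirical-Bayes posterior
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)` with prior degrees of
#' freedom `d0` and prior variance `s0^2` fitted by moments (on the log
#' scale) to the distribution of probe variances, and the test has
#' `d0 + d` degrees of freedom. `d0 = 0` reduces exactly to the ordinary t.
#' Fold change is `2^|mean_a - mean_b|` (linear scale, >= 1).
#'
#' @param study An [expression_study()].
#' @param group_a,group_b Group labels to compare; each must have >= 2
#'   samples.
#' @param moderated Use empirical-Bayes variance moderation (default `TRUE`).
#' @param prior Optional list with `d0` and `s02` overriding the fitted
#'   variance prior (e.g. `list(d0 = 0)` recovers the ordinary t exactly).
#' @return A data.frame with one row per probe: `probe_id`, `gene_symbol`,
#'   `comparison`, `mean_a`, `mean_b`, `t_stat`, `p_raw`, `p_adj`
#'   (Benjamini-Hochberg within this comparison), `fc`, `direction`.
#' @export
pairwise_test <- function(study, group_a, group_b, moderated = TRUE,
                          prior = NULL) {
  stopifnot(inherits(study, "expression_study"))
  ia <- which(study$group == group_a)
  ib <- which(study$group == group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need >= 2 samples")
  }
  xa <- study$matrix[, ia, drop = FALSE]
  xb <- study$matrix[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  d <- na + nb - 2L
  s2 <- (ssa + ssb) / d

  if (moderated) {
    fit <- if (is.null(prior)) fit_variance_prior(s2, d) else prior
    d0 <- fit$d0
    s02 <- if (is.null(fit$s02)) 0 else fit$s02
    s2_tilde <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else s02
    df_total <- d0 + d
  } else {
    s2_tilde <- s2
    df_total <- d
  }
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  diffm <- ma - mb
  tt <- diffm / se
  p <- 2 * stats::pt(-abs(tt), df = min(df_total, .Machine$double.xmax))
  zero <- se <= .Machine$double.eps * 100
  if (any(zero)) {
    warning(sum(zero), " probe(s) with zero pooled variance")
    tt[zero] <- sign(diffm[zero]) * Inf
    tt[zero & diffm == 0] <- 0
    p[zero] <- ifelse(diffm[zero] == 0, 1, 0)
  }
  data.frame(
    probe_id = study$probe_ids,
    gene_symbol = study$gene_symbols,
    comparison = paste0(group_a, "_vs_", group_b),
    mean_a = ma, mean_b = mb,
    t_stat = tt, p_raw = p, p_adj = bh_adjust(p),
    fc = 2^abs(diffm),
    direction = ifelse(diffm >= 0, paste0("up_in_", group_a),
                       paste0("up_in_", group_b)),
    row.names = NULL
  )
}

#' Fit the variance prior (d0, s0^2) by moments
#'
#' Fits a scaled inverse-chi-square prior to observed residual variances by
#' matching the mean and variance of `log(s^2)` against the theoretical
#' moments of a scaled F distribution: `e = log(s2) - digamma(d/2) +
#' log(d/2)` has mean `log(s0^2) - digamma(d0/2) + log(d0/2)` and variance
#' `trigamma(d/2) + trigamma(d0/2)`. Returns `d0 = Inf` when the observed
#' spread is no larger than sampling noise (complete shrinkage).
#'
#' @param s2 Observed per-probe variances (positive; zeros are ignored in
#'   the fit).
#' @param d Residual degrees of freedom of each `s2`.
#' @return List with `d0` and `s02`.
#' @export
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) * (sum(ok) - 1) / sum(ok)
  excess <- ev - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma(y) = x for y > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted ascending,
#' `adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, and returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select the discriminatory gene panel from differential-expression records
#'
#' Keeps records with `p_adj < alpha` and `fc >= fc_min` (the workflow's
#' defaults are 0.05 and 4, i.e. at least a 2 log2-unit group-mean gap) and
#' collapses surviving probes to unique gene symbols across all supplied
#' comparisons. The max-FC probe is each gene's representative (its
#' direction is recorded); all passing probes are kept per gene.
#'
#' @param records Data.frame of [pairwise_test()] rows (one or more
#'   comparisons concatenated).
#' @param alpha Adjusted-p threshold in (0, 1).
#' @param fc_min Minimum linear fold change, >= 1.
#' @return A [gene_panel()] (possibly of length zero).
#' @export
select_panel <- function(records, alpha = 0.05, fc_min = 4) {
  if (NROW(records) == 0L) stop("no differential-expression records supplied")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (fc_min < 1) stop("fc_min must be >= 1")
  keep <- records[records$p_adj < alpha & records$fc >= fc_min, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(gene_panel(character(0), list(), character(0)))
  }
  keep <- keep[order(-keep$fc), ]
  genes <- unique(keep$gene_symbol)
  probes <- lapply(genes, function(g) {
    unique(keep$probe_id[keep$gene_symbol == g])
  })
  direction <- vapply(genes, function(g) {
    keep$direction[keep$gene_symbol == g][1L]  # max-FC probe's direction
  }, character(1L))
  gene_panel(genes, probes, unname(direction))
}

#' Per-comparison counts of significant probes by direction
#'
#' Summarizes, for each pairwise comparison, how many probes are significant
#' (`p_adj < alpha`, `fc >= fc_min`) and in which direction, plus the number
#' of significant probes shared between every pair of comparisons.
#'
#' @param records Concatenated [pairwise_test()] rows.
#' @param alpha,fc_min Significance and fold-change thresholds; `fc_min = 1`
#'   counts all significant probes regardless of effect size.
#' @return List with `counts` (comparison x direction table as a
#'   data.frame) and `intersections` (named counts of shared significant
#'   probes per comparison pair).
#' @export
comparison_summary <- function(records, alpha = 0.05, fc_min = 1) {
  stopifnot(NROW(records) > 0L)
  sig <- records[records$p_adj < alpha & records$fc >= fc_min, , drop = FALSE]
  comps <- unique(records$comparison)
  counts <- do.call(rbind, lapply(comps, function(cmp) {
    s <- sig[sig$comparison == cmp, , drop = FALSE]
    dirs <- sort(unique(c(
      sub("^([^_]+)_vs_([^_]+)$", "up_in_\\1", cmp),
      sub("^([^_]+)_vs_([^_]+)$", "up_in_\\2", cmp)
    )))
    data.frame(
      comparison = cmp,
      n_significant = nrow(s),
      direction_1 = dirs[1L], n_1 = sum(s$direction == dirs[1L]),
      direction_2 = dirs[2L], n_2 = sum(s$direction == dirs[2L])
    )
  }))
  inter <- list()
  if (length(comps) > 1L) {
    for (i in seq_len(length(comps) - 1L)) {
      for (j in seq(i + 1L, length(comps))) {
        key <- paste(comps[i], comps[j], sep = " & ")
        inter[[key]] <- length(intersect(
          sig$probe_id[sig$comparison == comps[i]],
          sig$probe_id[sig$comparison == comps[j]]
        ))
      }
    }
  }
  list(counts = counts, intersections = unlist(inter))
}
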