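#' CUR leverage scores of probes
#'
#' Ranks probes by their leverage in a CUR decomposition sense: the matrix
#' is oriented samples x probes, each probe is centered across samples (so
#' leverage reflects variability rather than mean intensity), and the
#' leverage of probe j is the mean of its squared right-singular-vector
#' loadings over the first R components,
#' `l_j = (1/R) * sum_{r=1..R} v_{jr}^2`.
#' R is the number of components needed to absorb the requested fraction of
#' the total variance; the default policy ("full") takes the numerical rank
#' (smallest R with cumulative variance fraction >= 1 - 1e-8). With
#' orthonormal right singular vectors and R at most the matrix rank the
#' leverages sum to 1.
#'
#' @param study An [expression_study()] or a probes x samples matrix.
#' @param rank_policy `"full"` for the numerical rank, or a number in (0, 1]
#'   interpreted as the variance fraction R must absorb.
#' @param center Center each probe across samples before the SVD (default
#'   `TRUE`; `FALSE` reproduces a literal leverage on the raw intensities).
#' @return A `leverage_result` list: `leverages` (named, per probe),
#'   `rank_used`, `variance_absorbed`, `selected_probes` (all probes in
#'   descending leverage, ties broken by probe id).
#' @export
svd_leverages <- function(study, rank_policy = "full", center = TRUE) {
  x <- if (inherits(study, "expression_study")) study$matrix else study
  if (ncol(x) < 2L) stop("need >= 2 samples")
  xt <- t(x)                                  # samples x probes
  if (center) xt <- scale(xt, center = TRUE, scale = FALSE)
  sv <- svd(xt)
  d2 <- sv$d^2
  tot <- sum(d2)
  if (tot <= .Machine$double.eps * 100) stop("degenerate (constant) matrix")
  cumfrac <- cumsum(d2) / tot
  frac <- if (identical(rank_policy, "full")) 1 - 1e-8 else {
    if (!is.numeric(rank_policy) || rank_policy <= 0 || rank_policy > 1) {
      stop("rank_policy must be \"full\" or a fraction in (0, 1]")
    }
    rank_policy
  }
  R <- which(cumfrac >= frac - 1e-15)[1L]
  if (is.na(R)) stop("rank policy infeasible")
  lev <- rowMeans(sv$v[, seq_len(R), drop = FALSE]^2)
  names(lev) <- if (is.null(rownames(x))) {
    sprintf("probe_%d", seq_len(nrow(x)))
  } else {
    rownames(x)
  }
  ord <- order(-lev, names(lev))
  structure(
    list(leverages = lev, rank_used = R, variance_absorbed = cumfrac[R],
         selected_probes = names(lev)[ord]),
    class = "leverage_result"
  )
}

#' @export
print.leverage_result <- function(x, ...) {
  cat(sprintf("leverage_result: %d probes, rank %d (%.4f of variance)\n",
              length(x$leverages), x$rank_used, x$variance_absorbed))
  invisible(x)
}

#' Top-k probes by leverage
#'
#' @param leverage A `leverage_result` from [svd_leverages()].
#' @param k Number of probes, at most the total probe count.
#' @return Character vector of k probe ids in descending leverage; ties are
#'   broken by lexicographic probe id, so the selection is deterministic.
#' @export
top_k <- function(leverage, k) {
  stopifnot(inherits(leverage, "leverage_result"))
  if (k > length(leverage$leverages)) {
    stop("k exceeds the number of probes")
  }
  leverage$selected_probes[seq_len(k)]
}
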