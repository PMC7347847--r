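# Shared machinery: generalized eigenproblem B u = lambda * W u with W the
# pooled within-group covariance. Solved by Cholesky whitening of W so the
# returned axes satisfy u' W u = 1 (canonical scaling).
between_within_eigen <- function(x, group, ridge = NULL) {
  group <- droplevels(factor(group))
  G <- nlevels(group)
  if (G < 2L) stop("need >= 2 groups")
  n <- nrow(x)
  J <- ncol(x)
  grand <- colMeans(x)
  Sw <- matrix(0, J, J)
  Bm <- matrix(0, J, J)
  for (g in levels(group)) {
    xg <- x[group == g, , drop = FALSE]
    ng <- nrow(xg)
    if (ng < 2L) stop("every group needs >= 2 samples")
    mg <- colMeans(xg)
    Sw <- Sw + crossprod(sweep(xg, 2L, mg))
    d <- mg - grand
    Bm <- Bm + ng * tcrossprod(d)
  }
  Sw <- Sw / (n - G)        # pooled within-group covariance
  Bm <- Bm / (G - 1)        # between-group scatter on a covariance scale
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) {
    r <- if (is.null(ridge)) {
      max(1e-8 * sum(diag(Sw)) / J, 1e-10)  # floor covers all-zero scatter
    } else {
      ridge
    }
    warning("singular within-group scatter; ridge ", signif(r, 3), " added")
    Sw <- Sw + diag(r, J)
    ch <- chol(Sw)
  }
  Linv <- backsolve(ch, diag(J))            # inv(L) with Sw = L' L
  M <- t(Linv) %*% Bm %*% Linv
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  axes <- Linv %*% ee$vectors               # u' Sw u = I
  n_axes <- min(G - 1L, J)
  list(values = pmax(ee$values, 0), axes = axes, n_axes = n_axes,
       Sw = Sw, B = Bm, grand = grand, group = group)
}

#' Fit a canonical (MANOVA) biplot
#'
#' Projects samples, group means and gene vectors into the low-dimensional
#' space that maximizes between-group relative to within-group variation:
#' the canonical axes solve the generalized eigenproblem
#' `B u = lambda * W u` with `W` the pooled within-group covariance (divisor
#' n - G) and `B` the between-group scatter of group means (weighted by
#' group size, divisor G - 1). Axes are scaled so the pooled within-group
#' covariance of the canonical sample scores is the identity; with that
#' scaling the between-group variance of the scores on axis a equals the
#' eigenvalue `lambda_a`. At most `min(G - 1, J)` nontrivial axes exist.
#' Variable markers are structure correlations (correlation of each gene
#' with each canonical variate), which are stable when the number of genes
#' approaches the number of samples; `variable_scaling = "weights"` returns
#' the raw eigenvector weights instead.
#'
#' @param study An [expression_study()] restricted to the panel genes
#'   (probes are treated as variables), or a samples x variables matrix plus
#'   `group`.
#' @param group Group labels when `study` is a plain matrix.
#' @param n_axes Number of axes to retain (default all nontrivial ones).
#' @param variable_scaling `"correlation"` (default) or `"weights"`.
#' @param conf Confidence level for the chi-square circle radii around group
#'   means.
#' @return A `canonical_biplot_model` with `eigenvalues`, `axes`
#'   (variables x axes), `sample_coordinates`, `group_coordinates`,
#'   `variable_coordinates`, `group_radii`, `B`, `W_scatter`, `centering`.
#' @export
fit_canonical_biplot <- function(study, group = NULL, n_axes = NULL,
                                 variable_scaling = c("correlation", "weights"),
                                 conf = 0.95) {
  variable_scaling <- match.arg(variable_scaling)
  if (inherits(study, "expression_study")) {
    x <- t(study$matrix)
    group <- study$group
    varnames <- study$probe_ids
  } else {
    x <- as.matrix(study)
    if (is.null(group)) stop("group labels required for a plain matrix")
    varnames <- colnames(x)
  }
  bw <- between_within_eigen(x, group)
  A <- if (is.null(n_axes)) bw$n_axes else min(n_axes, bw$n_axes)
  U <- bw$axes[, seq_len(A), drop = FALSE]
  scores <- sweep(x, 2L, bw$grand) %*% U
  colnames(scores) <- paste0("axis_", seq_len(A))
  rownames(scores) <- rownames(x)
  gcoord <- apply(scores, 2L, function(s) tapply(s, bw$group, mean))
  vcoord <- if (variable_scaling == "correlation") {
    stats::cor(x, scores)
  } else {
    U
  }
  rownames(vcoord) <- varnames
  ng <- table(bw$group)
  radii <- sqrt(stats::qchisq(conf, df = A) / as.numeric(ng))
  structure(
    list(eigenvalues = bw$values[seq_len(A)], axes = U,
         sample_coordinates = scores, group_coordinates = gcoord,
         variable_coordinates = vcoord,
         group_radii = stats::setNames(radii, names(ng)),
         B = bw$B, W_scatter = bw$Sw, centering = bw$grand,
         variable_names = varnames, n_axes = A),
    class = "canonical_biplot_model"
  )
}

#' @export
print.canonical_biplot_model <- function(x, ...) {
  cat(sprintf("canonical_biplot_model: %d axes, eigenvalues %s\n",
              x$n_axes, paste(signif(x$eigenvalues, 4L), collapse = ", ")))
  invisible(x)
}

#' Project new samples onto fitted canonical axes
#'
#' @param model A `canonical_biplot_model`.
#' @param new_study An [expression_study()] (or samples x variables matrix)
#'   with exactly the variables of the training fit, in the same order.
#' @return Samples x axes coordinate matrix.
#' @export
project_samples <- function(model, new_study) {
  stopifnot(inherits(model, "canonical_biplot_model"))
  if (inherits(new_study, "expression_study")) {
    x <- t(new_study$matrix)
    vn <- new_study$probe_ids
  } else {
    x <- as.matrix(new_study)
    vn <- colnames(x)
  }
  if (!identical(as.character(vn), as.character(model$variable_names))) {
    stop("variable set/order does not match the fitted model")
  }
  out <- sweep(x, 2L, model$centering) %*% model$axes
  colnames(out) <- paste0("axis_", seq_len(ncol(out)))
  out
}
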