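#' Empirical-Bayes (ComBat-style) batch adjustment
#'
#' Removes per-batch location and scale effects from a log2 expression
#' matrix with the parametric empirical-Bayes procedure: per-gene
#' standardization, per-batch location (gamma) and scale (delta^2) estimates,
#' shrinkage of those estimates toward method-of-moments priors shared
#' across genes (normal prior on gamma, inverse-gamma on delta^2), and
#' back-transformation. Biological group labels are deliberately not used as
#' covariates by default: group and cohort are typically partially
#' confounded across public series, and protecting the group signal can
#' reinject batch differences. Set `protect_group = TRUE` to include group
#' means in the standardization model instead.
#'
#' @param study An [expression_study()] with at least two batches, each with
#'   at least two samples.
#' @param protect_group Include the biological group in the gene-wise
#'   standardization model (default `FALSE`).
#' @param eb If `FALSE`, the raw batch estimates are used without shrinkage.
#' @param tol,max_iter Convergence control of the iterative EB update
#'   (stops at `max |change in gamma*| < tol`).
#' @return A list with `study` (adjusted, same shape) and `model`, a
#'   `batch_adjust_model` holding per-gene grand means `alpha`, pooled
#'   variances `sigma2`, raw `gamma_hat`/`delta2_hat`, shrunk
#'   `gamma_star`/`delta2_star` (batch x gene grids) and the fitted prior
#'   hyperparameters.
#' @export
combat_adjust <- function(study, protect_group = FALSE, eb = TRUE,
                          tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(study, "expression_study"))
  batch <- droplevels(study$batch)
  if (nlevels(batch) < 2L) stop("batch adjustment needs >= 2 batches")
  n_per_batch <- table(batch)
  if (any(n_per_batch < 2L)) {
    stop("singleton batch: every batch needs >= 2 samples")
  }
  x <- study$matrix
  J <- nrow(x); n <- ncol(x)
  batches <- levels(batch)
  B <- length(batches)
  bidx <- lapply(batches, function(b) which(batch == b))

  # standardization model: batch means (+ optionally group means)
  design <- stats::model.matrix(~ 0 + batch)
  if (protect_group) {
    grp <- droplevels(study$group)
    if (nlevels(grp) > 1L) {
      design <- cbind(design, stats::model.matrix(~ grp)[, -1L, drop = FALSE])
    }
  }
  beta <- t(solve(crossprod(design), crossprod(design, t(x))))  # J x p
  w <- as.numeric(n_per_batch) / n
  grand <- as.numeric(beta[, seq_len(B), drop = FALSE] %*% w)  # weighted alpha
  fitted <- beta %*% t(design)
  sigma2 <- rowMeans((x - fitted)^2)
  zero_var <- sigma2 <= .Machine$double.eps * 100
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) set to their grand mean")
    sigma2[zero_var] <- 1  # placeholder; rows are overwritten at the end
  }
  stand_mean <- grand
  if (protect_group && ncol(beta) > B) {
    extra <- beta[, -seq_len(B), drop = FALSE] %*%
      t(design[, -seq_len(B), drop = FALSE])
    z <- (x - stand_mean - extra) / sqrt(sigma2)
  } else {
    extra <- 0
    z <- (x - stand_mean) / sqrt(sigma2)
  }

  gamma_hat <- t(vapply(bidx, function(ix) rowMeans(z[, ix, drop = FALSE]),
                        numeric(J)))
  delta2_hat <- t(vapply(bidx, function(ix) {
    apply(z[, ix, drop = FALSE], 1L, stats::var)
  }, numeric(J)))
  dimnames(gamma_hat) <- dimnames(delta2_hat) <-
    list(batches, study$probe_ids)

  # method-of-moments hyperpriors per batch
  gamma_bar <- rowMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 1L, stats::var)
  d_mean <- rowMeans(delta2_hat)
  d_var <- apply(delta2_hat, 1L, stats::var)
  lambda <- (2 * d_var + d_mean^2) / pmax(d_var, .Machine$double.eps)
  theta <- (d_mean * d_var + d_mean^3) / pmax(d_var, .Machine$double.eps)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (eb) {
    for (b in seq_len(B)) {
      nb <- length(bidx[[b]])
      if (d_var[b] < 1e-12 || !is.finite(tau2_bar[b]) || tau2_bar[b] < 1e-12) {
        # degenerate prior (e.g. noiseless data): location-only adjustment
        gamma_star[b, ] <- gamma_hat[b, ]
        delta2_star[b, ] <- 1
        next
      }
      g_new <- gamma_hat[b, ]
      d_new <- delta2_hat[b, ]
      zsq_b <- z[, bidx[[b]], drop = FALSE]
      for (it in seq_len(max_iter)) {
        g_old <- g_new
        g_new <- (nb * tau2_bar[b] * gamma_hat[b, ] + d_new * gamma_bar[b]) /
          (nb * tau2_bar[b] + d_new)
        ss <- rowSums((zsq_b - g_new)^2)
        d_new <- (theta[b] + 0.5 * ss) / (nb / 2 + lambda[b] - 1)
        if (max(abs(g_new - g_old)) < tol) break
      }
      gamma_star[b, ] <- g_new
      delta2_star[b, ] <- d_new
    }
  }

  adj <- z
  for (b in seq_len(B)) {
    ix <- bidx[[b]]
    adj[, ix] <- (z[, ix, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta2_star[b, ])
  }
  out_mat <- adj * sqrt(sigma2) + stand_mean + extra
  if (any(zero_var)) out_mat[zero_var, ] <- grand[zero_var]
  dimnames(out_mat) <- dimnames(x)

  out <- study
  out$matrix <- out_mat
  model <- structure(
    list(alpha = stats::setNames(grand, study$probe_ids), sigma2 = sigma2,
         gamma_hat = gamma_hat, delta2_hat = delta2_hat,
         gamma_star = gamma_star, delta2_star = delta2_star,
         prior = list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                      lambda = lambda, theta = theta),
         batches = batches, protect_group = protect_group),
    class = "batch_adjust_model"
  )
  list(study = out, model = model)
}

#' @export
print.batch_adjust_model <- function(x, ...) {
  cat(sprintf("batch_adjust_model: %d batches x %d genes\n",
              length(x$batches), length(x$alpha)))
  invisible(x)
}

#' Principal-component scores of the samples
#'
#' Column-centered SVD scores used to visualize cohort stabilization before
#' and after batch adjustment. Component variances are non-increasing and
#' score columns have zero mean.
#'
#' @param study An [expression_study()] (or a probes x samples matrix).
#' @param n_components Number of components, at most `min(samples - 1, probes)`.
#' @return A samples x components score matrix with attribute `"var"`, the
#'   per-component variances.
#' @export
pca_scores <- function(study, n_components = 2L) {
  x <- if (inherits(study, "expression_study")) study$matrix else study
  n <- ncol(x)
  if (n_components > min(n - 1L, nrow(x))) {
    stop("n_components must be <= min(samples - 1, probes)")
  }
  xt <- scale(t(x), center = TRUE, scale = FALSE)  # samples x probes
  sv <- svd(xt, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  attr(scores, "var") <- sv$d[seq_len(n_components)]^2 / (n - 1L)
  scores
}
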