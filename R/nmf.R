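#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative genes x samples matrix `X ~ W %*% H` (`W`:
#' J x K gene contributions, `H`: K x I sample memberships) by Lee-Seung
#' multiplicative updates minimizing the Frobenius reconstruction error.
#' The objective is non-increasing across iterations; iteration stops when
#' the relative objective change drops below `tol` or at `max_iter`.
#' Columns of `W` are scaled to unit sum on exit (compensated in `H`), which
#' fixes the diagonal scaling indeterminacy of the factorization.
#'
#' @param x Nonnegative numeric matrix (log2 microarray intensities are
#'   nonnegative already).
#' @param k Rank (number of clusters), at most `min(dim(x))`.
#' @param seed Integer seed for the random uniform initialization on
#'   `(0, mean(x))`.
#' @param max_iter,tol Iteration cap and relative-change tolerance.
#' @return An `nmf_model` list: `W`, `H`, `k`, `objective_trace`, `seed`.
#' @export
nmf_factorize <- function(x, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(x < 0)) stop("negative entries: NMF needs a nonnegative matrix")
  if (k > min(dim(x))) stop("k must be <= min(dim(x))")
  set.seed(seed)
  J <- nrow(x); I <- ncol(x)
  m <- mean(x)
  W <- matrix(stats::runif(J * k, 0, m), J, k)
  H <- matrix(stats::runif(k * I, 0, m), k, I)
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- sum((x - W %*% H)^2)
  obj <- prev
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, x) / (crossprod(W) %*% H + eps))
    W <- W * (x %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((x - W %*% H)^2)
    obj <- c(obj, cur)
    if (prev > 0 && abs(prev - cur) / prev < tol) break
    prev <- cur
  }
  # unit-sum W columns; push the scale into H but remember it so that
  # memberships can be compared on the algorithm's own balanced scale
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2L, cs, "/")
  H <- H * cs
  dimnames(W) <- list(rownames(x), paste0("cluster_", seq_len(k)))
  dimnames(H) <- list(paste0("cluster_", seq_len(k)), colnames(x))
  structure(
    list(W = W, H = H, k = k, scale = cs, objective_trace = obj,
         seed = seed),
    class = "nmf_model"
  )
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("nmf_model: rank %d, %d x %d, final error %.4g (%d iterations)\n",
              x$k, nrow(x$W), ncol(x$H), utils::tail(x$objective_trace, 1L),
              length(x$objective_trace) - 1L))
  invisible(x)
}

#' Hard cluster assignment from NMF memberships
#'
#' Each sample is assigned the cluster with the largest membership
#' coefficient in its `H` column; ties go to the lower cluster index.
#' Memberships are compared on the factorization's own balanced scale
#' (undoing the unit-sum W reporting convention), so the assignment is
#' invariant to the diagonal rescaling freedom of `W %*% H`.
#'
#' @param model An `nmf_model`.
#' @return Integer cluster label per sample (named).
#' @export
assign_clusters <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  h <- model$H
  if (!is.null(model$scale)) h <- h / model$scale  # recycles down rows
  labs <- apply(h, 2L, which.max)  # which.max takes the first maximum
  stats::setNames(as.integer(labs), colnames(model$H))
}

#' Per-cluster gene rankings from NMF contributions
#'
#' For each cluster k, genes are ranked by their contribution `W[j, k]`
#' descending; exact ties fall back to gene-id order.
#'
#' @param model An `nmf_model` with gene ids as rownames of `W`.
#' @return A list of character vectors, one ranked gene list per cluster.
#' @export
gene_contributions <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  genes <- rownames(model$W)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(model$W)))
  out <- lapply(seq_len(model$k), function(k) {
    genes[order(-model$W[, k], genes)]
  })
  names(out) <- colnames(model$W)
  out
}

#' Consensus NMF clustering over random restarts with cophenetic rank choice
#'
#' For each candidate rank K the factorization is repeated from `n_restarts`
#' random initializations; the I x I consensus matrix records how often two
#' samples land in the same argmax-H cluster. An average-linkage dendrogram
#' is built on `1 - consensus` and the cophenetic correlation between the
#' consensus dissimilarities and the tree's cophenetic distances measures
#' how tree-like (stable) the clustering is. The recommended rank maximizes
#' the cophenetic correlation over `k_range`.
#'
#' @param x Nonnegative genes x samples matrix.
#' @param k_range Candidate ranks (e.g. `2:4`).
#' @param n_restarts Restarts per rank (>= 2).
#' @param seed Base seed; restart r of rank K uses seed
#'   `seed + 1000 * K + r`.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `consensus_result` list: per-K `consensus` matrices,
#'   `cophenetic` correlations, `dendrogram`s (hclust), `cluster_labels`
#'   (cutree at K), and `recommended_k`.
#' @export
consensus_cluster <- function(x, k_range = 2:4, n_restarts = 30L, seed = 1L,
                              max_iter = 2000L, tol = 1e-6) {
  if (n_restarts < 2L) stop("n_restarts must be >= 2")
  if (any(k_range > min(dim(x)) | k_range < 1L)) {
    stop("k_range outside feasible ranks")
  }
  I <- ncol(x)
  per_k <- lapply(k_range, function(k) {
    consensus <- matrix(0, I, I)
    for (r in seq_len(n_restarts)) {
      fit <- nmf_factorize(x, k, seed = seed + 1000L * k + r,
                           max_iter = max_iter, tol = tol)
      labs <- assign_clusters(fit)
      consensus <- consensus + outer(labs, labs, "==")
    }
    consensus <- consensus / n_restarts
    dimnames(consensus) <- list(colnames(x), colnames(x))
    dd <- stats::as.dist(1 - consensus)
    tree <- stats::hclust(dd, method = "average")
    coph_d <- stats::cophenetic(tree)
    coph <- if (stats::sd(dd) == 0 || stats::sd(coph_d) == 0) {
      1  # degenerate: perfectly block-structured consensus
    } else {
      stats::cor(dd, coph_d)
    }
    list(consensus = consensus, dendrogram = tree, cophenetic = coph,
         cluster_labels = stats::cutree(tree, k = k))
  })
  names(per_k) <- paste0("k", k_range)
  coph <- vapply(per_k, `[[`, numeric(1L), "cophenetic")
  structure(
    list(k_range = k_range, per_k = per_k, cophenetic = coph,
         recommended_k = k_range[which.max(coph)]),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: cophenetic correlation by rank\n")
  print(round(x$cophenetic, 4L))
  cat("recommended K:", x$recommended_k, "\n")
  invisible(x)
}

#' Best-match accuracy and label matching for cluster evaluations
#'
#' Cluster labels are arbitrary up to permutation; this matches predicted
#' labels to reference labels by exhaustive permutation (exact for the small
#' K used here) and returns the best-match accuracy.
#'
#' @param predicted,reference Label vectors of equal length.
#' @return List with `accuracy` and the matched `labels`.
#' @export
match_labels <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  pl <- unique(predicted)
  rl <- unique(reference)
  if (length(pl) > 6L) stop("permutation matching supports <= 6 clusters")
  perms <- all_permutations(seq_along(rl))
  best_acc <- -1
  best <- predicted
  for (p in perms) {
    mapped <- rl[p[match(predicted, pl)]]
    mapped[is.na(mapped)] <- rl[1L]
    acc <- mean(mapped == reference)
    if (acc > best_acc) {
      best_acc <- acc
      best <- mapped
    }
  }
  list(accuracy = best_acc, labels = best)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
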