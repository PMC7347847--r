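#' Fit Gaussian linear discriminant analysis with pooled covariance
#'
#' Trains the classical LDA model on panel-gene expression: per-class mean
#' vectors, one pooled within-class covariance (divisor n - G) and class
#' priors (empirical by default). When the pooled covariance is
#' ill-conditioned — plausible with 27 genes and small cohorts — a ridge of
#' `1e-6 * mean(diag)` is added with a warning.
#'
#' @param study An [expression_study()] on the panel genes (probes are the
#'   features), or a samples x features matrix plus `group`.
#' @param group Class labels when `study` is a plain matrix.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return An `lda_model`: `class_means` (G x J), `pooled_covariance`,
#'   `priors`, `classes`, `feature_names`.
#' @export
fit_lda <- function(study, group = NULL, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (inherits(study, "expression_study")) {
    x <- t(study$matrix)
    group <- study$group
    fn <- study$probe_ids
  } else {
    x <- as.matrix(study)
    if (is.null(group)) stop("group labels required for a plain matrix")
    fn <- colnames(x)
  }
  group <- droplevels(factor(group))
  G <- nlevels(group)
  if (G < 2L) stop("need >= 2 classes")
  if (any(table(group) < 2L)) stop("every class needs >= 2 samples")
  n <- nrow(x); J <- ncol(x)
  means <- t(vapply(levels(group), function(g) {
    colMeans(x[group == g, , drop = FALSE])
  }, numeric(J)))
  Sw <- matrix(0, J, J)
  for (g in levels(group)) {
    Sw <- Sw + crossprod(sweep(x[group == g, , drop = FALSE], 2L,
                               means[g, ]))
  }
  Sw <- Sw / (n - G)
  if (!is.finite(rcond(Sw)) || rcond(Sw) < 1e-12) {
    r <- max(1e-6 * mean(diag(Sw)), 1e-10)  # floor covers zero covariance
    warning("ill-conditioned pooled covariance; ridge ", signif(r, 3),
            " added")
    Sw <- Sw + diag(r, J)
  }
  pr <- if (priors == "empirical") {
    as.numeric(table(group)) / n
  } else {
    rep(1 / G, G)
  }
  structure(
    list(class_means = means, pooled_covariance = Sw,
         priors = stats::setNames(pr, levels(group)),
         classes = levels(group), feature_names = fn),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes (%s), %d features\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$feature_names)))
  invisible(x)
}

#' Classify samples with a fitted LDA model
#'
#' Assigns each sample the class maximizing the linear discriminant score
#' `x' S^-1 mu_g - mu_g' S^-1 mu_g / 2 + log pi_g` and reports the
#' confusion matrix (true x predicted) and accuracy when true labels are
#' available.
#'
#' @param model An `lda_model`.
#' @param test An [expression_study()] with the training feature set in the
#'   training order, or a samples x features matrix.
#' @param group Optional true labels when `test` is a plain matrix.
#' @return A `classification_report`: `predicted`, `posterior` (rows sum to
#'   1), and, when truth is known, `confusion`, `accuracy`,
#'   `misassignments`.
#' @export
classify <- function(model, test, group = NULL) {
  stopifnot(inherits(model, "lda_model"))
  if (inherits(test, "expression_study")) {
    x <- t(test$matrix)
    group <- test$group
    fn <- test$probe_ids
  } else {
    x <- as.matrix(test)
    fn <- colnames(x)
  }
  if (!identical(as.character(fn), as.character(model$feature_names))) {
    stop("feature set/order does not match the trained model")
  }
  Sinv <- solve(model$pooled_covariance)
  disc <- x %*% Sinv %*% t(model$class_means)
  const <- -0.5 * rowSums((model$class_means %*% Sinv) * model$class_means) +
    log(model$priors)
  disc <- sweep(disc, 2L, const, "+")
  colnames(disc) <- model$classes
  post <- exp(disc - apply(disc, 1L, max))
  post <- post / rowSums(post)
  pred <- factor(model$classes[max.col(disc, ties.method = "first")],
                 levels = model$classes)
  out <- list(predicted = stats::setNames(pred, rownames(x)),
              posterior = post)
  if (!is.null(group)) {
    truth <- factor(group, levels = union(model$classes, unique(group)))
    confusion <- table(true = truth,
                       predicted = factor(pred, levels = levels(truth)))
    out$confusion <- confusion
    out$accuracy <- sum(diag(confusion)) / sum(confusion)
    wrong <- which(as.character(truth) != as.character(pred))
    ids <- if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
    out$misassignments <- data.frame(
      sample = ids[wrong],
      true = as.character(truth)[wrong],
      predicted = as.character(pred)[wrong]
    )
  }
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  if (!is.null(x$confusion)) {
    print(x$confusion)
    cat(sprintf("accuracy: %.3f (%d/%d)\n", x$accuracy,
                sum(diag(x$confusion)), sum(x$confusion)))
  } else {
    cat("classification_report:", length(x$predicted), "predictions\n")
  }
  invisible(x)
}
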