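panel_submatrix <- function(seed = 1L, noise_sd = 0.5,
                            n_per_group = c(DA = 19, AA = 28, GBM = 108)) {
  sim <- simulate_study(simulation_spec(
    n_per_group = n_per_group, n_background_genes = 0, probes_per_gene = 1,
    noise_sd = noise_sd, seed = seed))
  list(x = sim$study$matrix, group = sim$study$group)
}

test_that("an exact rank-1 nonnegative matrix is recovered", {
  set.seed(2)
  w <- runif(15, 1, 3)
  h <- runif(8, 1, 3)
  x <- outer(w, h)
  fit <- nmf_factorize(x, 1L, seed = 5L)
  rel_err <- sqrt(utils::tail(fit$objective_trace, 1L)) / sqrt(sum(x^2))
  expect_lt(rel_err, 1e-6)
  expect_equal(colSums(fit$W), 1, ignore_attr = TRUE)
})

test_that("the objective trace never increases and factors stay nonnegative", {
  dat <- panel_submatrix(seed = 3L,
                         n_per_group = c(DA = 8, AA = 8, GBM = 16))
  for (k in 2:3) {
    fit <- nmf_factorize(dat$x, k, seed = k)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
  expect_error(nmf_factorize(dat$x - 100, 2L), "nonnegative")
  expect_error(nmf_factorize(dat$x, 1000L), "k must be")
})

test_that("argmax-H assignment follows the tie rule and separates GBM", {
  m <- structure(list(
    W = matrix(1, 2, 2), k = 2L,
    H = matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 2, 3),
    objective_trace = 1, seed = 1L), class = "nmf_model")
  expect_equal(unname(assign_clusters(m)), c(1L, 1L, 2L))

  acc <- vapply(1:20, function(s) {
    dat <- panel_submatrix(seed = s)
    fit <- nmf_factorize(dat$x, 2L, seed = 100L + s)
    truth <- ifelse(dat$group == "GBM", 1L, 2L)
    match_labels(assign_clusters(fit), truth)$accuracy
  }, numeric(1L))
  expect_gte(mean(acc), 0.95)
})

test_that("cluster recovery reaches ARI >= 0.9 against two-class truth", {
  ari <- vapply(1:20, function(s) {
    dat <- panel_submatrix(seed = s)
    fit <- nmf_factorize(dat$x, 2L, seed = 200L + s)
    adjusted_rand(assign_clusters(fit), ifelse(dat$group == "GBM", 1L, 2L))
  }, numeric(1L))
  expect_gte(mean(ari >= 0.9), 0.9)
})

test_that("gene contributions recover planted block structure and rank ETNPPL first", {
  set.seed(6)
  # two-block matrix: block-A genes express in samples 1:10 only
  x <- matrix(runif(30 * 20, 0, 0.05), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  x[1:15, 1:10] <- x[1:15, 1:10] + 5
  x[16:30, 11:20] <- x[16:30, 11:20] + 5
  fit <- nmf_factorize(x, 2L, seed = 7L)
  ranks <- gene_contributions(fit)
  labs <- assign_clusters(fit)
  cl_a <- labs[1L]  # cluster containing samples 1:10
  top15 <- ranks[[cl_a]][1:15]
  expect_gte(mean(top15 %in% sprintf("g%02d", 1:15)), 0.9)

  # ties fall back to gene order
  m <- structure(list(W = matrix(1, 3, 1,
                                 dimnames = list(c("b", "a", "c"), NULL)),
                      H = matrix(1, 1, 2), k = 1L,
                      objective_trace = 1, seed = 1L), class = "nmf_model")
  expect_equal(gene_contributions(m)[[1L]], c("a", "b", "c"))

  # noiseless profile-seeded data: ETNPPL (largest lower-grade vs GBM gap)
  # tops the DA+AA cluster's ranking
  dat <- panel_submatrix(seed = 9L, noise_sd = 0)
  fit2 <- nmf_factorize(dat$x, 2L, seed = 11L)
  labs2 <- assign_clusters(fit2)
  daaa_cluster <- unname(labs2[which(dat$group == "DA")[1L]])
  contrib <- fit2$W[, daaa_cluster] - fit2$W[, -daaa_cluster]
  expect_identical(names(which.max(contrib)), "ETNPPL_p1")
})

test_that("consensus matrices are symmetric with unit diagonal; separable data is exact", {
  set.seed(10)
  x <- matrix(runif(20 * 12, 0, 0.05), 20, 12)
  x[1:10, 1:6] <- x[1:10, 1:6] + 5
  x[11:20, 7:12] <- x[11:20, 7:12] + 5
  cc <- consensus_cluster(x, k_range = 2L, n_restarts = 8L, seed = 3L)
  cons <- cc$per_k$k2$consensus
  expect_equal(cons, t(cons))
  expect_equal(unname(diag(cons)), rep(1, 12))
  expect_true(all(cons %in% c(0, 1)))
  expect_equal(cc$per_k$k2$cophenetic, 1)

  dat <- panel_submatrix(seed = 12L,
                         n_per_group = c(DA = 6, AA = 8, GBM = 20))
  cc2 <- consensus_cluster(dat$x, k_range = 2:3, n_restarts = 5L, seed = 4L)
  for (k in names(cc2$per_k)) {
    cons <- cc2$per_k[[k]]$consensus
    expect_equal(cons, t(cons))
    expect_equal(unname(diag(cons)), rep(1, ncol(dat$x)))
  }
  expect_error(consensus_cluster(dat$x, k_range = 50L), "feasible")
  expect_error(consensus_cluster(dat$x, k_range = 2L, n_restarts = 1L),
               ">= 2")
})

test_that("rescaling W and H inversely leaves the reconstruction unchanged", {
  dat <- panel_submatrix(seed = 13L,
                         n_per_group = c(DA = 6, AA = 6, GBM = 12))
  fit <- nmf_factorize(dat$x, 2L, seed = 14L)
  d <- diag(c(2, 0.5))
  expect_equal((fit$W %*% d) %*% (solve(d) %*% fit$H), fit$W %*% fit$H)
})
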