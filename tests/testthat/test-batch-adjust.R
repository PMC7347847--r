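make_batch_study <- function(n_per_batch = 50, n_genes = 200, shift = 1,
                             scale = 1.5, seed = 3L) {
  set.seed(seed)
  n <- 2 * n_per_batch
  mu <- runif(n_genes, 4, 12)
  x <- matrix(rnorm(n_genes * n, mu, 0.5), n_genes, n)
  batch <- rep(c("B1", "B2"), each = n_per_batch)
  b2 <- batch == "B2"
  x[, b2] <- mu + shift + scale * (x[, b2] - mu)
  expression_study(x, gene_symbols = paste0("g", seq_len(n_genes)),
                   group = rep(c("DA", "GBM"), n / 2), batch = batch)
}

test_that("a single batch or a singleton batch is rejected", {
  sim <- simulate_study(noiseless_spec())
  expect_error(combat_adjust(sim$study), ">= 2 batches")
  st <- toy_study()
  st$batch <- factor(c("B1", "B1", "B1", "B2"))
  expect_error(combat_adjust(st), "singleton")
})

test_that("a pure constant location shift is removed exactly", {
  # noiseless: residual variance after the batch model is zero, so genes
  # collapse to their grand means and batch means agree trivially
  set.seed(1)
  mu <- runif(30, 4, 12)
  x <- cbind(matrix(mu, 30, 4), matrix(mu + 2, 30, 4))
  st <- expression_study(x, gene_symbols = paste0("g", 1:30),
                         group = rep("DA", 8),
                         batch = rep(c("B1", "B2"), each = 4))
  expect_warning(adj <- combat_adjust(st), "zero-variance")
  m1 <- rowMeans(adj$study$matrix[, 1:4])
  m2 <- rowMeans(adj$study$matrix[, 5:8])
  expect_lt(max(abs(m1 - m2)), 1e-9)
  # and a second application changes nothing (idempotence)
  again <- suppressWarnings(combat_adjust(adj$study))
  expect_lt(max(abs(again$study$matrix - adj$study$matrix)), 1e-9)

  # noisy location-only case: the genome-wide +2 offset is removed; what
  # remains per gene is shrunken estimation noise, far below the injection
  st2 <- make_batch_study(shift = 2, scale = 1)
  adj2 <- combat_adjust(st2)
  gene_gap <- rowMeans(adj2$study$matrix[, 1:50]) -
    rowMeans(adj2$study$matrix[, 51:100])
  expect_lt(mean(abs(gene_gap)), 0.1)
  expect_lt(max(abs(gene_gap)), 0.5)
})

test_that("shrinkage is monotone toward the prior mean", {
  st <- make_batch_study()
  adj <- combat_adjust(st)
  m <- adj$model
  for (b in seq_along(m$batches)) {
    expect_true(all(
      abs(m$gamma_star[b, ] - m$prior$gamma_bar[b]) <=
        abs(m$gamma_hat[b, ] - m$prior$gamma_bar[b]) + 1e-12
    ))
  }
  expect_true(all(m$delta2_hat > 0))
})

test_that("per-gene grand means are preserved (exactly without shrinkage)", {
  st <- make_batch_study()
  raw <- combat_adjust(st, eb = FALSE)
  expect_lt(max(abs(rowMeans(raw$study$matrix) - rowMeans(st$matrix))), 1e-9)
  eb <- combat_adjust(st)
  expect_lt(max(abs(rowMeans(eb$study$matrix) - rowMeans(st$matrix))), 0.05)
})

test_that("adjustment matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  st <- make_batch_study(n_per_batch = 30, n_genes = 120)
  adj <- combat_adjust(st)
  ref <- suppressMessages(sva::ComBat(st$matrix, batch = st$batch))
  expect_lt(max(abs(adj$study$matrix - ref)), 1e-5)
})

test_that("injected batch locations are recovered accurately", {
  spec <- simulation_spec(n_per_group = c(DA = 100, AA = 100, GBM = 200),
                          n_background_genes = 500, probes_per_gene = 1,
                          noise_sd = 0.5, n_batches = 2,
                          batch_shift_sd = 1, batch_scale_sd = 0.15,
                          seed = 23L)
  sim <- simulate_study(spec)  # 200 samples per batch
  adj <- combat_adjust(sim$study)
  m <- adj$model
  rec <- m$gamma_star * rep(sqrt(m$sigma2), each = 2)    # back to log2 scale
  rec_c <- sweep(rec, 2L, colMeans(rec))                 # identifiable part
  inj <- sim$truth$batch_shift
  inj_c <- sweep(inj, 2L, colMeans(inj))
  expect_lt(mean(abs(rec_c - inj_c)), 0.1)
})

test_that("pca_scores are centered with non-increasing variances", {
  sim <- simulate_study(simulation_spec(
    n_per_group = c(DA = 10, AA = 10, GBM = 10), n_background_genes = 50,
    probes_per_gene = 1, seed = 4L))
  sc <- pca_scores(sim$study, 4L)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  v <- attr(sc, "var")
  expect_true(all(diff(v) <= 1e-10))
  expect_error(pca_scores(sim$study, 31L), "n_components")

  # exact rank-1 data: second component variance ~ 0
  x <- outer(1:20, seq(0.1, 1, length.out = 6))
  sc1 <- pca_scores(x, 2L)
  expect_lt(attr(sc1, "var")[2L], 1e-20)
})

test_that("adjustment shrinks the batch share of PC1 on confounded data", {
  spec <- simulation_spec(n_per_group = c(DA = 20, AA = 20, GBM = 20),
                          n_background_genes = 300, probes_per_gene = 1,
                          noise_sd = 0.5, n_batches = 2,
                          batch_shift_sd = 1.2, seed = 31L)
  sim <- simulate_study(spec)
  frac_batch_var <- function(study) {
    pc1 <- pca_scores(study, 1L)[, 1L]
    summary(stats::lm(pc1 ~ study$batch))$r.squared
  }
  before <- frac_batch_var(sim$study)
  after <- frac_batch_var(combat_adjust(sim$study)$study)
  expect_lt(after, before)
  expect_gt(before, 0.5)  # the injected effect did dominate PC1
  expect_lt(after, 0.1)
})
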