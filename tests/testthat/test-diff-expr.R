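sim_two_group <- function(n_genes = 100, n = 10, delta = 0, sd = 0.5,
                          seed = 2L) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * 2 * n, 7, sd), n_genes, 2 * n)
  x[, seq_len(n)] <- x[, seq_len(n)] + delta
  expression_study(x, gene_symbols = paste0("g", seq_len(n_genes)),
                   group = rep(c("A", "B"), each = n),
                   batch = rep("B1", 2 * n))
}

test_that("identical group means give t = 0 and p = 1; records are consistent", {
  x <- matrix(c(1, 2, 1, 2,
                3, 5, 3, 5), 2, 4, byrow = TRUE)
  st <- expression_study(x, gene_symbols = c("g1", "g2"),
                         group = c("A", "A", "B", "B"),
                         batch = rep("B1", 4))
  rec <- pairwise_test(st, "A", "B", moderated = FALSE)
  expect_equal(rec$t_stat, c(0, 0))
  expect_equal(rec$p_raw, c(1, 1))
  expect_equal(rec$fc, 2^abs(rec$mean_a - rec$mean_b))
  expect_true(all(rec$p_adj >= rec$p_raw))
})

test_that("moderated t with a d0 = 0 prior reduces exactly to the ordinary t", {
  st <- sim_two_group(n_genes = 50, seed = 21L)
  plain <- pairwise_test(st, "A", "B", moderated = FALSE)
  mod0 <- pairwise_test(st, "A", "B", moderated = TRUE,
                        prior = list(d0 = 0, s02 = 1))
  expect_equal(mod0$t_stat, plain$t_stat, tolerance = 1e-12)
  expect_equal(mod0$p_raw, plain$p_raw, tolerance = 1e-12)
  # the fitted prior also degenerates gracefully when variances carry no
  # information
  expect_equal(fit_variance_prior(rep(0, 50), 18)$d0, 0)
})

test_that("moderated t agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(33)
  G <- 300; n <- 8
  sd_g <- sqrt(8 * 0.25 / rchisq(G, 8))
  x <- matrix(rnorm(G * 2 * n, 7, rep(sd_g, 2 * n)), G, 2 * n)
  st <- expression_study(x, gene_symbols = paste0("g", 1:G),
                         group = rep(c("A", "B"), each = n),
                         batch = rep("B1", 2 * n))
  rec <- pairwise_test(st, "A", "B", moderated = TRUE)
  design <- stats::model.matrix(~ rep(c(1, 0), each = n))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_gt(stats::cor(rec$t_stat, fit$t[, 2L]), 0.9999)
  expect_lt(max(abs(rec$t_stat - fit$t[, 2L])), 0.05)
})

test_that("moderated test holds its type-I error at the nominal level", {
  spec <- simulation_spec(n_per_group = c(A = 10, B = 10),
                          n_background_genes = 10000, probes_per_gene = 1,
                          de_profile = data.frame(gene = character(0),
                                                  A = numeric(0),
                                                  B = numeric(0)),
                          heteroscedastic = TRUE, het_df = 8,
                          het_scale = 0.5, seed = 41L)
  sim <- simulate_study(spec)
  rec <- pairwise_test(sim$study, "A", "B", moderated = TRUE)
  rate <- mean(rec$p_raw < 0.05)
  ci_half <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (trial in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("panel selection filters, collapses probes, and is monotone", {
  rec <- data.frame(
    probe_id = c("a1", "a2", "b1", "c1"),
    gene_symbol = c("GA", "GA", "GB", "GC"),
    comparison = "A_vs_B",
    mean_a = c(9, 9, 8, 7), mean_b = c(5, 5.5, 6, 6.9),
    t_stat = 5, p_raw = 0.001,
    p_adj = c(0.01, 0.01, 0.01, 0.2),
    fc = c(16, 11.3, 4, 1.07),
    direction = c("up_in_A", "up_in_A", "up_in_A", "up_in_A")
  )
  pan <- select_panel(rec, alpha = 0.05, fc_min = 4)
  expect_setequal(pan$genes, c("GA", "GB"))
  expect_setequal(pan$probes[[match("GA", pan$genes)]], c("a1", "a2"))

  rec$fc[3] <- 3.99
  pan2 <- select_panel(rec, alpha = 0.05, fc_min = 4)
  expect_identical(pan2$genes, "GA")

  # monotonicity: tightening either threshold never adds a gene
  set.seed(15)
  st <- sim_two_group(n_genes = 200, delta = rep(c(0, 3), 100), seed = 16L)
  recs <- pairwise_test(st, "A", "B")
  for (i in 1:10) {
    a1 <- runif(1, 0.001, 0.3); a2 <- runif(1, 0.001, a1)
    f1 <- runif(1, 1, 6); f2 <- runif(1, f1, 8)
    loose <- select_panel(recs, a1, f1)$genes
    tight <- select_panel(recs, a2, f2)$genes
    expect_true(all(tight %in% loose))
  }
  expect_error(select_panel(rec[0, ]), "no differential")
})

test_that("comparison summaries count planted directions and ignore order", {
  spec <- simulation_spec(
    n_per_group = c(DA = 15, GBM = 15), n_background_genes = 450,
    probes_per_gene = 1, noise_sd = 0.5,
    de_profile = data.frame(gene = sprintf("UP%02d", 1:50),
                            DA = 7, GBM = 10),
    seed = 51L)
  sim <- simulate_study(spec)
  rec <- pairwise_test(sim$study, "DA", "GBM")
  cs <- comparison_summary(rec, alpha = 0.05, fc_min = 2)
  expect_equal(cs$counts$n_significant, 50, tolerance = 0.1)
  up_gbm <- cs$counts[[paste0("n_", which(c(cs$counts$direction_1,
                                            cs$counts$direction_2) ==
                                            "up_in_GBM"))]]
  expect_equal(up_gbm, 50, tolerance = 0.1)

  shuffled <- comparison_summary(rec[sample(nrow(rec)), ],
                                 alpha = 0.05, fc_min = 2)
  expect_equal(shuffled$counts, cs$counts)

  none <- comparison_summary(rec, alpha = 1e-300, fc_min = 1000)
  expect_equal(none$counts$n_significant, 0)
})
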