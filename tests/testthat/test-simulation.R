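test_that("exact-model draws match the generating mixture", {
  theta <- model_params(c(0.6, 0.25, 0.15), 2.5, -2, 1, 1, 0.84, 0.84)
  sim <- simulate_from_model(theta, 10000, seed = 2)
  freq <- tabulate(sim$labels + 1L, 3L) / 10000
  sds <- sqrt(theta$pi * (1 - theta$pi) / 10000)
  expect_true(all(abs(freq - theta$pi) < 3 * sds))
  # within-component latent correlation near rho
  for (k in 1:2) {
    zk <- unclass(sim$data)[sim$labels == k, ]
    expect_equal(cor(zk[, 1], zk[, 2]), 0.84, tolerance = 0.03)
  }
  # null component uncorrelated
  z0 <- unclass(sim$data)[sim$labels == 0, ]
  expect_lt(abs(cor(z0[, 1], z0[, 2])), 0.05)
  # determinism / seed sensitivity
  expect_identical(simulate_from_model(theta, 100, seed = 5),
                   simulate_from_model(theta, 100, seed = 5))
  expect_false(identical(unclass(simulate_from_model(theta, 100, seed = 5)$data),
                         unclass(simulate_from_model(theta, 100, seed = 6)$data)))
})

test_that("observed marginal choice never changes the fitted model", {
  theta <- model_params(c(0.6, 0.2, 0.2), 2, -2, 1, 1, 0.8, 0.8)
  lat <- simulate_from_model(theta, 500, seed = 3, marginal = "latent")
  lgn <- simulate_from_model(theta, 500, seed = 3, marginal = "lognormal")
  expect_identical(lat$labels, lgn$labels)
  # lognormal scores are a strictly increasing transform of the latent ones
  expect_identical(order(lat$data[, 1]), order(lgn$data[, 1]))
  cfg <- fit_config(n_starts = 1, seed = 3, max_iter = 30)
  f_lat <- suppressWarnings(fit_copula_mixture(lat$data, cfg))
  f_lgn <- suppressWarnings(fit_copula_mixture(lgn$data, cfg))
  expect_identical(f_lat$theta, f_lgn$theta)
})

test_that("violation generator draws per-gene parameters from the uniforms", {
  # degenerate ranges collapse to a fixed-parameter model
  cfg <- violation_config(n_genes = 400, mu1_range = c(1.2, 1.2),
                          mu2_range = c(-0.9, -0.9),
                          rho_range = c(0.85, 0.85), seed = 4)
  d <- simulate_violation(cfg)[[1]]
  expect_true(all(d$gene_mu[d$labels == 1] == 1.2))
  expect_true(all(d$gene_mu[d$labels == 2] == -0.9))
  expect_true(all(d$gene_rho[d$labels != 0] == 0.85))
  # mean of drawn up-component means matches the uniform(0.58, 1.58) mean
  all_up <- violation_config(n_genes = 5000, pi = c(0, 1, 0), seed = 7)
  d_up <- simulate_violation(all_up)[[1]]
  expect_equal(mean(d_up$gene_mu), 1.08, tolerance = 0.02)
  # datasets within one config are independent but reproducible
  two <- simulate_violation(violation_config(n_genes = 50, n_datasets = 2,
                                             seed = 1))
  expect_length(two, 2)
  expect_false(identical(two[[1]]$data, two[[2]]$data))
})

test_that("violation p-values are uniform under the pure null", {
  cfg <- violation_config(n_genes = 5000, pi = c(1, 0, 0), seed = 11)
  d <- simulate_violation(cfg)[[1]]
  expect_gt(ks.test(d$pvalues[, 1], "punif")$p.value, 0.01)
  expect_gt(ks.test(d$pvalues[, 2], "punif")$p.value, 0.01)
  expect_true(all(d$labels == 0))
})

test_that("cross-platform generator couples platforms through shared quantiles", {
  cfg <- cross_platform_config(n_genes = 1500, seed = 13)
  xp <- simulate_cross_platform(cfg)
  expect_true(all(xp$counts >= 0))
  expect_true(all(xp$counts == round(xp$counts)))
  expect_identical(dim(xp$counts), c(1500L, 6L))
  # average variance/mean ratio across replicates exceeds 1 (overdispersion)
  c1 <- xp$counts[, xp$condition == 1]
  vm <- apply(c1, 1, var) / pmax(rowMeans(c1), 1e-9)
  expect_gt(mean(vm, na.rm = TRUE), 1)
  # per-gene Spearman correlation between count and intensity positive
  sp <- vapply(seq_len(nrow(c1)), function(i)
    suppressWarnings(cor(xp$counts[i, ], xp$intensity[i, ],
                         method = "spearman")), numeric(1))
  expect_gt(mean(sp > 0, na.rm = TRUE), 0.95)
  # label proportions follow the configuration
  expect_equal(mean(xp$labels == 1), 0.1, tolerance = 1e-8)
  expect_equal(mean(xp$labels == 2), 0.3, tolerance = 1e-8)
})

test_that("null cross-platform data shows no systematic fold change", {
  cfg <- cross_platform_config(n_genes = 2000, prop_up = 0, prop_down = 0,
                               seed = 17)
  xp <- simulate_cross_platform(cfg)
  lfc <- platform_log_fc(xp$counts, xp$condition, "counts")
  expect_lt(abs(mean(lfc)), 0.05)
  lfa <- platform_log_fc(xp$intensity, xp$condition, "log_intensity")
  expect_lt(abs(mean(lfa)), 0.05)
  expect_error(cross_platform_config(n_reps = 2.5), "integer")
})

test_that("calibration curve compares estimated and realized error rates", {
  # perfect posteriors: zero estimated and realized error up to the truth
  n_de <- 40; n_null <- 60
  post <- data.frame(gene_id = sprintf("g%03d", 1:(n_de + n_null)),
                     p0 = c(rep(0, n_de), rep(1, n_null)))
  labels <- c(rep(1L, n_de), rep(0L, n_null))
  names(labels) <- post$gene_id
  sel <- select_degs(post, 0.1)
  cal <- evaluate_calibration(sel, labels)
  expect_equal(cal$empirical_fdr[seq_len(n_de)], rep(0, n_de))
  expect_equal(cal$cum_error[seq_len(n_de)], rep(0, n_de))
  # uninformative posteriors: realized error approaches the null fraction
  set.seed(23)
  n <- 4000
  labels2 <- rbinom(n, 1, 0.4)   # 60 % null
  post2 <- data.frame(gene_id = sprintf("g%04d", 1:n), p0 = runif(n))
  names(labels2) <- post2$gene_id
  cal2 <- evaluate_calibration(select_degs(post2, 0.5), labels2)
  expect_equal(cal2$empirical_fdr[n], 0.6, tolerance = 0.03)
})

test_that("ROC evaluation matches hand-counted concordance", {
  expect_equal(evaluate_roc(1:6, c(0, 0, 1, 0, 1, 1))$auc, 8 / 9)
  # perfect separation
  roc <- evaluate_roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  # label-independent scores are uninformative
  set.seed(29)
  expect_equal(evaluate_roc(rnorm(5000), rbinom(5000, 1, 0.3))$auc, 0.5,
               tolerance = 0.02)
  expect_error(evaluate_roc(1:4, c(1, 1, 1, 1)), "both classes")
})
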