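test_that("initialization is deterministic and respects constraints", {
  expect_identical(init_params(7, jitter = TRUE), init_params(7, jitter = TRUE))
  base <- init_params(1)
  expect_equal(base$pi, c(0.6, 0.2, 0.2))
  expect_equal(c(base$mu1, base$mu2), c(2, -2))
  thetas <- lapply(1:5, init_params, jitter = TRUE)
  for (th in thetas) {
    expect_gt(th$mu1, 0); expect_lt(th$mu2, 0)
    expect_true(th$rho1 > 0 && th$rho1 < 1)
    expect_equal(sum(th$pi), 1)
  }
  # multi-start jitters are distinct
  expect_gt(length(unique(vapply(thetas, function(t) t$mu1, numeric(1)))), 3L)
})

test_that("E-step responsibilities are normalized and match the printed formula", {
  theta <- default_theta()
  fc <- random_fc(25, seed = 11)
  ps <- pseudo_observations(fc, theta)
  resp <- e_step(ps, theta)
  expect_true(all(resp >= 0))
  expect_equal(rowSums(resp), rep(1, nrow(fc)), tolerance = 1e-12)
  # brute-force oracle on the same fixture
  expect_equal(unname(resp), oracle_posterior(unclass(fc), theta),
               tolerance = 1e-10)
  # degenerate proportions force the null component
  null_only <- model_params(c(1, 0, 0), 1, -1)
  r0 <- e_step(ps, null_only)
  expect_equal(unname(r0), matrix(rep(c(1, 0, 0), each = 25), ncol = 3))
})

test_that("E-step is symmetric for a gene at the origin under symmetric theta", {
  sym <- model_params(c(0.5, 0.25, 0.25), 2, -2, 1, 1, 0.6, 0.6)
  ps <- structure(list(u = matrix(0.5, 1, 2), z = matrix(0, 1, 2)),
                  class = "cdeg_pseudo")
  resp <- e_step(ps, sym)
  expect_equal(resp[1, 2], resp[1, 3])
})

test_that("M-step reproduces weighted moments and projects constraints", {
  theta <- default_theta()
  set.seed(21)
  n <- 40
  z <- matrix(rnorm(2 * n), ncol = 2)
  ps <- structure(list(u = mixture_cdf(z, theta), z = z),
                  class = "cdeg_pseudo")
  # responsibilities biased so the up/down components keep their signs:
  # no clamp binds and no relabelling happens, leaving pure moment updates
  s <- z[, 1] + z[, 2]
  resp <- cbind(runif(n, 0.2, 0.4), exp(s), exp(-s))
  resp <- resp / rowSums(resp)
  new <- m_step(ps, resp, prev = theta)
  # independent weighted-moment recomputation
  for (k in 1:2) {
    w <- resp[, k + 1]
    mu_hat <- weighted.mean((z[, 1] + z[, 2]) / 2, w)
    s2_hat <- sum(w * ((z[, 1] - mu_hat)^2 + (z[, 2] - mu_hat)^2)) /
      (2 * sum(w))
    rho_hat <- sum(w * (z[, 1] - mu_hat) * (z[, 2] - mu_hat)) /
      (sum(w) * s2_hat)
    expect_equal(c(new$mu1, new$mu2)[k], mu_hat, tolerance = 1e-10)
    expect_equal(c(new$sigma1, new$sigma2)[k], sqrt(s2_hat),
                 tolerance = 1e-10)
    expect_equal(c(new$rho1, new$rho2)[k],
                 min(max(rho_hat, 0.001), 0.999), tolerance = 1e-10)
  }
  expect_equal(new$pi, colMeans(resp), tolerance = 1e-10)
  # constraints hold after an M-step from arbitrary responsibilities
  r2 <- matrix(runif(3 * n), ncol = 3); r2 <- r2 / rowSums(r2)
  th2 <- m_step(ps, r2, prev = theta)
  expect_gt(th2$mu1, 0); expect_lt(th2$mu2, 0)
  expect_equal(sum(th2$pi), 1)
  expect_true(th2$rho1 > 0 && th2$rho1 < 1)
})

test_that("M-step recovers cluster means from hard symmetric assignments", {
  m <- 3
  z <- rbind(matrix(m, 10, 2), matrix(-m, 10, 2))
  ps <- structure(list(u = NULL, z = z), class = "cdeg_pseudo")
  resp <- rbind(matrix(rep(c(0, 1, 0), each = 10), ncol = 3),
                matrix(rep(c(0, 0, 1), each = 10), ncol = 3))
  new <- m_step(ps, resp, prev = default_theta())
  expect_equal(new$mu1, m)
  expect_equal(new$mu2, -m)
  # all-null responsibilities leave the frozen prior DE components
  resp0 <- matrix(rep(c(1, 0, 0), each = 20), ncol = 3)
  new0 <- m_step(ps, resp0, prev = default_theta())
  expect_gt(new0$pi[1], 0.999)
  expect_equal(new0$mu1, default_theta()$mu1)
})

test_that("EM at fixed pseudo-data never decreases the pseudo-log-likelihood", {
  theta_star <- model_params(c(0.6, 0.25, 0.15), 2.5, -2, 1, 1, 0.84, 0.84)
  for (seed in 1:3) {
    sim <- simulate_from_model(theta_star, 800, seed = seed)
    u <- apply(unclass(sim$data), 2, ecdf_transform)
    st <- copulaDEG:::inner_em(u, init_params(seed), tol = 1e-12,
                               inner_max = 40, shared_sigma = FALSE)
    expect_true(all(diff(st$inner_trace) >= -1e-8))
  }
})

test_that("fit is bit-identical under monotone transforms and errors on constant columns", {
  theta_star <- model_params(c(0.6, 0.25, 0.15), 2.5, -2, 1, 1, 0.84, 0.84)
  sim <- simulate_from_model(theta_star, 600, seed = 2)
  cfg <- fit_config(n_starts = 1, seed = 2, max_iter = 40)
  f1 <- suppressWarnings(fit_copula_mixture(sim$data, cfg))
  x3 <- unclass(sim$data)^3
  f2 <- suppressWarnings(fit_copula_mixture(x3, cfg))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  bad <- cbind(rep(1, 50), rnorm(50))
  expect_error(fit_copula_mixture(bad, cfg), "constant")
})

test_that("fit recovers generating parameters on moderate samples", {
  theta_star <- model_params(c(0.6, 0.25, 0.15), 2.5, -2, 1, 1, 0.84, 0.84)
  sim <- simulate_from_model(theta_star, 4000, seed = 42)
  fit <- fit_copula_mixture(sim$data, fit_config(n_starts = 1, seed = 42))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta$pi - theta_star$pi)), 0.05)
  expect_lt(abs(fit$theta$mu1 - theta_star$mu1), 0.25)
  expect_lt(abs(fit$theta$mu2 - theta_star$mu2), 0.25)
  expect_lt(abs(fit$theta$rho1 - theta_star$rho1), 0.08)
  expect_lt(abs(fit$theta$rho2 - theta_star$rho2), 0.08)
  # outer trace is recorded per iteration
  expect_length(fit$loglik_trace, fit$n_iter)
})

test_that("shared-sigma fits return equal component scales", {
  theta_star <- model_params(c(0.6, 0.2, 0.2), 2, -2, 1, 1, 0.8, 0.8)
  sim <- simulate_from_model(theta_star, 1500, seed = 9)
  fit <- suppressWarnings(fit_copula_mixture(
    sim$data, fit_config(n_starts = 1, seed = 9, shared_sigma = TRUE,
                         max_iter = 120)))
  expect_equal(fit$theta$sigma1, fit$theta$sigma2)
})
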