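# Independent brute-force oracles used to cross-check the implementation.
# These re-derive every quantity from the printed formulas with generic
# tools (solve/det for the Gaussian density, long bisection for the
# quantile) and share no code path with the package internals.

oracle_theta_list <- function(theta) {
  list(pi = theta$pi,
       mu = c(0, theta$mu1, theta$mu2),
       sigma = c(1, theta$sigma1, theta$sigma2),
       rho = c(0, theta$rho1, theta$rho2))
}

# generic bivariate normal density via the covariance matrix
oracle_bvn <- function(z1, z2, mu, sigma, rho) {
  S <- matrix(c(sigma^2, rho * sigma^2, rho * sigma^2, sigma^2), 2L)
  Sinv <- solve(S)
  d <- rbind(z1 - mu, z2 - mu)
  q <- colSums(d * (Sinv %*% d))
  exp(-q / 2) / (2 * pi * sqrt(det(S)))
}

oracle_G <- function(z, theta) {
  tl <- oracle_theta_list(theta)
  out <- 0
  for (k in 1:3)
    out <- out + tl$pi[k] * pnorm((z - tl$mu[k]) / tl$sigma[k])
  out
}

# long scalar bisection: machine-precision inverse of the mixture CDF
oracle_Ginv <- function(u, theta) {
  vapply(u, function(ui) {
    lo <- -60; hi <- 60
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (oracle_G(mid, theta) < ui) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

oracle_pseudo_z <- function(x, theta) {
  u <- apply(x, 2L, function(col) rank(col) / (length(col) + 1))
  matrix(oracle_Ginv(as.vector(u), theta), ncol = 2L)
}

# per-gene mixture density sum of the printed likelihood
oracle_mixture_density <- function(z, theta) {
  tl <- oracle_theta_list(theta)
  out <- 0
  for (k in 1:3)
    out <- out + tl$pi[k] *
      oracle_bvn(z[, 1], z[, 2], tl$mu[k], tl$sigma[k], tl$rho[k])
  out
}

oracle_loglik <- function(x, theta) {
  z <- oracle_pseudo_z(x, theta)
  sum(log(oracle_mixture_density(z, theta)))
}

oracle_posterior <- function(x, theta) {
  z <- oracle_pseudo_z(x, theta)
  tl <- oracle_theta_list(theta)
  num <- sapply(1:3, function(k)
    tl$pi[k] * oracle_bvn(z[, 1], z[, 2], tl$mu[k], tl$sigma[k], tl$rho[k]))
  num / rowSums(num)
}

# re-sort + cumulative-mean recomputation of the selection rule
oracle_selection <- function(p0, ids, alpha) {
  ord <- order(p0, ids)
  cum <- cumsum(p0[ord]) / seq_along(p0)
  i_max <- if (any(cum < alpha)) max(which(cum < alpha)) else 0L
  list(order = ord, cum_error = cum, i_max = i_max,
       selected_ids = ids[ord][seq_len(i_max)])
}

oracle_rankprod <- function(x) {
  n <- nrow(x)
  r1 <- rank(x[, 1]); r2 <- rank(x[, 2])
  down <- (r1 / n) * (r2 / n)
  up <- ((n + 1 - r1) / n) * ((n + 1 - r2) / n)
  unname(pmin(up, down))
}

# shared fixtures -----------------------------------------------------------

default_theta <- function()
  model_params(pi = c(0.5, 0.3, 0.2), mu1 = 1, mu2 = -1,
               sigma1 = 1, sigma2 = 1, rho1 = 0.5, rho2 = 0.5)

random_theta <- function(seed) {
  set.seed(seed)
  pi <- runif(3, 0.1, 1); pi <- pi / sum(pi)
  model_params(pi, mu1 = runif(1, 0.5, 3), mu2 = -runif(1, 0.5, 3),
               sigma1 = runif(1, 0.5, 2), sigma2 = runif(1, 0.5, 2),
               rho1 = runif(1, 0.1, 0.9), rho2 = runif(1, 0.1, 0.9))
}

random_fc <- function(n, seed) {
  set.seed(seed)
  fold_change_matrix(matrix(rnorm(2 * n), ncol = 2))
}

write_fc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
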