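#' Empirical CDF transform to pseudo-uniform scores
#'
#' Maps a vector of scores to `rank / (n + 1)` with average ranks for ties.
#' The `n + 1` denominator keeps every value strictly inside (0, 1) so the
#' latent quantile transform stays finite; the output depends on the input
#' only through its ordering, hence is invariant under any strictly
#' increasing transform.
#'
#' @param x numeric vector of at least 2 finite scores.
#' @return numeric vector of pseudo-uniform values in (0, 1).
#' @examples
#' ecdf_transform(c(3, 1, 2))       # 0.75 0.25 0.50
#' ecdf_transform(exp(c(3, 1, 2)))  # identical: rank-based
#' @export
ecdf_transform <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad) > 0L)
    stop("non-finite score at gene index ", bad[1L], call. = FALSE)
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Mixture CDF of the latent marginal
#'
#' The latent scores of both studies share the marginal CDF
#' `G(z) = sum_k pi_k Phi((z - mu_k) / sigma_k)` over the three components
#' (null pinned at N(0,1)). Strictly increasing with limits 0 and 1.
#'
#' @param z numeric vector of latent values.
#' @param theta a [model_params()] object.
#' @return numeric vector of probabilities.
#' @export
mixture_cdf <- function(z, theta) {
  validate_params(theta)
  mu <- comp_mu(theta); sg <- comp_sigma(theta); pi <- theta$pi
  pi[1] * stats::pnorm(z) +
    pi[2] * stats::pnorm((z - mu[2]) / sg[2]) +
    pi[3] * stats::pnorm((z - mu[3]) / sg[3])
}

# Mixture density g = G'; used by diagnostics and tests.
mixture_pdf <- function(z, theta) {
  mu <- comp_mu(theta); sg <- comp_sigma(theta); pi <- theta$pi
  pi[1] * stats::dnorm(z) +
    pi[2] * stats::dnorm(z, mu[2], sg[2]) +
    pi[3] * stats::dnorm(z, mu[3], sg[3])
}

#' Quantile function of the latent mixture marginal
#'
#' Numerical inverse of [mixture_cdf()]. A monotone interpolation grid
#' (4096 knots over an expanding bracket) provides starting values that
#' are polished by safeguarded Newton steps; any entry not meeting the
#' tolerance falls back to bisection. The returned `z` satisfies
#' `|mixture_cdf(z) - u| <= 1e-9`.
#'
#' @param u numeric vector of probabilities strictly inside (0, 1).
#' @param theta a [model_params()] object.
#' @return numeric vector of latent quantiles.
#' @export
mixture_quantile <- function(u, theta) {
  validate_params(theta)
  if (any(u <= 0 | u >= 1) || any(!is.finite(u)))
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  mu <- comp_mu(theta); sg <- comp_sigma(theta)
  lo <- min(mu - 8 * sg); hi <- max(mu + 8 * sg)
  # expand until the bracket covers the most extreme requested quantiles
  umin <- min(u); umax <- max(u)
  while (mixture_cdf(lo, theta) >= umin) lo <- lo - (hi - lo)
  while (mixture_cdf(hi, theta) <= umax) hi <- hi + (hi - lo)
  zg <- seq(lo, hi, length.out = 4096L)
  Gg <- mixture_cdf(zg, theta)
  # G is strictly increasing but saturates in floating point at the far
  # tails; keep the strictly increasing subset for inverse interpolation
  keep <- c(TRUE, diff(Gg) > 0)
  z <- stats::approx(Gg[keep], zg[keep], xout = u, rule = 2)$y
  for (it in 1:6) {
    err <- mixture_cdf(z, theta) - u
    if (max(abs(err)) <= 1e-13) break
    step <- err / pmax(mixture_pdf(z, theta), 1e-12)
    z <- z - sign(step) * pmin(abs(step), hi - lo)
  }
  bad <- which(abs(mixture_cdf(z, theta) - u) > 1e-9)
  if (length(bad) > 0L)
    z[bad] <- bisect_quantile(u[bad], theta, lo, hi)
  z
}

bisect_quantile <- function(u, theta, lo, hi) {
  lo <- rep(lo, length(u)); hi <- rep(hi, length(u))
  repeat {
    mid <- (lo + hi) / 2
    below <- mixture_cdf(mid, theta) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-13) break
  }
  (lo + hi) / 2
}

#' Latent bivariate-normal component density
#'
#' Density of component `k` at `(z1, z2)`: bivariate normal with common
#' mean `mu_k` in both coordinates, common variance `sigma_k^2`, and
#' correlation `rho_k`. Component 0 is the independent standard normal pair.
#'
#' @param z1,z2 numeric vectors of latent coordinates (recycled together).
#' @param k component index: 0 (non-DE), 1 (up) or 2 (down).
#' @param theta a [model_params()] object.
#' @return numeric vector of densities.
#' @export
component_density <- function(z1, z2, k, theta) {
  validate_params(theta)
  if (!k %in% 0:2) stop("k must be 0, 1 or 2", call. = FALSE)
  mu <- comp_mu(theta)[k + 1L]
  sg <- comp_sigma(theta)[k + 1L]
  rho <- comp_rho(theta)[k + 1L]
  d1 <- (z1 - mu) / sg
  d2 <- (z2 - mu) / sg
  q <- (d1 * d1 - 2 * rho * d1 * d2 + d2 * d2) / (1 - rho * rho)
  exp(-q / 2) / (2 * pi * sg * sg * sqrt(1 - rho * rho))
}

#' Pseudo-observations: ranks mapped to the latent scale
#'
#' Computes `u = rank/(n+1)` per study column and the pseudo-latent values
#' `z = G^{-1}(u)` under the supplied parameters. This is the plug-in step
#' of the semi-parametric model: the unknown marginals are replaced by
#' their empirical CDFs.
#'
#' @param data a [fold_change_matrix()] (or plain n x 2 numeric matrix).
#' @param theta a [model_params()] object.
#' @return An object of class `cdeg_pseudo` with fields `u` and `z`
#'   (both n x 2 matrices).
#' @export
pseudo_observations <- function(data, theta) {
  data <- as.matrix(data)
  u <- apply(data, 2L, ecdf_transform)
  z <- matrix(mixture_quantile(as.vector(u), theta), ncol = 2L)
  structure(list(u = u, z = z), class = "cdeg_pseudo")
}

# underflow floor applied to component mixtures before logs
DENSITY_FLOOR <- 1e-300

# n x 3 matrix of pi_k * h_k(z1, z2) for the current theta
weighted_component_densities <- function(z, theta) {
  cbind(theta$pi[1] * component_density(z[, 1], z[, 2], 0L, theta),
        theta$pi[2] * component_density(z[, 1], z[, 2], 1L, theta),
        theta$pi[3] * component_density(z[, 1], z[, 2], 2L, theta))
}

#' Pseudo-log-likelihood of the copula mixture
#'
#' Sum over genes of the log of the three-term mixture density
#' `sum_k pi_k h_k(z_{i,1}, z_{i,2})` evaluated at the pseudo-latent
#' values. Mixture densities that underflow are floored at 1e-300 before
#' the log; the number of floored genes is attached as attribute
#' `n_floored`.
#'
#' @param pseudo a [pseudo_observations()] object (its `z` must have been
#'   computed under the same `theta`).
#' @param theta a [model_params()] object.
#' @return scalar log-likelihood with attribute `n_floored`.
#' @export
pseudo_loglik <- function(pseudo, theta) {
  mix <- rowSums(weighted_component_densities(pseudo$z, theta))
  n_floored <- sum(mix < DENSITY_FLOOR)
  ll <- sum(log(pmax(mix, DENSITY_FLOOR)))
  attr(ll, "n_floored") <- n_floored
  ll
}
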