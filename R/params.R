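#' Model parameters for the three-component copula mixture
#'
#' Bundles the estimable parameters of the latent Gaussian mixture:
#' component proportions `pi = (pi0, pi1, pi2)` for the non-differential,
#' up-regulated and down-regulated components, latent means `mu1 > 0 > mu2`,
#' latent standard deviations `sigma1, sigma2 > 0`, and inter-study latent
#' correlations `rho1, rho2` in (0, 1). The null component is pinned at
#' mean 0, variance 1 and correlation 0 for identifiability (only contrasts
#' against the null scale are estimable from ranks) and is never stored.
#'
#' @param pi numeric(3), component proportions summing to 1.
#' @param mu1,mu2 latent means of the up- and down-regulated components;
#'   must satisfy `mu1 > 0 > mu2`.
#' @param sigma1,sigma2 positive latent standard deviations.
#' @param rho1,rho2 latent correlations in (0, 1).
#'
#' @return An object of class `cdeg_params`.
#' @examples
#' theta <- model_params(pi = c(0.6, 0.2, 0.2), mu1 = 2, mu2 = -2,
#'                       sigma1 = 1, sigma2 = 1, rho1 = 0.8, rho2 = 0.8)
#' theta
#' @export
model_params <- function(pi, mu1, mu2, sigma1 = 1, sigma2 = 1,
                         rho1 = 0.5, rho2 = 0.5) {
  theta <- structure(
    list(pi = as.numeric(pi), mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
         sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2),
         rho1 = as.numeric(rho1), rho2 = as.numeric(rho2)),
    class = "cdeg_params")
  validate_params(theta)
  theta
}

validate_params <- function(theta) {
  stopifnot(inherits(theta, "cdeg_params"))
  if (length(theta$pi) != 3L || any(!is.finite(theta$pi)))
    stop("pi must be a finite 3-vector", call. = FALSE)
  if (abs(sum(theta$pi) - 1) > 1e-8 || any(theta$pi < 0) || any(theta$pi > 1))
    stop("pi must lie on the probability simplex", call. = FALSE)
  if (!is.finite(theta$mu1) || !is.finite(theta$mu2) ||
      theta$mu1 <= 0 || theta$mu2 >= 0)
    stop("means must satisfy mu1 > 0 > mu2", call. = FALSE)
  if (theta$sigma1 <= 0 || theta$sigma2 <= 0)
    stop("sigma1 and sigma2 must be positive", call. = FALSE)
  if (theta$rho1 <= 0 || theta$rho1 >= 1 || theta$rho2 <= 0 || theta$rho2 >= 1)
    stop("correlations must lie strictly in (0, 1)", call. = FALSE)
  invisible(theta)
}

# Component parameter accessors; component 0 is the fixed null.
comp_mu    <- function(theta) c(0, theta$mu1, theta$mu2)
comp_sigma <- function(theta) c(1, theta$sigma1, theta$sigma2)
comp_rho   <- function(theta) c(0, theta$rho1, theta$rho2)

#' @export
print.cdeg_params <- function(x, ...) {
  cat("Copula mixture parameters (components: 0 = non-DE, 1 = up, 2 = down)\n")
  cat(sprintf("  pi    = (%.4f, %.4f, %.4f)\n", x$pi[1], x$pi[2], x$pi[3]))
  cat(sprintf("  mu    = (%.4f, %.4f)   [null fixed at 0]\n", x$mu1, x$mu2))
  cat(sprintf("  sigma = (%.4f, %.4f)   [null fixed at 1]\n",
              x$sigma1, x$sigma2))
  cat(sprintf("  rho   = (%.4f, %.4f)   [null fixed at 0]\n", x$rho1, x$rho2))
  invisible(x)
}
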