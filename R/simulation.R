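#' Simulate fold-change scores from the exact copula mixture
#'
#' Draws component labels from the mixture proportions, latent pairs from
#' the corresponding bivariate normal, maps them through the latent
#' mixture CDF to pseudo-uniform scores, and finally through the chosen
#' marginal quantile function to observed scores. With
#' `marginal = "latent"` the latent values themselves are returned (the
#' fitted model only ever sees their ranks, so any strictly increasing
#' marginal yields the same fit).
#'
#' @param theta a [model_params()] object (the generating truth).
#' @param n number of genes.
#' @param seed integer seed.
#' @param marginal observed marginal: `"latent"`, `"normal"` or
#'   `"lognormal"`.
#' @return list with `data` (a [fold_change_matrix()]) and `labels`
#'   (integer truth: 0 non-DE, 1 up, 2 down).
#' @export
simulate_from_model <- function(theta, n, seed = 1L,
                                marginal = c("latent", "normal", "lognormal")) {
  validate_params(theta)
  marginal <- match.arg(marginal)
  set.seed(seed)
  k <- sample(0:2, n, replace = TRUE, prob = theta$pi)
  z <- rbvn_component(k, theta)
  x <- switch(marginal,
              latent = z,
              normal = matrix(stats::qnorm(mixture_cdf(as.vector(z), theta)),
                              ncol = 2L),
              lognormal = matrix(stats::qlnorm(mixture_cdf(as.vector(z), theta)),
                                 ncol = 2L))
  list(data = fold_change_matrix(x), labels = k)
}

# Bivariate normal draws with per-gene component (or per-gene mu/sigma/rho).
rbvn <- function(n, mu, sigma, rho) {
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  cbind(mu + sigma * e1,
        mu + sigma * (rho * e1 + sqrt(1 - rho^2) * e2))
}

rbvn_component <- function(k, theta) {
  mu <- comp_mu(theta)[k + 1L]
  sg <- comp_sigma(theta)[k + 1L]
  rho <- comp_rho(theta)[k + 1L]
  rbvn(length(k), mu, sg, rho)
}

#' Configuration for the model-violation simulation
#'
#' Study conditions for benchmarking robustness: instead of one shared
#' mean and correlation per differential component, every differential
#' gene draws its own mean and inter-study correlation from uniform
#' ranges, mildly violating the fitted model's homogeneity assumption.
#' Defaults: 5000 genes, `mu1 ~ unif(0.58, 1.58)`,
#' `mu2 ~ unif(-1.58, 0.58)`, `rho ~ unif(0.80, 0.88)`, unit component
#' variance.
#'
#' @param n_genes genes per dataset.
#' @param pi component proportions (non-DE, up, down).
#' @param mu1_range,mu2_range uniform ranges for per-gene differential
#'   means.
#' @param rho_range uniform range for per-gene correlations.
#' @param n_datasets number of independent datasets to generate.
#' @param seed integer seed (dataset `d` uses `seed + d - 1`).
#' @return An object of class `cdeg_violation_config`.
#' @export
violation_config <- function(n_genes = 5000L, pi = c(0.6, 0.2, 0.2),
                             mu1_range = c(0.58, 1.58),
                             mu2_range = c(-1.58, 0.58),
                             rho_range = c(0.80, 0.88),
                             n_datasets = 1L, seed = 1L) {
  stopifnot(n_genes >= 10L, length(pi) == 3L, abs(sum(pi) - 1) < 1e-8,
            diff(mu1_range) >= 0, diff(mu2_range) >= 0, diff(rho_range) >= 0,
            n_datasets >= 1L)
  structure(list(n_genes = as.integer(n_genes), pi = pi,
                 mu1_range = mu1_range, mu2_range = mu2_range,
                 rho_range = rho_range, n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "cdeg_violation_config")
}

#' Simulate datasets with per-gene parameter heterogeneity
#'
#' Generates log-fold-change pairs from the three-component latent model
#' but with each differential gene carrying its own mean (uniform over the
#' configured range) and correlation; non-differential genes are
#' independent standard normal pairs. Per-platform p-values come from a
#' two-sided z-test of zero mean applied to the latent-scale scores (unit
#' component variance makes them z-scores).
#'
#' @param config a [violation_config()] object.
#' @return list of length `n_datasets`; each element has `data`
#'   (a [fold_change_matrix()]), `labels`, and `pvalues` (n x 2).
#' @export
simulate_violation <- function(config = violation_config()) {
  stopifnot(inherits(config, "cdeg_violation_config"))
  lapply(seq_len(config$n_datasets), function(d) {
    set.seed(config$seed + d - 1L)
    n <- config$n_genes
    k <- sample(0:2, n, replace = TRUE, prob = config$pi)
    mu <- numeric(n)
    rho <- numeric(n)
    up <- k == 1L; down <- k == 2L
    mu[up] <- stats::runif(sum(up), config$mu1_range[1], config$mu1_range[2])
    mu[down] <- stats::runif(sum(down), config$mu2_range[1], config$mu2_range[2])
    rho[up] <- stats::runif(sum(up), config$rho_range[1], config$rho_range[2])
    rho[down] <- stats::runif(sum(down), config$rho_range[1], config$rho_range[2])
    z <- rbvn(n, mu, 1, rho)
    pvalues <- matrix(2 * stats::pnorm(-abs(z)), ncol = 2L)
    list(data = fold_change_matrix(z), labels = k, pvalues = pvalues,
         gene_mu = mu, gene_rho = rho)
  })
}

#' Configuration for the coupled RNA-seq / microarray generator
#'
#' Study conditions for the realistic cross-platform benchmark: per-gene
#' baseline means drawn from a log-normal, per-gene negative-binomial
#' dispersions from a gamma, a fixed log2-fold-change magnitude for
#' differential genes, and a normal log-scale microarray error. Defaults:
#' 10000 genes, 10 % up- and 30 % down-regulated, 3 replicates per
#' condition, log-normal(meanlog 4, sdlog 1.5) baselines, gamma(shape 2,
#' rate 10) dispersions (mean 0.2), 2-fold differential shifts, array
#' noise SD 0.25 (log2 scale).
#'
#' @param n_genes,n_reps integer counts of genes and replicates per
#'   condition.
#' @param prop_up,prop_down proportions of up- and down-regulated genes
#'   (sum at most 1).
#' @param nb_mean_log_mu,nb_mean_log_sigma log-normal parameters for the
#'   baseline negative-binomial means.
#' @param nb_dispersion_shape,nb_dispersion_rate gamma parameters for the
#'   per-gene dispersion.
#' @param array_noise_sd microarray log2-scale error SD.
#' @param logfc_magnitude absolute log2 fold change of differential genes.
#' @param seed integer seed.
#' @return An object of class `cdeg_xplat_config`.
#' @export
cross_platform_config <- function(n_genes = 10000L, prop_up = 0.1,
                                  prop_down = 0.3, n_reps = 3L,
                                  nb_mean_log_mu = 4, nb_mean_log_sigma = 1.5,
                                  nb_dispersion_shape = 2,
                                  nb_dispersion_rate = 10,
                                  array_noise_sd = 0.25,
                                  logfc_magnitude = 1, seed = 1L) {
  if (n_genes != round(n_genes) || n_reps != round(n_reps))
    stop("n_genes and n_reps must be integers", call. = FALSE)
  stopifnot(prop_up >= 0, prop_down >= 0, prop_up + prop_down <= 1,
            nb_mean_log_sigma > 0, nb_dispersion_shape > 0,
            nb_dispersion_rate > 0, array_noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes), prop_up = prop_up,
                 prop_down = prop_down, n_reps = as.integer(n_reps),
                 nb_mean_log_mu = nb_mean_log_mu,
                 nb_mean_log_sigma = nb_mean_log_sigma,
                 nb_dispersion_shape = nb_dispersion_shape,
                 nb_dispersion_rate = nb_dispersion_rate,
                 array_noise_sd = array_noise_sd,
                 logfc_magnitude = logfc_magnitude,
                 seed = as.integer(seed)),
            class = "cdeg_xplat_config")
}

#' Simulate quantile-coupled RNA-seq counts and microarray intensities
#'
#' Per gene: a baseline mean from the log-normal, a dispersion from the
#' gamma, and a condition-2 mean shifted by `2^(+/- logfc_magnitude)` for
#' differential genes. For each gene x replicate x condition a single
#' shared uniform quantile drives both platforms — the negative-binomial
#' quantile function yields the RNA-seq count and the normal quantile on
#' the log2 scale yields the microarray intensity — so a gene's noise
#' realizations are concordant across platforms, as when both assay the
#' same biological sample.
#'
#' @param config a [cross_platform_config()] object.
#' @return list with `counts` (integer genes x 2*n_reps), `intensity`
#'   (numeric, same layout), `condition` (1/2 per column), `labels`
#'   (0/1/2 per gene), and `config`.
#' @export
simulate_cross_platform <- function(config = cross_platform_config()) {
  stopifnot(inherits(config, "cdeg_xplat_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_up <- round(config$prop_up * n)
  n_down <- round(config$prop_down * n)
  labels <- c(rep(1L, n_up), rep(2L, n_down), rep(0L, n - n_up - n_down))
  labels <- sample(labels)   # shuffle gene order

  base_mu <- stats::rlnorm(n, config$nb_mean_log_mu, config$nb_mean_log_sigma)
  disp <- stats::rgamma(n, shape = config$nb_dispersion_shape,
                        rate = config$nb_dispersion_rate)
  disp <- pmax(disp, 1e-4)
  lfc <- ifelse(labels == 1L, config$logfc_magnitude,
                ifelse(labels == 2L, -config$logfc_magnitude, 0))
  mu_cond <- cbind(base_mu, base_mu * 2^lfc)

  n_cols <- 2L * config$n_reps
  counts <- matrix(0L, n, n_cols)
  intensity <- matrix(0, n, n_cols)
  condition <- rep(1:2, each = config$n_reps)
  for (j in seq_len(n_cols)) {
    mu_j <- mu_cond[, condition[j]]
    q <- stats::runif(n)
    counts[, j] <- stats::qnbinom(q, size = 1 / disp, mu = mu_j)
    intensity[, j] <- stats::qnorm(q, mean = log2(mu_j),
                                   sd = config$array_noise_sd)
  }
  ids <- paste0("gene_", seq_len(n))
  reps <- paste0("cond", condition, "_rep", rep(seq_len(config$n_reps), 2L))
  dimnames(counts) <- list(ids, reps)
  dimnames(intensity) <- list(ids, reps)
  list(counts = counts, intensity = intensity, condition = condition,
       labels = labels, config = config)
}

#' Per-gene log2 fold changes from a simulated expression matrix
#'
#' Condition-2 minus condition-1 mean on the log2 scale. Counts get a
#' pseudocount of 0.5 before the log; intensities are assumed to be on the
#' log scale already.
#'
#' @param mat genes x replicates matrix.
#' @param condition vector of 1/2 condition assignments per column.
#' @param type `"counts"` (apply `log2(x + 0.5)`) or `"log_intensity"`.
#' @return numeric vector of per-gene log2 fold changes.
#' @export
platform_log_fc <- function(mat, condition,
                            type = c("counts", "log_intensity")) {
  type <- match.arg(type)
  stopifnot(length(condition) == ncol(mat), all(condition %in% 1:2))
  lm2 <- if (type == "counts") log2(mat + 0.5) else mat
  rowMeans(lm2[, condition == 2L, drop = FALSE]) -
    rowMeans(lm2[, condition == 1L, drop = FALSE])
}
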