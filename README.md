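# copulaDEG

Rank-based integration of differential gene-expression signals from two
studies or platforms — for example a microarray and an RNA-seq experiment
contrasting the same conditions — with a three-component Gaussian copula
mixture model. The package is for analysts who have two per-gene score
lists (log2 fold changes or test statistics) on incomparable scales and
want a single ranking and an error-rate-controlled DEG call set that
rewards *cross-study concordance*, not just single-study extremity.

## The model

Gene $i$ carries an unobserved state $K_i$: non-differential ($k = 0$,
proportion $\pi_0$), up-regulated ($k = 1$) or down-regulated ($k = 2$).
Given $K_i = k$, a latent pair follows a bivariate normal

$$(z_{i,1}, z_{i,2}) \mid K_i = k \sim
  N\!\left((\mu_k, \mu_k),\; \sigma_k^2
  \begin{pmatrix} 1 & \rho_k \\ \rho_k & 1 \end{pmatrix}\right),
\qquad \mu_0 = 0,\ \sigma_0 = 1,\ \rho_0 = 0,\ \mu_1 > 0 > \mu_2,$$

and the observed scores are $x_{i,j} = F_j^{-1}(G(z_{i,j}))$, where $G$
is the marginal mixture CDF of the latent scale and $F_1, F_2$ are
unknown study-specific marginals, replaced in fitting by the empirical
CDFs $u_{i,j} = \mathrm{rank}(x_{i,j})/(n+1)$. Differential components
have positive inter-study correlation; noise does not. Everything is
estimated from ranks, so the method is invariant to monotone rescaling
of either study. Estimation maximizes the pseudo-likelihood
$\prod_i \sum_k \pi_k h_k(G^{-1}(u_{i,1}), G^{-1}(u_{i,2}))$ by a
pseudo-EM scheme; genes are then ranked by the posterior probability
$p_0$ of being non-differential, and the selection cutoff keeps the
running mean of sorted $p_0$ — the expected proportion of
non-differential genes among the calls — below a target $\alpha$.
Fisher's and Stouffer's p-value combiners and a two-sided rank product
are included as baselines, plus simulation generators and
calibration/ROC utilities for benchmarking. The methods vignette
(`vignettes/copula-integration.Rmd`) documents the model, the
estimation schedule and all numerical choices.

## Worked example

Simulate 5000 genes from the model (60 % null, 25 % up, 15 % down,
latent means ±2.5/−2, correlation 0.84), fit, and select DEGs at
$\alpha = 0.05$:

```r
library(copulaDEG)

theta_true <- model_params(pi = c(0.6, 0.25, 0.15), mu1 = 2.5, mu2 = -2,
                           rho1 = 0.84, rho2 = 0.84)
sim <- simulate_from_model(theta_true, n = 5000, seed = 101)

fit <- fit_copula_mixture(sim$data, fit_config(seed = 101))
fit
#> Copula mixture fit: converged after 177 outer iterations (start 1)
#>   final pseudo-log-likelihood: -16169.3287
#> Copula mixture parameters (components: 0 = non-DE, 1 = up, 2 = down)
#>   pi    = (0.5844, 0.2409, 0.1747)
#>   mu    = (2.5105, -1.8294)   [null fixed at 0]
#>   sigma = (0.8151, 1.1415)   [null fixed at 1]
#>   rho   = (0.8390, 0.8713)   [null fixed at 0]

post <- posterior_probs(sim$data, fit$theta)
sel <- select_degs(post, alpha = 0.05)
attr(sel, "i_max")
#> [1] 1781
```

The fitted proportions and correlations sit close to the generating
values, and 1781 genes are called at a target non-DE rate of 5 %.
Because the truth is known here, the calibration of that estimate can be
checked — among the 1781 selected genes, 5.2 % are truly
non-differential — and the posterior ranking can be compared with the
rank-product baseline:

```r
cal <- evaluate_calibration(sel, setNames(sim$labels, rownames(sim$data)))
cal$empirical_fdr[attr(sel, "i_max")]
#> [1] 0.0522

evaluate_roc(-post$p0, sim$labels != 0)$auc        # 0.962
evaluate_roc(-rankprod(sim$data)$rp, sim$labels != 0)$auc  # 0.918
```

For real tables, `read_fold_changes("scores.tsv")` loads a TSV with
columns `gene_id`, `study1`, `study2`, and `run_pipeline()` writes the
per-gene results plus a JSON summary; `inst/cli/copuladeg` wraps the
same calls as `run` / `simulate` / `baselines` / `evaluate` subcommands.

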