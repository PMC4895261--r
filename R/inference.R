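#' Posterior component probabilities for each gene
#'
#' Applies the empirical-CDF transform and the latent quantile map, then
#' evaluates `p_k = pi_k h_k(z1, z2) / sum_k pi_k h_k(z1, z2)` for each
#' gene, the posterior probability of being non-differential (`p0`),
#' up-regulated (`p1`) or down-regulated (`p2`). The reported `label` is
#' the highest-posterior component, ties going to the smaller index.
#'
#' @param data a [fold_change_matrix()] (or plain n x 2 numeric matrix).
#' @param theta a [model_params()] object, typically from
#'   [fit_copula_mixture()].
#' @return data.frame with columns `gene_id, p0, p1, p2, label`.
#' @export
posterior_probs <- function(data, theta) {
  data <- as.matrix(data)
  if (ncol(data) != 2L) stop("expected 2 columns", call. = FALSE)
  ids <- rownames(data)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(data)))
  pseudo <- pseudo_observations(data, theta)
  resp <- e_step(pseudo, theta)
  out <- data.frame(gene_id = ids, p0 = resp[, 1], p1 = resp[, 2],
                    p2 = resp[, 3], stringsAsFactors = FALSE)
  out$label <- classify_genes(out)
  out
}

#' Classify genes by highest posterior probability
#'
#' @param posteriors data.frame with columns `p0, p1, p2` (rows summing
#'   to 1), as from [posterior_probs()].
#' @return integer vector of component labels (0 = non-DE, 1 = up,
#'   2 = down); posterior ties resolve to the smaller component index.
#' @export
classify_genes <- function(posteriors) {
  p <- as.matrix(posteriors[, c("p0", "p1", "p2")])
  max.col(p, ties.method = "first") - 1L
}

#' Select differentially expressed genes at a target non-DE discovery rate
#'
#' Ranks genes by `p0` ascending (the most convincingly differential genes
#' first) and computes, at each rank `i`, the running mean of the sorted
#' `p0` values — the expected proportion of non-differential genes among
#' the top `i` calls. The selection cutoff `i_max` is the largest rank at
#' which this expected rate stays strictly below `alpha`; the selected set
#' is the prefix of the ranking up to `i_max`. Ties in `p0` are kept
#' adjacent (stable sort by gene id within ties).
#'
#' @param posteriors data.frame from [posterior_probs()].
#' @param alpha target expected non-DE rate among selections, in (0, 1).
#' @return data.frame in ranked order with columns
#'   `gene_id, p0, rank, cum_error, selected` and attributes `i_max` and
#'   `alpha`.
#' @examples
#' post <- data.frame(gene_id = c("a", "b", "c"),
#'                    p0 = c(0.01, 0.02, 0.5),
#'                    p1 = c(0.99, 0.98, 0.5), p2 = 0)
#' select_degs(post, alpha = 0.05)
#' @export
select_degs <- function(posteriors, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  ord <- order(posteriors$p0, posteriors$gene_id, method = "radix")
  p0s <- posteriors$p0[ord]
  n <- length(p0s)
  cum_error <- cumsum(p0s) / seq_len(n)
  below <- which(cum_error < alpha)
  i_max <- if (length(below) > 0L) max(below) else 0L
  out <- data.frame(gene_id = posteriors$gene_id[ord], p0 = p0s,
                    rank = seq_len(n), cum_error = cum_error,
                    selected = seq_len(n) <= i_max,
                    stringsAsFactors = FALSE)
  attr(out, "i_max") <- i_max
  attr(out, "alpha") <- alpha
  out
}
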