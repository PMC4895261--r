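#' Fisher's method for combining two p-values per gene
#'
#' Combined statistic `-2 * sum(log p)` referred to a chi-square
#' distribution with 4 degrees of freedom (2 studies). Zeros are clamped
#' to 1e-300 before the log (with a warning counting occurrences).
#'
#' @param pvals n x 2 numeric matrix of p-values in `[0, 1]`.
#' @return numeric vector of combined p-values.
#' @examples
#' fisher_combine(cbind(0.5, 0.5))  # 0.5965736
#' @export
fisher_combine <- function(pvals) {
  pvals <- as.matrix(pvals)
  check_pvals(pvals)
  nzero <- sum(pvals == 0)
  if (nzero > 0) {
    warning(nzero, " zero p-value(s) clamped to 1e-300", call. = FALSE)
    pvals[pvals == 0] <- 1e-300
  }
  stat <- -2 * rowSums(log(pvals))
  stats::pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Stouffer's method for combining two p-values per gene
#'
#' Combined z-score `sum(qnorm(1 - p)) / sqrt(2)`; combined p-value is the
#' upper normal tail. Inputs are clamped to `[1e-15, 1 - 1e-15]` so that
#' numerically-zero p-values do not collapse the z-score to infinity.
#'
#' @inheritParams fisher_combine
#' @return numeric vector of combined p-values.
#' @export
stouffer_combine <- function(pvals) {
  pvals <- as.matrix(pvals)
  check_pvals(pvals)
  pvals <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  z <- rowSums(stats::qnorm(1 - pvals)) / sqrt(2)
  stats::pnorm(z, lower.tail = FALSE)
}

check_pvals <- function(pvals) {
  if (ncol(pvals) != 2L)
    stop("expected an n x 2 matrix of p-values", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  invisible(pvals)
}

#' Two-sided rank product statistic
#'
#' For each gene, the product of its normalized ranks across the two
#' studies, `RP_i = prod_j r_{i,j} / n_j`, computed on both tails:
#' ascending ranks flag genes consistently at the bottom of both lists
#' (down-regulated), descending ranks genes consistently at the top
#' (up-regulated). The reported statistic is the smaller of the two, with
#' the achieving tail recorded, so small values mean consistent extremity
#' in either direction. Ties receive average ranks.
#'
#' @param data a [fold_change_matrix()] (or plain n x 2 numeric matrix).
#' @return An object of class `cdeg_rankprod`: list with `rp` (per-gene
#'   statistic in (0, 1]), `direction` ("up"/"down"), `rp_up`, `rp_down`,
#'   `r` (ascending rank matrix), and `n_j`.
#' @export
rankprod <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) != 2L) stop("expected 2 columns", call. = FALSE)
  n <- nrow(data)
  r_asc <- apply(data, 2L, rank, ties.method = "average")
  r_desc <- n + 1 - r_asc
  rp_down <- unname((r_asc[, 1] / n) * (r_asc[, 2] / n))
  rp_up <- unname((r_desc[, 1] / n) * (r_desc[, 2] / n))
  rp <- pmin(rp_up, rp_down)
  structure(list(rp = rp,
                 direction = ifelse(rp_up <= rp_down, "up", "down"),
                 rp_up = rp_up, rp_down = rp_down,
                 r = r_asc, n_j = c(n, n)),
            class = "cdeg_rankprod")
}
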