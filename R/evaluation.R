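#' Calibration of the estimated non-DE discovery rate
#'
#' Pairs, at each rank of the selection ordering, the model's estimated
#' expected non-DE rate (`cum_error`, the running mean of sorted `p0`)
#' with the empirical false discovery rate — the realized fraction of
#' truly non-differential genes among the top-`i` calls. On
#' well-calibrated data the two curves track each other.
#'
#' @param selection a [select_degs()] table (ranked order).
#' @param labels integer truth labels (0 = non-DE), either named by gene
#'   id or in the same gene order as the data the selection came from;
#'   unnamed labels are matched by `gene_id` only when names are present
#'   on the vector, otherwise the selection's `gene_id` must index into
#'   the default `gene_<i>` naming.
#' @return data.frame with columns `rank, cum_error, empirical_fdr`.
#' @export
evaluate_calibration <- function(selection, labels) {
  if (!is.null(names(labels))) {
    lab <- labels[selection$gene_id]
  } else {
    idx <- match(selection$gene_id, paste0("gene_", seq_along(labels)))
    if (anyNA(idx))
      stop("labels must be named by gene id or follow gene_<i> naming",
           call. = FALSE)
    lab <- labels[idx]
  }
  if (anyNA(lab)) stop("labels missing for some selected genes", call. = FALSE)
  is_null <- as.integer(lab == 0L)
  data.frame(rank = selection$rank,
             cum_error = selection$cum_error,
             empirical_fdr = cumsum(is_null) / seq_along(is_null))
}

#' ROC curve and AUC for a differential-expression ranking
#'
#' Sweeps a threshold over the score (higher score = more likely
#' differential) and reports the false/true positive rates plus the area
#' under the curve. The AUC is the probability that a random differential
#' gene outranks a random non-differential one, computed by the rank-sum
#' identity with ties counted one half.
#'
#' @param score numeric ranking statistic, higher = more differential.
#' @param labels binary truth: TRUE/1 for differential genes.
#' @return list with `points` (data.frame `fpr, tpr` including the (0,0)
#'   and (1,1) endpoints) and `auc`.
#' @examples
#' evaluate_roc(1:6, c(0, 0, 1, 0, 1, 1))$auc  # 8/9
#' @export
evaluate_roc <- function(score, labels) {
  labels <- as.logical(labels)
  stopifnot(length(score) == length(labels), all(is.finite(score)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(score, decreasing = TRUE)
  lab_sorted <- labels[ord]
  score_sorted <- score[ord]
  # one operating point per distinct threshold (ties collapse)
  keep <- c(score_sorted[-length(score_sorted)] != score_sorted[-1], TRUE)
  tpr <- cumsum(lab_sorted)[keep] / n_pos
  fpr <- cumsum(!lab_sorted)[keep] / n_neg
  list(points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}
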