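#' Per-gene differential-expression scores for two studies
#'
#' Container for the model input: one differential-expression score per gene
#' per study (log2 fold changes, test statistics, or any monotone score —
#' only the ranks are used downstream).
#'
#' @param values numeric matrix with `n >= 10` rows (genes) and exactly 2
#'   columns (studies); all entries finite.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   rownames of `values` or `gene_1 ... gene_n`.
#' @param study_names length-2 character vector of study labels.
#'
#' @return An object of class `cdeg_fc`: the matrix with gene ids as
#'   rownames and study names as colnames.
#' @examples
#' m <- cbind(rnorm(20), rnorm(20))
#' fc <- fold_change_matrix(m)
#' dim(fc)
#' @export
fold_change_matrix <- function(values, gene_ids = NULL, study_names = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop("expected exactly 2 study columns, got ", ncol(values), call. = FALSE)
  if (nrow(values) < 10L)
    stop("need at least 10 genes for estimation, got ", nrow(values),
         call. = FALSE)
  storage.mode(values) <- "double"
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite score at gene index ", bad[1L, 1L],
         ", study ", bad[1L, 2L], call. = FALSE)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3L),
               collapse = ", "), call. = FALSE)
  if (is.null(study_names)) {
    study_names <- colnames(values)
    if (is.null(study_names)) study_names <- c("study1", "study2")
  }
  dimnames(values) <- list(gene_ids, study_names)
  class(values) <- c("cdeg_fc", "matrix", "array")
  values
}

gene_ids <- function(x) rownames(x)

#' @export
print.cdeg_fc <- function(x, ...) {
  cat(sprintf("Fold-change matrix: %d genes x 2 studies (%s, %s)\n",
              nrow(x), colnames(x)[1], colnames(x)[2]))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
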