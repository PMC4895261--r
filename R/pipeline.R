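#' Read a fold-change table from TSV/CSV
#'
#' Expects a header with a gene-identifier column and two numeric score
#' columns. Genes with any missing or non-finite score are dropped with a
#' message; duplicated gene ids are an error, as is ending up with fewer
#' than 10 usable genes.
#'
#' @param path file path; comma-separated if it ends in `.csv`, otherwise
#'   tab-separated.
#' @param id_col,col1,col2 column names for the gene identifier and the
#'   two study scores.
#' @return A [fold_change_matrix()].
#' @export
read_fold_changes <- function(path, id_col = "gene_id",
                              col1 = "study1", col2 = "study2") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, col1, col2))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicated gene ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3L), collapse = ", "),
         call. = FALSE)
  vals <- cbind(suppressWarnings(as.numeric(df[[col1]])),
                suppressWarnings(as.numeric(df[[col2]])))
  ok <- is.finite(vals[, 1]) & is.finite(vals[, 2])
  if (any(!ok))
    message("dropped ", sum(!ok), " gene(s) with missing/non-finite scores")
  if (sum(ok) < 10L)
    stop("fewer than 10 usable genes after filtering", call. = FALSE)
  fold_change_matrix(vals[ok, , drop = FALSE], gene_ids = ids[ok],
                     study_names = c(col1, col2))
}

#' Run the full integration pipeline on a fold-change table
#'
#' Reads the table, fits the copula mixture, computes posterior component
#' probabilities, applies the error-rate-controlled selection, optionally
#' adds the rank-product baseline (and Fisher/Stouffer when p-value
#' columns are supplied), and writes a per-gene TSV plus a JSON summary.
#'
#' @param input path to the fold-change table.
#' @param output_dir directory for `results.tsv` and `summary.json`
#'   (created if needed).
#' @param id_col,col1,col2 input column names.
#' @param alpha target expected non-DE rate for selection.
#' @param config a [fit_config()].
#' @param baselines add rank-product columns (and Fisher/Stouffer if
#'   `pval_col1`/`pval_col2` are given).
#' @param pval_col1,pval_col2 optional per-study p-value column names for
#'   the p-value combiners.
#' @return Invisibly, a list with `fit`, `posteriors`, `selection`, and
#'   the output paths.
#' @export
run_pipeline <- function(input, output_dir, id_col = "gene_id",
                         col1 = "study1", col2 = "study2", alpha = 0.05,
                         config = fit_config(), baselines = TRUE,
                         pval_col1 = NULL, pval_col2 = NULL) {
  fc <- read_fold_changes(input, id_col, col1, col2)
  fit <- fit_copula_mixture(fc, config)
  if (!fit$converged)
    warning("model fit did not converge; results may be unreliable",
            call. = FALSE)
  post <- posterior_probs(fc, fit$theta)
  sel <- select_degs(post, alpha)

  out <- data.frame(gene_id = rownames(fc),
                    x1 = fc[, 1], x2 = fc[, 2],
                    p0 = post$p0, p1 = post$p1, p2 = post$p2,
                    label = post$label, stringsAsFactors = FALSE)
  m <- match(out$gene_id, sel$gene_id)
  out$rank <- sel$rank[m]
  out$cum_error <- sel$cum_error[m]
  out$selected <- sel$selected[m]

  if (baselines) {
    rp <- rankprod(fc)
    out$rankprod <- rp$rp
    out$rp_direction <- rp$direction
    if (!is.null(pval_col1) && !is.null(pval_col2)) {
      sep <- if (grepl("\\.csv$", input, ignore.case = TRUE)) "," else "\t"
      df <- utils::read.table(input, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, check.names = FALSE)
      pv <- df[match(out$gene_id, as.character(df[[id_col]])),
               c(pval_col1, pval_col2)]
      pv <- as.matrix(pv)
      out$fisher_p <- fisher_combine(pv)
      out$stouffer_p <- stouffer_combine(pv)
    }
  }

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tsv_path <- file.path(output_dir, "results.tsv")
  json_path <- file.path(output_dir, "summary.json")
  out_fmt <- out
  num <- vapply(out_fmt, is.double, logical(1))
  out_fmt[num] <- lapply(out_fmt[num], signif, digits = 6)
  utils::write.table(out_fmt, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    n_genes = nrow(fc),
    theta = list(pi = fit$theta$pi, mu1 = fit$theta$mu1, mu2 = fit$theta$mu2,
                 sigma1 = fit$theta$sigma1, sigma2 = fit$theta$sigma2,
                 rho1 = fit$theta$rho1, rho2 = fit$theta$rho2),
    converged = fit$converged,
    n_iter = fit$n_iter,
    loglik_trace = fit$loglik_trace,
    alpha = alpha,
    i_max = attr(sel, "i_max"),
    n_selected = sum(sel$selected),
    label_counts = as.list(table(factor(post$label, levels = 0:2))))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, posteriors = post, selection = sel,
                 results_tsv = tsv_path, summary_json = json_path))
}
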