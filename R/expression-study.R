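#' Construct an expression study
#'
#' Bundles a genes x samples matrix of normalized log2 expression values with
#' a sample table assigning every column its factor levels: `genotype`,
#' `condition` (nutrient status), `tissue` and `replicate`. This is the input
#' container for [fit_gene_anova()] and [call_degs()].
#'
#' Rows of `exprs` containing missing values are dropped before any model is
#' fitted; the count of dropped genes is reported with a message and stored in
#' the `n_dropped` field.
#'
#' @param exprs numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames matching `samples$sample_id`).
#' @param samples data.frame with columns `sample_id`, `genotype`, `condition`,
#'   `tissue`, `replicate`; one row per column of `exprs`.
#' @return An object of class `expression_study` with fields `exprs`,
#'   `samples` and `n_dropped`.
#' @export
expression_study <- function(exprs, samples) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    .err("`exprs` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(exprs)))
    .err("`exprs` must have gene IDs as rownames")
  need <- c("sample_id", "genotype", "condition", "tissue", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    .err("`samples` is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(exprs))
    .err("`samples` has %d rows but `exprs` has %d columns",
         nrow(samples), ncol(exprs))
  if (is.null(colnames(exprs))) colnames(exprs) <- samples$sample_id
  if (!identical(colnames(exprs), as.character(samples$sample_id)))
    .err("colnames(exprs) must match samples$sample_id in order")
  if (anyNA(samples[need]))
    .err("sample table has incomplete factor assignments")

  keep <- stats::complete.cases(exprs)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("dropping %d gene(s) with missing values", n_dropped))
    exprs <- exprs[keep, , drop = FALSE]
  }
  structure(
    list(exprs = exprs,
         samples = as.data.frame(samples, stringsAsFactors = FALSE),
         n_dropped = n_dropped),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  for (f in c("genotype", "condition", "tissue"))
    cat(sprintf("  %-9s %s\n", f,
                paste(unique(x$samples[[f]]), collapse = ", ")))
  cat(sprintf("  replicates per cell: %s\n",
              paste(unique(table(interaction(
                x$samples$genotype, x$samples$condition, x$samples$tissue))),
                collapse = "/")))
  invisible(x)
}

#' Write / read an expression study as TSV
#'
#' The matrix file has a `gene_id` column followed by one column per sample;
#' the sample table file carries the factor assignments.
#'
#' @param study an [expression_study()] object.
#' @param exprs_path,samples_path file paths for the matrix and sample table.
#' @return `write_expression_study()` returns the paths invisibly;
#'   `read_expression_study()` returns an `expression_study`.
#' @export
write_expression_study <- function(study, exprs_path, samples_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene_id = rownames(study$exprs), study$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, exprs_path)
  .write_tsv(study$samples, samples_path)
  invisible(c(exprs_path, samples_path))
}

#' @rdname write_expression_study
#' @export
read_expression_study <- function(exprs_path, samples_path) {
  df <- .read_tsv(exprs_path)
  if (names(df)[1] != "gene_id") .err("first column of %s must be gene_id", exprs_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_study(m, .read_tsv(samples_path))
}
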