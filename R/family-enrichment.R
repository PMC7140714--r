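#' Gene-family overrepresentation test
#'
#' One-sided hypergeometric (Fisher exact, enrichment tail) test of each gene
#' family against a query set drawn from a gene universe. For a family of
#' size m in a universe of size N and a query of size n overlapping the
#' family in k genes, the p-value is `P(X >= k)` with
#' `X ~ Hypergeometric(N, m, n)`.
#'
#' Query members outside the universe are dropped with a message (their count
#' is reported); families may overlap. No multiple-testing correction is
#' applied by default, matching reporting of raw p-value thresholds;
#' `correct = "BH"` adds a `p_adjusted` column and flags on it instead.
#'
#' @param query character vector of gene IDs to test.
#' @param families named list of character vectors (family -> members).
#' @param universe character vector of all annotated gene IDs; defaults to
#'   the union of all family members.
#' @param alpha enrichment threshold on the p-value, default 0.01.
#' @param correct `"none"` (default) or `"BH"`.
#' @return A data.frame of class `enrichment_result`, sorted by p-value then
#'   family name, with columns `family`, `k` (overlap), `n` (query size),
#'   `m` (family size), `N` (universe size), `p_value` and `enriched`.
#' @export
enrich_families <- function(query, families, universe = NULL, alpha = 0.01,
                            correct = c("none", "BH")) {
  correct <- match.arg(correct)
  if (!length(families)) .err("`families` must be a non-empty named list")
  if (is.null(names(families)) || any(!nzchar(names(families))))
    .err("`families` must be named")
  if (is.null(universe)) universe <- unique(unlist(families, use.names = FALSE))
  universe <- .as_id_set(universe, "universe")
  if (!length(universe)) .err("the gene universe is empty")
  query <- .as_id_set(query, "query")

  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("dropping %d query gene(s) outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  fam_members <- lapply(families, function(f)
    intersect(unique(trimws(as.character(f))), universe))
  m <- lengths(fam_members)
  k <- vapply(fam_members, function(f) length(intersect(f, query)), integer(1))
  # upper tail P(X >= k); k = 0 gives exactly 1
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)

  res <- data.frame(family = names(families), k = k, n = n, m = m, N = N,
                    p_value = p, row.names = NULL, stringsAsFactors = FALSE)
  if (correct == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
    res$enriched <- res$p_adjusted < alpha
  } else {
    res$enriched <- res$p_value < alpha
  }
  res <- res[order(res$p_value, res$family), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, max_rows = 15L, ...) {
  cat(sprintf("family enrichment: %d families, %d enriched\n",
              nrow(x), sum(x$enriched)))
  print.data.frame(utils::head(as.data.frame(x), max_rows), digits = 4)
  if (nrow(x) > max_rows) cat(sprintf("... and %d more\n", nrow(x) - max_rows))
  invisible(x)
}
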