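#' Per-gene 3-way factorial ANOVA
#'
#' Fits, for every gene, the fixed-effects factorial model
#' `log2 expression ~ genotype * condition * tissue` by ordinary least
#' squares and returns p-values for all seven ANOVA terms (three main
#' effects, three two-way interactions, the three-way interaction) together
#' with, for every (genotype, tissue) contrast, the stressed-vs-reference
#' condition comparison computed as a linear contrast under the fitted model
#' (pooled residual variance, t distribution on the residual degrees of
#' freedom).
#'
#' Because the design matrix is shared by all genes, the model is fitted once
#' via a QR decomposition and applied to every gene simultaneously. With a
#' balanced design and sum-to-zero contrasts the sequential sums of squares
#' equal the marginal ones, so term order is immaterial.
#'
#' Genes with zero variance across all samples are reported with p = 1 for
#' every term and contrast (no evidence of any effect) rather than an error.
#'
#' @param study an [expression_study()].
#' @param ref_condition,stress_condition condition labels defining the
#'   contrast (default: first and second level in order of appearance).
#' @return An object of class `gene_anova` with components:
#'   \describe{
#'     \item{term_p}{genes x terms matrix of ANOVA p-values}
#'     \item{term_F}{the matching F statistics}
#'     \item{contrasts}{data.frame with one row per gene per
#'       (genotype, tissue) contrast: `log2fc`, sign-coded linear
#'       `fold_change`, contrast p-value `p_contrast`, and the condition
#'       main-effect p-value `p_condition`}
#'     \item{df_residual}{residual degrees of freedom}
#'   }
#' @export
fit_gene_anova <- function(study, ref_condition = NULL, stress_condition = NULL) {
  stopifnot(inherits(study, "expression_study"))
  s <- study$samples
  fac <- list(genotype = factor(s$genotype, levels = unique(s$genotype)),
              condition = factor(s$condition, levels = unique(s$condition)),
              tissue = factor(s$tissue, levels = unique(s$tissue)))
  for (nm in names(fac))
    if (nlevels(fac[[nm]]) < 2L)
      .err("degenerate design: factor `%s` has a single level (%s)",
           nm, levels(fac[[nm]]))
  cell <- interaction(fac$genotype, fac$condition, fac$tissue, drop = TRUE)
  if (any(table(cell) < 2L))
    .err("every design cell needs >= 2 replicates for ANOVA")

  if (is.null(ref_condition)) ref_condition <- levels(fac$condition)[1]
  if (is.null(stress_condition)) stress_condition <- levels(fac$condition)[2]
  if (!all(c(ref_condition, stress_condition) %in% levels(fac$condition)))
    .err("conditions must be among: %s",
         paste(levels(fac$condition), collapse = ", "))

  dat <- data.frame(fac)
  mm <- stats::model.matrix(
    ~ genotype * condition * tissue, dat,
    contrasts.arg = lapply(fac, function(f) stats::contr.sum(nlevels(f))))
  asgn <- attr(mm, "assign")
  term_labels <- attr(stats::terms(~ genotype * condition * tissue), "term.labels")

  Y <- t(study$exprs)                       # samples x genes
  qr_x <- qr(mm)
  p <- qr_x$rank
  n <- nrow(Y)
  df_res <- n - p
  eff <- qr.qty(qr_x, Y)                    # effects in Q-column order

  # sums of squares: per term (sequential = marginal here), residual
  ss_term <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
    rows <- which(asgn == k)
    colSums(eff[rows, , drop = FALSE]^2)
  }))
  rss <- colSums(eff[(p + 1):n, , drop = FALSE]^2)
  df_term <- vapply(seq_along(term_labels), function(k) sum(asgn == k), integer(1))

  ms_res <- rss / df_res
  Fmat <- ss_term / df_term / rep(ms_res, each = length(term_labels))
  Pmat <- stats::pf(Fmat, df_term, df_res, lower.tail = FALSE)
  # zero residual variance: perfect fit -> p = 0 where the term explains
  # variance, p = 1 where it does not; all-constant genes get p = 1 everywhere
  zero_res <- ms_res < .Machine$double.eps * 100
  if (any(zero_res)) {
    for (j in which(zero_res)) {
      has_ss <- ss_term[, j] > .Machine$double.eps * 100
      Pmat[, j] <- ifelse(has_ss, 0, 1)
      Fmat[, j] <- ifelse(has_ss, Inf, 0)
    }
  }
  term_F <- t(Fmat); term_p <- t(Pmat)
  rownames(term_F) <- rownames(term_p) <- rownames(study$exprs)
  colnames(term_F) <- colnames(term_p) <- term_labels

  # per-(genotype, tissue) condition contrast from cell means + pooled sigma^2
  gmeans <- rowsum(Y, cell) / as.vector(table(cell))   # cells x genes
  cell_n <- table(cell)
  contr_rows <- list()
  for (g in levels(fac$genotype)) for (t in levels(fac$tissue)) {
    c_str <- paste(g, stress_condition, t, sep = ".")
    c_ref <- paste(g, ref_condition, t, sep = ".")
    if (!all(c(c_str, c_ref) %in% rownames(gmeans))) next
    diff <- gmeans[c_str, ] - gmeans[c_ref, ]
    se2 <- ms_res * (1 / cell_n[[c_str]] + 1 / cell_n[[c_ref]])
    tstat <- diff / sqrt(se2)
    pval <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
    pval[ms_res < .Machine$double.eps * 100] <-
      ifelse(abs(diff[ms_res < .Machine$double.eps * 100]) >
               .Machine$double.eps * 100, 0, 1)
    ratio <- 2^diff
    fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
    contr_rows[[paste(g, t, sep = ".")]] <- data.frame(
      gene_id = rownames(study$exprs),
      contrast = paste(g, t, sep = "."),
      genotype = g, tissue = t,
      log2fc = unname(diff), fold_change = unname(fc),
      p_contrast = unname(pval),
      p_condition = unname(term_p[, "condition"]),
      stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, c(contr_rows, list(make.row.names = FALSE)))

  structure(list(term_p = term_p, term_F = term_F, contrasts = contrasts,
                 df_residual = df_res,
                 ref_condition = ref_condition,
                 stress_condition = stress_condition),
            class = "gene_anova")
}

#' @export
print.gene_anova <- function(x, ...) {
  cat(sprintf("gene_anova: %d genes, %d ANOVA terms, %d contrasts (%s vs %s)\n",
              nrow(x$term_p), ncol(x$term_p),
              length(unique(x$contrasts$contrast)),
              x$stress_condition, x$ref_condition))
  cat(sprintf("residual df: %d\n", x$df_residual))
  invisible(x)
}

#' @export
summary.gene_anova <- function(object, alpha = 0.05, ...) {
  sig <- colSums(object$term_p < alpha)
  cat(sprintf("Genes with term p < %.3g (of %d):\n", alpha, nrow(object$term_p)))
  print(sig)
  byc <- tapply(object$contrasts$p_contrast < alpha, object$contrasts$contrast, sum)
  cat(sprintf("Genes with contrast p < %.3g:\n", alpha))
  print(byc)
  invisible(list(term_significant = sig, contrast_significant = byc))
}

#' @export
coef.gene_anova <- function(object, ...) {
  # genes x contrasts matrix of log2 fold changes
  stats::xtabs(log2fc ~ gene_id + contrast, object$contrasts)
}

#' Call differentially expressed genes
#'
#' Applies the joint fold-change and p-value filter: a gene is called up in a
#' contrast iff its sign-coded linear fold change is `>= fc_threshold` and
#' its p-value is `< alpha`; down iff the fold change is `<= -fc_threshold`
#' with the same p condition. The boundary fold change exactly equal to the
#' threshold passes (an "at least" rule). The gating p-value is the
#' per-contrast condition comparison by default; set
#' `p_source = "condition_main_effect"` to gate on the condition main effect
#' instead. No multiple-testing correction is applied by default;
#' `correct = "BH"` applies Benjamini-Hochberg within each contrast before
#' thresholding.
#'
#' @param x an [expression_study()] or a fitted [fit_gene_anova()] object.
#' @param fc_threshold linear fold-change threshold (>= 1), default 1.5.
#' @param alpha p-value threshold, default 0.05.
#' @param p_source which p-value gates the call.
#' @param correct multiple-testing correction: `"none"` (default) or `"BH"`.
#' @param ... passed to [fit_gene_anova()] when `x` is an expression study.
#' @return An object of class `deg_results`: a list with `sets` (one
#'   [deg_set] per contrast x direction), `table` (the per-gene records with
#'   a `direction` column in up/down/unchanged) and the thresholds used.
#' @export
call_degs <- function(x, fc_threshold = 1.5, alpha = 0.05,
                      p_source = c("contrast", "condition_main_effect"),
                      correct = c("none", "BH"), ...) {
  if (inherits(x, "expression_study")) x <- fit_gene_anova(x, ...)
  stopifnot(inherits(x, "gene_anova"))
  if (!is.finite(fc_threshold) || fc_threshold < 1)
    .err("`fc_threshold` must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    .err("`alpha` must be in (0, 1]")
  p_source <- match.arg(p_source)
  correct <- match.arg(correct)

  tab <- x$contrasts
  tab$p <- if (p_source == "contrast") tab$p_contrast else tab$p_condition
  if (correct == "BH")
    tab$p <- stats::ave(tab$p, tab$contrast,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  tab$direction <- "unchanged"
  tab$direction[tab$fold_change >= fc_threshold & tab$p < alpha] <- "up"
  tab$direction[tab$fold_change <= -fc_threshold & tab$p < alpha] <- "down"

  sets <- list()
  for (ct in unique(tab$contrast)) for (dir in c("up", "down")) {
    ids <- tab$gene_id[tab$contrast == ct & tab$direction == dir]
    sets[[paste(ct, dir, sep = ":")]] <- deg_set(ct, dir, ids)
  }
  structure(list(sets = sets, table = tab,
                 fc_threshold = fc_threshold, alpha = alpha,
                 p_source = p_source, correct = correct),
            class = "deg_results")
}

#' A directed DEG set
#'
#' @param contrast contrast label, e.g. `"WT.shoot"`.
#' @param direction `"up"` or `"down"`.
#' @param gene_ids character vector of member gene IDs.
#' @return An object of class `deg_set`.
#' @export
deg_set <- function(contrast, direction, gene_ids) {
  direction <- match.arg(direction, c("up", "down"))
  structure(list(contrast = contrast, direction = direction,
                 gene_ids = sort(unique(as.character(gene_ids)))),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set %s:%s — %d genes\n", x$contrast, x$direction,
              length(x$gene_ids)))
  invisible(x)
}

#' @export
print.deg_results <- function(x, ...) {
  cat(sprintf("deg_results (FC >= %.2g, p < %.3g, p_source = %s)\n",
              x$fc_threshold, x$alpha, x$p_source))
  for (s in x$sets)
    cat(sprintf("  %-18s %6d genes\n",
                paste(s$contrast, s$direction, sep = ":"), length(s$gene_ids)))
  invisible(x)
}

#' Extract a DEG set from call_degs results
#'
#' @param degs a `deg_results` object.
#' @param contrast contrast label.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene IDs.
#' @export
deg_ids <- function(degs, contrast, direction = c("up", "down")) {
  stopifnot(inherits(degs, "deg_results"))
  direction <- match.arg(direction)
  key <- paste(contrast, direction, sep = ":")
  if (is.null(degs$sets[[key]]))
    .err("unknown contrast `%s`; available: %s", contrast,
         paste(unique(vapply(degs$sets, `[[`, "", "contrast")), collapse = ", "))
  degs$sets[[key]]$gene_ids
}
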