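# small balanced study used by several blocks
make_toy_study <- function(n_genes = 5, seed = 42, noise_sd = 0.5) {
  simulate_expression_study(
    synthetic_design(n_genes = n_genes, planted_deg_fraction = 0.4,
                     planted_log2fc = 1.5, noise_sd = noise_sd),
    seed = seed)$study
}

test_that("per-gene F statistics match a from-scratch sum-of-squares oracle", {
  study <- make_toy_study(n_genes = 5, seed = 7)
  fit <- fit_gene_anova(study)
  s <- study$samples
  for (g in rownames(study$exprs)) {
    o <- oracle_anova3(study$exprs[g, ], s$genotype, s$condition, s$tissue)
    expect_equal(unname(fit$term_F[g, o$term]), o$F, tolerance = 1e-8)
    expect_equal(unname(fit$term_p[g, o$term]), o$p, tolerance = 1e-8)
  }
})

test_that("the condition contrast matches an independent cell-means lm", {
  study <- make_toy_study(n_genes = 4, seed = 8)
  fit <- fit_gene_anova(study)
  s <- study$samples
  cell <- interaction(factor(s$genotype, unique(s$genotype)),
                      factor(s$condition, unique(s$condition)),
                      factor(s$tissue, unique(s$tissue)))
  for (g in rownames(study$exprs)) for (ct in c("WT.shoot", "OX.root")) {
    parts <- strsplit(ct, ".", fixed = TRUE)[[1]]
    o <- oracle_contrast(study$exprs[g, ], cell,
                         paste(parts[1], "-S", parts[2], sep = "."),
                         paste(parts[1], "nS", parts[2], sep = "."))
    row <- fit$contrasts[fit$contrasts$gene_id == g & fit$contrasts$contrast == ct, ]
    expect_equal(row$log2fc, o$estimate, tolerance = 1e-8)
    expect_equal(row$p_contrast, o$p, tolerance = 1e-8)
  }
})

test_that("a zero-variance gene yields p = 1 everywhere and fold change 1", {
  study <- make_toy_study(n_genes = 3, seed = 1)
  study$exprs[2, ] <- 8  # constant gene
  fit <- fit_gene_anova(study)
  expect_true(all(fit$term_p[2, ] == 1))
  rows <- fit$contrasts[fit$contrasts$gene_id == rownames(study$exprs)[2], ]
  expect_true(all(rows$p_contrast == 1))
  expect_true(all(rows$fold_change == 1))
})

test_that("clean two-group separation drives the contrast p to zero with fold change 4", {
  # all cells at 8 except the stressed WT/shoot cell at 10, tiny jitter
  d <- synthetic_design(n_genes = 1, planted_deg_fraction = 0, noise_sd = 1e-3)
  sim <- simulate_expression_study(d, seed = 3)
  study <- sim$study
  sel <- study$samples$genotype == "WT" & study$samples$tissue == "shoot" &
    study$samples$condition == "-S"
  study$exprs[1, ] <- 8 + rnorm(ncol(study$exprs), 0, 1e-6)
  study$exprs[1, sel] <- 10 + rnorm(sum(sel), 0, 1e-6)
  fit <- fit_gene_anova(study)
  row <- fit$contrasts[fit$contrasts$contrast == "WT.shoot", ]
  expect_lt(row$p_contrast, 1e-12)
  expect_equal(row$fold_change, 4, tolerance = 1e-4)
})

test_that("degenerate designs are rejected with the offending factor named", {
  sim <- simulate_expression_study(synthetic_design(n_genes = 5), seed = 1)
  study <- sim$study
  keep <- study$samples$tissue == "shoot"
  broken <- expression_study(study$exprs[, keep], study$samples[keep, ])
  expect_error(fit_gene_anova(broken), "tissue")
})

test_that("call_degs applies both filters jointly and honors the FC boundary", {
  study <- make_toy_study(n_genes = 6, seed = 10)
  fit <- fit_gene_anova(study)
  # doctor the contrast table to exercise the rule exactly
  tab <- fit$contrasts[fit$contrasts$contrast == "WT.shoot", ][1:4, ]
  tab$gene_id <- paste0("g", 1:4)
  tab$fold_change <- c(1.4, 3.0, 1.5, -1.5)
  tab$p_contrast <- c(1e-9, 0.2, 0.01, 0.01)
  fake <- fit
  fake$contrasts <- tab
  degs <- call_degs(fake)
  expect_false("g1" %in% deg_ids(degs, "WT.shoot", "up"))  # FC filter dominates
  expect_false("g2" %in% deg_ids(degs, "WT.shoot", "up"))  # p filter dominates
  expect_true("g3" %in% deg_ids(degs, "WT.shoot", "up"))   # boundary 1.5 passes
  expect_true("g4" %in% deg_ids(degs, "WT.shoot", "down")) # boundary -1.5 passes
})

test_that("up/down sets are disjoint and calls shrink as thresholds tighten", {
  study <- simulate_expression_study(
    synthetic_design(n_genes = 300, planted_deg_fraction = 0.2,
                     planted_log2fc = 1, noise_sd = 0.4), seed = 12)$study
  fit <- fit_gene_anova(study)
  base <- call_degs(fit, fc_threshold = 1.3, alpha = 0.10)
  for (ct in unique(base$table$contrast))
    expect_length(intersect(deg_ids(base, ct, "up"), deg_ids(base, ct, "down")), 0)
  for (params in list(c(1.5, 0.10), c(1.3, 0.05), c(2.0, 0.01))) {
    tighter <- call_degs(fit, fc_threshold = params[1], alpha = params[2])
    for (ct in unique(base$table$contrast)) for (dir in c("up", "down")) {
      expect_true(all(deg_ids(tighter, ct, dir) %in% deg_ids(base, ct, dir)),
                  label = sprintf("monotone at fc=%g alpha=%g %s:%s",
                                  params[1], params[2], ct, dir))
    }
  }
})

test_that("planted DEGs are recovered exactly in the near-noiseless limit", {
  sim <- simulate_expression_study(
    synthetic_design(n_genes = 100, planted_deg_fraction = 0.15,
                     planted_log2fc = 2, noise_sd = 1e-6), seed = 14)
  degs <- call_degs(sim$study)
  for (ct in names(sim$truth)) {
    tru <- sim$truth[[ct]]
    expect_setequal(deg_ids(degs, ct, "up"),
                    tru$gene_id[tru$direction == "up"])
    expect_setequal(deg_ids(degs, ct, "down"),
                    tru$gene_id[tru$direction == "down"])
  }
})

test_that("unknown contrasts and bad thresholds are rejected", {
  degs <- call_degs(make_toy_study(n_genes = 3, seed = 2))
  expect_error(deg_ids(degs, "WT.flower"), "available")
  fit <- fit_gene_anova(make_toy_study(n_genes = 3, seed = 2))
  expect_error(call_degs(fit, fc_threshold = 0.5), "fc_threshold")
  expect_error(call_degs(fit, alpha = 0), "alpha")
})
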