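#' Pipeline run configuration
#'
#' Collects the simulation designs and every analysis threshold used by
#' [run_pipeline()]. Defaults reproduce the study's reported thresholds:
#' fold change >= 1.5 with p < 0.05 for DEG calling, p < 0.01 for family
#' enrichment, conditioned degree >= 10 for hub selection, and a degree
#' difference of at least 9 and at least 20% for differential hubs.
#'
#' @param design a [synthetic_design()] for the expression arm.
#' @param n_net_nodes,n_net_hubs,net_hub_degree,net_background_mean
#'   parameters of [simulate_ppi_network()].
#' @param tap_n_background,tap_n_specific,tap_intensity_scale,tap_conditions,tap_tissues
#'   parameters of the TAP arm ([simulate_tap_table()] per tissue x
#'   condition).
#' @param fc_threshold,alpha DEG thresholds.
#' @param enrich_alpha family enrichment threshold.
#' @param hub_min_degree hub selection threshold.
#' @param diff_abs_min,diff_rel_min differential-hub thresholds.
#' @param min_specificity interactome call threshold.
#' @param seed master seed; per-stage seeds are small fixed offsets of it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = synthetic_design(),
                       n_net_nodes = 400L, n_net_hubs = 5L,
                       net_hub_degree = 20L, net_background_mean = 3,
                       tap_n_background = 50L, tap_n_specific = 10L,
                       tap_intensity_scale = 1e6,
                       tap_conditions = c("nS", "4d-S", "10d-S"),
                       tap_tissues = c("shoot", "root"),
                       fc_threshold = 1.5, alpha = 0.05,
                       enrich_alpha = 0.01, hub_min_degree = 10L,
                       diff_abs_min = 9L, diff_rel_min = 0.20,
                       min_specificity = 2, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(inherits(design, "synthetic_design"))
  if (fc_threshold < 1 || alpha <= 0 || alpha > 1 || enrich_alpha <= 0 ||
      enrich_alpha > 1 || diff_rel_min < 0 || min_specificity < 1)
    .err("a threshold is outside its documented range")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end-to-end: simulate the expression study, the
#' interaction network (placed over the same gene namespace) and the TAP-MS
#' tables; call DEGs by per-gene 3-way ANOVA with the fold-change/p filter;
#' Venn-partition the genotype DEG sets per tissue and direction; test
#' family overrepresentation; compute set-conditioned degrees, select hubs
#' and compare the two genotype-conditioned networks; score the TAP tables
#' and call condition-specific interactomes, Venn-partitioned across the
#' three growth conditions per tissue. Writes all stage outputs plus a
#' machine-readable `summary.json` and a `manifest.json` into `out_dir`.
#'
#' Planted-truth recovery statistics (DEG recovery and false-call rate, hub
#' recovery, TAP-specific recovery) are computed against the generators'
#' ground truth and included in the summary. Re-running with the same
#' config and seed reproduces byte-identical stage outputs and summary (the
#' manifest carries a timestamp and is exempt).
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the summary as a list.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("degnet_run_")) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  ## stage 1: simulate expression study
  sim <- simulate_expression_study(cfg$design, seed = cfg$seed)
  write_expression_study(sim$study, pth("expression.tsv"), pth("samples.tsv"))
  note("simulated %d genes x %d samples", nrow(sim$study$exprs),
       ncol(sim$study$exprs))

  ## stage 2: DEG calling
  fit <- fit_gene_anova(sim$study)
  degs <- call_degs(fit, fc_threshold = cfg$fc_threshold, alpha = cfg$alpha)
  .write_tsv(degs$table, pth("deg_table.tsv"))
  deg_sizes <- vapply(degs$sets, function(s) length(s$gene_ids), integer(1))
  note("DEG sets: %s", paste(names(deg_sizes), deg_sizes, collapse = ", "))

  # recovery against planted truth (direction-aware)
  rec <- lapply(names(sim$truth), function(ct) {
    tru <- sim$truth[[ct]]
    called_up <- deg_ids(degs, ct, "up"); called_dn <- deg_ids(degs, ct, "down")
    called <- c(called_up, called_dn)
    hit <- sum(tru$gene_id[tru$direction == "up"] %in% called_up) +
      sum(tru$gene_id[tru$direction == "down"] %in% called_dn)
    list(contrast = ct,
         n_planted = nrow(tru), n_called = length(called),
         recovery = if (nrow(tru)) hit / nrow(tru) else NA_real_,
         false_call_rate = if (length(called))
           sum(!called %in% tru$gene_id) / length(called) else 0)
  })
  names(rec) <- names(sim$truth)

  ## stage 3: Venn partition of genotype DEG sets per tissue x direction
  partitions <- list()
  gts <- cfg$design$genotypes[1:2]
  for (t in cfg$design$tissues) for (dir in c("up", "down")) {
    p <- partition_two(deg_ids(degs, paste(gts[1], t, sep = "."), dir),
                       deg_ids(degs, paste(gts[2], t, sep = "."), dir),
                       labels = gts)
    key <- paste(t, dir, sep = ".")
    partitions[[key]] <- list(
      specific_a = length(p$specific_a), specific_b = length(p$specific_b),
      common = length(p$common),
      common_percent = if (length(p$common) + length(p$specific_a) +
                           length(p$specific_b) > 0)
        common_fraction(p) else NA_real_)
    writeLines(p$common, pth(sprintf("degs_common_%s.txt", key)))
  }

  ## stage 4: family enrichment (planted family drawn from a DEG set)
  gene_ids <- rownames(sim$study$exprs)
  query <- deg_ids(degs, paste(gts[1], cfg$design$tissues[1], sep = "."), "up")
  families <- simulate_family_annotation(gene_ids, planted_from = query,
                                         seed = cfg$seed + 1L)
  write_family_gmt(families, pth("families.gmt"))
  enr <- enrich_families(query, families, universe = gene_ids,
                         alpha = cfg$enrich_alpha)
  .write_tsv(as.data.frame(enr), pth("enrichment.tsv"))
  note("enriched families at p < %g: %d", cfg$enrich_alpha, sum(enr$enriched))

  ## stage 5: interaction network + conditioned hub analysis
  n_nodes <- min(cfg$n_net_nodes, length(gene_ids))
  net <- simulate_ppi_network(n_nodes, cfg$n_net_hubs, cfg$net_hub_degree,
                              cfg$net_background_mean,
                              node_ids = gene_ids[seq_len(n_nodes)],
                              seed = cfg$seed + 2L)
  write_edge_list(net$graph, pth("network_edges.tsv"))

  deg_sets_by_gt <- lapply(gts, function(g)
    unique(c(deg_ids(degs, paste(g, cfg$design$tissues[1], sep = "."), "up"),
             deg_ids(degs, paste(g, cfg$design$tissues[1], sep = "."), "down"))))
  names(deg_sets_by_gt) <- gts
  recs <- conditioned_degrees(net$graph, deg_sets_by_gt)
  .write_tsv(as.data.frame(recs), pth("hub_records.tsv"))
  dh <- differential_hubs(recs, recs, gts[1], gts[2],
                          abs_min = cfg$diff_abs_min, rel_min = cfg$diff_rel_min)
  .write_tsv(as.data.frame(dh), pth("differential_hubs.tsv"))

  # planted-hub recovery: condition on the planted hubs' prey neighborhood
  prey <- setdiff(expand_first_neighbors(net$graph, net$hub_ids), net$hub_ids)
  hub_recs <- conditioned_degrees(net$graph, list(prey = prey))
  hubs <- select_hubs(hub_recs, "prey", min_degree = cfg$hub_min_degree)
  hub_recovery <- if (length(net$hub_ids))
    mean(net$hub_ids %in% hubs$node_id) else NA_real_
  .write_tsv(as.data.frame(hubs), pth("selected_hubs.tsv"))

  ## stage 6: TAP scoring per tissue x condition
  tap_sets <- list(); tap_recovery <- numeric(0)
  k <- 0L
  for (t in cfg$tap_tissues) {
    per_cond <- list()
    for (cond in cfg$tap_conditions) {
      k <- k + 1L
      tap <- simulate_tap_table(cfg$tap_n_background, cfg$tap_n_specific,
                                cfg$tap_intensity_scale, condition = cond,
                                tissue = t, seed = cfg$seed + 10L + k)
      write_tap_table(tap$table, pth(sprintf("tap_%s_%s.tsv", t, cond)))
      sc <- score_tap(tap$table)
      calls <- call_interactome(sc, min_specificity = cfg$min_specificity)
      ids <- calls[[paste(t, cond, sep = ".")]]
      per_cond[[cond]] <- ids
      writeLines(ids, pth(sprintf("interactome_%s_%s.txt", t, cond)))
      tap_recovery <- c(tap_recovery, if (length(tap$specific_ids))
        mean(tap$specific_ids %in% ids) else NA_real_)
    }
    tri <- partition_three(per_cond[[1]], per_cond[[2]], per_cond[[3]],
                           labels = cfg$tap_conditions)
    tap_sets[[t]] <- list(union_size = tri$union_size,
                          triple = length(tri$abc),
                          triple_percent = tri$triple_percent)
  }

  summary <- list(
    seed = cfg$seed,
    thresholds = cfg[c("fc_threshold", "alpha", "enrich_alpha",
                       "hub_min_degree", "diff_abs_min", "diff_rel_min",
                       "min_specificity")],
    deg_set_sizes = as.list(deg_sizes),
    deg_recovery = rec,
    deg_partitions = partitions,
    enrichment = list(n_enriched = sum(enr$enriched),
                      top_family = if (nrow(enr)) enr$family[1] else NA,
                      top_p = if (nrow(enr)) enr$p_value[1] else NA),
    hubs = list(n_selected = nrow(hubs),
                planted_hub_recovery = hub_recovery,
                n_differential_flagged = sum(dh$flagged)),
    tap = list(per_tissue = tap_sets,
               planted_specific_recovery = mean(tap_recovery)))
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  manifest <- list(package = "degnet",
                   version = as.character(utils::packageVersion("degnet")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "design")],
                   design = unclass(cfg$design))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, pth("run.log"))
  invisible(summary)
}
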