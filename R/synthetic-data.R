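#' Synthetic study design
#'
#' Describes the factorial layout and planted effects for
#' [simulate_expression_study()]. The default mirrors a two-genotype
#' (wild type vs overexpressor) x two-condition (sufficient vs deficient
#' sulfur) x two-tissue microarray study with three biological replicates.
#'
#' Baseline log2 expression per gene is drawn from Normal(8, 2), typical of
#' normalized array data. Planted differentially expressed genes (DEGs) are
#' shifted by +/- `planted_log2fc` in the stressed condition (the second
#' element of `conditions`) for the designated genotype and tissue; residual
#' noise is i.i.d. Gaussian with sd `noise_sd`.
#'
#' @param n_genes number of genes.
#' @param genotypes,conditions,tissues non-empty character vectors of factor
#'   levels; `conditions[1]` is the reference (control) level and
#'   `conditions[2]` the stressed level.
#' @param n_replicates biological replicates per design cell (>= 2).
#' @param planted_deg_fraction fraction of genes planted as DEGs per contrast.
#' @param planted_log2fc planted effect size in log2 units.
#' @param noise_sd residual standard deviation in log2 units (> 0).
#' @param baseline_mean,baseline_sd parameters of the per-gene baseline
#'   distribution on the log2 scale.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 1000L,
                             genotypes = c("WT", "OX"),
                             conditions = c("nS", "-S"),
                             tissues = c("shoot", "root"),
                             n_replicates = 3L,
                             planted_deg_fraction = 0.1,
                             planted_log2fc = 2,
                             noise_sd = 0.25,
                             baseline_mean = 8,
                             baseline_sd = 2) {
  n_genes <- .check_count(n_genes, "n_genes", min = 1L)
  n_replicates <- .check_count(n_replicates, "n_replicates", min = 2L)
  planted_deg_fraction <- .check_prob(planted_deg_fraction, "planted_deg_fraction")
  if (!is.finite(noise_sd) || noise_sd <= 0) .err("`noise_sd` must be > 0")
  for (nm in c("genotypes", "conditions", "tissues")) {
    v <- get(nm)
    if (!length(v) || anyDuplicated(v)) .err("`%s` must be non-empty and unique", nm)
  }
  if (length(conditions) < 2L)
    .err("`conditions` needs a reference and a stressed level")
  structure(list(n_genes = n_genes, genotypes = genotypes,
                 conditions = conditions, tissues = tissues,
                 n_replicates = n_replicates,
                 planted_deg_fraction = planted_deg_fraction,
                 planted_log2fc = planted_log2fc, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "synthetic_design")
}

#' Simulate an expression study with planted DEGs
#'
#' Generates a genes x samples log2 expression matrix under the factorial
#' design of `design`, planting `round(planted_deg_fraction * n_genes)` DEGs
#' per (genotype, tissue) contrast: each planted gene is shifted by
#' `+planted_log2fc` (up) or `-planted_log2fc` (down, sign drawn at random)
#' in the stressed condition of that genotype and tissue only.
#'
#' @param design a [synthetic_design()].
#' @param seed integer seed; all randomness flows from it.
#' @return A list with elements `study` (an [expression_study()]) and `truth`
#'   (per-contrast data.frames of planted gene IDs with their sign, plus the
#'   contrast labels), of class `planted_expression`.
#' @export
simulate_expression_study <- function(design = synthetic_design(), seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  d <- design
  cells <- expand.grid(replicate = seq_len(d$n_replicates),
                       condition = d$conditions, tissue = d$tissues,
                       genotype = d$genotypes,
                       stringsAsFactors = FALSE)
  cells <- cells[, c("genotype", "condition", "tissue", "replicate")]
  cells$sample_id <- sprintf("%s_%s_%s_r%d", cells$genotype, cells$condition,
                             cells$tissue, cells$replicate)
  cells <- cells[, c("sample_id", "genotype", "condition", "tissue", "replicate")]

  gene_ids <- sprintf("G%05d", seq_len(d$n_genes))
  baseline <- stats::rnorm(d$n_genes, d$baseline_mean, d$baseline_sd)
  mu <- matrix(baseline, nrow = d$n_genes, ncol = nrow(cells))
  dimnames(mu) <- list(gene_ids, cells$sample_id)

  stressed <- d$conditions[2]
  n_planted <- round(d$planted_deg_fraction * d$n_genes)
  truth <- list()
  for (g in d$genotypes) for (t in d$tissues) {
    contrast <- paste(g, t, sep = ".")
    if (n_planted > 0L) {
      ids <- sample(gene_ids, n_planted)
      sgn <- sample(c(1, -1), n_planted, replace = TRUE)
      cols <- cells$genotype == g & cells$tissue == t & cells$condition == stressed
      mu[ids, cols] <- mu[ids, cols] + sgn * d$planted_log2fc
      truth[[contrast]] <- data.frame(gene_id = ids,
                                      direction = ifelse(sgn > 0, "up", "down"),
                                      stringsAsFactors = FALSE)
    } else {
      truth[[contrast]] <- data.frame(gene_id = character(0),
                                      direction = character(0),
                                      stringsAsFactors = FALSE)
    }
  }

  y <- mu + matrix(stats::rnorm(length(mu), 0, d$noise_sd), nrow = nrow(mu))
  structure(list(study = expression_study(y, cells),
                 truth = truth, design = d, seed = seed),
            class = "planted_expression")
}

#' Simulate a scale-free interaction network with planted hubs
#'
#' Background topology follows a static power-law fitness model (fitness
#' proportional to rank^(-1/(exponent-1)), exponent 2.5) with the number of
#' edges chosen so that the mean background degree equals
#' `background_degree_mean`. Planted hubs then each receive edges to
#' `hub_degree` distinct uniformly sampled partners, guaranteeing degree >=
#' `hub_degree`. The result is always a simple undirected graph.
#'
#' @param n_nodes,n_hubs node counts, `n_hubs < n_nodes`.
#' @param hub_degree guaranteed minimum degree of each planted hub; must
#'   exceed `background_degree_mean` and be `< n_nodes`.
#' @param background_degree_mean mean degree of the background graph.
#' @param exponent power-law exponent of the background degree distribution.
#' @param node_ids optional character vector of length `n_nodes` supplying
#'   the node names (default `N0001`, ...), e.g. to place the network over
#'   gene identifiers.
#' @param seed integer seed.
#' @return A list of class `planted_network` with `graph` (an
#'   [igraph][igraph::graph] with character node names `N0001`, ...),
#'   `hub_ids` (planted hub node IDs) and the generating parameters.
#' @export
simulate_ppi_network <- function(n_nodes = 500L, n_hubs = 5L, hub_degree = 20L,
                                 background_degree_mean = 3, exponent = 2.5,
                                 node_ids = NULL, seed = 1L) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  n_hubs <- .check_count(n_hubs, "n_hubs", min = 0L)
  hub_degree <- .check_count(hub_degree, "hub_degree", min = 1L)
  if (n_hubs >= n_nodes) .err("`n_hubs` must be < `n_nodes`")
  if (hub_degree >= n_nodes)
    .err("infeasible degree: `hub_degree` (%d) must be < `n_nodes` (%d)",
         hub_degree, n_nodes)
  if (n_hubs > 0L && hub_degree <= background_degree_mean)
    .err("`hub_degree` must exceed `background_degree_mean`")
  set.seed(seed)
  ids <- if (is.null(node_ids)) sprintf("N%04d", seq_len(n_nodes)) else {
    node_ids <- .as_id_set(node_ids, "node_ids")
    if (length(node_ids) != n_nodes)
      .err("`node_ids` must have length n_nodes (%d)", n_nodes)
    node_ids
  }

  n_edges <- round(background_degree_mean * n_nodes / 2)
  g <- igraph::sample_fitness_pl(n_nodes, n_edges, exponent.out = exponent,
                                 loops = FALSE, multiple = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)

  hub_ids <- character(0)
  if (n_hubs > 0L) {
    hub_ids <- sample(ids, n_hubs)
    for (h in hub_ids) {
      nbrs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, h))]
      pool <- setdiff(ids, c(h, nbrs))
      add <- sample(pool, hub_degree)
      g <- igraph::add_edges(g, as.vector(rbind(h, add)))
    }
  }
  g <- igraph::simplify(g)
  structure(list(graph = g, hub_ids = sort(hub_ids),
                 n_nodes = n_nodes, n_hubs = n_hubs, hub_degree = hub_degree,
                 seed = seed),
            class = "planted_network")
}

#' Simulate a TAP-MS intensity table with planted bait-specific interactors
#'
#' Emulates a reduced MaxQuant-style protein table for one bait purification
#' against a negative (empty-tag) control, both run with one or two
#' replicates. Background proteins are detected in bait and control runs at
#' comparable intensities; planted specific interactors are detected only in
#' the bait runs. "Not detected" is encoded as `NA`, never as 0.
#'
#' @param n_background proteins present in both purifications.
#' @param n_specific planted bait-specific interactors (bait only).
#' @param bait_intensity_scale location of the log-normal intensity
#'   distribution (median intensity).
#' @param n_replicates 1 or 2 replicates per purification.
#' @param condition,tissue labels attached to every row.
#' @param seed integer seed.
#' @return A list of class `planted_tap` with `table` (a data.frame with
#'   columns `protein_id`, `mw_kda`, `bait_rep*`, `ctrl_rep*`, `condition`,
#'   `tissue`) and `specific_ids` (the planted bait-specific protein IDs).
#' @export
simulate_tap_table <- function(n_background = 50L, n_specific = 10L,
                               bait_intensity_scale = 1e6, n_replicates = 2L,
                               condition = "nS", tissue = "shoot", seed = 1L) {
  n_background <- .check_count(n_background, "n_background", min = 1L)
  n_specific <- .check_count(n_specific, "n_specific", min = 0L)
  if (!n_replicates %in% c(1L, 2L))
    .err("`n_replicates` must be 1 or 2")
  if (!is.finite(bait_intensity_scale) || bait_intensity_scale <= 0)
    .err("`bait_intensity_scale` must be > 0")
  set.seed(seed)
  n <- n_background + n_specific
  ids <- sprintf("P%04d", seq_len(n))
  specific <- if (n_specific > 0L) ids[seq_len(n_specific) + n_background] else character(0)
  mw <- round(stats::rlnorm(n, log(40), 0.5), 1)  # kDa, median ~40

  rint <- function(n) stats::rlnorm(n, log(bait_intensity_scale), 0.8)
  tab <- data.frame(protein_id = ids, mw_kda = mw, stringsAsFactors = FALSE)
  for (r in seq_len(n_replicates)) tab[[sprintf("bait_rep%d", r)]] <- rint(n)
  for (r in seq_len(n_replicates)) {
    v <- rint(n)
    v[ids %in% specific] <- NA_real_  # not detected in control
    tab[[sprintf("ctrl_rep%d", r)]] <- v
  }
  tab$condition <- condition
  tab$tissue <- tissue
  structure(list(table = tab, specific_ids = specific, seed = seed),
            class = "planted_tap")
}

#' Simulate a gene-family annotation
#'
#' Draws `n_families` families of random sizes from a gene universe and,
#' optionally, plants one family drawn predominantly from a given gene set so
#' that downstream enrichment has a known positive.
#'
#' @param universe character vector of gene IDs.
#' @param n_families number of random background families.
#' @param mean_size mean family size (sizes are Poisson-distributed, min 2).
#' @param planted_from optional gene set; when given, a family named
#'   `"planted_family"` of size `planted_size` is drawn from it (topped up
#'   from the universe if the set is smaller).
#' @param planted_size size of the planted family.
#' @param seed integer seed.
#' @return A named list of character vectors (family -> member gene IDs),
#'   usable as the annotation of [enrich_families()].
#' @export
simulate_family_annotation <- function(universe, n_families = 20L,
                                       mean_size = 30, planted_from = NULL,
                                       planted_size = 25L, seed = 1L) {
  universe <- .as_id_set(universe, "universe")
  n_families <- .check_count(n_families, "n_families", min = 0L)
  set.seed(seed)
  fam <- list()
  if (n_families > 0L) {
    sizes <- pmax(2L, stats::rpois(n_families, mean_size))
    sizes <- pmin(sizes, length(universe))
    fam <- lapply(sizes, function(s) sample(universe, s))
    names(fam) <- sprintf("family_%02d", seq_len(n_families))
  }
  if (!is.null(planted_from)) {
    planted_from <- intersect(.as_id_set(planted_from, "planted_from"), universe)
    k <- min(planted_size, length(planted_from))
    members <- sample(planted_from, k)
    if (k < planted_size)
      members <- c(members, sample(setdiff(universe, members), planted_size - k))
    fam$planted_family <- members
  }
  fam
}

#' Writers for synthetic pipeline inputs
#'
#' `write_edge_list()` writes a two-column TSV of interactor IDs;
#' `write_tap_table()` writes the intensity table with `NA` rendered as the
#' explicit marker `ND` (not detected); `write_family_gmt()` writes a GMT-like
#' file (family, description, members, tab-separated); `write_truth_json()`
#' serializes planted truth to JSON.
#'
#' @param graph an igraph object with named vertices.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  .write_tsv(data.frame(interactor_a = el[, 1], interactor_b = el[, 2],
                        stringsAsFactors = FALSE), path)
}

#' @rdname write_edge_list
#' @param tap_table data.frame as produced by [simulate_tap_table()].
#' @export
write_tap_table <- function(tap_table, path) {
  out <- tap_table
  for (j in grep("^(bait|ctrl)_rep", names(out)))
    out[[j]] <- ifelse(is.na(out[[j]]), "ND", format(out[[j]], digits = 15))
  .write_tsv(out, path)
}

#' @rdname write_edge_list
#' @param families named list of character vectors.
#' @export
write_family_gmt <- function(families, path) {
  lines <- vapply(names(families), function(nm)
    paste(c(nm, "synthetic", families[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param truth a list (e.g. planted truth fields) to serialize.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a GMT-like family annotation file
#'
#' Each line: family name, description, then member gene IDs, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_family_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) .err("malformed GMT line: %s", substr(ln, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Read a TAP intensity table written by [write_tap_table()]
#'
#' The `ND` marker (and empty fields) in intensity columns become `NA`.
#'
#' @param path file path.
#' @return data.frame with numeric intensity columns.
#' @export
read_tap_table <- function(path) {
  tab <- .read_tsv(path)
  for (j in grep("^(bait|ctrl)_rep", names(tab))) {
    v <- as.character(tab[[j]])
    v[v %in% c("ND", "")] <- NA
    tab[[j]] <- as.numeric(v)
  }
  tab
}
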