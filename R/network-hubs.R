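#' Read an interaction edge list
#'
#' Reads a tab-separated file whose first two columns (configurable) hold
#' interactor identifiers, one undirected interaction per line; extra columns
#' (as in BioGRID TAB exports) are ignored. Self-loops are dropped and
#' duplicate unordered pairs collapsed, each with a message reporting the
#' count. Evidence multiplicity is flattened: one edge per unordered pair.
#'
#' @param path file path.
#' @param columns integer length-2: which columns hold the two interactor IDs.
#' @param header does the file start with a header line?
#' @return A simple undirected [igraph][igraph::graph] with named vertices.
#' @export
read_edge_list <- function(path, columns = c(1L, 2L), header = TRUE) {
  if (file.exists(path) && file.size(path) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  tab <- tryCatch(
    utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) .err("cannot read edge list %s: %s", path, conditionMessage(e)))
  if (nrow(tab) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  if (ncol(tab) < max(columns))
    .err("edge list %s has %d column(s); need column(s) %s",
         path, ncol(tab), paste(columns, collapse = ", "))
  a <- trimws(as.character(tab[[columns[1]]]))
  b <- trimws(as.character(tab[[columns[2]]]))
  bad <- which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))
  if (length(bad))
    .err("malformed edge at line %d of %s", bad[1] + as.integer(header), path)
  edges_to_graph(a, b)
}

#' Build a simple undirected graph from two ID vectors
#'
#' @param a,b character vectors of equal length: the interacting pairs.
#' @return A simple undirected igraph; self-loops and duplicate unordered
#'   pairs are removed (counts reported via message).
#' @export
edges_to_graph <- function(a, b) {
  stopifnot(length(a) == length(b))
  loops <- a == b
  if (any(loops))
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
  a2 <- a[!loops]; b2 <- b[!loops]
  key <- paste(pmin(a2, b2), pmax(a2, b2), sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]), directed = FALSE)
  g
}

#' Set-conditioned node degrees
#'
#' For every node of an interaction network, counts its total number of
#' interaction partners (`degree_total`) and, for each labeled query set,
#' how many of those partners belong to the set (`degree_<label>`). This is
#' the conditioning step behind transcriptomic-hub scatter plots
#' (degree-in-set vs total degree) and differential-hub comparison.
#'
#' Set members absent from the network contribute nothing. IDs listed in
#' `exclude` (typically the bait protein, which trivially touches every
#' prey) are removed from every query set before counting; the nodes
#' themselves stay in the network.
#'
#' @param net an undirected igraph with named vertices.
#' @param sets named list of character vectors (label -> member IDs).
#' @param exclude character vector of IDs removed from every set.
#' @return A data.frame of class `hub_records`: `node_id`, `degree_total`,
#'   then one `degree_<label>` column per set.
#' @export
conditioned_degrees <- function(net, sets, exclude = character(0)) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::any_multiple(net) || any(igraph::which_loop(net)))
    .err("network must be a simple graph; use edges_to_graph()/read_edge_list()")
  if (!length(sets) || is.null(names(sets))) .err("`sets` must be a named list")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) .err("network vertices must be named")
  adj <- igraph::as_adj_list(net, mode = "all")
  nbr_names <- lapply(adj, function(v) nodes[as.integer(v)])
  out <- data.frame(node_id = nodes,
                    degree_total = lengths(nbr_names),
                    stringsAsFactors = FALSE)
  for (lab in names(sets)) {
    members <- setdiff(.as_id_set(sets[[lab]], lab), exclude)
    out[[paste0("degree_", lab)]] <-
      vapply(nbr_names, function(nb) sum(nb %in% members), integer(1))
  }
  rownames(out) <- NULL
  stopifnot(all(vapply(names(sets), function(lab)
    all(out[[paste0("degree_", lab)]] <= out$degree_total), logical(1))))
  class(out) <- c("hub_records", "data.frame")
  out
}

#' Select hubs by degree-within-set
#'
#' Nodes whose conditioned degree for `set_label` is at least `min_degree`
#' (the boundary value is included: "equal or higher") are selected and
#' ranked by that degree descending, ties broken by node ID ascending. A
#' `tier` column annotates a secondary tier at `annotate_degree` (default 3)
#' for plot labeling.
#'
#' @param records a [conditioned_degrees()] result.
#' @param set_label which set's conditioned degree to rank on.
#' @param min_degree selection threshold (>= 1), default 10.
#' @param annotate_degree secondary-tier threshold, default 3.
#' @return The selected rows, ranked, with columns `rank` and `tier`
#'   (`"hub"` at `min_degree`, `"annotated"` at `annotate_degree`).
#' @export
select_hubs <- function(records, set_label, min_degree = 10L,
                        annotate_degree = 3L) {
  min_degree <- .check_count(min_degree, "min_degree", min = 1L)
  col <- paste0("degree_", set_label)
  if (!col %in% names(records))
    .err("unknown set label `%s`; available: %s", set_label,
         paste(sub("^degree_", "", setdiff(grep("^degree_", names(records),
                                                value = TRUE), "degree_total")),
               collapse = ", "))
  d <- records[[col]]
  sel <- records[d >= min_degree, , drop = FALSE]
  sel <- sel[order(-sel[[col]], sel$node_id), , drop = FALSE]
  if (nrow(sel)) sel$rank <- seq_len(nrow(sel)) else sel$rank <- integer(0)
  sel$tier <- "hub"
  rownames(sel) <- NULL
  attr(sel, "annotated") <- records$node_id[d >= annotate_degree & d < min_degree]
  sel
}

#' Differential hub comparison between two conditioned networks
#'
#' For every node present in either record table, compares its conditioned
#' degree under two query sets (e.g. DEGs of two genotypes): the absolute
#' difference `|d1 - d2|` and the relative difference
#' `|d1 - d2| / denom(d1, d2)` (0 when both degrees are 0). A node is
#' flagged as a differential hub iff the absolute difference is at least
#' `abs_min` AND the relative difference is at least `rel_min`.
#'
#' The relative-difference denominator defaults to `max(d1, d2)` — the
#' symmetric, conservative reading of "in relation to each other" — and can
#' be switched to `min` or `mean`.
#'
#' @param records1,records2 two [conditioned_degrees()] results over the
#'   same network.
#' @param set_label1,set_label2 the set label to compare in each table
#'   (`set_label2` defaults to `set_label1`).
#' @param abs_min minimum absolute degree difference, default 9.
#' @param rel_min minimum relative difference, default 0.20.
#' @param rel_denominator `"max"` (default), `"min"` or `"mean"`.
#' @return A data.frame of class `differential_hubs`: `node_id`, `d1`, `d2`,
#'   `abs_diff`, `rel_diff`, `flagged`, `direction`
#'   (`higher-in-1`/`higher-in-2`/`equal`), sorted by `abs_diff` descending
#'   among flagged nodes first.
#' @export
differential_hubs <- function(records1, records2, set_label1, set_label2 = set_label1,
                              abs_min = 9L, rel_min = 0.20,
                              rel_denominator = c("max", "min", "mean")) {
  rel_denominator <- match.arg(rel_denominator)
  abs_min <- .check_count(abs_min, "abs_min", min = 0L)
  if (!is.finite(rel_min) || rel_min < 0) .err("`rel_min` must be >= 0")
  c1 <- paste0("degree_", set_label1); c2 <- paste0("degree_", set_label2)
  if (!c1 %in% names(records1)) .err("records1 lacks set label `%s`", set_label1)
  if (!c2 %in% names(records2)) .err("records2 lacks set label `%s`", set_label2)

  nodes <- union(records1$node_id, records2$node_id)
  d1 <- records1[[c1]][match(nodes, records1$node_id)]
  d2 <- records2[[c2]][match(nodes, records2$node_id)]
  d1[is.na(d1)] <- 0L; d2[is.na(d2)] <- 0L
  abs_diff <- abs(d1 - d2)
  denom <- switch(rel_denominator,
                  max = pmax(d1, d2), min = pmin(d1, d2), mean = (d1 + d2) / 2)
  rel_diff <- ifelse(denom > 0, abs_diff / denom, 0)
  out <- data.frame(node_id = nodes, d1 = d1, d2 = d2,
                    abs_diff = abs_diff, rel_diff = rel_diff,
                    flagged = abs_diff >= abs_min & rel_diff >= rel_min,
                    direction = ifelse(d1 > d2, "higher-in-1",
                                       ifelse(d2 > d1, "higher-in-2", "equal")),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$flagged, -out$abs_diff, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_hubs", "data.frame")
  out
}

#' First-neighbor expansion of a seed set
#'
#' Returns the seeds together with every node adjacent to a seed in the
#' network. Seeds absent from the network pass through unchanged (they have
#' no neighbors to add).
#'
#' @param net an undirected igraph with named vertices.
#' @param seeds character vector of seed IDs.
#' @return Sorted character vector: seeds plus all their first neighbors.
#' @export
expand_first_neighbors <- function(net, seeds) {
  seeds <- .as_id_set(seeds, "seeds")
  if (!length(seeds)) return(character(0))
  nodes <- igraph::V(net)$name
  present <- intersect(seeds, nodes)
  nbrs <- if (length(present)) {
    idx <- unlist(igraph::adjacent_vertices(net, present), use.names = FALSE)
    nodes[unique(as.integer(idx))]
  } else character(0)
  sort(union(seeds, nbrs))
}

#' Scatter data for hub plots
#'
#' Returns (and optionally draws) the degree-in-set vs total-degree scatter
#' behind hub identification figures.
#'
#' @param records a [conditioned_degrees()] result.
#' @param set_label which conditioned degree to plot.
#' @param plot draw a base-graphics scatter?
#' @return Invisibly, a data.frame `node_id`, `degree_total`,
#'   `degree_in_set`.
#' @export
hub_scatter <- function(records, set_label, plot = interactive()) {
  col <- paste0("degree_", set_label)
  if (!col %in% names(records)) .err("unknown set label `%s`", set_label)
  df <- data.frame(node_id = records$node_id,
                   degree_total = records$degree_total,
                   degree_in_set = records[[col]],
                   stringsAsFactors = FALSE)
  if (plot) {
    plot(df$degree_total, df$degree_in_set,
         xlab = "degree (total)", ylab = sprintf("degree (%s)", set_label),
         pch = 19, col = "#00000088")
  }
  invisible(df)
}
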