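test_that("edge lists read with deduplication and self-loop removal", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "edges.tsv")
  writeLines(c("interactor_a\tinteractor_b", "a\tb", "b\ta", "a\ta"), f)
  expect_message(expect_message(g <- read_edge_list(f), "self-loop"),
                 "duplicate")
  expect_identical(igraph::ecount(g), 1)
  el <- igraph::as_edgelist(g)
  expect_setequal(as.vector(el), c("a", "b"))

  # empty file -> empty network
  f0 <- file.path(dir, "empty.tsv")
  file.create(f0)
  expect_identical(igraph::vcount(read_edge_list(f0)), 0)

  # malformed line reported with its number
  f2 <- file.path(dir, "bad.tsv")
  writeLines(c("interactor_a\tinteractor_b", "a\tb", "c\t"), f2)
  expect_error(read_edge_list(f2), "line 3")
})

test_that("conditioned degrees satisfy the star-graph and saturation identities", {
  g <- edges_to_graph(rep("c", 5), paste0("x", 1:5))
  rec <- conditioned_degrees(g, list(q = c("x1", "x2")))
  crow <- rec[rec$node_id == "c", ]
  expect_identical(crow$degree_total, 5L)
  expect_identical(crow$degree_q, 2L)
  # set = all nodes -> degree_in_set == degree_total everywhere
  recAll <- conditioned_degrees(g, list(all = rec$node_id))
  expect_identical(recAll$degree_all, recAll$degree_total)
})

test_that("conditioned degrees match an exhaustive edge scan on random graphs", {
  set.seed(303)
  for (i in 1:8) {
    net <- simulate_ppi_network(n_nodes = 80, n_hubs = 2, hub_degree = 12,
                                background_degree_mean = 3, seed = 300 + i)
    g <- net$graph
    members <- sample(igraph::V(g)$name, 25)
    rec <- conditioned_degrees(g, list(q = members))
    o <- oracle_conditioned_degrees(igraph::as_edgelist(g),
                                    igraph::V(g)$name, members)
    o <- o[match(rec$node_id, o$node_id), ]
    expect_identical(rec$degree_total, o$degree_total)
    expect_identical(rec$degree_q, o$degree_in_set)
    # invariants: bounded by total degree; handshake lemma
    expect_true(all(rec$degree_q <= rec$degree_total))
    expect_identical(sum(rec$degree_total), 2L * nrow(igraph::as_edgelist(g)))
  }
})

test_that("excluded IDs (e.g. the bait) do not count as set partners", {
  g <- edges_to_graph(c("bait", "bait", "p1"), c("p1", "p2", "p2"))
  with_bait <- conditioned_degrees(g, list(q = c("bait", "p1", "p2")))
  no_bait <- conditioned_degrees(g, list(q = c("bait", "p1", "p2")),
                                 exclude = "bait")
  expect_identical(with_bait$degree_q[with_bait$node_id == "p1"], 2L)
  expect_identical(no_bait$degree_q[no_bait$node_id == "p1"], 1L)
})

test_that("hub selection is inclusive at the threshold and ranks deterministically", {
  rec <- structure(
    data.frame(node_id = c("A", "B", "C", "D", "E"),
               degree_total = c(80, 30, 12, 15, 10),
               degree_q = c(59L, 24L, 9L, 10L, 10L),
               stringsAsFactors = FALSE),
    class = c("hub_records", "data.frame"))
  sel <- select_hubs(rec, "q", min_degree = 10)
  expect_identical(sel$node_id, c("A", "B", "D", "E"))  # 9 excluded, ties by ID
  expect_identical(sel$rank, 1:4)
  expect_identical(attr(sel, "annotated"), "C")  # secondary tier at >= 3
  expect_error(select_hubs(rec, "nope"), "unknown set label")
  # single node exactly at the boundary is kept
  sel10 <- select_hubs(rec[4, ], "q", min_degree = 10)
  expect_identical(sel10$node_id, "D")
})

test_that("planted hubs are fully recovered from their prey neighborhood", {
  net <- simulate_ppi_network(n_nodes = 200, n_hubs = 4, hub_degree = 20,
                              background_degree_mean = 3, seed = 99)
  prey <- setdiff(expand_first_neighbors(net$graph, net$hub_ids), net$hub_ids)
  rec <- conditioned_degrees(net$graph, list(prey = prey))
  sel <- select_hubs(rec, "prey", min_degree = 10)
  expect_true(all(net$hub_ids %in% sel$node_id))
  # planted hubs rank at the top
  expect_true(all(match(net$hub_ids, sel$node_id) <= 4 + 2))
})

test_that("differential hub rule applies both thresholds and is antisymmetric", {
  mk <- function(ids, d) structure(
    data.frame(node_id = ids, degree_total = d + 50L, degree_q = as.integer(d),
               stringsAsFactors = FALSE),
    class = c("hub_records", "data.frame"))
  r1 <- mk(c("n1", "n2", "n3"), c(20, 50, 100))
  r2 <- mk(c("n1", "n2", "n3"), c(10, 42, 85))
  dh <- differential_hubs(r1, r2, "q", abs_min = 9, rel_min = 0.20)
  expect_identical(dh$flagged[match(c("n1", "n2", "n3"), dh$node_id)],
                   c(TRUE, FALSE, FALSE))  # (20,10) yes; (50,42) |d|<9; (100,85) rel<20%
  expect_identical(dh$direction[dh$node_id == "n1"], "higher-in-1")

  swapped <- differential_hubs(r2, r1, "q", abs_min = 9, rel_min = 0.20)
  expect_setequal(dh$node_id[dh$flagged], swapped$node_id[swapped$flagged])
  expect_identical(swapped$direction[swapped$node_id == "n1"], "higher-in-2")
  # both zero -> rel_diff defined as 0, never flagged
  r0a <- mk("z", 0); r0b <- mk("z", 0)
  d0 <- differential_hubs(r0a, r0b, "q")
  expect_identical(d0$rel_diff, 0)
  expect_false(d0$flagged)
})

test_that("first-neighbor expansion equals the union of adjacency lists", {
  g <- edges_to_graph(c("a", "b"), c("b", "c"))  # path a-b-c
  expect_identical(expand_first_neighbors(g, "a"), c("a", "b"))
  expect_identical(expand_first_neighbors(g, character(0)), character(0))
  # seeds not in the network pass through unchanged
  expect_identical(expand_first_neighbors(g, "ghost"), "ghost")

  set.seed(404)
  net <- simulate_ppi_network(n_nodes = 70, n_hubs = 2, hub_degree = 10, seed = 8)
  g <- net$graph
  for (i in 1:5) {
    seeds <- sample(igraph::V(g)$name, 6)
    got <- expand_first_neighbors(g, seeds)
    el <- igraph::as_edgelist(g)
    want <- seeds
    for (j in seq_len(nrow(el))) {
      if (el[j, 1] %in% seeds) want <- c(want, el[j, 2])
      if (el[j, 2] %in% seeds) want <- c(want, el[j, 1])
    }
    expect_setequal(got, unique(want))
  }
})
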