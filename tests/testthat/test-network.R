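path_graph <- function(...) {
  nodes <- c(...)
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
    directed = FALSE, vertices = nodes)
}

test_that("merged graph is the induced subgraph with correct roles", {
  ppi <- path_graph("A", "B", "C")
  g <- build_merged_graph(ppi, mutated = "A", degs = "C")
  expect_setequal(igraph::V(g)$name, c("A", "C"))
  expect_equal(igraph::ecount(g), 0)  # B excluded, so the path is broken

  g2 <- build_merged_graph(ppi, mutated = c("A", "B"), degs = c("B", "C"))
  roles <- stats::setNames(igraph::V(g2)$role, igraph::V(g2)$name)
  expect_identical(roles[["B"]], "BOTH")
  expect_identical(roles[["A"]], "MUTATED")
  expect_identical(roles[["C"]], "DEG")
  expect_equal(igraph::ecount(g2), 2)

  expect_message(build_merged_graph(ppi, mutated = c("A", "ZZZ"), degs = "C"),
                 "dropped 1 mutated")
  expect_error(build_merged_graph(ppi, mutated = "X", degs = "Y"), "no mutated")
})

test_that("every merged edge exists in the PPI and joins two kept nodes", {
  set.seed(31)
  for (rep in 1:10) {
    ppi <- generate_ppi(30, attach_m = 2, seed = rep)
    keep_mut <- sample(igraph::V(ppi)$name, 8)
    keep_deg <- sample(igraph::V(ppi)$name, 8)
    g <- build_merged_graph(ppi, keep_mut, keep_deg)
    kept <- union(keep_mut, keep_deg)
    el <- igraph::as_edgelist(g)
    for (r in seq_len(nrow(el))) {
      expect_true(all(el[r, ] %in% kept))
      expect_true(igraph::are_adjacent(ppi, el[r, 1], el[r, 2]))
    }
    # and no induced edge is missing
    ppi_el <- igraph::as_edgelist(ppi)
    both_kept <- ppi_el[ppi_el[, 1] %in% kept & ppi_el[, 2] %in% kept, , drop = FALSE]
    expect_equal(igraph::ecount(g), nrow(both_kept))
  }
})

test_that("semi-local extraction stops at two hops and equals BFS depth 2", {
  g <- build_merged_graph(path_graph("v", "a", "b", "c"),
                          mutated = "v", degs = c("a", "b", "c"))
  net <- extract_semilocal(g, "v")
  expect_setequal(igraph::V(net)$name, c("v", "a", "b"))  # c is 3 hops away
  expect_identical(igraph::graph_attr(net, "source"), "v")

  iso <- build_merged_graph(
    igraph::make_empty_graph(directed = FALSE) + igraph::vertices(c("v", "w")),
    mutated = "v", degs = "w")
  net_iso <- extract_semilocal(iso, "v")
  expect_identical(igraph::V(net_iso)$name, "v")

  expect_error(extract_semilocal(g, "a"), "not mutated")

  set.seed(32)
  for (rep in 1:10) {
    ra <- random_attributed_graph(12)
    v <- sample(names(ra$roles)[ra$roles != "DEG"], 1)
    net <- extract_semilocal(ra$graph, v)
    bfs_nodes <- names(ra$roles)[as.numeric(
      igraph::distances(ra$graph, v = v)) <= 2]
    expect_setequal(igraph::V(net)$name, bfs_nodes)
  }
})

test_that("the two-node mutated-DEG chain scores exactly 2", {
  # v(mutated) -- u(DEG): score(v) = deg(v) + b(u); b(u) = c(v) = deg(u) = 1
  g <- build_merged_graph(path_graph("v", "u"), mutated = "v", degs = "u")
  net <- extract_semilocal(g, "v")
  m <- new_mutation_matrix(matrix(1L, 1, 1, dimnames = list("v", "p1")))
  sc <- mutation_scores(m)
  expect_equal(score_gene(net, sc, m), 2)
})

test_that("isolated sources score zero", {
  g <- build_merged_graph(
    igraph::make_empty_graph(directed = FALSE) + igraph::vertices("v"),
    mutated = "v", degs = character(0))
  net <- extract_semilocal(g, "v")
  m <- new_mutation_matrix(matrix(1L, 1, 1, dimnames = list("v", "p1")))
  expect_equal(score_gene(net, mutation_scores(m), m), 0)
})

test_that("score_gene matches the brute-force oracle on random attributed graphs", {
  set.seed(33)
  for (rep in 1:30) {
    ra <- random_attributed_graph(sample(6:12, 1))
    sources <- names(ra$roles)[ra$roles != "DEG"]
    v <- sample(sources, 1)
    net <- extract_semilocal(ra$graph, v)
    keep <- igraph::V(net)$name
    A <- ra$A[keep, keep, drop = FALSE]
    for (mode in c("gravity", "literal")) {
      for (cv in c("literal", "nw")) {
        got <- score_gene(net, ra$scores, ra$m, mif_mode = mode, c_variant = cv)
        want <- naive_score_gene(A, ra$roles[keep], v, ra$scores, ra$m,
                                 mif_mode = mode, c_variant = cv)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("two-hop neighbor counting agrees with the oracle too", {
  set.seed(34)
  for (rep in 1:10) {
    ra <- random_attributed_graph(10)
    v <- sample(names(ra$roles)[ra$roles != "DEG"], 1)
    net <- extract_semilocal(ra$graph, v)
    keep <- igraph::V(net)$name
    got <- score_gene(net, ra$scores, ra$m, neighbor_count = "two_hop")
    want <- naive_score_gene(ra$A[keep, keep, drop = FALSE], ra$roles[keep], v,
                             ra$scores, ra$m, neighbor_count = "two_hop")
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("scores are nonnegative and at least the in-network degree", {
  set.seed(35)
  for (rep in 1:15) {
    ra <- random_attributed_graph(10)
    for (v in names(ra$roles)[ra$roles != "DEG"]) {
      net <- extract_semilocal(ra$graph, v)
      s <- score_gene(net, ra$scores, ra$m)
      expect_gte(s, igraph::degree(net, v))
    }
  }
})

test_that("attaching a DEG neighbor to the source never decreases its score", {
  set.seed(36)
  for (rep in 1:10) {
    ra <- random_attributed_graph(8)
    v <- sample(names(ra$roles)[ra$roles != "DEG"], 1)
    s0 <- score_gene(extract_semilocal(ra$graph, v), ra$scores, ra$m)
    g2 <- igraph::add_vertices(ra$graph, 1, name = "new_deg", role = "DEG")
    g2 <- igraph::add_edges(g2, c(v, "new_deg"))
    s1 <- score_gene(extract_semilocal(g2, v), ra$scores, ra$m)
    expect_gte(s1, s0)
  }
})

test_that("rankings are sorted, complete, deterministic, and break ties alphabetically", {
  set.seed(37)
  ra <- random_attributed_graph(12)
  r1 <- rank_drivers(ra$graph, ra$scores, ra$m)
  r2 <- rank_drivers(ra$graph, ra$scores, ra$m)
  expect_identical(r1, r2)
  expect_setequal(r1$gene, names(ra$roles)[ra$roles != "DEG"])
  expect_true(all(diff(r1$score) <= 1e-12))
  expect_identical(r1$rank, seq_len(nrow(r1)))

  # two isolated mutated nodes: equal score (0) and equal M -> alphabetical
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("zeta", "alpha"))
  gm <- build_merged_graph(g, mutated = c("zeta", "alpha"), degs = character(0))
  m <- new_mutation_matrix(matrix(c(1L, 1L), 2, 1,
                                  dimnames = list(c("zeta", "alpha"), "p1")))
  r <- rank_drivers(gm, mutation_scores(m), m)
  expect_identical(r$gene, c("alpha", "zeta"))
})

test_that("a mutated hub wired to many DEGs outranks a degree-one mutated gene", {
  # star: hub -- d1..d6 (DEGs), plus leaf -- d1
  edges <- data.frame(from = c(rep("hub", 6), "leaf"),
                      to = c(paste0("d", 1:6), "d1"))
  ppi <- igraph::graph_from_data_frame(edges, directed = FALSE)
  m <- new_mutation_matrix(matrix(c(1L, 0L, 0L, 1L), 2, 2,
                                  dimnames = list(c("hub", "leaf"), c("p1", "p2"))))
  g <- build_merged_graph(ppi, mutated = c("hub", "leaf"), degs = paste0("d", 1:6))
  r <- rank_drivers(g, mutation_scores(m), m)
  expect_identical(r$gene[1], "hub")
  expect_gt(r$score[1], r$score[r$gene == "leaf"])
})
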