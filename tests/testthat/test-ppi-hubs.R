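test_that("edge-table loading scales, filters inclusively and simplifies", {
  rows <- data.frame(protein1 = c("A", "B", "C"),
                     protein2 = c("B", "C", "D"),
                     combined_score = c(350, 400, 900))
  g <- load_interaction_table(rows, 0.400)
  expect_equal(igraph::ecount(g), 2)  # 400 retained at the boundary

  rev2 <- data.frame(protein1 = c("A", "B"), protein2 = c("B", "A"),
                     combined_score = c(500, 700))
  g2 <- load_interaction_table(rev2)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$confidence, 0.7)  # max of duplicates

  loop <- data.frame(protein1 = "A", protein2 = "A", combined_score = 900)
  g3 <- load_interaction_table(loop, keep_nodes = "A")
  expect_equal(igraph::ecount(g3), 0)
  expect_equal(igraph::vcount(g3), 1)

  frac <- data.frame(protein1 = "A", protein2 = "B", combined_score = 0.9)
  expect_equal(igraph::E(load_interaction_table(frac))$confidence, 0.9)
  bad <- data.frame(protein1 = "A", protein2 = "B", combined_score = -5)
  expect_error(load_interaction_table(bad), "negative")
})

test_that("network statistics match hand-computed small graphs", {
  tri <- graph_from_pairs(c("A", "B"), c("B", "C"), c("A", "C"))
  st <- network_stats(tri)
  expect_equal(st$avg_neighbors, 2)
  expect_equal(st$diameter, 1)
  expect_equal(st$radius, 1)

  path <- graph_from_pairs(c("A", "B"), c("B", "C"))
  sp <- network_stats(path)
  expect_equal(sp$avg_neighbors, 1.333)
  expect_equal(sp$diameter, 2)
  expect_equal(sp$radius, 1)

  # disconnected: diameter/radius from the largest component
  disc <- graph_from_pairs(c("A", "B"), c("B", "C"), isolated = "Z")
  expect_equal(network_stats(disc)$diameter, 2)
  expect_error(network_stats(igraph::make_empty_graph(0)), "empty")
})

test_that("per-node scores match their definitions on canonical graphs", {
  tri <- graph_from_pairs(c("A", "B"), c("B", "C"), c("A", "C"))
  expect_equal(degree_score(tri, "A"), 2)
  expect_equal(mnc_score(tri, "A"), 2)
  expect_equal(mcc_score(tri, "A"), 2)  # (3-1)!

  k4 <- graph_from_pairs(c("A", "B"), c("A", "C"), c("A", "D"),
                         c("B", "C"), c("B", "D"), c("C", "D"))
  expect_equal(mcc_score(k4, "A"), 6)  # (4-1)!

  star <- graph_from_pairs(c("S", "L1"), c("S", "L2"), c("S", "L3"),
                           c("S", "L4"))
  expect_equal(degree_score(star, "S"), 4)
  expect_equal(mnc_score(star, "S"), 1)
  expect_equal(mcc_score(star, "S"), 4)  # four 2-cliques, 1! each

  iso <- graph_from_pairs(c("A", "B"), isolated = "Z")
  expect_equal(degree_score(iso, "Z"), 0)
  expect_equal(mnc_score(iso, "Z"), 0)
  expect_equal(mcc_score(iso, "Z"), 1)  # singleton maximal clique, 0!
  expect_error(degree_score(iso, "QQ"), "unknown node")
})

test_that("maximal clique enumeration is exact and relabel-invariant", {
  k3 <- graph_from_pairs(c("A", "B"), c("B", "C"), c("A", "C"))
  expect_identical(enumerate_maximal_cliques(k3), list(c("A", "B", "C")))

  path <- graph_from_pairs(c("A", "B"), c("B", "C"))
  expect_identical(enumerate_maximal_cliques(path),
                   list(c("A", "B"), c("B", "C")))

  edgeless <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(edgeless)$name <- c("W", "X", "Y", "Z")
  expect_identical(enumerate_maximal_cliques(edgeless),
                   list("W", "X", "Y", "Z"))

  # relabeling permutes the same clique structure
  set.seed(11)
  A <- rand_adj(8, 0.4)
  perm <- sample(8)
  B <- A[perm, perm]
  cl_a <- enumerate_maximal_cliques(adj_to_graph(A))
  cl_b <- enumerate_maximal_cliques(adj_to_graph(B))
  expect_setequal(vapply(cl_a, paste, "", collapse = "+"),
                  vapply(cl_b, paste, "", collapse = "+"))
})

test_that("scores agree with exhaustive brute-force oracles", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    A <- rand_adj(n, runif(1, 0.2, 0.7))
    g <- adj_to_graph(A)
    expect_setequal(
      vapply(enumerate_maximal_cliques(g), paste, "", collapse = "+"),
      vapply(oracle_maximal_cliques(A), paste, "", collapse = "+"))
    for (v in rownames(A)) {
      expect_equal(degree_score(g, v), sum(A[v, ]))
      expect_equal(mnc_score(g, v), oracle_mnc(A, v))
      expect_equal(mcc_score(g, v), oracle_mcc(A, v))
    }
  }
})

test_that("rankings are deterministic with lexicographic ties", {
  k4 <- graph_from_pairs(c("D", "B"), c("D", "C"), c("D", "A"),
                         c("B", "C"), c("B", "A"), c("C", "A"))
  r <- rank_nodes(k4, "Degree", k = 4)
  expect_identical(r$gene, c("A", "B", "C", "D"))  # all tied at 3
  expect_true(all(diff(r$score) <= 0))

  star <- graph_from_pairs(c("S", "A"), c("S", "B"))
  expect_identical(rank_nodes(star, "MCC", k = 1)$gene, "S")
  expect_warning(rank_nodes(star, "Degree", k = 10), "exceeds")
})

test_that("consensus intersects top-k slices", {
  r1 <- data.frame(rank = 1:3, gene = c("A", "B", "C"), score = 3:1)
  r2 <- data.frame(rank = 1:3, gene = c("C", "B", "A"), score = 3:1)
  r3 <- data.frame(rank = 1:3, gene = c("X", "Y", "Z"), score = 3:1)
  expect_identical(consensus_top(list(r1, r1), 3), c("A", "B", "C"))
  expect_identical(consensus_top(list(r1, r2), 3), c("A", "B", "C"))
  expect_identical(consensus_top(list(r1, r3), 3), character(0))
  expect_identical(consensus_top(list(r1, r2), 1), character(0))
})
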