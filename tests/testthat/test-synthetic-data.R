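test_that("compound generator honors counts, planted violators and ranges", {
  tab <- gen_compounds(27, frac_violators = 0, seed = 1)
  expect_equal(nrow(tab), 27)
  v <- count_lipinski_violations(tab$mw, tab$hba, tab$hbd, tab$mlogp)
  expect_true(all(v <= 1))
  expect_true(all(tab$bioavailability > 0.5))

  tab2 <- gen_compounds(10, frac_violators = 0.5, seed = 7)
  v2 <- count_lipinski_violations(tab2$mw, tab2$hba, tab2$hbd, tab2$mlogp)
  expect_equal(sum(v2 >= 2), 5)

  # physically plausible descriptor ranges, discrete Abbott levels
  expect_true(all(tab2$mw >= 50 & tab2$mw <= 900))
  expect_true(all(tab2$hba %in% 0:15))
  expect_true(all(tab2$hbd %in% 0:8))
  expect_true(all(tab2$mlogp >= -3 & tab2$mlogp <= 7))
  expect_true(all(tab2$bioavailability %in% c(0.11, 0.17, 0.55, 0.56, 0.85)))

  expect_equal(nrow(gen_compounds(0, 0.5, seed = 1)), 0)
  expect_error(gen_compounds(-1, 0, 1), "non-negative")
  expect_error(gen_compounds(5, 1.2, 1), "\\[0, 1\\]")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_compounds(10, 0.5, seed = 7),
                   gen_compounds(10, 0.5, seed = 7))
  expect_identical(gen_gene_universe(100, seed = 3),
                   gen_gene_universe(100, seed = 3))
  u <- gen_gene_universe(50, seed = 1)
  expect_identical(gen_ppi(u[1:20], u[1], seed = 5),
                   gen_ppi(u[1:20], u[1], seed = 5))
  expect_identical(
    gen_associations(letters[1:5], u, c(2, 5), 0.5, seed = 2),
    gen_associations(letters[1:5], u, c(2, 5), 0.5, seed = 2))
  # global RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(gen_compounds(5, 0, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("gene universe is unique, uppercase, and honors injections", {
  u <- gen_gene_universe(100, seed = 3)
  expect_length(u, 100)
  expect_false(anyDuplicated(u) > 0)
  expect_identical(u, toupper(u))
  expect_length(gen_gene_universe(0, seed = 3), 0)
  expect_true("TLR4" %in% gen_gene_universe(50, seed = 2, include = "TLR4"))
  expect_error(gen_gene_universe(2, include = c("A", "B", "C")), "more symbols")
})

test_that("association tables realize the requested pooled-set overlap", {
  u <- gen_gene_universe(500, seed = 1)
  cmp <- sprintf("c%02d", 1:20)
  jaccard <- function(a, b)
    length(intersect(a, b)) / length(union(a, b))
  for (ov in c(0, 0.5, 1)) {
    ab <- gen_associations(cmp, u, c(3, 10), overlap = ov, seed = 11)
    pa <- unique(ab$A$gene_symbol)
    pb <- unique(ab$B$gene_symbol)
    expect_true(all(c(pa, pb) %in% u))
    expect_true(all(c(ab$A$compound_id, ab$B$compound_id) %in% cmp))
    j <- jaccard(pa, pb)
    if (ov == 1) expect_setequal(pa, pb)
    if (ov == 0) expect_length(intersect(pa, pb), 0)
    expect_lte(abs(j - ov), 0.1)
  }
  expect_error(gen_associations(cmp, u, c(3, 10), overlap = 2), "\\[0, 1\\]")
})

test_that("orphan compounds never reach the cross-source intersection", {
  u <- gen_gene_universe(500, seed = 4)
  cmp <- sprintf("c%02d", 1:27)
  orp <- cmp[22:27]
  ab <- gen_associations(cmp, u, c(5, 15), 0.5, seed = 3,
                         orphan_compounds = orp, top_compound = cmp[1])
  pooled <- intersect_compound_sources(ab$A$gene_symbol, ab$B$gene_symbol)
  both <- rbind(ab$A, ab$B)
  conn <- compound_connectivity(both, pooled$common, compounds = cmp)
  expect_setequal(conn$orphans, orp)
  # the planted top compound covers the whole pooled intersection
  top_genes <- both$gene_symbol[both$compound_id == cmp[1]]
  expect_true(all(pooled$common %in% top_genes))
})

test_that("disease lists intersect the compound targets exactly as planted", {
  u <- gen_gene_universe(1000, seed = 5)
  ct <- u[1:100]
  dl <- gen_disease_sets(u, c(300, 200, 150), 42, ct, seed = 6)
  pool <- union_disease_sources(dl[[1]], dl[[2]], dl[[3]])
  expect_length(intersect(pool$genes, ct), 42)
  expect_equal(vapply(dl, nrow, integer(1), USE.NAMES = FALSE),
               c(300, 200, 150))

  dl0 <- gen_disease_sets(u, c(50, 50, 50), 0, ct, seed = 6)
  pool0 <- union_disease_sources(dl0[[1]], dl0[[2]], dl0[[3]])
  expect_length(intersect(pool0$genes, ct), 0)

  small <- gen_disease_sets(u[1:15], c(10, 10, 10), 0, character(0), seed = 1)
  un <- union_disease_sources(small[[1]], small[[2]], small[[3]])
  expect_lte(length(un$genes), 15)

  expect_error(gen_disease_sets(u, c(10, 10, 10), 50, ct[1:20], seed = 1),
               "hit_overlap")
  expect_error(gen_disease_sets(u[1:5], c(10, 10, 10), 0, ct, seed = 1),
               "exceed")
})

test_that("ppi generator plants hub wiring, cliques and score floors", {
  nodes <- sprintf("P%02d", 1:10)
  ppi <- gen_ppi(nodes, "P01", clique_sizes = 3, background_edge_prob = 0,
                 seed = 2, hub_coverage = 1)
  hub_deg <- sum(ppi$protein1 == "P01") + sum(ppi$protein2 == "P01")
  expect_equal(hub_deg, 9)
  expect_true(all(ppi$combined_score >= 700))  # all edges planted here

  full <- gen_ppi(sprintf("Q%d", 1:5), "Q1", clique_sizes = integer(0),
                  background_edge_prob = 1, seed = 3, hub_coverage = 0.8)
  expect_equal(nrow(full), 10)

  expect_false(any(ppi$protein1 == ppi$protein2))
  key <- paste(pmin(ppi$protein1, ppi$protein2),
               pmax(ppi$protein1, ppi$protein2))
  expect_false(anyDuplicated(key) > 0)
  expect_error(gen_ppi(nodes, "ZZZ", seed = 1), "planted_hub")
})

test_that("annotation generator plants the requested enrichment fold", {
  u <- gen_gene_universe(2000, seed = 8)
  q <- u[1:42]
  coll <- gen_annotations(u, 50, c(50, 400), planted_term = "PLANTED",
                          query = q, fold = 5, seed = 9)
  expect_length(coll, 50)
  expect_true("PLANTED" %in% names(coll))
  expect_true(all(unlist(coll) %in% u))
  K <- length(coll[["PLANTED"]])
  overlap <- length(intersect(coll[["PLANTED"]], q))
  expect_gte(overlap, 5 * length(q) * K / length(u))
  expect_length(gen_annotations(u, 0, c(5, 10)), 0)
  expect_error(gen_annotations(u[1:20], 5, c(10, 50)), "universe")
})
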