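# counts how many of all C(N, n) equally likely draws reach overlap >= k:
# an enumeration oracle fully independent of the distribution functions
enum_upper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K carry the annotation
  mean(hits >= k)
}

test_that("upper-tail probabilities match enumeration on the worked example", {
  expect_equal(hypergeometric_upper_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeometric_upper_tail(4, 5, 4, 10),
               enum_upper_tail(4, 5, 4, 10))
  expect_equal(hypergeometric_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_upper_tail(6, 6, 6, 6), 1)
  expect_error(hypergeometric_upper_tail(5, 4, 4, 10), "inconsistent")
  expect_error(hypergeometric_upper_tail(2, 5, 4, 3), "inconsistent")
})

test_that("BH adjustment matches hand computation and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.04, 0.5)), c(0.08, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.5, 0.001, 0.04, 0.2)
  q <- bh_fdr(p)
  expect_identical(order(p), order(q))  # order-preserving
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment fills statistics, filters and sorts correctly", {
  universe <- sprintf("G%03d", 1:100)
  coll <- list(hit = universe[1:20], miss = universe[51:60],
               partial = universe[c(1:5, 61:70)])
  query <- universe[1:10]
  res <- enrich(query, coll, universe)
  expect_false("miss" %in% res$term)          # zero overlap absent
  expect_identical(res$term[1], "hit")        # smallest p first
  expect_equal(res$overlap[res$term == "hit"], 10)
  expect_equal(res$rich_factor, res$overlap / res$term_size)
  expect_equal(res$gene_percentage, 100 * res$overlap / res$query_size)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(res$significant[res$term == "hit"])

  # saturated query: every term has p = 1
  sat <- enrich(universe, coll, universe)
  expect_true(all(sat$p_value == 1))

  expect_error(enrich(c("NOT_THERE"), coll, universe), "outside")
  expect_error(enrich("A", coll, character(0)), "empty universe")
})

test_that("gene-percentage reporting keeps the category and tie rules", {
  res <- data.frame(
    term = sprintf("t%02d", 1:15), category = rep(c("BP", "CC"), c(12, 3)),
    overlap = 3, term_size = 10, query_size = 42, universe_size = 2000,
    p_value = seq(0.001, 0.015, by = 0.001), q_value = 0.02,
    rich_factor = 0.3,
    gene_percentage = c(rep(50, 2), seq(40, 31, length.out = 10), 20, 20, 10),
    significant = TRUE, genes = "")
  top <- top_by_gene_percentage(res, m = 10, category = "BP")
  expect_equal(nrow(top), 10)
  expect_true(all(top$category == "BP"))
  expect_identical(top$term[1:2], c("t01", "t02"))  # tie -> smaller p first
  expect_equal(nrow(top_by_gene_percentage(res, m = 10, category = "CC")), 3)
})

test_that("bubble tables project significant rows exactly", {
  universe <- sprintf("G%03d", 1:200)
  coll <- list(strong = universe[1:20], weak = universe[c(1, 101:140)])
  res <- enrich(universe[1:20], coll, universe, category = "pathway")
  bt <- bubble_table(res)
  expect_true(all(bt$term %in% res$term[res$significant]))
  expect_equal(nrow(bt), sum(res$significant))
  i <- match(bt$term, res$term)
  expect_equal(bt$rich_factor, res$rich_factor[i])
  expect_equal(bt$q_value, res$q_value[i])
  expect_equal(bt$overlap, res$overlap[i])
  none <- res[res$p_value > 2, ]  # empty frame keeps structure
  expect_equal(nrow(bubble_table(none)), 0)
})

test_that("GMT round-trips through write and read", {
  coll <- list(alpha = c("G1", "G2", "G3"), beta = c("G2", "G4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_equal(back[order(names(back))], coll[order(names(coll))])
})
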