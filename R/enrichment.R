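#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` query genes are drawn
#' without replacement from a universe of `N` genes of which `K` carry
#' the annotation. Computed via [stats::phyper()], which is numerically
#' stable for universes well beyond 1e5 genes. This one-sided test
#' (equivalent to one-sided Fisher) is the enrichment statistic used
#' throughout the package.
#'
#' @param k Observed overlap (vectorized).
#' @param K Term size.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in (0, 1].
#' @examples
#' hypergeometric_upper_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg Q values
#'
#' Step-up FDR adjustment with monotonicity enforcement, preserving the
#' input order. A single p-value is returned unchanged.
#'
#' @param p_values Numeric vector in (0, 1].
#' @return Numeric vector of Q values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of a gene set
#'
#' One-sided hypergeometric enrichment of `query` against every term of
#' an annotation collection, with BH-FDR Q values, rich factor
#' (`overlap / term size`) and gene percentage
#' (`100 * overlap / query size`). Terms are first restricted to the
#' universe; only terms overlapping the query appear in the result, but
#' the FDR adjustment spans all tested (overlapping) terms. Terms with
#' raw `p < alpha` are flagged significant, and Q is reported alongside.
#' Results are sorted by p ascending (ties by term id).
#'
#' @param query Character vector of query genes; must lie within the
#'   universe.
#' @param collection Named list of character vectors (e.g. from
#'   [gen_annotations()] or [read_gmt()]).
#' @param universe Character vector of background genes; defaults to the
#'   union of all collection genes.
#' @param alpha Raw-p significance gate, default 0.05.
#' @param category Optional single category label attached to every
#'   result row (`"BP"`, `"CC"`, `"MF"`, `"pathway"`, ...).
#' @return Data frame with columns `term`, `category`, `overlap`,
#'   `term_size`, `query_size`, `universe_size`, `p_value`, `q_value`,
#'   `rich_factor`, `gene_percentage`, `significant`, plus a
#'   comma-separated `genes` column listing the overlapping symbols.
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05,
                   category = NA_character_) {
  query <- normalize_symbols(query)
  if (is.null(universe)) universe <- unique(unlist(collection, use.names = FALSE))
  universe <- normalize_symbols(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(tm) {
    genes <- intersect(normalize_symbols(collection[[tm]]), universe)
    hit <- intersect(genes, query)
    if (!length(genes) || !length(hit)) return(NULL)
    K <- length(genes); k <- length(hit)
    data.frame(term = tm, category = category, overlap = k, term_size = K,
               query_size = n, universe_size = N,
               p_value = hypergeometric_upper_tail(k, K, n, N),
               rich_factor = k / K, gene_percentage = 100 * k / n,
               genes = paste(hit, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term = character(0), category = character(0),
                      overlap = integer(0), term_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      rich_factor = numeric(0), gene_percentage = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "category", "overlap", "term_size", "query_size",
          "universe_size", "p_value", "q_value", "rich_factor",
          "gene_percentage", "significant", "genes")]
}

#' Top terms by gene percentage
#'
#' The reporting rule for functional keywords: within one category, the
#' top `m` terms by gene percentage (descending), ties resolved by
#' ascending p-value.
#'
#' @param results Data frame from [enrich()].
#' @param m Number of terms, default 10.
#' @param category Optional category filter.
#' @return Ordered subset of `results`.
#' @export
top_by_gene_percentage <- function(results, m = 10L, category = NULL) {
  m <- check_count(m, "m")
  if (!is.null(category))
    results <- results[!is.na(results$category) &
                         results$category == category, , drop = FALSE]
  ord <- order(-results$gene_percentage, results$p_value, results$term)
  out <- results[utils::head(ord, m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bubble-plot table
#'
#' Plot-ready projection of the significant terms: term, rich factor,
#' Q value, and overlap count (the bubble size). No graphics are
#' produced.
#'
#' @param results Data frame from [enrich()].
#' @return Data frame `term`, `rich_factor`, `q_value`, `overlap`.
#' @export
bubble_table <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  out <- sig[, c("term", "rich_factor", "q_value", "overlap")]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a tab-separated GMT file
#'   (term, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
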