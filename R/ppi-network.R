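#' Build an interaction network from a scored edge table
#'
#' Reads STRING-dialect rows (`protein1`, `protein2`, `combined_score`)
#' into a simple undirected [igraph][igraph::igraph] graph. Scores are
#' auto-scaled: if any score exceeds 1 the whole column is treated as the
#' 0-1000 integer scale and divided by 1000. Rows are kept when the
#' normalized score is at least `min_confidence` (inclusive, so the
#' medium-confidence cutoff 0.400 retains a score of 400); self-loops are
#' dropped; duplicate and reversed pairs collapse to one edge keeping the
#' maximum score.
#'
#' @param rows Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (a `nodeA`/`nodeB` naming is also accepted).
#' @param min_confidence Minimum normalized confidence, default 0.400.
#' @param keep_nodes Optional character vector of query nodes added to
#'   the graph even if isolated after filtering.
#' @return An undirected igraph with edge attribute `confidence` in
#'   [0, 1].
#' @export
load_interaction_table <- function(rows, min_confidence = 0.400,
                                   keep_nodes = NULL) {
  stopifnot(is.data.frame(rows))
  nm <- names(rows)
  a <- rows[[if ("protein1" %in% nm) "protein1" else "nodeA"]]
  b <- rows[[if ("protein2" %in% nm) "protein2" else "nodeB"]]
  s <- as.numeric(rows[["combined_score"]])
  if (any(is.na(s)) || any(s < 0))
    stop("malformed or negative combined scores", call. = FALSE)
  if (length(s) && any(s > 1)) s <- s / 1000
  if (any(s > 1))
    stop("combined scores exceed both supported scales", call. = FALSE)

  a <- normalize_one(a); b <- normalize_one(b)
  keep <- a != b & s >= min_confidence
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) {
    verts <- normalize_symbols(keep_nodes)
    g <- igraph::make_empty_graph(length(verts), directed = FALSE)
    igraph::V(g)$name <- verts
    return(g)
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(s, key, max)
  ord <- sort(names(best))
  parts <- strsplit(ord, "\r", fixed = TRUE)
  el <- cbind(vapply(parts, `[`, character(1), 1L),
              vapply(parts, `[`, character(1), 2L))
  verts <- sort(unique(c(el, normalize_symbols(keep_nodes))))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               confidence = as.numeric(best[ord])),
    directed = FALSE, vertices = verts)
}

#' Topological summary of an interaction network
#'
#' Node and edge counts, average number of neighbors (`2E/N`, rounded to
#' 3 decimals for reporting), and unweighted diameter and radius. On a
#' disconnected graph the diameter and radius are computed on the
#' largest connected component.
#'
#' @param net An igraph as built by [load_interaction_table()].
#' @return A list with `nodes`, `edges`, `avg_neighbors`, `diameter`,
#'   `radius`.
#' @examples
#' g <- igraph::make_ring(3)
#' network_stats(g)  # avg 2, diameter 1, radius 1
#' @export
network_stats <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  e <- igraph::ecount(net)
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  list(nodes = n,
       edges = e,
       avg_neighbors = round(2 * e / n, 3),
       diameter = as.integer(igraph::diameter(sub, weights = NA)),
       radius = as.integer(igraph::radius(sub)))
}

#' Read a STRING-dialect TSV edge list
#' @param path Path to a tab-separated file with columns `protein1`,
#'   `protein2`, `combined_score`.
#' @return Data frame suitable for [load_interaction_table()].
#' @export
read_string_tsv <- function(path) {
  if (!file.exists(path))
    stop("interaction edge-list file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
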