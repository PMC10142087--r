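#' Enumerate all maximal cliques
#'
#' Pivoting Bron-Kerbosch enumeration of the maximal cliques of a simple
#' undirected graph. A clique is maximal when no further node is adjacent
#' to all of its members; isolated nodes yield singleton maximal cliques.
#' Every maximal clique is returned exactly once, as a sorted character
#' vector of symbols.
#'
#' @param net An igraph.
#' @return List of character vectors, in a deterministic order.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' enumerate_maximal_cliques(g)
#' @export
enumerate_maximal_cliques <- function(net) {
  n <- igraph::vcount(net)
  labels <- igraph::V(net)$name
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 0L) return(list())
  adj <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(net, v)))
  out <- vector("list", 0L)
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    # pivot: the candidate covering most of P, shrinking the branch set
    cand_px <- c(P, X)
    cover <- vapply(cand_px, function(u) length(intersect(P, adj[[u]])),
                    integer(1))
    u <- cand_px[which.max(cover)]
    for (v in setdiff(P, adj[[u]])) {
      nv <- adj[[v]]
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(out, function(ix) sort(labels[ix]))
  cliques[order(vapply(cliques, paste, character(1), collapse = "\r"))]
}

#' Degree score
#'
#' Number of neighbors of `v` in the network.
#'
#' @param net An igraph.
#' @param v Node symbol.
#' @return Integer degree.
#' @export
degree_score <- function(net, v) {
  check_node(net, v)
  as.integer(igraph::degree(net, v))
}

#' Maximum Neighborhood Component (MNC) score
#'
#' Size of the largest connected component of the subgraph induced by
#' the neighbors of `v` (with `v` itself excluded). An isolated node
#' scores 0.
#'
#' @inheritParams degree_score
#' @return Integer score.
#' @export
mnc_score <- function(net, v) {
  check_node(net, v)
  nb <- igraph::neighbors(net, v)
  if (!length(nb)) return(0L)
  sub <- igraph::induced_subgraph(net, nb)
  as.integer(max(igraph::components(sub)$csize))
}

#' Maximal Clique Centrality (MCC) score
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`.
#' An isolated node lies in its own singleton maximal clique and scores
#' `0! = 1`.
#'
#' @inheritParams degree_score
#' @param cliques Optional precomputed output of
#'   [enumerate_maximal_cliques()] (so one enumeration can serve many
#'   nodes).
#' @return Numeric score >= 1.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- LETTERS[1:4]
#' mcc_score(g, "A")  # (4-1)! = 6
#' @export
mcc_score <- function(net, v, cliques = NULL) {
  check_node(net, v)
  if (is.null(cliques)) cliques <- enumerate_maximal_cliques(net)
  sizes <- lengths(cliques)
  mine <- vapply(cliques, function(cl) v %in% cl, logical(1))
  sum(factorial(sizes[mine] - 1))
}

check_node <- function(net, v) {
  nm <- igraph::V(net)$name
  if (!v %in% nm) stop("unknown node: ", v, call. = FALSE)
  invisible(TRUE)
}

#' Score every node by a hub-ranking method
#'
#' @param net An igraph.
#' @param method One of `"MCC"`, `"MNC"`, `"Degree"`.
#' @return Named numeric vector of scores over all nodes.
#' @export
hub_scores <- function(net, method = c("MCC", "MNC", "Degree")) {
  method <- match.arg(method)
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
    nodes <- igraph::V(net)$name
  }
  sc <- switch(method,
    Degree = as.numeric(igraph::degree(net)),
    MNC = vapply(nodes, function(v) as.numeric(mnc_score(net, v)),
                 numeric(1)),
    MCC = {
      cl <- enumerate_maximal_cliques(net)
      vapply(nodes, function(v) mcc_score(net, v, cliques = cl), numeric(1))
    })
  stats::setNames(as.numeric(sc), nodes)
}

#' Rank hub genes
#'
#' Top-`k` nodes under one ranking method, scores non-increasing, ties
#' broken by ascending symbol so the ranking is fully deterministic.
#'
#' @inheritParams hub_scores
#' @param k Number of nodes to return; values beyond the node count
#'   truncate with a warning.
#' @return Data frame `rank`, `gene`, `score`, `method`.
#' @export
rank_nodes <- function(net, method = c("MCC", "MNC", "Degree"), k = 10L) {
  method <- match.arg(method)
  k <- check_count(k, "k")
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  sc <- hub_scores(net, method)
  if (k > length(sc)) {
    warning("k exceeds node count; returning all ", length(sc), " nodes")
    k <- length(sc)
  }
  ord <- order(-sc, names(sc))
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), gene = names(sc)[top],
             score = as.numeric(sc[top]), method = method,
             stringsAsFactors = FALSE)
}

#' Consensus of several hub rankings
#'
#' Genes present in the top-`k` slice of every supplied ranking — the
#' criterion used to call a gene an essential target across all three
#' ranking algorithms.
#'
#' @param rankings List of data frames from [rank_nodes()].
#' @param k Slice depth.
#' @return Sorted character vector.
#' @export
consensus_top <- function(rankings, k = 3L) {
  stopifnot(length(rankings) >= 1L)
  k <- check_count(k, "k")
  slices <- lapply(rankings, function(r) utils::head(r$gene, k))
  sort(Reduce(intersect, slices))
}
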