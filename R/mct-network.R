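#' Assemble the mushroom-compound-target network
#'
#' Builds the tripartite network linking one mushroom node to its
#' screened compounds and each compound to its targets within the common
#' target set. Only compounds with at least one link into `common` enter
#' the network (orphans are excluded), and only common targets with at
#' least one link appear; every compound node is joined to the mushroom
#' node by a structural provenance edge. Edges are deduplicated.
#'
#' @param mushroom_id Label of the mushroom node.
#' @param associations Data frame with columns `compound_id`,
#'   `gene_symbol`.
#' @param common Character vector: the common target set (non-empty).
#' @return An object of class `mct_network`: a list with `nodes`
#'   (data frame `id`, `role`), `edges` (data frame `from`, `to`,
#'   `kind`), and `mushroom`.
#' @export
build_mct <- function(mushroom_id, associations, common) {
  if (!length(common)) stop("empty common target set", call. = FALSE)
  common <- normalize_symbols(common)
  assoc <- unique(data.frame(
    compound_id = as.character(associations$compound_id),
    gene_symbol = normalize_one(associations$gene_symbol),
    stringsAsFactors = FALSE))
  assoc <- assoc[assoc$gene_symbol %in% common, , drop = FALSE]
  compounds <- sort(unique(assoc$compound_id))
  targets <- sort(unique(assoc$gene_symbol))
  nodes <- data.frame(
    id = c(mushroom_id, compounds, targets),
    role = c("mushroom", rep("compound", length(compounds)),
             rep("target", length(targets))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    if (length(compounds))
      data.frame(from = mushroom_id, to = compounds,
                 kind = "mushroom-compound", stringsAsFactors = FALSE),
    if (nrow(assoc))
      data.frame(from = assoc$compound_id, to = assoc$gene_symbol,
                 kind = "compound-target", stringsAsFactors = FALSE))
  edges <- edges[order(edges$kind, edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mushroom = mushroom_id),
            class = "mct_network")
}

#' Role-wise counts of an M-C-T network
#'
#' @param net An `mct_network`.
#' @return List with `mushroom`, `compound`, `target` node counts,
#'   `nodes` (their sum) and `edges`.
#' @export
mct_counts <- function(net) {
  stopifnot(inherits(net, "mct_network"))
  tab <- table(factor(net$nodes$role,
                      levels = c("mushroom", "compound", "target")))
  list(mushroom = as.integer(tab[["mushroom"]]),
       compound = as.integer(tab[["compound"]]),
       target = as.integer(tab[["target"]]),
       nodes = nrow(net$nodes),
       edges = nrow(net$edges))
}

#' Prioritize compounds by target degree
#'
#' Ranks the compound nodes by their number of distinct target
#' neighbors. The structural mushroom-compound edge is excluded from the
#' score, so a compound's degree equals its count of common targets;
#' this shifts every degree by the same constant and leaves the ranking
#' unchanged. Ties break by ascending compound id.
#'
#' @param net An `mct_network`.
#' @param k Number of compounds to return; larger values return the
#'   full list.
#' @return Data frame `rank`, `compound_id`, `degree`.
#' @export
top_compounds_by_degree <- function(net, k = 5L) {
  stopifnot(inherits(net, "mct_network"))
  k <- check_count(k, "k")
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  ct <- net$edges[net$edges$kind == "compound-target", , drop = FALSE]
  compounds <- net$nodes$id[net$nodes$role == "compound"]
  deg <- table(factor(ct$from, levels = sort(compounds)))
  ord <- order(-as.integer(deg), names(deg))
  k <- min(k, length(deg))
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), compound_id = names(deg)[top],
             degree = as.integer(deg[top]), stringsAsFactors = FALSE)
}

#' @export
print.mct_network <- function(x, ...) {
  ct <- mct_counts(x)
  cat("mushroom-compound-target network:", ct$nodes, "nodes (",
      ct$mushroom, "mushroom,", ct$compound, "compounds,",
      ct$target, "targets ),", ct$edges, "edges\n")
  invisible(x)
}
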