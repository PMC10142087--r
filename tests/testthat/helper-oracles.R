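# Independent brute-force oracles for the graph centralities, plus small
# random-graph fixtures. These deliberately avoid the package's own code
# paths (and igraph's clique machinery): cliques are found by scanning
# every vertex subset with bitmasks, components by hand-rolled BFS.

rand_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("N%02d", seq_len(n)), sprintf("N%02d", seq_len(n)))
  A
}

adj_to_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# all maximal cliques by exhaustive subset scan (n <= 15)
oracle_maximal_cliques <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 15L)
  labs <- rownames(A)
  bit <- 2^(seq_len(n) - 1)
  nb <- vapply(seq_len(n), function(v) sum(bit[A[v, ] == 1L]), numeric(1))
  S <- 0:(2^n - 1)
  is_clique <- rep(TRUE, length(S))
  for (v in seq_len(n)) {
    in_s <- bitwAnd(S, bit[v]) > 0
    covered <- bitwAnd(S, bitwOr(nb[v], bit[v])) == S
    is_clique <- is_clique & (!in_s | covered)
  }
  extendable <- rep(FALSE, length(S))
  for (u in seq_len(n)) {
    in_s <- bitwAnd(S, bit[u]) > 0
    covers <- bitwAnd(S, nb[u]) == S
    extendable <- extendable | (!in_s & covers)
  }
  keep <- is_clique & !extendable & S > 0
  lapply(S[keep], function(s) sort(labs[bitwAnd(s, bit) > 0]))
}

oracle_mcc <- function(A, v) {
  cl <- oracle_maximal_cliques(A)
  mine <- vapply(cl, function(x) v %in% x, logical(1))
  sum(factorial(lengths(cl)[mine] - 1))
}

# largest connected component of the neighbor-induced subgraph, by BFS
oracle_mnc <- function(A, v) {
  nb <- which(A[rownames(A) == v, ] == 1L)
  if (!length(nb)) return(0L)
  sub <- A[nb, nb, drop = FALSE]
  seen <- rep(FALSE, length(nb))
  best <- 0L
  for (i in seq_along(nb)) {
    if (seen[i]) next
    queue <- i
    seen[i] <- TRUE
    size <- 0L
    while (length(queue)) {
      x <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      nxt <- which(sub[x, ] == 1L & !seen)
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    best <- max(best, size)
  }
  best
}

# seeded sample without disturbing the ambient RNG state
with_seed_sample <- function(x, size, seed) {
  withr::with_seed(seed, sample(x, size))
}

# tiny named graph from an edge list, for hand-checkable cases
graph_from_pairs <- function(..., isolated = character(0)) {
  pairs <- list(...)
  el <- do.call(rbind, pairs)
  verts <- sort(unique(c(as.vector(el), isolated)))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]),
    directed = FALSE, vertices = verts)
}
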