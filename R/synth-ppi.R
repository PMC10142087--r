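#' Generate a synthetic scored protein-interaction edge table
#'
#' Emulates a STRING-style export over a fixed node set with planted,
#' recoverable hub structure: the `planted_hub` is a member of every
#' planted clique and is additionally wired to at least `hub_coverage`
#' (>= 0.8) of all other nodes; remaining unordered pairs appear
#' independently with probability `background_edge_prob`. Planted edges
#' (hub wiring and clique edges) carry combined scores of 700-1000 so a
#' medium-confidence filter at 400 never removes planted structure;
#' background scores are uniform over 150-1000.
#'
#' @param nodes Character vector of node symbols.
#' @param planted_hub Symbol of the planted hub; must be in `nodes`.
#' @param clique_sizes Integer vector of planted clique sizes (each >= 2);
#'   every planted clique contains the hub.
#' @param background_edge_prob Probability of each background edge.
#' @param seed Integer seed.
#' @param hub_coverage Fraction of non-hub nodes the hub is wired to
#'   (minimum 0.8).
#' @return A data frame with columns `protein1`, `protein2`,
#'   `combined_score` (integer, 0-1000 scale); no self-loops, no
#'   duplicate unordered pairs.
#' @export
gen_ppi <- function(nodes, planted_hub, clique_sizes = c(5L, 4L, 3L),
                    background_edge_prob = 0.2, seed = 1L,
                    hub_coverage = 0.85) {
  nodes <- unique(as.character(nodes))
  background_edge_prob <- check_fraction(background_edge_prob,
                                         "background_edge_prob")
  if (!planted_hub %in% nodes)
    stop("`planted_hub` must be one of `nodes`", call. = FALSE)
  if (length(clique_sizes) && any(clique_sizes < 2L))
    stop("clique sizes must be >= 2", call. = FALSE)
  if (hub_coverage < 0.8 || hub_coverage > 1)
    stop("`hub_coverage` must be in [0.8, 1]", call. = FALSE)
  n <- length(nodes)
  if (n < 2L)
    return(data.frame(protein1 = character(0), protein2 = character(0),
                      combined_score = integer(0)))

  with_local_seed(seed, {
    others <- setdiff(nodes, planted_hub)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    edges <- new.env(parent = emptyenv())
    add <- function(a, b, score) {
      k <- key(a, b)
      cur <- edges[[k]]
      if (is.null(cur) || cur[[3]] < score)
        edges[[k]] <- list(pmin(a, b), pmax(a, b), score)
    }

    # hub wiring
    wired <- sample(others, ceiling(hub_coverage * length(others)))
    for (w in wired) add(planted_hub, w, sample(700:1000, 1L))
    # planted cliques, all containing the hub
    for (cs in clique_sizes) {
      members <- c(planted_hub, sample(others, min(cs - 1L, length(others))))
      prs <- utils::combn(sort(members), 2L)
      for (j in seq_len(ncol(prs)))
        add(prs[1, j], prs[2, j], sample(700:1000, 1L))
    }
    # background
    if (background_edge_prob > 0 && n >= 2L) {
      prs <- utils::combn(sort(nodes), 2L)
      keep <- stats::runif(ncol(prs)) < background_edge_prob
      for (j in which(keep))
        add(prs[1, j], prs[2, j], sample(150:1000, 1L))
    }

    ks <- sort(ls(edges))
    out <- data.frame(
      protein1 = vapply(ks, function(k) edges[[k]][[1]], character(1)),
      protein2 = vapply(ks, function(k) edges[[k]][[2]], character(1)),
      combined_score = vapply(ks, function(k) as.integer(edges[[k]][[3]]),
                              integer(1)),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic annotation-term collection
#'
#' Emulates a GO/KEGG-style gene-set collection as a named list of gene
#' vectors. When `planted_term` is given, that term's overlap with
#' `query` is planted at `ceiling(fold)` times its hypergeometric
#' expectation `|query| * K / |universe|` (capped by the term and query
#' sizes), so enrichment should recover it; all other terms are sampled
#' uniformly from the universe. With `fold = 1` the planted term is
#' statistically unremarkable.
#'
#' @param universe Gene universe.
#' @param n_terms Number of terms.
#' @param size_range Length-2 range of term sizes.
#' @param planted_term Name of the planted term, or `NULL` for none.
#' @param query Query gene set used to plant the enrichment.
#' @param fold Enrichment fold of the planted term (>= 1).
#' @param seed Integer seed.
#' @return Named list of character vectors (a GMT-style collection).
#' @export
gen_annotations <- function(universe, n_terms = 50L,
                            size_range = c(50L, 400L),
                            planted_term = NULL, query = character(0),
                            fold = 5, seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms")
  stopifnot(length(size_range) == 2L, size_range[1] >= 1L,
            size_range[1] <= size_range[2])
  if (size_range[2] > length(universe) && n_terms > 0L)
    stop("size range exceeds the universe", call. = FALSE)
  if (fold < 1) stop("`fold` must be >= 1", call. = FALSE)
  if (!all(query %in% universe))
    stop("`query` must be a subset of `universe`", call. = FALSE)
  if (n_terms == 0L) return(setNames(list(), character(0)))

  with_local_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
    terms <- lapply(sizes, function(k) sort(sample(universe, k)))
    names(terms) <- sprintf("T%04d", seq_len(n_terms))
    if (!is.null(planted_term) && length(query)) {
      K <- sizes[1]
      expect <- length(query) * K / length(universe)
      k_hit <- min(ceiling(fold * expect), length(query), K)
      genes <- c(sample(query, k_hit),
                 sample(setdiff(universe, query), K - k_hit))
      terms[[1]] <- sort(genes)
      names(terms)[1] <- planted_term
    }
    terms
  })
}

#' Synthetic frontier-orbital energies for a compound panel
#'
#' Draws plausible HOMO levels and HOMO-LUMO gaps for each compound.
#' When `key_id` names a compound, that row is anchored at the worked
#' example used throughout the package: HOMO -0.224, LUMO -0.0589
#' (gap 0.1651, chemical hardness 0.08255).
#'
#' @param compound_ids Character vector of compound ids.
#' @param seed Integer seed.
#' @param key_id Optional id anchored at the worked-example energies.
#' @return Data frame with columns `compound_id`, `homo`, `lumo`, `units`.
#' @export
gen_orbitals <- function(compound_ids, seed = 1L, key_id = NULL) {
  with_local_seed(seed, {
    n <- length(compound_ids)
    homo <- round(stats::runif(n, -0.35, -0.18), 4)
    gap <- round(stats::runif(n, 0.17, 0.45), 4)
    out <- data.frame(compound_id = as.character(compound_ids),
                      homo = homo, lumo = homo + gap,
                      units = "kcal/mol", stringsAsFactors = FALSE)
    if (!is.null(key_id) && key_id %in% out$compound_id) {
      i <- match(key_id, out$compound_id)
      out$homo[i] <- -0.224
      out$lumo[i] <- -0.0589
    }
    out
  })
}

#' Reference orbital energies for the standard drugs
#'
#' Synthetic stand-ins for aspirin and indomethacin frontier-orbital
#' energies, constructed so both standards are chemically harder
#' (larger gap) than the worked-example candidate (hardness 0.08255).
#'
#' @return Data frame with columns `compound_id`, `homo`, `lumo`, `units`.
#' @export
standard_orbitals <- function() {
  data.frame(
    compound_id = c("Aspirin", "Indomethacin"),
    homo = c(-0.260, -0.215),
    lumo = c(0.020, -0.035),
    units = "kcal/mol",
    stringsAsFactors = FALSE
  )
}

#' Example docking-score table
#'
#' Bundled benchmark scores (kcal/mol, more negative = stronger) for a
#' naphthylcarboxamide candidate against two inflammation targets, with
#' aspirin and indomethacin as reference ligands on the same receptors:
#' NOS2 (PDB 1NSI), where the candidate binds much more strongly than
#' both references, and TLR4 (PDB 3UL7), where all three ligands are
#' comparable.
#'
#' @return Data frame with columns `ligand`, `target`, `target_pdb`,
#'   `score_kcal_mol`.
#' @export
example_docking_scores <- function() {
  data.frame(
    ligand = rep(c("N-(3-chlorophenyl)naphthylcarboxamide",
                   "Aspirin", "Indomethacin"), 2),
    target = rep(c("NOS2", "TLR4"), each = 3),
    target_pdb = rep(c("1NSI", "3UL7"), each = 3),
    score_kcal_mol = c(-8.85, -6.467, -7.491,
                       -4.027, -4.178, -4.168),
    stringsAsFactors = FALSE
  )
}

#' Synthetic docking-score table
#'
#' Starts from [example_docking_scores()] and appends seeded random
#' scores for any additional targets, for the same three ligands.
#'
#' @param extra_targets Character vector of additional target names.
#' @param seed Integer seed.
#' @return Data frame in the same shape as [example_docking_scores()].
#' @export
gen_docking <- function(extra_targets = character(0), seed = 1L) {
  base <- example_docking_scores()
  if (!length(extra_targets)) return(base)
  with_local_seed(seed, {
    ligs <- unique(base$ligand)
    extra <- do.call(rbind, lapply(extra_targets, function(tg) {
      data.frame(ligand = ligs, target = tg,
                 target_pdb = paste0(sample(LETTERS, 1L),
                                     paste(sample(c(LETTERS, 0:9), 3L,
                                                  replace = TRUE), collapse = "")),
                 score_kcal_mol = round(stats::runif(length(ligs), -9.5, -3), 3),
                 stringsAsFactors = FALSE)
    }))
    rbind(base, extra)
  })
}
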