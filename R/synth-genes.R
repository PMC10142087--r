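#' Generate a synthetic gene universe
#'
#' Produces `n` unique, uppercase, HGNC-like synthetic symbols
#' (`G000001`, ...) in a seed-dependent order. A few real symbols can be
#' injected via `include` for readability (e.g. naming the planted hub
#' `TLR4`); this is purely cosmetic.
#'
#' @param n Number of symbols.
#' @param seed Integer seed.
#' @param include Character vector of symbols guaranteed to be present
#'   (counted toward `n`).
#' @return Character vector of `n` unique symbols.
#' @examples
#' gen_gene_universe(5, seed = 3)
#' @export
gen_gene_universe <- function(n, seed = 1L, include = character(0)) {
  n <- check_count(n, "n")
  include <- unique(toupper(trimws(include)))
  if (length(include) > n)
    stop("`include` has more symbols than `n`", call. = FALSE)
  if (n == 0L) return(character(0))
  with_local_seed(seed, {
    pool <- sprintf("G%06d", seq_len(max(2L * n, 10L)))
    out <- c(include, sample(setdiff(pool, include), n - length(include)))
    sample(out)  # shuffle so injected symbols sit at random positions
  })
}

#' Generate two sourced compound-target association tables
#'
#' Emulates the output of two independent target-prediction services
#' queried with the same compound structures (sources tagged `"A"` and
#' `"B"`). The pooled target sets of the two sources are constructed so
#' their Jaccard index matches `overlap` (realized value within 0.1);
#' each compound then draws a per-source target count uniformly from
#' `per_source_range`.
#'
#' Planted structure for downstream tests:
#' * `orphan_compounds` receive targets private to a single source, so
#'   they never appear in the cross-source intersection (they become the
#'   disconnected metabolites of the compound-target network);
#' * `top_compound`, when given, is linked to every pooled target of both
#'   sources, making it the highest-degree compound;
#' * `force_shared` symbols are guaranteed members of both pooled sets;
#' * every non-orphan compound draws at least one shared target.
#'
#' @param compounds Character vector of compound ids.
#' @param universe Gene universe the targets are drawn from.
#' @param per_source_range Length-2 integer range of targets per compound
#'   per source.
#' @param overlap Requested Jaccard index of the two pooled target sets.
#' @param seed Integer seed.
#' @param orphan_compounds Compound ids planted with single-source-only
#'   targets.
#' @param top_compound Optional compound id planted as the best-connected.
#' @param force_shared Symbols forced into the shared region.
#' @return A list with data frames `A` and `B`, each with columns
#'   `compound_id`, `gene_symbol`, `source`.
#' @export
gen_associations <- function(compounds, universe,
                             per_source_range = c(5L, 30L),
                             overlap = 0.5, seed = 1L,
                             orphan_compounds = character(0),
                             top_compound = NULL,
                             force_shared = character(0)) {
  overlap <- check_fraction(overlap, "overlap")
  stopifnot(length(per_source_range) == 2L, per_source_range[1] >= 1L,
            per_source_range[1] <= per_source_range[2])
  if (length(universe) == 0L && length(compounds) > 0L)
    stop("`universe` must be non-empty", call. = FALSE)
  if (!all(orphan_compounds %in% compounds))
    stop("orphan_compounds must be a subset of compounds", call. = FALSE)
  force_shared <- intersect(unique(toupper(force_shared)), universe)

  with_local_seed(seed, {
    linked <- setdiff(compounds, orphan_compounds)
    n_orp <- length(orphan_compounds)
    per_orphan <- min(per_source_range[2], 5L)
    orp_need <- per_orphan * n_orp
    # pooled set sizes: enough genes to serve the per-compound draws
    m <- min(max(per_source_range[2] * 2L, length(linked) * 2L),
             max(1L, floor(length(universe) / 3)))
    # orphan-private genes enlarge the pooled union; size the shared
    # region so the realized Jaccard still matches the request
    s <- round(overlap * (2 * m + 2 * orp_need) / (1 + overlap))
    s <- min(max(s, length(force_shared)), m)

    shared <- unique(c(force_shared,
                       sample(setdiff(universe, force_shared),
                              max(0L, s - length(force_shared)))))
    rest <- setdiff(universe, shared)
    a_only <- if (m - s > 0) sample(rest, min(m - s, length(rest))) else character(0)
    rest <- setdiff(rest, a_only)
    b_only <- if (m - s > 0) sample(rest, min(m - s, length(rest))) else character(0)
    rest <- setdiff(rest, b_only)

    pool_a <- c(shared, a_only)
    pool_b <- c(shared, b_only)
    # orphan pools: one fixed private slice per orphan per source, kept
    # outside both pooled sets so orphans never reach the intersection
    if (n_orp > 0L && length(rest) < 2L * orp_need)
      stop("universe too small for the requested orphan compounds", call. = FALSE)
    orp_a <- if (n_orp) sample(rest, orp_need) else character(0)
    orp_b <- if (n_orp) sample(setdiff(rest, orp_a), orp_need) else character(0)

    draw_source <- function(tag, pool, orp_pool) {
      rows <- lapply(compounds, function(cid) {
        k <- sample(per_source_range[1]:per_source_range[2], 1L)
        genes <- if (cid %in% orphan_compounds) {
          i <- match(cid, orphan_compounds)
          orp_pool[seq.int((i - 1L) * per_orphan + 1L, i * per_orphan)]
        } else if (!is.null(top_compound) && cid == top_compound) {
          pool
        } else {
          # at least one shared target so the compound can reach the
          # cross-source intersection (when a shared region exists)
          anchor <- if (length(shared)) sample(shared, 1L) else character(0)
          unique(c(anchor, sample(pool, min(k, length(pool)))))
        }
        data.frame(compound_id = cid, gene_symbol = genes, source = tag,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      # make sure the full pool is realized so the pooled Jaccard is exact
      missing <- setdiff(pool, df$gene_symbol)
      if (length(missing) && length(linked)) {
        df <- rbind(df, data.frame(
          compound_id = sample(linked, length(missing), replace = TRUE),
          gene_symbol = missing, source = tag, stringsAsFactors = FALSE))
      }
      unique(df[order(df$compound_id, df$gene_symbol), ])
    }

    list(A = draw_source("A", pool_a, orp_a),
         B = draw_source("B", pool_b, orp_b))
  })
}

#' Generate three sourced disease gene lists
#'
#' Emulates disease-gene exports from three curated databases. The union
#' of the three lists intersects `compound_targets` in exactly
#' `hit_overlap` symbols (the planted "common targets"); all filler genes
#' are drawn outside `compound_targets` so the intersection is exact.
#'
#' @param universe Gene universe.
#' @param sizes Integer vector of three list sizes.
#' @param hit_overlap Exact size of the intersection with
#'   `compound_targets`.
#' @param compound_targets Symbols the planted hits are drawn from.
#' @param seed Integer seed.
#' @param hits Optional explicit hit set (length `hit_overlap`, subset of
#'   `compound_targets`); sampled when `NULL`.
#' @return A list of three data frames (`gene_symbol`, `source`) with
#'   sources `"DisGeNET"`, `"OMIM"`, `"MalaCards"`.
#' @export
gen_disease_sets <- function(universe, sizes, hit_overlap, compound_targets,
                             seed = 1L, hits = NULL) {
  hit_overlap <- check_count(hit_overlap, "hit_overlap")
  sizes <- vapply(sizes, check_count, integer(1), name = "sizes")
  if (length(sizes) != 3L) stop("`sizes` must have length 3", call. = FALSE)
  if (hit_overlap > length(compound_targets))
    stop("hit_overlap exceeds |compound_targets|", call. = FALSE)
  if (any(sizes > length(universe)))
    stop("list sizes exceed the universe", call. = FALSE)
  if (!is.null(hits)) {
    hits <- unique(hits)
    if (length(hits) != hit_overlap || !all(hits %in% compound_targets))
      stop("`hits` must be `hit_overlap` symbols from `compound_targets`",
           call. = FALSE)
  }
  sources <- c("DisGeNET", "OMIM", "MalaCards")
  with_local_seed(seed, {
    if (is.null(hits))
      hits <- sample(compound_targets, hit_overlap)
    filler_pool <- setdiff(universe, compound_targets)
    assign_to <- rep_len(seq_len(3L), length(hits))   # round-robin
    out <- lapply(seq_len(3L), function(i) {
      mine <- hits[assign_to == i]
      need <- sizes[i] - length(mine)
      if (need < 0L)
        stop("size of list ", i, " too small for its planted hits", call. = FALSE)
      if (need > length(filler_pool))
        stop("universe too small to fill disease list ", i, call. = FALSE)
      genes <- sort(c(mine, sample(filler_pool, need)))
      data.frame(gene_symbol = genes, source = sources[i],
                 stringsAsFactors = FALSE)
    })
    names(out) <- sources
    out
  })
}
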