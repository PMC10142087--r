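#' Normalize gene symbols
#'
#' Uppercases, trims whitespace, drops empty strings, deduplicates, and
#' returns the symbols in sorted order (deterministic iteration).
#' Idempotent.
#'
#' @param raw Character vector of raw symbols.
#' @return Sorted character vector of unique normalized symbols.
#' @examples
#' normalize_symbols(c("tlr4", " TLR4", "Egfr"))
#' @export
normalize_symbols <- function(raw) {
  if (!length(raw)) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  sort(unique(x[x != "" & !is.na(x)]))
}

#' Intersect two compound-target sources
#'
#' Two-set Venn analysis of the pooled target sets of two prediction
#' sources (e.g. two structure-based target databases queried with the
#' same compounds). Region counts always satisfy
#' `A_only + B_only + common = |A U B|`.
#'
#' @param sea,stp Character vectors of (already normalized) gene symbols
#'   from the two sources.
#' @return A list with `common` (sorted intersection) and `venn`
#'   (named counts: `A_only`, `B_only`, `common`, `union`).
#' @export
intersect_compound_sources <- function(sea, stp) {
  a <- normalize_symbols(sea)
  b <- normalize_symbols(stp)
  common <- intersect(a, b)
  list(common = sort(common),
       venn = c(A_only = length(setdiff(a, b)),
                B_only = length(setdiff(b, a)),
                common = length(common),
                union = length(union(a, b))))
}

#' Union of three disease-gene sources
#'
#' Pools three provenance-tagged disease gene lists, retaining per-source
#' membership for reporting.
#'
#' @param ... Two or more data frames with columns `gene_symbol`,
#'   `source` (as produced by [gen_disease_sets()]), or plain character
#'   vectors.
#' @return A list with `genes` (sorted union) and `provenance` (data
#'   frame `gene_symbol`, `source`, one row per source membership).
#' @export
union_disease_sources <- function(...) {
  inputs <- list(...)
  prov <- do.call(rbind, lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.data.frame(x)) {
      data.frame(gene_symbol = normalize_one(x$gene_symbol),
                 source = as.character(x$source),
                 stringsAsFactors = FALSE)
    } else {
      x <- normalize_one(x)
      data.frame(gene_symbol = x,
                 source = rep(paste0("source", i), length(x)),
                 stringsAsFactors = FALSE)
    }
  }))
  prov <- unique(prov[prov$gene_symbol != "", ])
  prov <- prov[order(prov$gene_symbol, prov$source), ]
  rownames(prov) <- NULL
  list(genes = sort(unique(prov$gene_symbol)), provenance = prov)
}

# element-wise normalization that keeps vector length (for provenance rows)
normalize_one <- function(x) toupper(trimws(as.character(x)))

#' Common targets of compounds and disease
#'
#' Sorted intersection of the pooled compound-target set and the pooled
#' disease-gene set: the "common targets" the downstream network stages
#' operate on.
#'
#' @param compound_targets,disease_targets Character vectors of symbols.
#' @return Sorted character vector.
#' @export
common_disease_targets <- function(compound_targets, disease_targets) {
  sort(intersect(normalize_symbols(compound_targets),
                 normalize_symbols(disease_targets)))
}

#' Per-compound connectivity into the common target set
#'
#' Counts, for every compound, its distinct links into the common target
#' set; duplicate (compound, gene) pairs across sources collapse to one
#' link before counting. Compounds with zero links are reported as
#' orphans.
#'
#' @param associations Data frame with columns `compound_id`,
#'   `gene_symbol` (extra columns ignored).
#' @param common Character vector: the common target set.
#' @param compounds Optional character vector of all screened compound
#'   ids. When given, association rows referencing unknown compounds are
#'   an error, and compounds absent from `associations` count as orphans.
#' @return A list with `counts` (data frame `compound_id`,
#'   `n_common_targets`) and `orphans` (character vector).
#' @export
compound_connectivity <- function(associations, common, compounds = NULL) {
  stopifnot(is.data.frame(associations))
  assoc <- unique(data.frame(
    compound_id = as.character(associations$compound_id),
    gene_symbol = normalize_one(associations$gene_symbol),
    stringsAsFactors = FALSE))
  if (!is.null(compounds)) {
    unknown <- setdiff(assoc$compound_id, compounds)
    if (length(unknown))
      stop("associations reference unknown compounds: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  } else {
    compounds <- sort(unique(assoc$compound_id))
  }
  hits <- assoc[assoc$gene_symbol %in% common, , drop = FALSE]
  tab <- table(factor(hits$compound_id, levels = sort(unique(compounds))))
  counts <- data.frame(compound_id = names(tab),
                       n_common_targets = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(counts = counts,
       orphans = counts$compound_id[counts$n_common_targets == 0L])
}
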