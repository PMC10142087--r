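#' Default pipeline configuration
#'
#' Every screening and network threshold is a named key with its
#' conventional value: Lipinski gate (at most one violation,
#' bioavailability > 0.50), STRING medium confidence 0.400, enrichment
#' alpha 0.05, top-3 hub consensus, -8 kcal/mol strong-binder cutoff,
#' 0.5 kcal/mol comparable margin. The synthetic block describes the
#' study-shaped generator conditions: 27 compounds (6 of them planted
#' without disease-relevant targets), a 2000-gene universe, 42 planted
#' common targets, a planted hub named TLR4, and a fold-5 planted
#' pathway term.
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    mushroom = "W.extensa",
    min_confidence = 0.400,
    alpha = 0.05,
    consensus_k = 3L,
    strong_threshold = -8,
    comparable_margin = 0.5,
    synthetic = list(
      n_compounds = 27L,
      frac_violators = 0,
      n_orphans = 6L,
      n_genes = 2000L,
      per_source_range = c(5L, 30L),
      assoc_overlap = 0.5,
      disease_sizes = c(600L, 450L, 350L),
      hit_overlap = 42L,
      planted_hub = "TLR4",
      clique_sizes = c(5L, 4L, 3L),
      background_edge_prob = 0.2,
      hub_coverage = 0.85,
      n_terms = 50L,
      term_size_range = c(50L, 400L),
      planted_term = "HIF-1 signaling pathway",
      planted_term_fold = 5
    )
  )
}

#' Read a pipeline configuration file
#'
#' Loads a YAML configuration and merges it over [default_config()]
#' (file keys win; missing keys keep their defaults).
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Select the planted common-target set: a hitting set over the shared
# compound-target pool that covers every connected compound (so the
# compound-target network keeps all non-orphan compounds), force-includes
# the planted hub, then fills to the requested size at random.
plant_common_targets <- function(assoc_pool, shared_pool, n_hits, hub, seed) {
  with_local_seed(seed, {
    hits <- character(0)
    if (!is.null(hub) && hub %in% shared_pool) hits <- hub
    per_comp <- split(assoc_pool$gene_symbol, assoc_pool$compound_id)
    for (genes in per_comp) {
      genes <- intersect(genes, shared_pool)
      if (length(genes) && !any(genes %in% hits))
        hits <- c(hits, sample(genes, 1L))
    }
    if (length(hits) > n_hits)
      stop("hit_overlap too small to cover every connected compound",
           call. = FALSE)
    extra <- setdiff(shared_pool, hits)
    hits <- c(hits, sample(extra, n_hits - length(hits)))
    sort(hits)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the end-to-end workflow — compound screening, compound- and
#' disease-target extraction and Venn algebra, PPI construction and hub
#' ranking by MCC/MNC/Degree, mushroom-compound-target assembly,
#' pathway/GO-style enrichment, frontier-orbital reactivity, and
#' docking-score comparison — on seeded synthetic inputs (or files
#' supplied under `config$inputs`). Each stage runs inside an error
#' wrapper so failures abort with the stage name; stage outputs, a JSON
#' summary and a checksum manifest are written when `outdir` is given.
#'
#' @param config Configuration list (see [default_config()]); file paths
#'   under `config$inputs` (`ppi_edges`, `orbitals`, `docking`) override
#'   the corresponding generators.
#' @param seed Integer seed driving every generator.
#' @param outdir Optional output directory.
#' @return A list with per-stage results and a `summary` naming the key
#'   targets, key compound and top pathway.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         outdir = NULL) {
  seed <- check_count(seed, "seed")
  syn <- config$synthetic
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  compounds <- stage("compounds", gen_compounds(
    syn$n_compounds, syn$frac_violators, seed = seed))
  scr <- stage("screen", screen_compounds(compounds))
  retained <- scr$retained

  universe <- stage("universe", gen_gene_universe(
    syn$n_genes, seed = seed + 1L, include = syn$planted_hub))

  orphans <- utils::tail(retained$id, syn$n_orphans)
  assoc <- stage("associations", gen_associations(
    retained$id, universe, syn$per_source_range, syn$assoc_overlap,
    seed = seed + 2L, orphan_compounds = orphans,
    top_compound = retained$id[1], force_shared = syn$planted_hub))
  pooled <- stage("compound_targets", intersect_compound_sources(
    assoc$A$gene_symbol, assoc$B$gene_symbol))

  assoc_all <- rbind(assoc$A, assoc$B)
  hits <- stage("plant_common", plant_common_targets(
    assoc_all[!assoc_all$compound_id %in% orphans, ],
    pooled$common, syn$hit_overlap, syn$planted_hub, seed + 3L))
  disease <- stage("disease_sets", gen_disease_sets(
    universe, syn$disease_sizes, syn$hit_overlap, pooled$common,
    seed = seed + 4L, hits = hits))
  disease_union <- stage("disease_union", do.call(
    union_disease_sources, unname(disease)))
  common <- stage("common_targets", common_disease_targets(
    pooled$common, disease_union$genes))

  connectivity <- stage("connectivity", compound_connectivity(
    assoc_all, common, compounds = retained$id))

  hub <- if (!is.null(syn$planted_hub) && syn$planted_hub %in% common)
    syn$planted_hub else common[1]
  ppi_edges <- stage("ppi_edges", {
    if (!is.null(config$inputs$ppi_edges))
      read_string_tsv(config$inputs$ppi_edges)
    else
      gen_ppi(common, hub, syn$clique_sizes, syn$background_edge_prob,
              seed = seed + 5L, hub_coverage = syn$hub_coverage)
  })
  net <- stage("ppi_network", load_interaction_table(
    ppi_edges, config$min_confidence, keep_nodes = common))
  stats <- stage("network_stats", network_stats(net))
  rankings <- stage("hub_ranking", lapply(
    c(MCC = "MCC", MNC = "MNC", Degree = "Degree"),
    function(m) rank_nodes(net, m, k = min(10L, length(common)))))
  consensus <- stage("consensus", consensus_top(rankings, config$consensus_k))

  mct <- stage("mct", build_mct(config$mushroom, assoc_all, common))
  mct_n <- mct_counts(mct)
  top_cmp <- stage("top_compounds", top_compounds_by_degree(mct, k = 5L))

  pathways <- stage("annotations", gen_annotations(
    universe, syn$n_terms, syn$term_size_range, syn$planted_term,
    query = common, fold = syn$planted_term_fold, seed = seed + 6L))
  enr <- stage("enrichment", enrich(common, pathways, universe,
                                    alpha = config$alpha,
                                    category = "pathway"))
  bubbles <- stage("bubble_table", bubble_table(enr))
  top_pathway <- if (nrow(bubbles)) enr$term[1] else NA_character_

  orbitals <- stage("orbitals", {
    if (!is.null(config$inputs$orbitals))
      read_orbitals_csv(config$inputs$orbitals)
    else
      gen_orbitals(top_cmp$compound_id, seed = seed + 7L,
                   key_id = top_cmp$compound_id[1])
  })
  reactivity <- stage("reactivity", reactivity_report(
    orbitals, standard_orbitals()))

  docking <- stage("docking", {
    if (!is.null(config$inputs$docking))
      read_docking_csv(config$inputs$docking)
    else
      gen_docking(seed = seed + 8L)
  })
  dock_cmp <- stage("docking_comparison", compare_docking_scores(
    docking, strong_threshold = config$strong_threshold,
    comparable_margin = config$comparable_margin))

  summary <- list(
    seed = seed,
    n_compounds = nrow(compounds),
    n_screened = scr$report$n_retained,
    n_compound_targets = length(pooled$common),
    n_disease_targets = length(disease_union$genes),
    n_common_targets = length(common),
    n_connected_compounds = sum(connectivity$counts$n_common_targets > 0L),
    n_orphan_compounds = length(connectivity$orphans),
    avg_neighbors = stats$avg_neighbors,
    key_targets = consensus,
    key_compound = top_cmp$compound_id[1],
    mct_nodes = mct_n$nodes,
    mct_edges = mct_n$edges,
    top_pathway = top_pathway,
    n_significant_pathways = sum(enr$significant),
    key_compound_hardness = reactivity$hardness[
      reactivity$role == "candidate"][1],
    docking = stats::setNames(dock_cmp$classification,
                              paste(dock_cmp$ligand, dock_cmp$target))
  )

  result <- list(compounds = compounds, screen_report = scr$report,
                 associations = assoc, compound_targets = pooled,
                 disease = disease_union, common_targets = common,
                 connectivity = connectivity, ppi_edges = ppi_edges,
                 network = net, network_stats = stats,
                 rankings = rankings, consensus = consensus,
                 mct = mct, mct_counts = mct_n, top_compounds = top_cmp,
                 enrichment = enr, bubble_table = bubbles,
                 reactivity = reactivity, docking = dock_cmp,
                 summary = summary)
  if (!is.null(outdir)) write_pipeline_outputs(result, config, outdir)
  result
}

# Per-stage TSV/CSV/JSON outputs plus a checksum manifest, so re-runs
# with the same config and seed can be verified byte-for-byte.
write_pipeline_outputs <- function(result, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  utils::write.csv(result$compounds, p("compounds.csv"), row.names = FALSE)
  write_tsv_file(rbind(result$associations$A, result$associations$B),
                 p("associations.tsv"))
  write_tsv_file(data.frame(gene_symbol = result$common_targets),
                 p("common_targets.tsv"))
  write_tsv_file(result$ppi_edges, p("ppi_edges.tsv"))
  write_tsv_file(do.call(rbind, result$rankings), p("hub_rankings.tsv"))
  write_tsv_file(result$mct$nodes, p("mct_nodes.tsv"))
  write_tsv_file(result$mct$edges, p("mct_edges.tsv"))
  write_tsv_file(result$enrichment, p("enrichment.tsv"))
  utils::write.csv(result$bubble_table, p("bubble_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$reactivity, p("reactivity.csv"), row.names = FALSE)
  utils::write.csv(result$docking, p("docking_comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    seed = result$summary$seed,
    config = config[setdiff(names(config), "inputs")],
    package_version = as.character(utils::packageVersion("netpharm")),
    checksums = as.list(tools::md5sum(file.path(outdir, sort(files))))
  )
  names(manifest$checksums) <- sort(files)
  jsonlite::write_json(manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
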