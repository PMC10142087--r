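#' Write every synthetic pipeline input to disk
#'
#' Generates the full set of study-shaped synthetic inputs under one
#' seed and writes them in their interchange formats: compound table
#' (CSV), two compound-target association tables (TSV), three disease
#' gene lists (TSV), a STRING-dialect scored edge list (TSV), an
#' annotation collection (GMT), orbital energies (CSV) and docking
#' scores (CSV). Identical `(config, seed)` calls produce byte-identical
#' files.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
synth_write_all <- function(config = default_config(), seed = 1L, outdir) {
  res <- run_pipeline(config, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  utils::write.csv(res$compounds, p("compounds.csv"), row.names = FALSE)
  write_tsv_file(res$associations$A, p("associations_A.tsv"))
  write_tsv_file(res$associations$B, p("associations_B.tsv"))
  syn <- config$synthetic
  disease <- gen_disease_sets(
    gen_gene_universe(syn$n_genes, seed = seed + 1L,
                      include = syn$planted_hub),
    syn$disease_sizes, syn$hit_overlap, res$compound_targets$common,
    seed = seed + 4L,
    hits = intersect(res$common_targets, res$compound_targets$common))
  for (i in seq_along(disease))
    write_tsv_file(disease[[i]],
                   p(sprintf("disease_%s.tsv", tolower(names(disease)[i]))))
  write_tsv_file(res$ppi_edges, p("ppi_edges.tsv"))
  pathways <- gen_annotations(
    gen_gene_universe(syn$n_genes, seed = seed + 1L,
                      include = syn$planted_hub),
    syn$n_terms, syn$term_size_range, syn$planted_term,
    query = res$common_targets, fold = syn$planted_term_fold,
    seed = seed + 6L)
  write_gmt(pathways, p("pathways.gmt"))
  utils::write.csv(gen_orbitals(res$top_compounds$compound_id,
                                seed = seed + 7L,
                                key_id = res$top_compounds$compound_id[1]),
                   p("orbitals.csv"), row.names = FALSE)
  utils::write.csv(gen_docking(seed = seed + 8L), p("docking.csv"),
                   row.names = FALSE)
  invisible(list.files(outdir, full.names = TRUE))
}
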