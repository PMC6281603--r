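# Run the whole pipeline on a synthetic dataset; heavyweight results for
# the default configuration are cached for reuse across test files.
run_pipeline <- function(config = sim_config(), dir = tempfile("simrun"),
                         min_egenes = 4) {
  sim <- sim_dataset(config, dir)
  genes <- collapse_gene_model(sim$paths$gtf)
  snps <- dplyr::distinct(sim$gwas, rsid, chrom, pos)
  pairs <- find_spatial_pairs(
    read_interaction_set(sim$interaction_files),
    assign_snps_to_fragments(snps, sim$fragments),
    assign_genes_to_fragments(genes, sim$fragments)
  )
  assoc <- call_spatial_eqtls(pairs, sim$eqtl, snps = snps, genes = genes)
  sig <- filter_significant(assoc)
  sets <- filter_min_egenes(build_phenotype_sets(sim$gwas, sig),
                            min_count = min_egenes)
  list(sim = sim, genes = genes, snps = snps, pairs = pairs,
       assoc = assoc, sig = sig, sets = sets,
       M = share_matrix(sets))
}

.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (!exists("run", envir = .pipeline_cache)) {
    assign("run", run_pipeline(sim_config(seed = 1)),
           envir = .pipeline_cache)
  }
  get("run", envir = .pipeline_cache)
}

# A small, fast configuration for determinism and IO tests.
small_config <- function(seed = 11L, background_interactions = 20L, ...) {
  sim_config(
    seed = seed,
    n_chromosomes = 2L,
    chromosome_length = 30000L,
    site_spacing_mean = 500,
    n_genes_per_chromosome = 6L,
    n_traits = 4L,
    n_planted_clusters = 2L,
    core_locus_size = 2L,
    private_egenes_per_trait = 1L,
    background_interactions = background_interactions,
    ...
  )
}
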