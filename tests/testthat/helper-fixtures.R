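# Shared fixtures. The default study-scale genome (2 Mb, 1000 genes) is
# built once and reused across test files; cohorts are re-simulated per
# seed against it.

no_planted <- function() {
  data.frame(gene_id = character(0), selection_prob = numeric(0),
             orientation_bias = numeric(0))
}

write_tiny_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]])
  })), path)
  path
}

# A small, fast simulation setting for unit tests (no planted drivers
# unless a test asks for them).
small_config <- function(seed = 7, ...) {
  defaults <- list(seed = seed, n_chroms = 3, chrom_length = 60000,
                   n_genes = 30, gene_length = 1400, donor_pos = 30000,
                   n_tumors = 4, background_insertions_per_tumor = 40,
                   planted_drivers = no_planted())
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}

small_world <- function(seed = 7, ...) {
  cfg <- small_config(seed = seed, ...)
  gen <- simulate_genome(cfg)
  idx <- build_ta_index(gen$genome)
  genes <- load_gene_models(gen$genes, idx)
  list(cfg = cfg, genome = gen$genome, idx = idx, genes = genes)
}

# Memoized default-scale genome shared by calibration/recovery suites.
.world_cache <- new.env(parent = emptyenv())
default_world <- function() {
  if (is.null(.world_cache$world)) {
    cfg <- sim_config(seed = 1)
    gen <- simulate_genome(cfg)
    idx <- build_ta_index(gen$genome)
    genes <- load_gene_models(gen$genes, idx)
    .world_cache$world <- list(cfg = cfg, genome = gen$genome, idx = idx,
                               genes = genes)
  }
  .world_cache$world
}
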