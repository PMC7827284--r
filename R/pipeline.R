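# End-to-end pipeline runner: ingest (or simulate) -> donor inference and
# filtering -> per-gene collapse -> driver tiers -> enrichment -> reports,
# with a machine-readable run manifest.

#' Run the full SB driver analysis pipeline
#'
#' The configuration is a YAML (or list) with either a \code{simulate}
#' block (overrides for \code{\link{sim_config}}) or an \code{inputs} block
#' (\code{genome}, \code{annotation}, \code{insertions} file paths), plus
#' optional analysis settings: \code{donor} ("auto", a chromosome name, or
#' "none"), \code{alpha}, \code{trunk_min_reads}, \code{min_tumors},
#' \code{allele_mode}, \code{oncoprint_tier} (which tier to export), and an
#' \code{enrichment} block (\code{curated_lists}: named list-file paths;
#' drivers of the discovery tier are tested against each over the universe
#' of all testable genes).
#'
#' All randomness derives from \code{seed} in the configuration, so a fixed
#' configuration reproduces an identical result bundle.
#'
#' @param config YAML file path or an equivalent named list.
#' @param out_dir Output directory (created if needed); overrides
#'   \code{config$out_dir}.
#' @return Invisibly, the result bundle: index, genes, insertions, donor
#'   call, matrix, drivers, enrichment tables and the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  trunk_min_reads <- config$trunk_min_reads %||% 100
  min_tumors <- config$min_tumors %||% 3
  allele_mode <- config$allele_mode %||% "gene_trap_only"
  donor_mode <- config$donor %||% "auto"

  manifest <- list(package = "sbdriver",
                   version = as.character(packageVersion("sbdriver")),
                   seed = seed,
                   settings = list(alpha = alpha,
                                   trunk_min_reads = trunk_min_reads,
                                   min_tumors = min_tumors,
                                   allele_mode = allele_mode,
                                   donor = donor_mode))

  tumors <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    if (!is.null(sim_args$planted_drivers)) {
      sim_args$planted_drivers <-
        do.call(rbind, lapply(sim_args$planted_drivers, as.data.frame))
    }
    cfg <- do.call(sim_config, sim_args)
    gen <- simulate_genome(cfg)
    index <- build_ta_index(gen$genome)
    genes <- load_gene_models(gen$genes, index)
    cohort <- simulate_cohort(cfg, index, genes)
    insertions <- cohort$insertions
    tumors <- cohort$tumors
    truth <- cohort$truth
    Biostrings::writeXStringSet(gen$genome, file.path(out_dir, "genome.fa"))
    write_gene_models(genes, file.path(out_dir, "annotation.bed"))
    write_insertions(insertions, file.path(out_dir, "insertions.bed"))
    manifest$inputs <- list(mode = "simulation",
                            n_tumors = cfg$n_tumors,
                            planted_drivers = cfg$planted_drivers$gene_id)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c("genome", "annotation", "insertions")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop("missing input file: ", f, call. = FALSE)
      }
    }
    index <- build_ta_index(inp$genome)
    genes <- load_gene_models(inp$annotation, index)
    insertions <- parse_insertions(inp$insertions)
    manifest$inputs <- list(mode = "files", files = inp)
  } else {
    stop("config needs a 'simulate' or 'inputs' block", call. = FALSE)
  }

  # insertions must sit on indexed TA sites
  bad <- vapply(seq_len(nrow(insertions)), function(i) {
    !insertions$pos[i] %in% index$sites[[insertions$chrom[i]]]
  }, logical(1))
  if (any(bad)) {
    stop(sum(bad), " insertion(s) not at an indexed TA site ",
         "(genome/insertion mismatch)", call. = FALSE)
  }

  if (identical(donor_mode, "auto")) {
    donor_call <- infer_donor_chromosome(insertions, index)
    donor <- donor_call$donor
  } else if (identical(donor_mode, "none")) {
    donor_call <- NULL
    donor <- NA_character_
  } else {
    donor_call <- NULL
    donor <- donor_mode
  }
  kept <- if (is.na(donor)) insertions else filter_donor(insertions, donor)
  matrix <- assign_and_collapse(kept, genes, tumors = tumors)
  drivers <- call_drivers(matrix, genes, index, donor, alpha = alpha,
                          trunk_min_reads = trunk_min_reads,
                          min_tumors = min_tumors,
                          allele_mode = allele_mode)
  write_driver_results(drivers, file.path(out_dir, "drivers.tsv"))
  write_cohort_matrix(matrix, file.path(out_dir, "cohort_matrix.tsv"))

  tier <- config$oncoprint_tier %||% "trunk"
  tier_genes <- drivers$gene_id[drivers[[tier]]]
  if (length(tier_genes)) {
    oncoprint_export(matrix, tier_genes,
                     file.path(out_dir, "oncoprint.tsv"))
  }

  enrich <- NULL
  if (!is.null(config$enrichment)) {
    universe <- genes$gene_id[genes$testable &
                                (is.na(donor) | genes$chrom != donor)]
    called <- drivers$gene_id[drivers$discovery]
    enrich <- lapply(config$enrichment$curated_lists, function(p) {
      lst <- read_gene_list(p)
      tryCatch(overlap_enrichment(called, lst, universe),
               error = function(e) {
                 warning("enrichment skipped for ", p, ": ",
                         conditionMessage(e), call. = FALSE)
                 list(error = conditionMessage(e))
               })
    })
    manifest$enrichment <- lapply(enrich, function(e) {
      if (!is.null(e$error)) return(list(error = e$error))
      e[c("a", "b", "c", "d", "universe_n", "chi2", "p_two_tailed",
          "direction")]
    })
  }

  manifest$counts <- list(
    parsed = nrow(insertions),
    donor_filtered = nrow(insertions) - nrow(kept),
    kept = nrow(kept),
    assigned = unname(matrix$ledger["assigned"]),
    intergenic = unname(matrix$ledger["intergenic"]))
  manifest$donor <- list(chromosome = donor,
                         tie = if (!is.null(donor_call)) donor_call$tie)
  manifest$results <- list(
    tested_genes = nrow(drivers),
    discovery = sum(drivers$discovery),
    progression_genome = sum(drivers$progression_genome),
    trunk = sum(drivers$trunk),
    discovery_genes = drivers$gene_id[drivers$discovery],
    trunk_genes = drivers$gene_id[drivers$trunk])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(index = index, genes = genes, insertions = insertions,
                 donor = donor, donor_call = donor_call, matrix = matrix,
                 drivers = drivers, enrichment = enrich, truth = truth,
                 manifest = manifest))
}
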