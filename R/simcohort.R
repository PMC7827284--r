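# Synthetic SB screen generator.
#
# Emulates the data-generating process the analysis assumes: a toy genome
# with a tunable TA density, non-overlapping gene footprints, per-tumor
# insertion profiles mixing (a) local hopping around the donor concatemer
# locus, (b) uniform background over genomic TA sites, and (c) planted
# driver genes receiving clonal, high-read-depth insertions, plus optional
# raw junction reads carrying the transposon IRDR motif.

# Terminal transposon sequence used as the junction motif on simulated reads.
SB_IRDR_MOTIF <- "GTGTATGTAAACTTCCGACTTCAACTG"

#' Configuration of a synthetic SB cohort
#'
#' The defaults describe a compact but structurally faithful screen: a 2 Mb
#' genome over 4 chromosomes tiled with 1000 genes, a donor concatemer locus
#' mid-chromosome-1 whose local hopping contributes half of each tumor's
#' insertions, 30 tumors with a mean burden of 250 background clonotypes,
#' and three planted tumor suppressor drivers of decreasing penetrance.
#' Clonal (selected) insertions draw read depths from a shifted negative
#' binomial with all mass at >= 100 reads; background insertions draw from a
#' geometric with mass concentrated at 1 read, mirroring the operational
#' clonal/background split of SBCapSeq read depths.
#'
#' @param seed Integer master seed; genome, cohort and read generation use
#'   independent streams derived from it.
#' @param n_chroms,chrom_length Genome shape (chromosomes are named
#'   \code{chr1..chrN}).
#' @param gc_ta_density Target TA sites per base (max 0.25; 0.0625 is the
#'   uniform-composition expectation).
#' @param n_genes,gene_length Genes tiled evenly and without overlap across
#'   chromosomes, alternating strand.
#' @param donor_chrom,donor_pos Donor concatemer locus.
#' @param hop_fraction Fraction of each tumor's non-selected insertions drawn
#'   from the local-hopping kernel (geometric distance decay around
#'   \code{donor_pos}, mapped to the nearest TA site on the donor chromosome).
#' @param hop_decay Per-base geometric decay rate of hop distance
#'   (1e-4 = 10 kb mean hop).
#' @param n_tumors Number of tumors.
#' @param background_insertions_per_tumor Poisson mean of per-tumor
#'   non-selected insertion counts.
#' @param planted_drivers Data frame with columns \code{gene_id},
#'   \code{selection_prob} (per-tumor probability of a clonal insertion) and
#'   \code{orientation_bias} (probability the insertion is '+'-oriented);
#'   may have zero rows for a null cohort.
#' @param clonal_min,clonal_mu,clonal_size Clonal read depth = clonal_min +
#'   NegBinom(size = clonal_size, mu = clonal_mu).
#' @param bg_geom_prob Background read depth = 1 + Geometric(bg_geom_prob).
#' @param irdr_motif Junction motif prepended to simulated reads.
#' @param flank_len Genomic flank length on simulated junction reads.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 500000L,
                       gc_ta_density = 0.0625,
                       n_genes = 1000L,
                       gene_length = 1400L,
                       donor_chrom = "chr1",
                       donor_pos = 250000L,
                       hop_fraction = 0.5,
                       hop_decay = 1e-4,
                       n_tumors = 30L,
                       background_insertions_per_tumor = 250,
                       planted_drivers = default_planted_drivers(),
                       clonal_min = 100L,
                       clonal_mu = 150,
                       clonal_size = 2,
                       bg_geom_prob = 0.5,
                       irdr_motif = SB_IRDR_MOTIF,
                       flank_len = 30L) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_chroms, "n_chroms", min = 1)
  assert_scalar_number(chrom_length, "chrom_length", min = 100)
  assert_scalar_number(gc_ta_density, "gc_ta_density", min = 0, max = 0.25)
  assert_scalar_number(hop_fraction, "hop_fraction", min = 0, max = 1)
  assert_scalar_number(hop_decay, "hop_decay", min = 1e-9, max = 1)
  assert_scalar_number(n_tumors, "n_tumors", min = 1)
  assert_scalar_number(background_insertions_per_tumor,
                       "background_insertions_per_tumor", min = 0)
  assert_scalar_number(bg_geom_prob, "bg_geom_prob", min = 1e-9, max = 1)
  assert_scalar_number(flank_len, "flank_len", min = 10)
  if (nchar(irdr_motif) < 12) stop("irdr_motif must be >= 12 bases")
  planted_drivers <- as.data.frame(planted_drivers)
  if (nrow(planted_drivers) > 0) {
    stopifnot(all(c("gene_id", "selection_prob", "orientation_bias") %in%
                    names(planted_drivers)))
    if (any(planted_drivers$selection_prob < 0 |
              planted_drivers$selection_prob > 1) ||
        any(planted_drivers$orientation_bias < 0 |
              planted_drivers$orientation_bias > 1)) {
      stop("planted driver probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_ta_density = gc_ta_density, n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              donor_chrom = donor_chrom, donor_pos = as.integer(donor_pos),
              hop_fraction = hop_fraction, hop_decay = hop_decay,
              n_tumors = as.integer(n_tumors),
              background_insertions_per_tumor = background_insertions_per_tumor,
              planted_drivers = planted_drivers,
              clonal_min = as.integer(clonal_min), clonal_mu = clonal_mu,
              clonal_size = clonal_size, bg_geom_prob = bg_geom_prob,
              irdr_motif = toupper(irdr_motif),
              flank_len = as.integer(flank_len))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_planted_drivers <- function() {
  data.frame(gene_id = c("G0375", "G0625", "G0875"),
             selection_prob = c(0.6, 0.5, 0.4),
             orientation_bias = c(0.5, 0.5, 0.5))
}

#' Simulate a toy reference genome and gene annotation
#'
#' Bases are drawn i.i.d. with P(T) = P(A) = sqrt(gc_ta_density) so the
#' expected TA-dinucleotide density matches the target; genes are tiled
#' evenly across chromosomes without overlap, alternating strand.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome} (a \code{DNAStringSet}) and \code{genes}
#'   (5-column annotation data frame: chrom, start, end, gene_id, strand).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q <- sqrt(config$gc_ta_density)
  probs <- c(q, q, (1 - 2 * q) / 2, (1 - 2 * q) / 2)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  # even split of genes over chromosomes
  gpc <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  slot <- floor(config$chrom_length / max(gpc, 1))
  if (max(gpc) > 0 && slot < config$gene_length + 20) {
    stop("chrom_length too small to place requested genes", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "genome"), {
    seqs <- vapply(chroms, function(ch) {
      paste(sample(c("T", "A", "C", "G"), config$chrom_length,
                   replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    if (gpc[ci] == 0) next
    offset <- floor((slot - config$gene_length) / 2)
    starts <- (seq_len(gpc[ci]) - 1L) * slot + offset
    ids <- sprintf("G%04d", gid + seq_len(gpc[ci]))
    rows[[ci]] <- data.frame(
      chrom = chroms[ci], start = as.integer(starts),
      end = as.integer(starts + config$gene_length), gene_id = ids,
      strand = rep_len(c("+", "-"), gpc[ci]))
    gid <- gid + gpc[ci]
  }
  list(genome = genome, genes = do.call(rbind, rows))
}

# Map positions to the nearest indexed TA site on one chromosome.
nearest_ta <- function(sites, pos) {
  i <- findInterval(pos, sites)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(sites))
  left <- sites[lo]
  right <- sites[hi]
  ifelse(abs(pos - left) <= abs(right - pos), left, right)
}

#' Simulate per-tumor SB insertion profiles
#'
#' Each tumor receives a Poisson number of non-selected insertions, split
#' between the local-hopping kernel on the donor chromosome and a uniform
#' draw over all genomic TA sites, plus (per planted driver, with its
#' selection probability) one clonal insertion at a uniformly chosen TA site
#' inside the gene footprint. Multiple events at the same TA site within a
#' tumor are merged keeping the deepest record, so each (tumor, site) pair
#' is one clonotype.
#'
#' @param config A \code{\link{sim_config}}.
#' @param index \code{TASiteIndex} of the simulated genome.
#' @param genes Gene models from \code{\link{load_gene_models}}.
#' @return List with \code{insertions} (data frame: tumor_id, chrom, pos,
#'   orientation, read_count), \code{truth} (list with \code{driver_hits},
#'   \code{background}, \code{donor_chrom}) and \code{tumors} (full roster).
#' @export
simulate_cohort <- function(config, index, genes) {
  stopifnot(inherits(config, "sim_config"), inherits(index, "TASiteIndex"))
  pd <- config$planted_drivers
  if (nrow(pd) > 0) {
    miss <- setdiff(pd$gene_id, genes$gene_id)
    if (length(miss)) {
      stop("planted gene(s) absent from annotation: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  gene_sites <- list()
  for (g in pd$gene_id) {
    row <- genes[genes$gene_id == g, , drop = FALSE][1, ]
    s <- index$sites[[row$chrom]]
    s <- s[s >= row$start & s < row$end]
    if (length(s) == 0) {
      stop("planted gene has zero TA sites (uninsertable): ", g,
           call. = FALSE)
    }
    gene_sites[[g]] <- list(chrom = row$chrom, sites = s)
  }
  all_chrom <- rep(names(index$sites), lengths(index$sites))
  all_pos <- unlist(index$sites, use.names = FALSE)
  if (length(all_pos) == 0) stop("index contains no TA sites", call. = FALSE)
  donor_sites <- index$sites[[config$donor_chrom]]
  tumors <- sprintf("T%03d", seq_len(config$n_tumors))

  recs <- with_seed(derive_seed(config$seed, "cohort"), {
    out <- vector("list", config$n_tumors)
    for (t in seq_len(config$n_tumors)) {
      tid <- tumors[t]
      n_bg <- rpois(1, config$background_insertions_per_tumor)
      n_hop <- rbinom(1, n_bg, config$hop_fraction)
      if (length(donor_sites) == 0) n_hop <- 0L
      n_unif <- n_bg - n_hop
      parts <- list()
      if (n_hop > 0) {
        d <- rgeom(n_hop, config$hop_decay) *
          sample(c(-1L, 1L), n_hop, replace = TRUE)
        target <- pmin(pmax(config$donor_pos + d, 0L),
                       config$chrom_length - 2L)
        parts$hop <- data.frame(
          chrom = config$donor_chrom,
          pos = nearest_ta(donor_sites, target),
          orientation = sample(c("+", "-"), n_hop, replace = TRUE),
          read_count = as.integer(1L + rgeom(n_hop, config$bg_geom_prob)),
          source = "background", gene_id = NA_character_)
      }
      if (n_unif > 0) {
        i <- sample.int(length(all_pos), n_unif, replace = TRUE)
        parts$unif <- data.frame(
          chrom = all_chrom[i], pos = all_pos[i],
          orientation = sample(c("+", "-"), n_unif, replace = TRUE),
          read_count = as.integer(1L + rgeom(n_unif, config$bg_geom_prob)),
          source = "background", gene_id = NA_character_)
      }
      if (nrow(pd) > 0) {
        hit <- runif(nrow(pd)) < pd$selection_prob
        if (any(hit)) {
          hits <- lapply(which(hit), function(j) {
            gs <- gene_sites[[pd$gene_id[j]]]
            data.frame(
              chrom = gs$chrom,
              pos = gs$sites[sample.int(length(gs$sites), 1)],
              orientation = if (runif(1) < pd$orientation_bias[j]) "+" else "-",
              read_count = as.integer(config$clonal_min +
                rnbinom(1, size = config$clonal_size,
                        mu = config$clonal_mu)),
              source = "driver", gene_id = pd$gene_id[j])
          })
          parts$driver <- do.call(rbind, hits)
        }
      }
      if (length(parts) == 0) next
      df <- do.call(rbind, parts)
      df$tumor_id <- tid
      # one clonotype per (tumor, site): keep the deepest record,
      # planted-driver records preferred on ties
      ord <- order(df$chrom, df$pos, -df$read_count,
                   df$source != "driver")
      df <- df[ord, ]
      df <- df[!duplicated(df[, c("chrom", "pos")]), ]
      out[[t]] <- df
    }
    out
  })
  recs <- do.call(rbind, recs)
  rownames(recs) <- NULL
  cols <- c("tumor_id", "chrom", "pos", "orientation", "read_count")
  list(
    insertions = recs[, cols],
    truth = list(driver_hits = recs[recs$source == "driver",
                                    c(cols, "gene_id")],
                 background = recs[recs$source == "background", cols],
                 donor_chrom = config$donor_chrom),
    tumors = tumors)
}

#' Write / read an insertion profile file
#'
#' Six tab-separated BED-like columns: chrom, start, end (= start + 2),
#' orientation, read_count, tumor_id; '#' lines are comments.
#'
#' @param insertions Insertion data frame (tumor_id, chrom, pos,
#'   orientation, read_count).
#' @param path Output path.
#' @export
write_insertions <- function(insertions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\torientation\tread_count\ttumor_id", con)
  df <- data.frame(chrom = insertions$chrom,
                   start = insertions$pos,
                   end = insertions$pos + 2L,
                   orientation = insertions$orientation,
                   read_count = insertions$read_count,
                   tumor_id = insertions$tumor_id)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate SBCapSeq-style junction reads for a cohort
#'
#' Each insertion yields \code{read_count} identical error-free reads of the
#' form [IRDR motif][genomic flank], the flank starting at the TA site and
#' reading into the genome on the insertion's strand ('-' reads report the
#' reverse-complement flank). Flanks running off a chromosome end are
#' truncated and flagged with a warning.
#'
#' @param insertions Insertion data frame.
#' @param genome \code{DNAStringSet} (or FASTA path).
#' @param config A \code{\link{sim_config}} (motif and flank length).
#' @param path Optional FASTQ output path.
#' @return A named \code{DNAStringSet} of reads (names
#'   \code{tumor:insertion:read}); written as FASTQ when \code{path} given.
#' @export
simulate_reads <- function(insertions, genome, config, path = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  n <- nrow(insertions)
  if (n == 0) {
    reads <- Biostrings::DNAStringSet()
  } else {
    if (any(grepl(":", insertions$tumor_id, fixed = TRUE))) {
      stop("tumor ids must not contain ':'", call. = FALSE)
    }
    seqs <- as.character(genome)
    lens <- nchar(seqs)
    flanks <- character(n)
    truncated <- logical(n)
    for (i in seq_len(n)) {
      ch <- insertions$chrom[i]
      p <- insertions$pos[i] # 0-based TA leftmost base
      L <- lens[[ch]]
      if (insertions$orientation[i] == "+") {
        from <- p + 1L
        to <- min(p + config$flank_len, L)
        truncated[i] <- to - from + 1L < config$flank_len
        flanks[i] <- substr(seqs[[ch]], from, to)
      } else {
        to <- p + 2L
        from <- max(to - config$flank_len + 1L, 1L)
        truncated[i] <- to - from + 1L < config$flank_len
        flanks[i] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(substr(seqs[[ch]], from, to))))
      }
    }
    if (any(truncated)) {
      warning(sum(truncated), " flank(s) truncated at chromosome end")
    }
    counts <- insertions$read_count
    read_seq <- rep(paste0(config$irdr_motif, flanks), counts)
    read_name <- sprintf("%s:%d:%d",
                         rep(insertions$tumor_id, counts),
                         rep(seq_len(n), counts),
                         sequence(counts))
    reads <- Biostrings::DNAStringSet(read_seq)
    names(reads) <- read_name
  }
  if (!is.null(path)) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
  }
  invisible(reads)
}
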