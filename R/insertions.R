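# Insertion-profile ingestion and preprocessing: junction extraction,
# donor-chromosome inference/removal, gene assignment, per-gene collapse
# and read-depth filtering.

#' Parse a 6-column SB insertion file
#'
#' Expects tab-separated columns chrom, start, end (= start + 2, the TA
#' dinucleotide), orientation, read_count, tumor_id; '#' lines ignored.
#'
#' @param path File path.
#' @return Data frame with columns tumor_id, chrom, pos (0-based TA leftmost
#'   base), orientation, read_count.
#' @export
parse_insertions <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(tumor_id = character(0), chrom = character(0),
                      pos = integer(0), orientation = character(0),
                      read_count = integer(0)))
  }
  sp <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf != 6)) {
    stop("line ", lineno[which(nf != 6)[1]],
         ": expected 6 tab-separated columns", call. = FALSE)
  }
  m <- matrix(unlist(sp), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  reads <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(reads))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": non-integer coordinate or read count",
         call. = FALSE)
  }
  bad <- which(end - start != 2L)
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": end - start must equal 2 (TA site)",
         call. = FALSE)
  }
  bad <- which(reads < 1L)
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": read_count must be >= 1", call. = FALSE)
  }
  bad <- which(!m[, 4] %in% c("+", "-"))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": orientation must be '+' or '-'",
         call. = FALSE)
  }
  data.frame(tumor_id = m[, 6], chrom = m[, 1], pos = start,
             orientation = m[, 4], read_count = reads)
}

#' Recover insertion sites from IRDR junction reads
#'
#' A simplified junction extractor for error-free reads of the form
#' [IRDR motif][genomic flank]: reads lacking the motif are dropped; the
#' flank is placed by exact match against both genome strands; a placement
#' is accepted only if it is unique genome-wide and begins at an indexed TA
#' site; per-site read tallies become read counts. The tumor id is taken
#' from the read name prefix before the first ':' (the demultiplexed
#' barcode).
#'
#' @param reads FASTQ path or named \code{DNAStringSet}.
#' @param irdr_motif Motif string (>= 12 bases).
#' @param genome FASTA path or \code{DNAStringSet}.
#' @param index \code{TASiteIndex} of the same genome.
#' @return Insertion data frame (tumor_id, chrom, pos, orientation,
#'   read_count) with an attribute \code{stats} counting total, no-motif,
#'   ambiguous, unplaced and placed reads.
#' @export
extract_junctions <- function(reads, irdr_motif, genome, index) {
  if (nchar(irdr_motif) < 12) {
    stop("irdr_motif must be >= 12 bases", call. = FALSE)
  }
  if (is.character(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  stats <- c(total = length(reads), no_motif = 0L, ambiguous = 0L,
             unplaced = 0L, placed = 0L)
  empty <- data.frame(tumor_id = character(0), chrom = character(0),
                      pos = integer(0), orientation = character(0),
                      read_count = integer(0))
  if (length(reads) == 0) {
    attr(empty, "stats") <- stats
    return(empty)
  }
  tumor <- sub(":.*$", "", names(reads))
  seqs <- toupper(as.character(reads))
  motif <- toupper(irdr_motif)
  hit <- regexpr(motif, seqs, fixed = TRUE)
  has_motif <- hit > 0
  stats["no_motif"] <- sum(!has_motif)
  flank <- substring(seqs[has_motif],
                     hit[has_motif] + nchar(motif))
  tumor <- tumor[has_motif]
  long_enough <- nchar(flank) >= 10
  stats["unplaced"] <- stats["unplaced"] + sum(!long_enough)
  flank <- flank[long_enough]
  tumor <- tumor[long_enough]
  if (length(flank) == 0) {
    attr(empty, "stats") <- stats
    return(empty)
  }

  uf <- unique(flank)
  # locate each unique flank on both strands of every chromosome
  place <- locate_flanks(uf, genome, index)
  idx <- match(flank, uf)
  status <- place$status[idx]
  stats["ambiguous"] <- sum(status == "ambiguous")
  stats["unplaced"] <- stats["unplaced"] + sum(status == "unplaced")
  ok <- status == "placed"
  stats["placed"] <- sum(ok)
  if (!any(ok)) {
    attr(empty, "stats") <- stats
    return(empty)
  }
  df <- data.frame(tumor_id = tumor[ok],
                   chrom = place$chrom[idx][ok],
                   pos = place$pos[idx][ok],
                   orientation = place$orientation[idx][ok])
  agg <- aggregate(list(read_count = rep(1L, nrow(df))),
                   df[, c("tumor_id", "chrom", "pos", "orientation")],
                   FUN = sum)
  agg <- agg[order(agg$tumor_id, agg$chrom, agg$pos), ]
  rownames(agg) <- NULL
  out <- agg[, c("tumor_id", "chrom", "pos", "orientation", "read_count")]
  attr(out, "stats") <- stats
  out
}

# Exact placement of unique flank strings on both genome strands.
# Returns, per flank: status (placed / ambiguous / unplaced) and, when
# placed, chrom, 0-based TA position, orientation.
locate_flanks <- function(uf, genome, index) {
  n <- length(uf)
  n_occ <- integer(n)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)
  at_ta <- logical(n)
  widths <- nchar(uf)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(uf)))
  for (w in unique(widths)) {
    sel <- which(widths == w)
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(uf[sel]))
    pd_rev <- Biostrings::PDict(Biostrings::DNAStringSet(rc[sel]))
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      hits_f <- Biostrings::matchPDict(pd_fwd, subj)
      hits_r <- Biostrings::matchPDict(pd_rev, subj)
      sites <- index$sites[[ch]]
      for (j in seq_along(sel)) {
        i <- sel[j]
        sf <- IRanges::start(hits_f[[j]])
        sr <- IRanges::start(hits_r[[j]])
        n_occ[i] <- n_occ[i] + length(sf) + length(sr)
        if (length(sf)) {
          p <- sf[1] - 1L # 0-based; '+' flank starts at the TA
          if (is.na(chrom[i])) {
            chrom[i] <- ch; pos[i] <- p; orientation[i] <- "+"
            at_ta[i] <- p %in% sites
          }
        }
        if (length(sr)) {
          p <- sr[1] - 1L + w - 2L # '-' flank ends at the TA
          if (is.na(chrom[i])) {
            chrom[i] <- ch; pos[i] <- p; orientation[i] <- "-"
            at_ta[i] <- p %in% sites
          }
        }
      }
    }
  }
  status <- ifelse(n_occ == 1 & at_ta, "placed",
                   ifelse(n_occ > 1, "ambiguous", "unplaced"))
  list(status = status, chrom = chrom, pos = pos, orientation = orientation)
}

#' Infer the donor concatemer chromosome from insertion density
#'
#' Local hopping inflates reintegration density on the chromosome carrying
#' the transposon concatemer. Because SB can only integrate at TA
#' dinucleotides, density is normalized per indexed TA site (not per base):
#' the donor call is the chromosome maximizing insertions per TA site.
#'
#' @param insertions Insertion data frame.
#' @param index \code{TASiteIndex}.
#' @return List with \code{donor} (chromosome name), \code{density} (data
#'   frame: chrom, n_insertions, n_ta_sites, density) and \code{tie}
#'   (logical; TRUE when the maximum density is shared, broken by
#'   chromosome-name order).
#' @export
infer_donor_chromosome <- function(insertions, index) {
  if (nrow(insertions) == 0) {
    stop("cannot infer donor chromosome from zero insertions", call. = FALSE)
  }
  chroms <- sort(names(index$sites))
  n_ins <- vapply(chroms, function(ch) sum(insertions$chrom == ch),
                  integer(1))
  n_ta <- lengths(index$sites)[chroms]
  dens <- ifelse(n_ta > 0, n_ins / n_ta, NA_real_)
  tab <- data.frame(chrom = chroms, n_insertions = n_ins,
                    n_ta_sites = as.integer(n_ta), density = dens,
                    row.names = NULL)
  ok <- which(!is.na(dens))
  best <- ok[which.max(dens[ok])]
  tie <- sum(dens[ok] == dens[best]) > 1
  list(donor = chroms[best], density = tab, tie = tie)
}

#' Remove all insertions on the donor chromosome
#'
#' Donor-chromosome insertions are dominated by local hopping rather than
#' selection and are filtered away before driver statistics.
#'
#' @param insertions Insertion data frame.
#' @param donor Donor chromosome name.
#' @return The insertions not on \code{donor}, order preserved.
#' @export
filter_donor <- function(insertions, donor) {
  out <- insertions[insertions$chrom != donor, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse insertions to a gene-by-tumor matrix of maximal read depths
#'
#' Assigns each insertion to every gene footprint containing its TA site and
#' keeps, per (gene, tumor), only the insertion with the highest read count
#' (ties broken by smallest coordinate, i.e. the 5'-most site on the
#' reference). Intergenic insertions are dropped from the matrix but
#' tallied, and the per-tumor genome-wide insertion count n_i (pre-collapse,
#' including intergenic events) is retained: the recurrence null asks where
#' each of a tumor's independent insertions lands.
#'
#' @param insertions Insertion data frame (donor-filtered upstream if
#'   desired).
#' @param genes Gene models from \code{\link{load_gene_models}}.
#' @param tumors Optional full tumor roster; tumors without insertions stay
#'   in the matrix as all-absent columns. Defaults to the tumors observed.
#' @return A \code{CohortMatrix}: list with \code{genes}, \code{tumors},
#'   \code{reads} (gene x tumor matrix, 0 = absent), \code{orient}
#'   (matching orientation matrix), \code{n_i} (named per-tumor insertion
#'   counts), \code{tumor_reads} (per-tumor read-count vectors backing
#'   depth-filter recomputation) and \code{ledger} (parsed / assigned /
#'   intergenic tallies).
#' @export
assign_and_collapse <- function(insertions, genes, tumors = NULL) {
  if (is.null(tumors)) tumors <- sort(unique(insertions$tumor_id))
  tumors <- as.character(tumors)
  gene_ids <- genes$gene_id
  reads <- matrix(0L, nrow = length(gene_ids), ncol = length(tumors),
                  dimnames = list(gene_ids, tumors))
  orient <- matrix(NA_character_, nrow = length(gene_ids),
                   ncol = length(tumors),
                   dimnames = list(gene_ids, tumors))
  n_i <- setNames(integer(length(tumors)), tumors)
  tumor_reads <- setNames(vector("list", length(tumors)), tumors)
  for (t in tumors) tumor_reads[[t]] <- integer(0)
  n_assigned_events <- 0L
  hit_any <- logical(nrow(insertions))
  if (nrow(insertions) > 0) {
    tb <- table(factor(insertions$tumor_id, levels = tumors))
    n_i[] <- as.integer(tb)
    tumor_reads <- split(insertions$read_count,
                         factor(insertions$tumor_id, levels = tumors))
    for (ch in unique(genes$chrom)) {
      g_idx <- which(genes$chrom == ch)
      i_idx <- which(insertions$chrom == ch)
      if (length(i_idx) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(insertions$pos[i_idx] + 1L, width = 1L),
        IRanges::IRanges(genes$start[g_idx] + 1L, genes$end[g_idx]))
      if (length(ov) == 0) next
      qi <- i_idx[S4Vectors::queryHits(ov)]
      gi <- g_idx[S4Vectors::subjectHits(ov)]
      hit_any[qi] <- TRUE
      n_assigned_events <- n_assigned_events + length(qi)
      # per (gene, tumor): max read count, ties to smallest coordinate
      ord <- order(gi, insertions$tumor_id[qi],
                   -insertions$read_count[qi], insertions$pos[qi])
      qi <- qi[ord]; gi <- gi[ord]
      key <- paste(gi, insertions$tumor_id[qi])
      first <- !duplicated(key)
      qi <- qi[first]; gi <- gi[first]
      rows <- gene_ids[gi]
      cols <- insertions$tumor_id[qi]
      reads[cbind(rows, cols)] <- insertions$read_count[qi]
      orient[cbind(rows, cols)] <- insertions$orientation[qi]
    }
  }
  structure(
    list(genes = gene_ids, tumors = tumors, reads = reads, orient = orient,
         n_i = n_i, tumor_reads = tumor_reads,
         ledger = c(parsed = nrow(insertions),
                    assigned = sum(hit_any),
                    intergenic = sum(!hit_any),
                    assigned_events = n_assigned_events)),
    class = "CohortMatrix")
}

#' @export
print.CohortMatrix <- function(x, ...) {
  cat("CohortMatrix:", length(x$genes), "genes x", length(x$tumors),
      "tumors;", sum(x$reads > 0), "occupied cells\n")
  cat("  per-tumor insertions (n_i): median",
      stats::median(x$n_i), "\n")
  invisible(x)
}

#' Apply a minimum read-depth filter to a cohort matrix
#'
#' Cells below \code{min_reads} become absent, and the per-tumor insertion
#' counts n_i are recomputed over the surviving (>= min_reads) insertions so
#' the trunk-tier null reflects the filtered landscape. The threshold is
#' inclusive: 100 survives a min_reads of 100.
#'
#' @param matrix A \code{CohortMatrix}.
#' @param min_reads Minimum read depth (>= 1).
#' @return A filtered \code{CohortMatrix}.
#' @export
apply_depth_filter <- function(matrix, min_reads) {
  stopifnot(inherits(matrix, "CohortMatrix"))
  assert_scalar_number(min_reads, "min_reads", min = 1)
  out <- matrix
  drop <- out$reads < min_reads
  out$reads[drop] <- 0L
  out$orient[drop] <- NA_character_
  out$tumor_reads <- lapply(matrix$tumor_reads,
                            function(r) r[r >= min_reads])
  out$n_i <- setNames(vapply(out$tumor_reads, length, integer(1)),
                      names(matrix$n_i))
  out
}

#' Export a cohort matrix as tab-separated text
#'
#' Cells are "read_count:orientation", '.' for absent.
#'
#' @param matrix A \code{CohortMatrix}.
#' @param path Output path.
#' @export
write_cohort_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "CohortMatrix"))
  cells <- ifelse(matrix$reads > 0,
                  paste0(matrix$reads, ":", matrix$orient), ".")
  dim(cells) <- dim(matrix$reads)
  df <- data.frame(gene_id = matrix$genes, cells, check.names = FALSE)
  colnames(df) <- c("gene_id", matrix$tumors)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
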