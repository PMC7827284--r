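# Reference model: TA-site index and gene footprints.
#
# All coordinates in the package are 0-based, half-open (BED convention).
# A TA site is identified by the 0-based position of the leftmost base of
# the dinucleotide on the forward strand. TA is its own reverse complement,
# so a forward-strand scan enumerates every legal SB integration site.

#' Find all TA dinucleotide positions in a DNA sequence
#'
#' Sleeping Beauty integrates exclusively at TA dinucleotides; this scan
#' defines the universe of legal insertion sites for one sequence.
#'
#' @param seq A single character string over \code{A,C,G,T,N}
#'   (case-insensitive). \code{N} never matches.
#' @return Integer vector of 0-based positions \code{p} such that
#'   \code{substr(seq, p+1, p+2) == "TA"}, strictly increasing. Adjacent
#'   matches are all reported (\code{"TATA"} yields 0 and 2).
#' @examples
#' find_ta_sites("TATA") # 0 2
#' @export
find_ta_sites <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    stop("'seq' must be a single character string", call. = FALSE)
  }
  s <- toupper(seq)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0) {
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(s, bad, bad), as.integer(bad)), call. = FALSE)
  }
  if (nchar(s) < 2) return(integer(0))
  m <- gregexpr("TA", s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Build a TA-site index from a reference genome
#'
#' @param genome Path to a FASTA file, or a \code{Biostrings::DNAStringSet}.
#' @return An object of class \code{TASiteIndex}: a list with
#'   \code{chrom_lengths} (named integer vector), \code{sites} (named list of
#'   sorted 0-based integer positions) and \code{total_sites}.
#' @export
build_ta_index <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("'genome' must be a FASTA path or a DNAStringSet", call. = FALSE)
  }
  if (length(genome) == 0) stop("empty genome: no sequences", call. = FALSE)
  nm <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in genome: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(genome) <- nm
  hits <- Biostrings::vmatchPattern("TA", genome)
  sites <- lapply(hits, function(ir) as.integer(IRanges::start(ir)) - 1L)
  names(sites) <- nm
  structure(
    list(chrom_lengths = setNames(Biostrings::width(genome), nm),
         sites = sites,
         total_sites = sum(lengths(sites))),
    class = "TASiteIndex")
}

#' @export
print.TASiteIndex <- function(x, ...) {
  cat("TASiteIndex:", length(x$chrom_lengths), "chromosome(s),",
      x$total_sites, "TA sites\n")
  for (ch in names(x$chrom_lengths)) {
    cat(sprintf("  %s  length=%d  ta_sites=%d\n", ch,
                x$chrom_lengths[[ch]], length(x$sites[[ch]])))
  }
  invisible(x)
}

# Number of indexed TA sites with start <= p < end on `chrom` (binary search).
count_ta_in_interval <- function(index, chrom, start, end) {
  s <- index$sites[[chrom]]
  if (is.null(s) || length(s) == 0) return(0L)
  findInterval(end - 1L, s) - findInterval(start - 1L, s)
}

#' Write / read a TA-site index as tab-separated text
#'
#' Two columns: chromosome, 0-based position. Chromosome lengths are carried
#' in '##length' header comments so the round trip is lossless.
#'
#' @param index A \code{TASiteIndex}.
#' @param path Output (input) file path.
#' @export
write_ta_index <- function(index, path) {
  stopifnot(inherits(index, "TASiteIndex"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(index$chrom_lengths)) {
    writeLines(sprintf("##length\t%s\t%d", ch, index$chrom_lengths[[ch]]), con)
  }
  df <- data.frame(
    chrom = rep(names(index$sites), lengths(index$sites)),
    pos = unlist(index$sites, use.names = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ta_index
#' @export
read_ta_index <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^##length\t", lines, value = TRUE)
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  lens <- setNames(as.integer(vapply(parts, `[`, "", 3)),
                   vapply(parts, `[`, "", 2))
  body <- lines[!startsWith(lines, "#")]
  sites <- setNames(vector("list", length(lens)), names(lens))
  for (ch in names(lens)) sites[[ch]] <- integer(0)
  if (length(body)) {
    sp <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(sp, `[`, "", 1)
    pos <- as.integer(vapply(sp, `[`, "", 2))
    for (ch in unique(chrom)) sites[[ch]] <- sort(pos[chrom == ch])
  }
  structure(list(chrom_lengths = lens, sites = sites,
                 total_sites = sum(lengths(sites))),
            class = "TASiteIndex")
}

#' Load gene models and count the TA sites in each footprint
#'
#' Gene footprints are gene bodies only (no promoter flank). An insertion is
#' assignable to a gene when the leftmost base of its TA site lies inside
#' \code{[start, end)}; \code{ta_count} counts those sites and is the
#' numerator of the per-gene hit probability used by the recurrence null.
#' Overlapping genes each keep their own footprint, so one insertion may be
#' assigned to several genes.
#'
#' @param annotation Path to a 5-column tab-separated BED-like file
#'   (chrom, start, end, gene_id, strand; '#' lines ignored), or an
#'   equivalent data frame.
#' @param index A \code{TASiteIndex} for the same genome.
#' @return Data frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{ta_count}, \code{testable}
#'   (\code{ta_count > 0}; genes without a single TA site cannot be hit and
#'   are excluded from testing downstream).
#' @export
load_gene_models <- function(annotation, index) {
  stopifnot(inherits(index, "TASiteIndex"))
  if (is.character(annotation)) {
    genes <- read.table(annotation, sep = "\t", comment.char = "#",
                        col.names = c("chrom", "start", "end", "gene_id",
                                      "strand"),
                        colClasses = c("character", "integer", "integer",
                                       "character", "character"))
  } else {
    genes <- as.data.frame(annotation)[, c("chrom", "start", "end",
                                           "gene_id", "strand")]
  }
  if (nrow(genes) == 0) stop("annotation contains no genes", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  bad <- which(genes$start >= genes$end)
  if (length(bad)) {
    stop("start >= end for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  missing_chrom <- setdiff(unique(genes$chrom), names(index$chrom_lengths))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from index: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  oob <- which(genes$start < 0 |
                 genes$end > index$chrom_lengths[genes$chrom])
  if (length(oob)) {
    stop("interval outside chromosome bounds for gene(s): ",
         paste(genes$gene_id[oob], collapse = ", "), call. = FALSE)
  }
  genes$ta_count <- vapply(seq_len(nrow(genes)), function(i) {
    count_ta_in_interval(index, genes$chrom[i], genes$start[i], genes$end[i])
  }, integer(1))
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "ta_count")]
  genes$testable <- genes$ta_count > 0L
  genes
}

#' Write gene models back to the 5-column BED-like annotation format
#'
#' @param genes Gene model data frame (as from \code{load_gene_models} or
#'   \code{simulate_genome}).
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "gene_id", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
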