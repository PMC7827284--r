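# Cohort summaries and oncoprint matrix export.

#' Summarize a tumor spectrum table
#'
#' Counts tumors and tumor-bearing mice per histological classification and
#' reports cohort totals with the average tumor burden. Mice with zero
#' tumors count in the denominator, so the full mouse roster is required.
#' The tumors-per-mouse ratio is rounded half-to-even to 2 decimals.
#'
#' @param tumor_table Data frame with one row per tumor: columns
#'   \code{mouse_id}, \code{classification}.
#' @param mice Character vector: the full mouse roster of the cohort.
#' @return A \code{CohortSummary}: list with \code{by_class} (data frame:
#'   classification, tumors, mice), \code{total_tumors}, \code{total_mice},
#'   \code{tumors_per_mouse}.
#' @export
summarize_cohort <- function(tumor_table, mice) {
  mice <- unique(as.character(mice))
  if (length(mice) == 0) stop("empty mouse roster", call. = FALSE)
  tt <- as.data.frame(tumor_table)
  if (nrow(tt) > 0) {
    stopifnot(all(c("mouse_id", "classification") %in% names(tt)))
    stray <- setdiff(unique(tt$mouse_id), mice)
    if (length(stray)) {
      stop("tumor rows reference mice absent from the roster: ",
           paste(head(stray, 5), collapse = ", "), call. = FALSE)
    }
    by_class <- do.call(rbind, lapply(
      split(tt, tt$classification), function(d) {
        data.frame(classification = d$classification[1],
                   tumors = nrow(d),
                   mice = length(unique(d$mouse_id)))
      }))
    by_class <- by_class[order(-by_class$tumors,
                               by_class$classification), ]
    rownames(by_class) <- NULL
  } else {
    by_class <- data.frame(classification = character(0),
                           tumors = integer(0), mice = integer(0))
  }
  structure(
    list(by_class = by_class,
         total_tumors = nrow(tt),
         total_mice = length(mice),
         tumors_per_mouse = round(nrow(tt) / length(mice), 2)),
    class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("CohortSummary: %d tumors over %d mice (%.2f tumors/mouse)\n",
              x$total_tumors, x$total_mice, x$tumors_per_mouse))
  if (nrow(x$by_class)) print(x$by_class, row.names = FALSE)
  invisible(x)
}

# Read-depth tier boundaries for oncoprint cells. Only the 100-read
# boundary is semantically load-bearing (the clonal/background split);
# the others subdivide the display.
ONCOPRINT_TIERS <- c(background = 1, subclonal = 10, clonal = 100,
                     high_clonal = 300)

read_depth_tier <- function(reads) {
  tier <- rep("absent", length(reads))
  tier[reads >= 1] <- "background"
  tier[reads >= 10] <- "subclonal"
  tier[reads >= 100] <- "clonal"
  tier[reads >= 300] <- "high_clonal"
  tier
}

#' Export an oncoprint / waterfall matrix for called driver genes
#'
#' Rows are the requested driver genes ordered by recurrence (descending k)
#' then alphabetically; columns are tumors ordered by per-tumor hit count
#' (descending) then by name, giving the waterfall layout. Cells carry a
#' read-depth tier (background 1-9, subclonal 10-99, clonal 100-299,
#' high_clonal >= 300) and the orientation glyph of the collapsed
#' insertion. Two files are written: the tier matrix ('.' = absent) and a
#' long-format mutation annotation table consumable by generic oncoprint
#' renderers.
#'
#' @param matrix A \code{CohortMatrix}.
#' @param drivers A \code{DriverResult} data frame, or a character vector of
#'   gene ids.
#' @param path Output path for the matrix; the annotation table goes to
#'   \code{<path>.annotations.tsv}.
#' @return Invisibly, the tier matrix (character).
#' @export
oncoprint_export <- function(matrix, drivers, path) {
  stopifnot(inherits(matrix, "CohortMatrix"))
  gene_ids <- if (is.data.frame(drivers)) drivers$gene_id else
    as.character(drivers)
  missing <- setdiff(gene_ids, matrix$genes)
  if (length(missing)) {
    stop("driver gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(gene_ids) == 0) {
    writeLines(paste(c("gene_id", matrix$tumors), collapse = "\t"), path)
    empty <- matrix(character(0), nrow = 0, ncol = length(matrix$tumors),
                    dimnames = list(NULL, matrix$tumors))
    return(invisible(empty))
  }
  sub_reads <- matrix$reads[gene_ids, , drop = FALSE]
  sub_orient <- matrix$orient[gene_ids, , drop = FALSE]
  k <- rowSums(sub_reads > 0)
  row_ord <- order(-k, gene_ids)
  col_ord <- order(-colSums(sub_reads > 0), matrix$tumors)
  sub_reads <- sub_reads[row_ord, col_ord, drop = FALSE]
  sub_orient <- sub_orient[row_ord, col_ord, drop = FALSE]
  tiers <- read_depth_tier(sub_reads)
  dim(tiers) <- dim(sub_reads)
  cells <- ifelse(tiers == "absent", ".",
                  paste0(tiers, ":", sub_orient))
  dim(cells) <- dim(sub_reads)
  dimnames(cells) <- dimnames(sub_reads)
  df <- data.frame(gene_id = rownames(cells), cells, check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(cells))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  occ <- which(sub_reads > 0, arr.ind = TRUE)
  ann <- data.frame(
    sample = colnames(sub_reads)[occ[, "col"]],
    gene = rownames(sub_reads)[occ[, "row"]],
    tier = tiers[occ],
    orientation = sub_orient[occ],
    read_count = sub_reads[occ])
  ann <- ann[order(ann$gene, ann$sample), ]
  write.table(ann, paste0(path, ".annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(cells)
}
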