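# Overlap of called driver genes with curated tumor-suppressor lists:
# 2x2 chi-square with Yates' continuity correction, three-set Venn
# partitions, novel-gene triage.

#' Chi-square test with Yates' continuity correction on a 2x2 table
#'
#' chi2 = sum over cells of (max(|O - E| - 0.5, 0))^2 / E, with expecteds
#' from the marginals; |O - E| below 0.5 is clamped to zero so a perfectly
#' proportional table scores exactly 0 and the statistic stays
#' non-negative. p is the upper tail of chi-square with 1 df.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @return List with \code{chi2} and \code{p_two_tailed}.
#' @examples
#' chi_square_yates(matrix(c(20, 5, 5, 20), 2)) # chi2 = 15.68
#' @export
chi_square_yates <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(is.na(tab)) || any(tab < 0)) {
    stop("'table' must be a 2x2 matrix of non-negative counts",
         call. = FALSE)
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate marginal: a row or column sums to zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(tab)
  chi2 <- sum(pmax(abs(tab - expected) - 0.5, 0)^2 / expected)
  list(chi2 = chi2, p_two_tailed = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Enrichment of called drivers in a curated gene list
#'
#' Tabulates the 2x2 membership table (curated x driver) over an explicit
#' gene universe and applies the Yates-corrected chi-square. Symbol matching
#' is exact and case-sensitive after whitespace stripping; curated symbols
#' outside the universe are dropped before tabulation. The universe must be
#' supplied by the caller — there is no defensible default, and the
#' statistic is sensitive to it.
#'
#' @param driver_genes Character vector of called driver symbols (must be a
#'   subset of \code{universe}).
#' @param curated_list Character vector of curated symbols (e.g. a CGC-TSG
#'   ortholog list).
#' @param universe Character vector: all genes eligible to be called.
#' @return An \code{OverlapTable}: list with cells \code{a} (curated &
#'   driver), \code{b} (curated only), \code{c} (driver only), \code{d}
#'   (neither), \code{universe_n}, \code{chi2}, \code{p_two_tailed},
#'   \code{direction} ("enriched"/"depleted"/"none" by the sign of
#'   a - E[a]), and the overlapping symbols.
#' @export
overlap_enrichment <- function(driver_genes, curated_list, universe) {
  norm <- function(x) unique(trimws(as.character(x)))
  drivers <- norm(driver_genes)
  curated <- norm(curated_list)
  universe <- norm(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  extra <- setdiff(drivers, universe)
  if (length(extra)) {
    stop("driver gene(s) outside the universe: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }
  curated <- intersect(curated, universe)
  a <- length(intersect(curated, drivers))
  b <- length(curated) - a
  c_ <- length(drivers) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(curated = c("yes", "no"),
                                driver = c("yes", "no")))
  test <- chi_square_yates(tab)
  e_a <- (a + b) * (a + c_) / length(universe)
  structure(
    list(a = a, b = b, c = c_, d = d, universe_n = length(universe),
         chi2 = test$chi2, p_two_tailed = test$p_two_tailed,
         direction = if (a > e_a) "enriched" else if (a < e_a) "depleted"
                     else "none",
         expected_overlap = e_a,
         overlap_genes = sort(intersect(curated, drivers))),
    class = "OverlapTable")
}

#' @export
print.OverlapTable <- function(x, ...) {
  cat(sprintf(
    "OverlapTable: a=%d b=%d c=%d d=%d (N=%d)\n  chi2(Yates)=%.3f  p=%.3g  %s (expected overlap %.1f)\n",
    x$a, x$b, x$c, x$d, x$universe_n, x$chi2, x$p_two_tailed, x$direction,
    x$expected_overlap))
  invisible(x)
}

#' Three-set Venn partition of two curated lists against the driver set
#'
#' @param list_a,list_b,drivers Character vectors of gene symbols.
#' @return List with the seven region counts (\code{a_only}, \code{b_only},
#'   \code{drivers_only}, \code{ab}, \code{a_drivers}, \code{b_drivers},
#'   \code{abd}), \code{union_n}, and \code{novel}: the driver symbols in
#'   neither curated list (the candidates for novel tumor suppressors).
#' @export
venn_partition <- function(list_a, list_b, drivers) {
  a <- unique(trimws(list_a))
  b <- unique(trimws(list_b))
  d <- unique(trimws(drivers))
  u <- union(union(a, b), d)
  in_a <- u %in% a
  in_b <- u %in% b
  in_d <- u %in% d
  list(a_only = sum(in_a & !in_b & !in_d),
       b_only = sum(!in_a & in_b & !in_d),
       drivers_only = sum(!in_a & !in_b & in_d),
       ab = sum(in_a & in_b & !in_d),
       a_drivers = sum(in_a & !in_b & in_d),
       b_drivers = sum(!in_a & in_b & in_d),
       abd = sum(in_a & in_b & in_d),
       union_n = length(u),
       novel = sort(setdiff(d, union(a, b))))
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and '#' comments are skipped; symbols are whitespace-trimmed.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Apply a two-column ortholog map to a symbol list
#'
#' @param symbols Character vector (e.g. human CGC symbols).
#' @param map_path Tab-separated two-column file: from_symbol, to_symbol.
#' @return Mapped symbols (unmapped symbols dropped).
#' @export
map_orthologs <- function(symbols, map_path) {
  map <- read.table(map_path, sep = "\t",
                    col.names = c("from", "to"),
                    colClasses = "character", comment.char = "#")
  unique(map$to[match(trimws(symbols), map$from, nomatch = 0)])
}
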