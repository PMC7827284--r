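# Bundled whole-body SB screen tumor-spectrum tables.

#' Tumor spectrum of the whole-body SB screen cohorts
#'
#' Per-tumor rows and full mouse rosters for the three whole-body SB
#' mutagenesis cohorts compared in the screen: the promoterless gene-trap
#' allele (SB-Onc2.3, 79 tumors over 107 mice), the CAG-promoter allele
#' (SB-Onc3, 237 tumors over 87 mice) and the MSCV-promoter allele
#' (SB-Onc2, 112 tumors over 78 mice). The per-tumor rows are a
#' deterministic expansion of the published per-classification tumor and
#' mouse counts: within each classification, tumors are assigned
#' round-robin to as many mice as the published mouse count, so every
#' per-classification marginal (tumors, tumor-bearing mice) and both cohort
#' totals are reproduced exactly. Mice with no tumors appear only in the
#' roster.
#'
#' @param cohort One of \code{"SB-Onc2.3"}, \code{"SB-Onc3"},
#'   \code{"SB-Onc2"}.
#' @return List with \code{tumors} (data frame: mouse_id, classification;
#'   one row per tumor) and \code{mice} (character roster), ready for
#'   \code{\link{summarize_cohort}}.
#' @export
sb_tumor_spectrum <- function(cohort = c("SB-Onc2.3", "SB-Onc3",
                                         "SB-Onc2")) {
  cohort <- match.arg(cohort)
  tdir <- system.file("extdata", package = "sbdriver")
  tt <- read.table(file.path(tdir, "tumor_spectrum_tumors.tsv"),
                   sep = "\t", header = TRUE, colClasses = "character")
  mm <- read.table(file.path(tdir, "tumor_spectrum_mice.tsv"),
                   sep = "\t", header = TRUE, colClasses = "character")
  list(tumors = tt[tt$cohort == cohort, c("mouse_id", "classification")],
       mice = mm$mouse_id[mm$cohort == cohort])
}
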