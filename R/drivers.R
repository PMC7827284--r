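# Statistical core: per-gene recurrence significance under a TA-content
# null, multiple-testing tiers, driver classification and activating
# insertion pattern detection.
#
# The null model: a tumor with n_i independent insertions, each landing
# uniformly on one of the non-donor genomic TA sites, hits gene g (TA
# fraction p_g = ta_count_g / total non-donor TA sites) with probability
#   pi_i = 1 - (1 - p_g)^n_i.
# The number of tumors hitting g is then Poisson-binomial over the
# heterogeneous pi_i, and the recurrence p-value is the exact upper tail
# P(X >= k), computed by dynamic programming.

#' Per-tumor probability of hitting a gene under the TA-content null
#'
#' @param gene One row of a gene-model data frame (needs \code{ta_count},
#'   \code{chrom}).
#' @param index \code{TASiteIndex}.
#' @param n_i The tumor's genome-wide insertion count (post donor filter).
#' @param donor Donor chromosome name (its TA sites are excluded from the
#'   null universe because donor insertions are filtered before testing).
#' @return Probability \code{1 - (1 - p_g)^n_i}; 0 when the gene has no TA
#'   site or the tumor no insertions.
#' @export
gene_hit_probability <- function(gene, index, n_i, donor) {
  stopifnot(inherits(index, "TASiteIndex"))
  if (gene$chrom == donor) {
    stop("gene lies on the donor chromosome and cannot be tested",
         call. = FALSE)
  }
  if (n_i < 0) stop("n_i must be >= 0", call. = FALSE)
  total <- index$total_sites - length(index$sites[[donor]])
  if (total <= 0 || gene$ta_count == 0 || n_i == 0) return(0)
  p_g <- gene$ta_count / total
  1 - (1 - p_g)^n_i
}

#' Exact Poisson-binomial upper tail P(X >= k)
#'
#' X is the sum of independent Bernoulli variables with heterogeneous
#' success probabilities. The count distribution is built by exact dynamic
#' programming (iterated convolution), which is numerically stable and
#' practical for thousands of tumors.
#'
#' @param probs Vector of success probabilities in [0, 1].
#' @param k Integer threshold; \code{k <= 0} returns 1, \code{k >
#'   length(probs)} returns 0.
#' @return P(X >= k).
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 2) # 0.25
#' @export
poisson_binomial_tail <- function(probs, k) {
  if (length(probs) && (any(is.na(probs)) || any(probs < 0 | probs > 1))) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- length(probs)
  if (k <= 0) return(1)
  if (k > n) return(0)
  dp <- 1 # P(count = 0) over zero variables
  for (p in probs) {
    dp <- c(dp * (1 - p), 0) + c(0, dp * p)
  }
  sum(dp[(k + 1):(n + 1)])
}

#' Benjamini-Hochberg and Holm p-value adjustment
#'
#' Thin wrappers over \code{stats::p.adjust}: step-up FDR control (BH) for
#' the discovery tier and step-down FWER control (Holm) for the
#' genome-significant and trunk tiers.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' @rdname bh_adjust
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "holm")
}

#' Classify driver genes into discovery / progression / trunk tiers
#'
#' Two passes over the collapsed gene-by-tumor matrix:
#' \enumerate{
#'   \item All insertions, no read-depth filter: per-gene recurrence
#'     p-values via the Poisson-binomial tail; \emph{discovery} drivers are
#'     BH q < alpha, \emph{genome-significant progression} drivers are Holm
#'     p < alpha.
#'   \item Depth-filtered matrix (\code{apply_depth_filter} at
#'     \code{trunk_min_reads}, n_i recomputed over surviving insertions):
#'     \emph{trunk} drivers are Holm p < alpha with hits in at least
#'     \code{min_tumors} tumors — recurrent, highly clonal events.
#' }
#' In each pass only genes with at least one hit and at least one TA site
#' are tested (and counted in the number of tests m). Genes on the donor
#' chromosome are excluded.
#'
#' @param matrix \code{CohortMatrix} from \code{\link{assign_and_collapse}}
#'   (donor-filtered insertions).
#' @param genes Gene models.
#' @param index \code{TASiteIndex}.
#' @param donor Donor chromosome name (use \code{NA} if no donor applies).
#' @param alpha Significance level for every tier (default 0.05).
#' @param trunk_min_reads Trunk read-depth floor, inclusive (default 100).
#' @param min_tumors Trunk recurrence floor (default 3 tumors).
#' @param allele_mode \code{"gene_trap_only"} for a promoterless gene-trap
#'   transposon (every pattern is inactivating) or \code{"promoter_bearing"}
#'   (activating patterns detectable; see
#'   \code{\link{orientation_pattern}}).
#' @return A \code{DriverResult} data frame: gene_id, chrom, ta_count, k,
#'   expected_hits, p_raw, q_bh, p_holm, k_trunk, p_trunk_raw, p_trunk_holm,
#'   discovery, progression_genome, trunk, pattern. Genes never hit are
#'   omitted.
#' @export
call_drivers <- function(matrix, genes, index, donor,
                         alpha = 0.05, trunk_min_reads = 100,
                         min_tumors = 3,
                         allele_mode = c("gene_trap_only",
                                         "promoter_bearing")) {
  stopifnot(inherits(matrix, "CohortMatrix"), inherits(index, "TASiteIndex"))
  allele_mode <- match.arg(allele_mode)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  genes <- genes[match(matrix$genes, genes$gene_id), , drop = FALSE]
  off_donor <- if (is.na(donor)) rep(TRUE, nrow(genes)) else
    genes$chrom != donor
  testable <- off_donor & genes$ta_count > 0L
  empty <- driver_result_frame(NULL)
  if (sum(matrix$reads) == 0) {
    message("call_drivers: empty cohort matrix, no genes tested")
    return(empty)
  }
  total_ta <- index$total_sites -
    if (is.na(donor)) 0L else length(index$sites[[donor]])
  if (total_ta <= 0) stop("no TA sites outside the donor chromosome")

  pass <- function(mat) {
    k <- rowSums(mat$reads > 0)
    test <- testable & k >= 1
    idx <- which(test)
    p_g <- genes$ta_count[idx] / total_ta
    n_i <- as.numeric(mat$n_i)
    res <- lapply(seq_along(idx), function(j) {
      pi_i <- 1 - (1 - p_g[j])^n_i
      c(expected = sum(pi_i),
        p_raw = poisson_binomial_tail(pi_i, k[idx[j]]))
    })
    res <- do.call(rbind, res)
    list(idx = idx, k = k[idx],
         expected = if (length(idx)) res[, "expected"] else numeric(0),
         p_raw = if (length(idx)) res[, "p_raw"] else numeric(0))
  }

  p1 <- pass(matrix)
  filt <- apply_depth_filter(matrix, trunk_min_reads)
  p2 <- pass(filt)

  if (length(p1$idx) == 0) {
    message("call_drivers: no testable genes with hits")
    return(empty)
  }
  q_bh <- bh_adjust(p1$p_raw)
  p_holm <- holm_adjust(p1$p_raw)
  res <- data.frame(
    gene_id = genes$gene_id[p1$idx], chrom = genes$chrom[p1$idx],
    ta_count = genes$ta_count[p1$idx], k = as.integer(p1$k),
    expected_hits = p1$expected, p_raw = p1$p_raw, q_bh = q_bh,
    p_holm = p_holm, k_trunk = 0L, p_trunk_raw = NA_real_,
    p_trunk_holm = NA_real_)
  res$discovery <- res$q_bh < alpha
  res$progression_genome <- res$p_holm < alpha
  if (length(p2$idx)) {
    holm2 <- holm_adjust(p2$p_raw)
    m2 <- match(genes$gene_id[p2$idx], res$gene_id)
    res$k_trunk[m2] <- as.integer(p2$k)
    res$p_trunk_raw[m2] <- p2$p_raw
    res$p_trunk_holm[m2] <- holm2
  }
  res$trunk <- !is.na(res$p_trunk_holm) & res$p_trunk_holm < alpha &
    res$k_trunk >= min_tumors

  # orientation pattern of the collapsed insertions, relative to gene strand
  strand <- genes$strand[p1$idx]
  sense <- vapply(seq_along(p1$idx), function(j) {
    o <- matrix$orient[p1$idx[j], ]
    sum(o == strand[j], na.rm = TRUE)
  }, numeric(1))
  res$pattern <- orientation_pattern(sense, res$k, allele_mode,
                                     alpha = alpha)
  res <- res[order(res$p_raw, -res$k, res$gene_id), ]
  rownames(res) <- NULL
  class(res) <- c("DriverResult", "data.frame")
  res
}

driver_result_frame <- function(x) {
  res <- data.frame(gene_id = character(0), chrom = character(0),
                    ta_count = integer(0), k = integer(0),
                    expected_hits = numeric(0), p_raw = numeric(0),
                    q_bh = numeric(0), p_holm = numeric(0),
                    k_trunk = integer(0), p_trunk_raw = numeric(0),
                    p_trunk_holm = numeric(0), discovery = logical(0),
                    progression_genome = logical(0), trunk = logical(0),
                    pattern = character(0))
  class(res) <- c("DriverResult", "data.frame")
  res
}

#' Classify per-gene insertion orientation patterns
#'
#' For a promoterless gene-trap transposon (\code{gene_trap_only}) every
#' recurrent pattern is inactivating: without an internal promoter the cargo
#' cannot activate a proto-oncogene, regardless of orientation. For a
#' promoter-bearing transposon, a gene is called \emph{activating} when its
#' collapsed insertions are significantly sense-biased: an exact two-sided
#' binomial test of the sense count against 0.5, BH-corrected across the
#' genes tested, must reach q < alpha \emph{and} the sense fraction must be
#' at least \code{sense_frac_min}.
#'
#' @param sense Per-gene count of sense-oriented (gene-strand-matching)
#'   collapsed insertions.
#' @param total Per-gene count of contributing tumors.
#' @param allele_mode \code{"gene_trap_only"} or \code{"promoter_bearing"}.
#' @param alpha Significance level (default 0.05).
#' @param sense_frac_min Minimum sense fraction for an activating call
#'   (default 0.7, the directional-bias level seen in strongly activated
#'   targets of promoter-bearing screens).
#' @return Character vector: \code{"activating"} or \code{"inactivating"}.
#' @export
orientation_pattern <- function(sense, total,
                                allele_mode = c("gene_trap_only",
                                                "promoter_bearing"),
                                alpha = 0.05, sense_frac_min = 0.7) {
  allele_mode <- match.arg(allele_mode)
  n <- length(sense)
  if (length(total) != n) stop("sense/total length mismatch", call. = FALSE)
  if (allele_mode == "gene_trap_only") {
    return(rep("inactivating", n))
  }
  if (n == 0) return(character(0))
  if (any(sense > total)) stop("sense count exceeds total", call. = FALSE)
  p <- vapply(seq_len(n), function(i) {
    if (total[i] == 0) return(1)
    binom.test(sense[i], total[i], p = 0.5,
               alternative = "two.sided")$p.value
  }, numeric(1))
  q <- bh_adjust(p)
  frac <- ifelse(total > 0, sense / total, 0)
  ifelse(q < alpha & frac >= sense_frac_min, "activating", "inactivating")
}

#' Write driver results as tab-separated text and JSON
#'
#' @param drivers A \code{DriverResult} data frame.
#' @param path Output path for the table; a sibling \code{.json} report is
#'   written when \code{json} is TRUE.
#' @param json Also write a JSON report (default TRUE).
#' @export
write_driver_results <- function(drivers, path, json = TRUE) {
  out <- as.data.frame(drivers)
  out$tiers <- vapply(seq_len(nrow(out)), function(i) {
    paste(c("discovery", "progression_genome",
            "trunk")[c(out$discovery[i], out$progression_genome[i],
                       out$trunk[i])], collapse = ",")
  }, character(1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    jsonlite::write_json(out, sub("\\.[^.]*$", "", path) %+% ".json",
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
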