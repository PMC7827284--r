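# Ingestion and preprocessing: parsing, junction extraction, donor
# inference/filtering, per-gene collapse and depth filtering.

test_that("parse_insertions validates the 6-column BED-like format", {
  path <- tempfile()
  writeLines(c("#chrom\tstart\tend\torientation\tread_count\ttumor_id",
               "chr2\t10\t12\t+\t150\tT1",
               "chr1\t5\t7\t-\t1\tT2"), path)
  ins <- parse_insertions(path)
  expect_identical(ins$tumor_id, c("T1", "T2"))
  expect_identical(ins$pos, c(10L, 5L))
  expect_identical(ins$orientation, c("+", "-"))
  expect_identical(ins$read_count, c(150L, 1L))

  bad <- tempfile()
  writeLines("chr2\t10\t12\t+\t0\tT1", bad)
  expect_error(parse_insertions(bad), "read_count")
  writeLines("chr2\t10\t13\t+\t5\tT1", bad)
  expect_error(parse_insertions(bad), "end - start")
  writeLines("chr2\t10\t12\t+\t5", bad)
  expect_error(parse_insertions(bad), "6 tab-separated")
  writeLines("chr2\tx\t12\t+\t5\tT1", bad)
  expect_error(parse_insertions(bad), "non-integer")
})

test_that("simulator output survives a write/parse round trip", {
  w <- small_world(seed = 12)
  co <- simulate_cohort(w$cfg, w$idx, w$genes)
  path <- tempfile()
  write_insertions(co$insertions, path)
  back <- parse_insertions(path)
  ord <- function(d) {
    d <- d[order(d$tumor_id, d$chrom, d$pos), ]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(back), ord(co$insertions[, names(back)]))
})

test_that("junction extraction drops motif-less reads, places the rest", {
  w <- small_world(seed = 13)
  site <- w$idx$sites$chr2[20]
  ins <- data.frame(tumor_id = "T001", chrom = "chr2", pos = site,
                    orientation = "+", read_count = 1L)
  reads <- simulate_reads(ins, w$genome, w$cfg)
  noise <- Biostrings::DNAStringSet(c("T002:noise" = strrep("ACGT", 20)))
  rec <- extract_junctions(c(reads, noise), w$cfg$irdr_motif, w$genome,
                           w$idx)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$pos, site)
  expect_identical(rec$read_count, 1L)
  st <- attr(rec, "stats")
  expect_identical(unname(st["no_motif"]), 1L)
  expect_identical(unname(st["placed"]), 1L)
  expect_error(extract_junctions(reads, "TA", w$genome, w$idx), ">= 12")
})

test_that("extract_junctions inverts simulate_reads on a full cohort", {
  w <- small_world(seed = 7, planted_drivers = data.frame(
    gene_id = "G0015", selection_prob = 1, orientation_bias = 0.5))
  co <- simulate_cohort(w$cfg, w$idx, w$genes)
  reads <- simulate_reads(co$insertions, w$genome, w$cfg)
  rec <- extract_junctions(reads, w$cfg$irdr_motif, w$genome, w$idx)
  attr(rec, "stats") <- NULL
  truth <- co$insertions[order(co$insertions$tumor_id, co$insertions$chrom,
                               co$insertions$pos), ]
  rownames(truth) <- NULL
  expect_identical(rec, truth[, names(rec)])
})

test_that("donor inference maximizes insertions per TA site", {
  w <- small_world(seed = 2)
  ins <- data.frame(tumor_id = "T1", chrom = "chr1",
                    pos = w$idx$sites$chr1[1:10], orientation = "+",
                    read_count = 1L)
  call <- infer_donor_chromosome(ins, w$idx)
  expect_identical(call$donor, "chr1")
  expect_false(call$tie)
  expect_error(infer_donor_chromosome(ins[0, ], w$idx), "zero insertions")
})

test_that("donor density ties break by chromosome name and are flagged", {
  idx <- build_ta_index(write_tiny_fasta(list(chrA = "TATACC",
                                              chrB = "GGTATA")))
  # one insertion on each chromosome: identical density (2 TA sites each)
  ins <- data.frame(tumor_id = "T1", chrom = c("chrB", "chrA"),
                    pos = c(2L, 0L), orientation = "+", read_count = 1L)
  call <- infer_donor_chromosome(ins, idx)
  expect_identical(call$donor, "chrA")
  expect_true(call$tie)
})

test_that("filter_donor removes exactly the donor chromosome, stably", {
  ins <- data.frame(tumor_id = "T1", chrom = rep(c("chr1", "chr2"), c(4, 6)),
                    pos = 1:10, orientation = "+", read_count = 1L)
  out <- filter_donor(ins, "chr1")
  expect_identical(nrow(out), 6L)
  expect_true(all(out$chrom == "chr2"))
  expect_identical(out$pos, ins$pos[ins$chrom == "chr2"])
  expect_identical(filter_donor(ins, "chrX"), ins)     # identity
  expect_identical(filter_donor(out, "chr1"), out)     # idempotent
})

test_that("per-gene collapse keeps the deepest insertion, 5'-most on ties", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                      end = 100L, strand = "+", ta_count = 10L,
                      testable = TRUE)
  ins <- data.frame(tumor_id = "T1", chrom = "chr1", pos = c(10L, 40L),
                    orientation = c("-", "+"), read_count = c(5L, 120L))
  m <- assign_and_collapse(ins, genes)
  expect_identical(unname(m$reads["g1", "T1"]), 120L)
  expect_identical(unname(m$orient["g1", "T1"]), "+")

  tie <- data.frame(tumor_id = "T1", chrom = "chr1", pos = c(40L, 10L),
                    orientation = c("+", "-"), read_count = c(80L, 80L))
  m2 <- assign_and_collapse(tie, genes)
  expect_identical(unname(m2$reads["g1", "T1"]), 80L)
  expect_identical(unname(m2$orient["g1", "T1"]), "-") # pos 10 is 5'-most
})

test_that("collapsed cells equal a brute-force max over the truth table", {
  w <- small_world(seed = 21)
  co <- simulate_cohort(w$cfg, w$idx, w$genes)
  kept <- filter_donor(co$insertions, w$cfg$donor_chrom)
  m <- assign_and_collapse(kept, w$genes, tumors = co$tumors)
  for (gi in sample(seq_len(nrow(w$genes)), 10)) {
    g <- w$genes[gi, ]
    for (t in co$tumors) {
      inside <- kept$tumor_id == t & kept$chrom == g$chrom &
        kept$pos >= g$start & kept$pos < g$end
      want <- if (any(inside)) max(kept$read_count[inside]) else 0L
      expect_identical(unname(m$reads[g$gene_id, t]), as.integer(want))
    }
  }
  # conservation ledger: every kept insertion is assigned or intergenic
  expect_identical(unname(m$ledger["assigned"] + m$ledger["intergenic"]),
                   nrow(kept))
  # n_i counts pre-collapse, genome-wide, per tumor
  expect_identical(m$n_i, table(factor(kept$tumor_id, co$tumors)) |>
                     as.integer() |> setNames(co$tumors))
})

test_that("tumors with zero insertions remain as all-absent columns", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                      end = 100L, strand = "+", ta_count = 10L,
                      testable = TRUE)
  ins <- data.frame(tumor_id = "T1", chrom = "chr1", pos = 10L,
                    orientation = "+", read_count = 3L)
  m <- assign_and_collapse(ins, genes, tumors = c("T1", "T2"))
  expect_identical(unname(m$reads["g1", "T2"]), 0L)
  expect_identical(unname(m$n_i["T2"]), 0L)
})

test_that("depth filter has an inclusive boundary and recomputes n_i", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
                      strand = "+", ta_count = 5L, testable = TRUE)
  ins <- data.frame(tumor_id = "T1", chrom = "chr1",
                    pos = c(10L, 110L, 210L), orientation = "+",
                    read_count = c(99L, 100L, 250L))
  m <- assign_and_collapse(ins, genes)
  f <- apply_depth_filter(m, 100)
  expect_identical(unname(f$reads[, "T1"]), c(0L, 100L, 250L))
  expect_true(is.na(f$orient["g1", "T1"]))
  expect_identical(unname(f$n_i["T1"]), 2L)
  # min_reads 1 is the identity
  expect_identical(apply_depth_filter(m, 1)$reads, m$reads)
  expect_identical(apply_depth_filter(m, 1)$n_i, m$n_i)
})

test_that("donor filtering commutes with collapse on donor-free genes", {
  w <- small_world(seed = 30)
  co <- simulate_cohort(w$cfg, w$idx, w$genes)
  donor <- w$cfg$donor_chrom
  m1 <- assign_and_collapse(filter_donor(co$insertions, donor), w$genes,
                            tumors = co$tumors)
  m2 <- assign_and_collapse(co$insertions, w$genes, tumors = co$tumors)
  off <- w$genes$gene_id[w$genes$chrom != donor]
  expect_identical(m1$reads[off, ], m2$reads[off, ])
})
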