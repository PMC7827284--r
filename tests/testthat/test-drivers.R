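# Recurrence statistics and driver classification.

test_that("gene_hit_probability follows 1 - (1 - p_g)^n_i", {
  idx <- build_ta_index(write_tiny_fasta(list(chr1 = "TATA",
                                              chr2 = "TAGGTACC")))
  # chr2 has 2 of the 4 TA sites; donor chr1 removes the other 2
  gene <- data.frame(gene_id = "g", chrom = "chr2", start = 0L, end = 8L,
                     strand = "+", ta_count = 2L)
  expect_equal(gene_hit_probability(gene, idx, n_i = 1, donor = "chr1"), 1)
  gene1 <- transform(gene, ta_count = 1L) # p_g = 0.5
  expect_equal(gene_hit_probability(gene1, idx, n_i = 1, donor = "chr1"),
               0.5)
  gene0 <- transform(gene, ta_count = 0L)
  expect_equal(gene_hit_probability(gene0, idx, n_i = 10, donor = "chr1"), 0)
  expect_equal(gene_hit_probability(gene, idx, n_i = 0, donor = "chr1"), 0)
  donor_gene <- transform(gene, chrom = "chr1")
  expect_error(gene_hit_probability(donor_gene, idx, 1, donor = "chr1"),
               "donor")
})

test_that("hit probability reproduces the direct arithmetic example", {
  # p_g = 0.01, n_i = 100 -> 1 - 0.99^100
  idx <- structure(list(chrom_lengths = c(chrA = 1000L, chrB = 10L),
                        sites = list(chrA = as.integer(1:100 * 2),
                                     chrB = integer(0)),
                        total_sites = 100L), class = "TASiteIndex")
  gene <- data.frame(gene_id = "g", chrom = "chrA", start = 0L, end = 10L,
                     strand = "+", ta_count = 1L)
  expect_equal(gene_hit_probability(gene, idx, n_i = 100, donor = "chrB"),
               1 - 0.99^100, tolerance = 1e-12)
  expect_equal(round(1 - 0.99^100, 4), 0.634)
})

test_that("poisson_binomial_tail matches hand-computable cases", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_tail(c(0.1, 0.2, 0.3), 2), 0.098,
               tolerance = 1e-12)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 0), 1)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 3), 0)
  expect_equal(poisson_binomial_tail(numeric(0), 0), 1)
  expect_error(poisson_binomial_tail(c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("poisson_binomial_tail equals exhaustive enumeration", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    probs <- runif(n)
    k <- sample(0:(n + 1), 1)
    expect_equal(poisson_binomial_tail(probs, k), pb_tail_enum(probs, k),
                 tolerance = 1e-10)
  }
})

test_that("poisson_binomial_tail is stable for thousands of tumors", {
  probs <- rep(0.01, 5000)
  tail <- poisson_binomial_tail(probs, 50)
  # binomial reference: identical probabilities reduce to pbinom
  expect_equal(tail, pbinom(49, 5000, 0.01, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("BH and Holm adjustments reproduce hand computations", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.5)), "\\[0, 1\\]")
  # Holm dominates the raw p-value; BH never exceeds Holm
  set.seed(5)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= holm_adjust(p)))
})

test_that("call_drivers recovers planted drivers in nested tiers", {
  w <- default_world()
  co <- simulate_cohort(w$cfg, w$idx, w$genes)
  kept <- filter_donor(co$insertions, w$cfg$donor_chrom)
  m <- assign_and_collapse(kept, w$genes, tumors = co$tumors)
  dr <- call_drivers(m, w$genes, w$idx, w$cfg$donor_chrom)
  planted <- w$cfg$planted_drivers$gene_id
  hit <- dr[match(planted, dr$gene_id), ]
  expect_true(all(hit$discovery))
  expect_true(all(hit$progression_genome))
  expect_true(all(hit$trunk))
  # tier nesting: Holm-significant implies BH-significant
  expect_true(all(dr$discovery[dr$progression_genome]))
  # every trunk driver recurs in >= 3 tumors at >= 100 reads
  expect_true(all(dr$k_trunk[dr$trunk] >= 3))
  # all patterns inactivating under the promoterless gene-trap allele
  expect_true(all(dr$pattern == "inactivating"))
  # expected hits bounded by cohort size; adjusted p-values ordered
  expect_true(all(dr$expected_hits >= 0 &
                    dr$expected_hits <= length(co$tumors)))
  expect_true(all(dr$p_holm >= dr$p_raw - 1e-12))
  # no donor-chromosome gene is ever tested
  expect_false(any(dr$chrom == w$cfg$donor_chrom))
})

test_that("an empty cohort yields an empty driver table", {
  w <- small_world(seed = 14)
  m <- assign_and_collapse(
    data.frame(tumor_id = character(0), chrom = character(0),
               pos = integer(0), orientation = character(0),
               read_count = integer(0)),
    w$genes, tumors = c("T001", "T002"))
  expect_message(dr <- call_drivers(m, w$genes, w$idx, "chr1"), "empty")
  expect_identical(nrow(dr), 0L)
})

test_that("adding a hit tumor never increases the recurrence p-value", {
  set.seed(31)
  probs <- runif(10, 0.05, 0.4)
  k <- 4
  p0 <- poisson_binomial_tail(probs, k)
  # the new tumor is itself a hit: k and the probability vector both grow
  p1 <- poisson_binomial_tail(c(probs, 0.3), k + 1)
  expect_lte(p1, p0 + 1e-12)
})

test_that("orientation_pattern separates activating from inactivating", {
  expect_identical(orientation_pattern(10, 10, "gene_trap_only"),
                   "inactivating")
  # promoter-bearing, one gene, 10/10 sense: p = 2 * 0.5^10
  expect_identical(orientation_pattern(10, 10, "promoter_bearing"),
                   "activating")
  p <- binom.test(10, 10, 0.5)$p.value
  expect_equal(p, 2 * 0.5^10, tolerance = 1e-12)
  expect_identical(orientation_pattern(5, 10, "promoter_bearing"),
                   "inactivating")
  # significant but anti-sense-biased: not activating
  expect_identical(orientation_pattern(0, 12, "promoter_bearing"),
                   "inactivating")
  expect_error(orientation_pattern(3, 2, "promoter_bearing"), "exceeds")
})

test_that("sense-biased planted drivers are called activating when the
           transposon carries a promoter", {
  w <- default_world()
  cfg <- sim_config(seed = 17, planted_drivers = data.frame(
    gene_id = c("G0375", "G0625"), selection_prob = c(0.8, 0.8),
    orientation_bias = c(1, 0.5)))
  co <- simulate_cohort(cfg, w$idx, w$genes)
  kept <- filter_donor(co$insertions, cfg$donor_chrom)
  m <- assign_and_collapse(kept, w$genes, tumors = co$tumors)
  dr <- call_drivers(m, w$genes, w$idx, cfg$donor_chrom,
                     allele_mode = "promoter_bearing")
  # G0375 is on the '+' strand with all-sense insertions
  expect_identical(dr$pattern[dr$gene_id == "G0375"], "activating")
  expect_identical(dr$pattern[dr$gene_id == "G0625"], "inactivating")
})
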