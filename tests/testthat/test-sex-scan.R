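test_that("genotype tables exclude missing calls and unknown-sex samples", {
  gm <- strict_male_het_matrix(3, 2)
  gm$calls[1, 4] <- NA  # one male missing at site 1
  tab <- genotype_table(gm, 1)
  expect_equal(unname(tab$female), c(3, 0, 0))
  expect_equal(unname(tab$male), c(0, 1, 0))

  gm$samples$sex[1] <- "unknown"
  expect_equal(unname(genotype_table(gm, 2)$female), c(2, 0, 0))

  gm$calls[2, ] <- NA
  tab <- genotype_table(gm, 2)
  expect_equal(unname(c(tab$female, tab$male)), rep(0, 6))
})

test_that("fully sex-specific tables give the closed-form p", {
  # strict segregation: the observed table is a least-probable one for its
  # margins, so p = 1 / choose(a + b, a) for a != b; in a balanced cohort
  # the reflected table ties it exactly, doubling the p
  for (ab in list(c(16, 15), c(16, 14), c(5, 4))) {
    p <- fisher_exact_2x3(c(ab[1], 0, 0), c(0, ab[2], 0))
    expect_equal(p, 1 / choose(sum(ab), ab[1]), tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x3(c(10, 0, 0), c(0, 10, 0)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(signif(fisher_exact_2x3(c(16, 0, 0), c(0, 15, 0)), 3), 3.33e-9)
  expect_equal(signif(fisher_exact_2x3(c(16, 0, 0), c(0, 14, 0)), 3), 6.88e-9)
})

test_that("degenerate margins force p = 1 and empty strata error", {
  expect_equal(fisher_exact_2x3(c(16, 0, 0), c(15, 0, 0)), 1)
  expect_error(fisher_exact_2x3(c(0, 0, 0), c(1, 2, 3)), "empty sex stratum")
})

test_that("exact 2x3 p matches enumeration oracle and fisher.test", {
  expect_equal(fisher_exact_2x3(c(3, 2, 1), c(1, 2, 3)),
               oracle_fisher_2x3(c(3, 2, 1), c(1, 2, 3)), tolerance = 1e-9)
  set.seed(42)
  for (t in random_tables(200)) {
    expect_equal(fisher_exact_2x3(t[1, ], t[2, ]),
                 oracle_fisher_2x3(t[1, ], t[2, ]), tolerance = 1e-9)
  }
  # cross-check against an entirely independent implementation
  for (t in random_tables(50)) {
    keep <- colSums(t) > 0
    expect_equal(fisher_exact_2x3(t[1, ], t[2, ]),
                 fisher.test(t[, keep, drop = FALSE])$p.value,
                 tolerance = 1e-6)
  }
})

test_that("the exact p is invariant to row swap and column permutation", {
  set.seed(7)
  for (t in random_tables(50)) {
    p <- fisher_exact_2x3(t[1, ], t[2, ])
    expect_equal(fisher_exact_2x3(t[2, ], t[1, ]), p, tolerance = 1e-9)
    perm <- sample(3)
    expect_equal(fisher_exact_2x3(t[1, perm], t[2, perm]), p,
                 tolerance = 1e-9)
  }
})

test_that("HWE exact test matches its enumeration oracle", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  expect_equal(hwe_exact_p(3, 5, 2), oracle_hwe(3, 5, 2), tolerance = 1e-9)
  p_excess <- hwe_exact_p(0, 50, 0)
  expect_equal(p_excess, oracle_hwe(0, 50, 0), tolerance = 1e-9)
  expect_lt(p_excess, 1e-4)
  set.seed(9)
  for (i in 1:200) {
    g <- as.vector(rmultinom(1, sample(2:40, 1), c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact_p(g[1], g[2], g[3]), oracle_hwe(g[1], g[2], g[3]),
                 tolerance = 1e-9)
  }
})

test_that("strict segregation classes and their mirror symmetry", {
  expect_equal(classify_segregation(c(16, 0, 0), c(0, 15, 0)), "male_het")
  expect_equal(classify_segregation(c(16, 0, 0), c(15, 0, 0)), "none")
  expect_equal(classify_segregation(c(0, 16, 0), c(15, 0, 0)), "female_het")
  # hom-alt females count as strict too
  expect_equal(classify_segregation(c(0, 0, 16), c(0, 15, 0)), "male_het")
  # mirror property: swapping the sexes swaps the class
  set.seed(3)
  mirror <- c(male_het = "female_het", female_het = "male_het",
              none = "none")
  for (i in 1:100) {
    f <- as.vector(rmultinom(1, 16, runif(3)))
    m <- as.vector(rmultinom(1, 15, runif(3)))
    cls <- classify_segregation(f, m, 16, 15)
    expect_equal(classify_segregation(m, f, 15, 16),
                 unname(mirror[cls]))
  }
})

test_that("call-fraction guard downgrades sparsely genotyped sites", {
  # 11 of 15 males genotyped: 11/15 < 0.8
  expect_equal(classify_segregation(c(16, 0, 0), c(0, 11, 0),
                                    n_females = 16, n_males = 15), "none")
  expect_equal(classify_segregation(c(16, 0, 0), c(0, 12, 0),
                                    n_females = 16, n_males = 15), "male_het")
})

test_that("scan flags a planted strict site and ignores monomorphic sites", {
  gm <- strict_male_het_matrix(16, 15, positions = c(100L, 200L))
  gm$calls[2, ] <- 0L  # monomorphic site
  scan <- scan_genome(gm)
  expect_true(scan$sex_specific[1])
  expect_equal(scan$segregation, c("male_het", "none"))
  expect_equal(scan$fisher_p[2], 1)
  expect_false(scan$significant[2])
  expect_equal(scan$fisher_p[1], 1 / choose(31, 16), tolerance = 1e-12)
  expect_equal(infer_heterogamety(scan)$system, "XY")
})

test_that("significance boundary sits between 13+13 and 14+14", {
  scan14 <- scan_genome(strict_male_het_matrix(14, 14))
  scan13 <- scan_genome(strict_male_het_matrix(13, 13))
  # balanced cohorts carry the reflected-table tie
  expect_equal(scan14$fisher_p[1], 2 / choose(28, 14), tolerance = 1e-12)
  expect_equal(scan13$fisher_p[1], 2 / choose(26, 13), tolerance = 1e-12)
  expect_true(scan14$significant[1])
  expect_false(scan13$significant[1])
})

test_that("HWE filter scope controls which stratum feeds the filter", {
  gm <- strict_male_het_matrix(16, 15)
  gm$calls[1, 1:16] <- 1L  # all females het too (het-excess artefact)
  scan_f <- scan_genome(gm, scan_config(hwe_scope = "females_only"))
  expect_equal(scan_f$hwe_p[1], hwe_exact_p(0, 16, 0))
  scan_m <- scan_genome(gm, scan_config(hwe_scope = "males_only"))
  expect_equal(scan_m$hwe_p[1], hwe_exact_p(0, 15, 0))
  scan_a <- scan_genome(gm, scan_config(hwe_scope = "all_samples"))
  expect_equal(scan_a$hwe_p[1], hwe_exact_p(0, 31, 0))
  expect_equal(scan_genome(gm, scan_config(hwe_scope = "none"))$hwe_p[1], 1)
  # a 31-sample all-het artefact is far out of HWE and is filtered
  expect_lt(scan_a$hwe_p[1], 1e-4)
  expect_false(scan_a$significant[1])
  # a true sex-linked site survives under the homogametic control stratum
  gm2 <- strict_male_het_matrix(16, 15)
  expect_true(
    scan_genome(gm2, scan_config(hwe_scope = "females_only"))$significant[1])
})

test_that("a null scan of HWE background yields no significant site", {
  set.seed(21)
  n <- 31
  samples <- toy_samples(16, 15)
  p <- runif(1000, 0.05, 0.5)
  calls <- matrix(rbinom(1000 * n, 2L, rep(p, n)), nrow = 1000)
  sites <- tibble::tibble(scaffold = "bg", pos = seq_len(1000) * 10L,
                          ref = "A", alt = "T")
  scan <- scan_genome(genotype_matrix(sites, samples, calls))
  expect_equal(sum(scan$significant), 0)
})

test_that("region re-scan recovers the published indel at the printed p", {
  v <- reference_region_variants()
  gm <- counts_to_matrix(v)
  gm2 <- filter_biallelic(gm, c("snp", "indel"), quiet = TRUE)
  res <- rescan_region(gm2, "scaffold_064", c(3723782, 3730295))
  indel <- res[res$variant_class == "indel", ]
  expect_equal(nrow(indel), 1L)
  expect_equal(indel$ref, "GTAATGTAG")
  expect_equal(indel$segregation, "male_het")
  expect_true(indel$sex_specific)
  expect_equal(signif(indel$fisher_p, 3), 3.33e-9)
  # empty window is empty, not an error
  expect_equal(nrow(rescan_region(gm2, "scaffold_064", c(1, 2))), 0L)
})

test_that("Manhattan export accumulates positions across scaffolds", {
  gm <- strict_male_het_matrix(3, 3, positions = c(100L, 200L))
  gm$sites$scaffold <- c("a", "b")
  gm$sites$pos <- c(100L, 50L)
  gm <- genotype_matrix(gm$sites, gm$samples, gm$calls)
  mt <- manhattan_table(scan_genome(gm))
  expect_equal(mt$cum_pos, c(100, 150))
  expect_equal(mt$scaffold_index, c(1L, 2L))
})
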