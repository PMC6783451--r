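# build a two-site genotype matrix from explicit genotype pairs
pair_calls <- function(gi, gj) {
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(gi)),
    sex = rep(c("female", "male"), length.out = length(gi)))
  sites <- tibble::tibble(scaffold = "sc", pos = c(100L, 200L),
                          ref = "A", alt = "T")
  genotype_matrix(sites, samples, rbind(gi, gj))
}

test_that("EM resolves perfect coupling without off-diagonal mass", {
  # 16 hom-ref/hom-ref and 15 het/het samples: the only phase-consistent
  # solution puts all mass on AB and ab
  gi <- rep(c(0L, 1L), c(16, 15))
  fr <- em_haplotype_frequencies(gi, gi)
  expect_equal(unname(fr$freqs),
               c(47 / 62, 0, 0, 15 / 62), tolerance = 1e-8)
  expect_equal(fr$n_informative, 31L)
})

test_that("EM frequencies sum to one and reproduce allele margins", {
  set.seed(5)
  for (i in 1:25) {
    gi <- hwe_calls(40, runif(1, 0.2, 0.8))
    gj <- hwe_calls(40, runif(1, 0.2, 0.8))
    gi[sample(40, 3)] <- NA
    fr <- em_haplotype_frequencies(gi, gj)
    expect_equal(sum(fr$freqs), 1, tolerance = 1e-9)
    if (fr$informative) {
      expect_equal(fr$freqs[["p_AB"]] + fr$freqs[["p_Ab"]], fr$p_A,
                   tolerance = 1e-6)
      expect_equal(fr$freqs[["p_AB"]] + fr$freqs[["p_aB"]], fr$p_B,
                   tolerance = 1e-6)
    }
  }
})

test_that("EM recovers phased haplotype frequencies from unphased data", {
  set.seed(17)
  for (i in 1:10) {
    h <- as.vector(rmultinom(1, 1, rep(1, 4)))  # pick a skewed target
    target <- (c(4, 2, 2, 4) + 6 * h) / sum(c(4, 2, 2, 4) + 6 * h)
    haps <- sample(4, 1000, replace = TRUE, prob = target)
    # haplotypes: 1=AB, 2=Ab, 3=aB, 4=ab; genotype = #alt alleles
    a_dose <- c(0L, 0L, 1L, 1L)[haps]   # 'a' is the alt allele at site i
    b_dose <- c(0L, 1L, 0L, 1L)[haps]
    gi <- a_dose[seq(1, 999, 2)] + a_dose[seq(2, 1000, 2)]
    gj <- b_dose[seq(1, 999, 2)] + b_dose[seq(2, 1000, 2)]
    phased <- tabulate(haps, 4) / 1000
    fr <- em_haplotype_frequencies(gi, gj)
    expect_lt(max(abs(fr$freqs - phased)), 0.02)
  }
})

test_that("pairwise LD honours zero-cell and independence identities", {
  # zero cell at the MLE -> D' = 1
  gi <- rep(c(0L, 1L), c(16, 15))
  ld <- pairwise_ld(em_haplotype_frequencies(gi, gi))
  expect_equal(ld$d_prime, 1)
  expect_gte(ld$lod, 2)
  expect_equal(ld$pair_class, "strong_ld")
  # exact independence -> D = 0, r2 = 0, lod = 0
  gi2 <- rep(c(0L, 0L, 2L, 2L), each = 5)
  gj2 <- rep(c(0L, 2L, 0L, 2L), each = 5)
  ld2 <- pairwise_ld(em_haplotype_frequencies(gi2, gj2))
  expect_equal(ld2$D, 0, tolerance = 1e-9)
  expect_equal(ld2$r2, 0, tolerance = 1e-9)
  expect_equal(ld2$lod, 0, tolerance = 1e-6)
})

test_that("monomorphic input is uninformative, not an error", {
  fr <- em_haplotype_frequencies(rep(0L, 20), hwe_calls(20, 0.4))
  expect_false(fr$informative)
  expect_equal(pairwise_ld(fr)$pair_class, "uninformative")
})

test_that("D' CI bounds bracket the MLE and are grid-stable", {
  set.seed(23)
  for (i in 1:15) {
    gi <- hwe_calls(31, runif(1, 0.15, 0.5))
    gj <- ifelse(runif(31) < 0.8, gi, hwe_calls(31, 0.3))
    fr <- em_haplotype_frequencies(gi, gj)
    if (!fr$informative) next
    ld <- pairwise_ld(fr)
    expect_true(ld$ci_low >= 0 && ld$ci_high <= 1)
    expect_lte(ld$ci_low, ld$ci_high)
    expect_lte(ld$ci_low, ld$d_prime + 1e-9)
    # the interval brackets an interior MLE; at the boundary D' = 1 the
    # upper tail-quantile bound legitimately sits a few grid steps below
    if (ld$d_prime < 0.99) {
      expect_gte(ld$ci_high, ld$d_prime - 1e-9)
    } else {
      expect_gte(ld$ci_high, ld$d_prime - 0.01)
    }
    fine <- pairwise_ld(fr, ld_config(dprime_grid_step = 1e-4))
    expect_lte(abs(ld$ci_low - fine$ci_low), 0.001 + 1e-9)
    expect_lte(abs(ld$ci_high - fine$ci_high), 0.001 + 1e-9)
  }
})

test_that("five perfectly linked markers form one block", {
  set.seed(31)
  g <- rep(c(0L, 1L), c(16, 15))
  calls <- matrix(rep(g, each = 5), nrow = 5)
  sites <- tibble::tibble(scaffold = "sc", pos = c(100L, 300L, 700L, 900L, 1500L),
                          ref = "A", alt = "T")
  gm <- genotype_matrix(sites, toy_samples(16, 15), calls)
  b <- gabriel_blocks(gm, "sc")
  expect_equal(nrow(b), 1L)
  expect_equal(b$first_pos, 100L)
  expect_equal(b$last_pos, 1500L)
  expect_equal(b$span_bp, 1401L)
  expect_equal(b$n_markers, 5L)
})

test_that("two linked clusters split by equilibrium markers give two blocks", {
  set.seed(47)
  ok <- 0L
  for (rep_i in 1:20) {
    n <- 62
    gA <- hwe_calls(n, 0.4)     # cluster A genotype, shared by its 5 markers
    gB <- hwe_calls(n, 0.4)
    mid <- replicate(3, hwe_calls(n, 0.4))  # independent separators
    calls <- rbind(matrix(rep(gA, each = 5), 5),
                   t(mid),
                   matrix(rep(gB, each = 5), 5))
    sites <- tibble::tibble(scaffold = "sc",
                            pos = as.integer(seq(100, by = 150, length.out = 13)),
                            ref = "A", alt = "T")
    gm <- genotype_matrix(sites, toy_samples(31, 31), calls)
    b <- gabriel_blocks(gm, "sc")
    cluster_blocks <- sum(b$n_markers >= 4)
    if (nrow(b) == 2 && cluster_blocks == 2 &&
        b$first_pos[1] == 100L && b$last_pos[2] == 1900L) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("a single eligible marker yields no blocks", {
  g <- hwe_calls(31, 0.4)
  sites <- tibble::tibble(scaffold = "sc", pos = c(100L, 200L),
                          ref = "A", alt = "T")
  calls <- rbind(g, rep(0L, 31))  # second marker monomorphic (MAF 0)
  gm <- genotype_matrix(sites, toy_samples(16, 15), calls)
  expect_equal(nrow(gabriel_blocks(gm, "sc")), 0L)
})

test_that("blocks are disjoint and block endpoints are strong-LD pairs", {
  sim <- simulate_cohort(cohort_config(seed = 19L, n_flank_sites = 3L),
                         reference = FALSE)
  gm <- filter_biallelic(sim$gm, "snp", quiet = TRUE)
  r <- sim$truth$region
  win <- c(r$first_core_pos - 5000L, r$last_core_pos + 5000L)
  pairs <- scaffold_pairwise_ld(gm, r$scaffold, window = win)
  b <- gabriel_blocks(gm, r$scaffold, window = win, pairs = pairs)
  expect_gt(nrow(b), 0L)
  if (nrow(b) > 1) {
    expect_true(all(b$first_pos[-1] > b$last_pos[-nrow(b)]))
  }
  for (k in seq_len(nrow(b))) {
    end_pair <- pairs[pairs$pos_i == b$first_pos[k] &
                        pairs$pos_j == b$last_pos[k], ]
    expect_equal(end_pair$pair_class, "strong_ld")
  }
})

test_that("every eligible core pair is in complete LD at error rate zero", {
  sim <- simulate_cohort(cohort_config(seed = 29L, missing_rate = 0),
                         reference = FALSE)
  gm <- filter_biallelic(sim$gm, "snp", quiet = TRUE)
  r <- sim$truth$region
  core <- subset_region(gm, r$scaffold,
                        c(r$first_core_pos, r$last_core_pos))
  core_pos <- sim$truth$sites$pos[sim$truth$sites$site_class == "core"]
  keep <- core$sites$pos %in% core_pos
  core <- genotype_matrix(core$sites[keep, ], core$samples,
                          core$calls[keep, , drop = FALSE])
  pairs <- scaffold_pairwise_ld(core, r$scaffold)
  expect_true(all(pairs$d_prime == 1))
  expect_true(all(pairs$pair_class == "strong_ld"))
})

test_that("block spans use the 1-based inclusive convention", {
  expect_equal(block_span(3723703, 3726876), 3174L)
  expect_equal(block_span(13757866, 13758271), 406L)
  expect_equal(block_span(5, 5), 1L)
  expect_error(block_span(10, 9), "first_pos")
})
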