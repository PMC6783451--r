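revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("a full-span amplicon is found and the 3' anchor is enforced", {
  tmpl <- "ACGTACGGTTCAGGCATTAC"
  pp <- primer_pair("t", forward = substr(tmpl, 1, 6),
                    reverse = revcomp(substr(tmpl, 15, 20)))
  prod <- insilico_pcr(pp, tmpl)
  expect_equal(prod$length_bp, 20L)
  # mismatch at the forward primer's 3'-terminal base kills binding
  fwd_bad <- paste0(substr(tmpl, 1, 5), "A")  # template has G at pos 6
  expect_equal(nrow(insilico_pcr(primer_pair("t", fwd_bad,
                                             revcomp(substr(tmpl, 15, 20))),
                                 tmpl)), 0L)
  # two mismatches away from the anchor still bind
  fwd_mm <- paste0("TT", substr(tmpl, 3, 6))
  expect_equal(insilico_pcr(primer_pair("t", fwd_mm,
                                        revcomp(substr(tmpl, 15, 20))),
                            tmpl)$length_bp, 20L)
  # a template shorter than the primer yields nothing, silently
  expect_equal(nrow(insilico_pcr(pp, "ACG")), 0L)
})

test_that("a heterozygous deletion yields two products differing by its length", {
  set.seed(11)
  left <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  del <- "GTAATGTA"
  right <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  hap_ref <- paste0(left, del, right)
  hap_del <- paste0(left, right)
  pp <- primer_pair("del", forward = substr(left, 1, 18),
                    reverse = revcomp(substr(right, 43, 60)))
  prods <- insilico_pcr(pp, c(hap_ref, hap_del))
  expect_equal(nrow(prods), 2L)
  expect_equal(diff(sort(prods$length_bp)), nchar(del))
  expect_equal(max(prods$length_bp), nchar(hap_ref))
})

test_that("in-silico PCR is strand symmetric", {
  set.seed(13)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  fwd <- substr(tmpl, 21, 40)
  rev <- revcomp(substr(tmpl, 141, 160))
  a <- insilico_pcr(primer_pair("fw", fwd, rev), tmpl)
  b <- insilico_pcr(primer_pair("rc", rev, fwd), revcomp(tmpl))
  expect_equal(sort(a$length_bp), sort(b$length_bp))
  expect_equal(a$length_bp, 140L)
})

test_that("sex-calling rules reproduce the published band logic", {
  size_rule <- assay_rule("size_dimorphism")
  p <- function(lens) tibble::tibble(length_bp = lens)
  expect_equal(call_sex(p(c(142L, 149L)), size_rule)$call, "male")
  expect_equal(call_sex(p(149L), size_rule)$call, "female")
  expect_equal(call_sex(p(integer(0)), size_rule)$call, "undetermined")

  pres_rule <- assay_rule("presence", control_bp = 268L)
  expect_equal(call_sex(p(c(113L, 268L)), pres_rule)$call, "male")
  expect_equal(call_sex(p(268L), pres_rule)$call, "female")
  expect_equal(call_sex(p(integer(0)), pres_rule)$call, "undetermined")
  expect_equal(call_sex(p(113L), pres_rule)$call, "undetermined")
})

test_that("accuracy scoring counts undetermined as incorrect", {
  truth <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          sex = c("male", "male", "female", "female"))
  calls <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          call = c("male", "undetermined", "female", "male"))
  acc <- assay_accuracy(calls, truth)
  expect_equal(acc$accuracy, 0.5)
  expect_equal(acc$accuracy_male, 0.5)
  expect_equal(acc$accuracy_female, 0.5)
  expect_equal(acc$n_undetermined, 1L)
  expect_error(
    assay_accuracy(tibble::tibble(sample_id = "zz", call = "male"), truth),
    "not in truth")
})

# shared fixture: a small cohort with a planted heterozygous male indel
indel_cohort <- function(seed, error_rate = 0) {
  cohort_config(
    scaffolds = c(scA = 40000L, scB = 40000L), sd_scaffold = "scA",
    sd_start = 15000L, n_core_sites = 5L, core_spacing_bp = 400L,
    n_background_sites = 60L, missing_rate = 0, error_rate = error_rate,
    core_indel = TRUE, seed = seed)
}

indel_assay <- function(sim) {
  gm <- sim$gm
  i <- which(gm$sites$variant_class == "indel")
  pos <- gm$sites$pos[i]
  ref <- sim$ref[["scA"]]
  window <- c(pos - 400L, pos + 400L)
  fwd <- substr(ref, pos - 60, pos - 41)
  rev <- revcomp(substr(ref, pos + 41, pos + 60))
  list(pair = primer_pair("indel_span", fwd, rev), window = window,
       target = gm$sites[i, ])
}

test_that("the size-dimorphism assay is perfect on an error-free cohort", {
  sim <- simulate_cohort(indel_cohort(seed = 5L))
  a <- indel_assay(sim)
  calls <- run_assay(sim$gm, sim$ref, "scA", a$window, a$pair,
                     assay_rule("size_dimorphism"))
  acc <- assay_accuracy(calls, sim$gm$samples)
  expect_equal(acc$accuracy, 1)
  # male lanes show the 8-bp double band, female lanes a single band
  male_prods <- calls$products[[match("M01", calls$sample_id)]]
  expect_equal(diff(male_prods), 8L)
  expect_equal(length(calls$products[[match("F01", calls$sample_id)]]), 1L)
})

test_that("per-sex assay errors track the genotyping error model", {
  # an error at the target flips a male call always (het -> hom, single
  # band) but a female call only when hom_ref -> het (half of errors)
  e <- 0.3
  wrong_m <- 0L; wrong_f <- 0L; n_m <- 0L; n_f <- 0L
  for (seed in 1:8) {
    sim <- simulate_cohort(indel_cohort(seed = 100L + seed, error_rate = e))
    a <- indel_assay(sim)
    calls <- run_assay(sim$gm, sim$ref, "scA", a$window, a$pair,
                       assay_rule("size_dimorphism"))
    j <- dplyr::inner_join(calls, sim$gm$samples, by = "sample_id")
    wrong_m <- wrong_m + sum(j$sex == "male" & j$call != "male")
    wrong_f <- wrong_f + sum(j$sex == "female" & j$call != "female")
    n_m <- n_m + sum(j$sex == "male"); n_f <- n_f + sum(j$sex == "female")
  }
  expect_equal(wrong_m / n_m, e, tolerance = 3 * sqrt(e * (1 - e) / n_m) / e)
  expect_equal(wrong_f / n_f, e / 2,
               tolerance = 3 * sqrt(e / 2 * (1 - e / 2) / n_f) / (e / 2))
})

test_that("diagnostic site ranking puts block indels before SNPs", {
  scan <- scan_genome(filter_biallelic(
    counts_to_matrix(reference_region_variants()), c("snp", "indel"),
    quiet = TRUE))
  summaries <- tibble::tibble(
    scaffold = "scaffold_064", scaffold_size_bp = NA_integer_,
    n_total_sites = 51L, n_sex_specific = 51L,
    region_start = 3723782L, region_end = 3730295L, region_size_bp = 6514L,
    n_ld_blocks = 4L, max_block_span_bp = 3174L,
    max_block_start = 3723703L, max_block_end = 3726876L)
  mr <- select_marker_region(summaries, scan)
  picks <- pick_diagnostic_sites(mr)
  expect_gt(nrow(picks), 0L)
  expect_equal(picks$variant_class[1], "indel")
  expect_true(all(picks$pos >= 3723703 & picks$pos <= 3726876))
  expect_equal(nrow(pick_diagnostic_sites(
    structure(list(found = FALSE), class = "marker_region"))), 0L)
})
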