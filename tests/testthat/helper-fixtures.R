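# small in-code fixtures shared across test files

toy_samples <- function(n_f = 2, n_m = 2) {
  tibble::tibble(
    sample_id = c(sprintf("F%02d", seq_len(n_f)),
                  sprintf("M%02d", seq_len(n_m))),
    sex = rep(c("female", "male"), c(n_f, n_m)))
}

# a matrix where every female is hom-ref and every male het at each site
strict_male_het_matrix <- function(n_f, n_m, positions = c(100L, 200L),
                                   scaffold = "sc1") {
  samples <- toy_samples(n_f, n_m)
  sites <- tibble::tibble(scaffold = scaffold, pos = positions,
                          ref = "A", alt = "T")
  calls <- matrix(rep(rep(c(0L, 1L), c(n_f, n_m)), each = length(positions)),
                  nrow = length(positions))
  genotype_matrix(sites, samples, calls)
}

write_toy_vcf <- function(path, extra_site = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=sc1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "sc1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t0|1",
    "sc1\t200\t.\tG\tC\t.\t.\t.\tGT\t./1\t1/1",
    "sc1\t300\t.\tT\tA\t.\t.\t.\tGT\t./.\t0/0")
  writeLines(c(lines, extra_site), path)
  path
}

# HWE genotypes, independent of sex, at one site for n samples
hwe_calls <- function(n, p) rbinom(n, 2L, p)
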