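#' Published male-specific variants of the tuna scaffold_064 region
#'
#' The 51 male-specific variants (50 SNPs and one 8-bp deletion) reported
#' in the ~6.5 kb sex-determination region of Pacific bluefin tuna
#' scaffold_064, from whole-genome resequencing of 16 females and 15
#' males: position, alleles, per-sex genotype counts
#' (hom-ref/het/hom-alt; one site has a single ungenotyped male) and the
#' published exact p-value. Every row is homozygous-reference in all
#' females and heterozygous in all genotyped males.
#'
#' @return A tibble with columns `scaffold`, `pos`, `ref`, `alt`,
#'   `f_hom_ref`, `f_het`, `f_hom_alt`, `m_hom_ref`, `m_het`,
#'   `m_hom_alt`, `p_printed`.
#' @export
reference_region_variants <- function() {
  readr::read_tsv(system.file("extdata", "scaffold064_variants.tsv",
                              package = "sexmarkr"),
                  col_types = "cicciiiiiid", progress = FALSE)
}

#' Published per-scaffold summary of the tuna sex-specific scan
#'
#' One row per scaffold that carried sex-specific SNPs in the published
#' Pacific bluefin tuna scan (250 sex-specific SNPs genome-wide): scaffold
#' size, total and sex-specific SNP counts, region bounds, and — for the
#' seven scaffolds with more than 10 sex-specific SNPs — the LD-block
#' count and maximum-block bounds. All sizes use the 1-based inclusive
#' convention.
#'
#' @return A tibble.
#' @export
reference_scaffold_summary <- function() {
  readr::read_tsv(system.file("extdata", "scaffold_summary.tsv",
                              package = "sexmarkr"),
                  col_types = "ciiiiiiiiii", progress = FALSE)
}

#' Published sex-identification primer pairs
#'
#' The three sex-specific primer pairs designed in the largest LD block of
#' tuna scaffold_064 plus the mitochondrial ND4 internal-control pair:
#' pair I (113-bp male-specific product), pair II (143 bp, allele-specific
#' reverse primers combined at equal concentrations), pair III (142-bp
#' male-specific and 149-bp both-sex products) and pair IV (268-bp ND4
#' control).
#'
#' @return A tibble: `pair`, `name`, `role`, `sequence` (5' to 3'),
#'   `expected_bp` (";"-separated when a pair yields two products).
#' @export
reference_primers <- function() {
  readr::read_tsv(system.file("extdata", "sex_primers.tsv",
                              package = "sexmarkr"),
                  col_types = "ccccc", progress = FALSE)
}

#' Assemble a genotype matrix from a published-style count table
#'
#' Expands per-sex genotype counts (as in the shipped
#' [reference_region_variants()] table) into an explicit genotype matrix:
#' for each site the females fill the female count classes in sample
#' order, the males likewise, and any shortfall against the cohort size
#' becomes a missing call. Within-sex sample order is arbitrary under the
#' scan's statistics, which depend on counts only.
#'
#' @param counts Tibble with the [reference_region_variants()] columns.
#' @param n_females,n_males Cohort sizes the counts came from.
#' @return A [genotype_matrix()].
#' @export
counts_to_matrix <- function(counts, n_females = 16L, n_males = 15L) {
  expand_sex <- function(c0, c1, c2, n) {
    g <- rep(c(0L, 1L, 2L, NA_integer_),
             c(c0, c1, c2, n - (c0 + c1 + c2)))
    g
  }
  calls <- t(mapply(function(f0, f1, f2, m0, m1, m2) {
    c(expand_sex(f0, f1, f2, n_females), expand_sex(m0, m1, m2, n_males))
  }, counts$f_hom_ref, counts$f_het, counts$f_hom_alt,
     counts$m_hom_ref, counts$m_het, counts$m_hom_alt))
  samples <- tibble(
    sample_id = c(sprintf("F%02d", seq_len(n_females)),
                  sprintf("M%02d", seq_len(n_males))),
    sex = rep(c("female", "male"), c(n_females, n_males)))
  genotype_matrix(counts[, c("scaffold", "pos", "ref", "alt")], samples,
                  calls)
}
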