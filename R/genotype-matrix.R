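#' Construct a genotype matrix
#'
#' The central container of the pipeline: an ordered set of variant sites, a
#' cohort of sexed samples, and a sites-by-samples grid of diploid biallelic
#' genotype calls. Calls are encoded as the count of alternate alleles
#' (`0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing).
#'
#' @param sites A tibble with columns `scaffold` (character), `pos`
#'   (1-based bp, integer), `ref`, `alt` (character alleles; `alt` may hold
#'   several comma-separated alleles for multiallelic sites prior to
#'   filtering). A `variant_class` column (`"snp"`, `"indel"`, `"other"`) is
#'   derived if absent.
#' @param samples A tibble with columns `sample_id` (unique character) and
#'   `sex` (`"female"`, `"male"`, or `"unknown"`). Typically from
#'   [read_sex_map()].
#' @param calls An integer matrix with `nrow(sites)` rows and
#'   `nrow(samples)` columns holding values in `{0, 1, 2, NA}`.
#'
#' @details Within each scaffold, positions must be strictly increasing; the
#'   constructor enforces this, mirroring sorted VCF input. Samples of
#'   unknown sex are carried in the container but excluded from every
#'   sex-contrast computation downstream.
#'
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' sites <- tibble::tibble(scaffold = "s1", pos = c(100L, 200L),
#'                         ref = c("A", "G"), alt = c("T", "C"))
#' samples <- tibble::tibble(sample_id = c("f1", "m1"),
#'                           sex = c("female", "male"))
#' gm <- genotype_matrix(sites, samples, matrix(c(0L, 1L, 0L, 1L), 2, 2))
#' gm
genotype_matrix <- function(sites, samples, calls) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  if (!all(c("scaffold", "pos", "ref", "alt") %in% names(sites))) {
    .stop("`sites` needs columns scaffold, pos, ref, alt", "bad_sites")
  }
  if (!all(c("sample_id", "sex") %in% names(samples))) {
    .stop("`samples` needs columns sample_id, sex", "bad_samples")
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- samples$sample_id[duplicated(samples$sample_id)][1]
    .stop(paste0("duplicate sample_id ", dup), "duplicate_sample")
  }
  if (!all(samples$sex %in% c("female", "male", "unknown"))) {
    .stop("sample sex must be female, male or unknown", "bad_sex")
  }
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) .stop("positions must be >= 1", "bad_position")
  if (any(nchar(sites$ref) == 0L)) .stop("ref allele must be non-empty", "bad_allele")
  if (!"variant_class" %in% names(sites)) {
    sites$variant_class <- variant_class(sites$ref, sites$alt)
  }
  calls <- matrix(as.integer(calls), nrow = nrow(sites), ncol = nrow(samples))
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_))) {
    .stop("calls must be 0, 1, 2 or NA", "bad_calls")
  }
  # strictly increasing positions within scaffold (file order preserved)
  viol <- vapply(split(sites$pos, factor(sites$scaffold, unique(sites$scaffold))),
                 function(p) any(diff(p) <= 0), logical(1))
  if (length(viol) && any(viol)) {
    .stop("site positions must be strictly increasing within each scaffold",
          "unsorted_sites")
  }
  colnames(calls) <- samples$sample_id
  structure(list(sites = sites, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' Classify variants as SNP, indel or other
#'
#' A site is a `snp` when the reference and the single alternate allele are
#' both one base; an `indel` when they differ in length; `other` otherwise
#' (including multiallelic records, which are classified on their first
#' alternate but removed by [filter_biallelic()]).
#'
#' @param ref,alt Character vectors of alleles; `alt` may be comma-separated.
#' @return Character vector in `{"snp", "indel", "other"}`.
#' @export
variant_class <- function(ref, alt) {
  first_alt <- sub(",.*$", "", alt)
  dplyr::case_when(
    nchar(ref) == 1L & nchar(first_alt) == 1L ~ "snp",
    nchar(ref) != nchar(first_alt) ~ "indel",
    TRUE ~ "other"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  ns <- table(factor(x$samples$sex, c("female", "male", "unknown")))
  cat(sprintf(
    "<genotype_matrix> %d sites x %d samples (%dF / %dM / %d unknown), %d scaffold(s)\n",
    nrow(x$sites), nrow(x$samples), ns[["female"]], ns[["male"]],
    ns[["unknown"]], length(unique(x$sites$scaffold))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Tidy a genotype matrix into long form
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per site-sample call: `scaffold`, `pos`,
#'   `sample_id`, `sex`, `genotype` (factor `hom_ref`/`het`/`hom_alt`, `NA`
#'   for missing calls).
#' @export
tidy.genotype_matrix <- function(x, ...) {
  long <- tibble(
    scaffold = rep(x$sites$scaffold, times = ncol(x$calls)),
    pos = rep(x$sites$pos, times = ncol(x$calls)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$calls)),
    sex = rep(x$samples$sex, each = nrow(x$calls)),
    genotype = factor(c("hom_ref", "het", "hom_alt")[as.vector(x$calls) + 1L],
                      levels = c("hom_ref", "het", "hom_alt"))
  )
  long
}

#' One-row summary of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: site/sample/scaffold tallies, per-class site
#'   counts and the overall missing-call rate.
#' @export
glance.genotype_matrix <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_samples = nrow(x$samples),
    n_females = sum(x$samples$sex == "female"),
    n_males = sum(x$samples$sex == "male"),
    n_scaffolds = length(unique(x$sites$scaffold)),
    n_snp = sum(x$sites$variant_class == "snp"),
    n_indel = sum(x$sites$variant_class == "indel"),
    missing_rate = mean(is.na(x$calls))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Restrict a genotype matrix to biallelic sites of given classes
#'
#' Multiallelic records (more than one alternate allele) are dropped rather
#' than split: splitting would fabricate sites the cohort was never tested
#' at. Sites whose class is outside `keep_classes` are dropped too. The
#' genome-wide scan uses `keep_classes = "snp"`; the indel-inclusive region
#' re-scan uses `c("snp", "indel")`.
#'
#' @param gm A [genotype_matrix()].
#' @param keep_classes Character vector of retained variant classes.
#' @param quiet Suppress the removal-count message.
#' @return A filtered `genotype_matrix`. Idempotent.
#' @export
filter_biallelic <- function(gm, keep_classes = "snp", quiet = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  multi <- grepl(",", gm$sites$alt, fixed = TRUE)
  keep <- !multi & gm$sites$variant_class %in% keep_classes
  if (!quiet) {
    inform(sprintf(
      "filter_biallelic: kept %d of %d sites (%d multiallelic, %d off-class removed)",
      sum(keep), length(keep), sum(multi), sum(!keep & !multi)))
  }
  genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                  gm$calls[keep, , drop = FALSE])
}

#' Subset a genotype matrix to a scaffold window
#'
#' @param gm A [genotype_matrix()].
#' @param scaffold Scaffold name.
#' @param window Optional `c(start, end)` in 1-based inclusive bp; `NULL`
#'   keeps the whole scaffold.
#' @return A `genotype_matrix` restricted to the window (possibly 0 sites).
#' @export
subset_region <- function(gm, scaffold, window = NULL) {
  keep <- gm$sites$scaffold == scaffold
  if (!is.null(window)) {
    keep <- keep & gm$sites$pos >= window[1] & gm$sites$pos <= window[2]
  }
  genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                  gm$calls[keep, , drop = FALSE])
}
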