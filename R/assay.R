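#' Define a PCR primer pair
#'
#' @param name Pair name (e.g. `"pair_III"`).
#' @param forward Forward primer, 5' to 3', over `A/C/G/T`.
#' @param reverse One or more reverse primers, 5' to 3'. Allele-specific
#'   designs carry two reverse primers (combined at equal concentrations in
#'   the tube); each is tried independently in silico.
#' @param expected_bp Optional expected product length(s), for reporting.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(name, forward, reverse, expected_bp = NULL) {
  check_seq <- function(s) {
    if (!all(grepl("^[ACGT]+$", s))) .stop("primer sequences must be A/C/G/T",
                                           "bad_primer")
  }
  check_seq(forward); check_seq(reverse)
  stopifnot(length(forward) == 1L, length(reverse) >= 1L)
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse), expected_bp = expected_bp),
            class = "primer_pair")
}

#' Define a sex-calling rule for assay products
#'
#' Two decision rules mirror the bench designs: `presence` — a
#' male-specific product whose amplification is only meaningful when an
#' internal control (e.g. a mitochondrial ND4 product) co-amplifies, so a
#' failed control yields `undetermined` rather than `female`; and
#' `size_dimorphism` — an amplicon spanning an indel, so heterozygous
#' (male) templates give a double band and homozygous templates one.
#'
#' @param kind `"presence"` or `"size_dimorphism"`.
#' @param control_bp Control product length; required for `presence`.
#' @return An `assay_rule` list.
#' @export
assay_rule <- function(kind = c("presence", "size_dimorphism"),
                       control_bp = NULL) {
  kind <- match.arg(kind)
  if (kind == "presence" && is.null(control_bp)) {
    .stop("presence rule requires control_bp", "bad_rule")
  }
  structure(list(kind = kind, control_bp = control_bp), class = "assay_rule")
}

#' Rank diagnostic variants inside a marker region
#'
#' Candidate variants for primer design: the sex-specific sites lying
#' within the selected block, with indels first (they support
#' size-dimorphism designs directly), then SNPs ordered by p-value and
#' position.
#'
#' @param region A `marker_region` from [select_marker_region()].
#' @param scan Optional `sex_scan` tibble; defaults to the sites carried by
#'   the region.
#' @return A tibble of candidate sites in priority order.
#' @export
pick_diagnostic_sites <- function(region, scan = NULL) {
  if (!isTRUE(region$found)) return(tibble())
  sites <- if (is.null(scan)) region$sites else {
    scan |>
      dplyr::filter(.data$sex_specific, .data$scaffold == region$scaffold,
                    .data$pos >= region$block_start,
                    .data$pos <= region$block_end)
  }
  sites |>
    dplyr::arrange(dplyr::desc(.data$variant_class == "indel"),
                   .data$fisher_p, .data$pos)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all binding sites of `primer` on the plus strand of `template`:
# <= max_mismatch total mismatches AND an exact match over the 3'-terminal
# `anchor` bases. Returns start positions (of the primer's 5' end).
.bind_sites <- function(primer, template, max_mismatch, anchor) {
  k <- nchar(primer); L <- nchar(template)
  if (L < k) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch)
  starts <- BiocGenerics::start(hits)
  if (length(starts) == 0) return(integer(0))
  tail_ok <- vapply(starts, function(s) {
    substr(template, s + k - anchor, s + k - 1L) ==
      substr(primer, k - anchor + 1L, k)
  }, logical(1))
  starts[tail_ok]
}

#' In-silico PCR on haplotype templates
#'
#' Models amplification as sequence matching (no thermodynamics): a primer
#' binds where its 3'-terminal `anchor_len` bases match exactly and it has
#' at most `max_mismatch` mismatches overall; every forward/reverse
#' binding pair in convergent orientation within `max_product_bp` yields a
#' product whose length is the inclusive distance between the two primers'
#' outermost 5' ends. Each member of the reverse set is tried. Duplicate
#' product lengths are deduplicated per haplotype.
#'
#' @param pair A [primer_pair()].
#' @param templates Character vector of template sequences (typically the
#'   two haplotypes of one sample across the marker region).
#' @param max_mismatch Maximum total mismatches per primer (default 2).
#' @param anchor_len Length of the exact 3'-terminal anchor (default 3).
#' @param max_product_bp Maximum amplicon length (default 2000).
#' @return A tibble: `primer_pair`, `haplotype_index` (1-based),
#'   `length_bp`. Zero rows when nothing amplifies (e.g. template shorter
#'   than a primer).
#' @export
insilico_pcr <- function(pair, templates, max_mismatch = 2L,
                         anchor_len = 3L, max_product_bp = 2000L) {
  stopifnot(inherits(pair, "primer_pair"))
  templates <- toupper(templates)
  out <- purrr::imap_dfr(templates, function(tmpl, h) {
    f_starts <- .bind_sites(pair$forward, tmpl, max_mismatch, anchor_len)
    if (length(f_starts) == 0) return(tibble())
    purrr::map_dfr(pair$reverse, function(rv) {
      rc <- .revcomp(rv)
      r_starts <- .bind_sites(rc, tmpl, max_mismatch, anchor_len)
      if (length(r_starts) == 0) return(tibble())
      r_ends <- r_starts + nchar(rv) - 1L  # reverse primer 5' end on plus strand
      combos <- tidyr::expand_grid(f = f_starts, r = r_ends) |>
        dplyr::mutate(length_bp = .data$r - .data$f + 1L) |>
        dplyr::filter(.data$length_bp >= nchar(pair$forward) + nchar(rv),
                      .data$length_bp <= max_product_bp)
      if (nrow(combos) == 0) return(tibble())
      tibble(haplotype_index = as.integer(h), length_bp = combos$length_bp)
    })
  })
  if (nrow(out) == 0) {
    return(tibble(primer_pair = character(0), haplotype_index = integer(0),
                  length_bp = integer(0)))
  }
  out |>
    dplyr::distinct(.data$haplotype_index, .data$length_bp) |>
    dplyr::mutate(primer_pair = pair$name, .before = 1) |>
    dplyr::arrange(.data$haplotype_index, .data$length_bp)
}

#' Call sex from assay products
#'
#' @param products Tibble from [insilico_pcr()] (products of all primer
#'   pairs run on one sample, both haplotypes pooled — as on a gel lane).
#' @param rule An [assay_rule()].
#' @param sample_id Optional sample label carried into the result.
#' @return A one-row tibble: `sample_id`, `call`
#'   (`male`/`female`/`undetermined`), `products` (list column of distinct
#'   lengths).
#' @export
call_sex <- function(products, rule, sample_id = NA_character_) {
  lens <- sort(unique(products$length_bp))
  if (rule$kind == "presence") {
    control <- rule$control_bp %in% lens
    target <- setdiff(lens, rule$control_bp)
    call <- if (!control) "undetermined"
      else if (length(target) > 0) "male" else "female"
  } else {
    target <- setdiff(lens, rule$control_bp %||% integer(0))
    call <- if (length(target) >= 2) "male"
      else if (length(target) == 1) "female" else "undetermined"
  }
  tibble(sample_id = sample_id, call = call, products = list(lens))
}

#' Score assay calls against known sex
#'
#' @param calls Tibble of per-sample calls (columns `sample_id`, `call`).
#' @param truth Tibble with `sample_id`, `sex` — e.g. from
#'   [read_sex_map()]. Every called sample must be present.
#' @return A one-row tibble: `n`, `n_correct`, `accuracy`, per-sex
#'   accuracies and `n_undetermined`. Undetermined calls count as
#'   incorrect — the conservative reading of bench amplification failures.
#' @export
assay_accuracy <- function(calls, truth) {
  unknown <- setdiff(calls$sample_id, truth$sample_id)
  if (length(unknown)) {
    .stop(paste0("sample(s) not in truth: ", paste(unknown, collapse = ", ")),
          "unknown_sample")
  }
  j <- dplyr::inner_join(calls, truth, by = "sample_id") |>
    dplyr::mutate(correct = .data$call == .data$sex)
  by_sex <- function(s) {
    sub <- j[j$sex == s, ]
    if (nrow(sub) == 0) NA_real_ else mean(sub$correct)
  }
  tibble(n = nrow(j), n_correct = sum(j$correct),
         accuracy = mean(j$correct),
         accuracy_male = by_sex("male"),
         accuracy_female = by_sex("female"),
         n_undetermined = sum(j$call == "undetermined"))
}

#' Build a sample's two haplotype templates across a window
#'
#' Substitutes the sample's alleles into the reference window to produce
#' the two sequence templates in-silico PCR runs on. Heterozygous sites
#' place the reference allele on haplotype 1 and the alternate on
#' haplotype 2 — for a sex-linked region in the heterogametic sex this
#' reconstructs the X-like and Y-like haplotypes, since all alternates
#' travel together on the sex-limited chromosome; elsewhere phase is
#' arbitrary, which only matters to multi-locus designs. Indels shift
#' coordinates; variants are applied right to left.
#'
#' @param gm A [genotype_matrix()].
#' @param ref_seqs Named character vector of scaffold sequences.
#' @param scaffold,window Region to excise (`c(start, end)` bp).
#' @param sample_id Sample whose genotypes are substituted.
#' @return Character vector of two template sequences. Sites with missing
#'   calls keep the reference allele on both haplotypes.
#' @export
sample_haplotypes <- function(gm, ref_seqs, scaffold, window, sample_id) {
  if (!scaffold %in% names(ref_seqs)) {
    .stop(paste0("scaffold not in reference: ", scaffold), "missing_scaffold")
  }
  if (!sample_id %in% gm$samples$sample_id) {
    .stop(paste0("unknown sample ", sample_id), "unknown_sample")
  }
  base <- substr(ref_seqs[[scaffold]], window[1], window[2])
  keep <- which(gm$sites$scaffold == scaffold & gm$sites$pos >= window[1] &
                  gm$sites$pos + nchar(gm$sites$ref) - 1L <= window[2])
  col <- match(sample_id, gm$samples$sample_id)
  hap <- c(base, base)
  for (i in rev(keep)) {  # right-to-left so indel shifts don't corrupt offsets
    g <- gm$calls[i, col]
    if (is.na(g) || g == 0L) next
    off <- gm$sites$pos[i] - window[1] + 1L
    ref <- gm$sites$ref[i]; alt <- gm$sites$alt[i]
    splice <- function(s) paste0(substr(s, 1L, off - 1L), alt,
                                 substr(s, off + nchar(ref), nchar(s)))
    if (g == 2L) hap <- c(splice(hap[1]), splice(hap[2]))
    else hap[2] <- splice(hap[2])
  }
  hap
}

#' Run a sex-identification assay over a cohort in silico
#'
#' For each sample: build the two haplotype templates over the assay
#' window, amplify with every primer pair, pool the products, and call sex
#' under the rule.
#'
#' @param gm A [genotype_matrix()].
#' @param ref_seqs Named character vector of scaffold sequences.
#' @param scaffold,window Assay region.
#' @param pairs A [primer_pair()] or list of them.
#' @param rule An [assay_rule()].
#' @param ... Passed to [insilico_pcr()].
#' @return A tibble of per-sample calls ([call_sex()] rows).
#' @export
run_assay <- function(gm, ref_seqs, scaffold, window, pairs, rule, ...) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  purrr::map_dfr(gm$samples$sample_id, function(sid) {
    haps <- sample_haplotypes(gm, ref_seqs, scaffold, window, sid)
    prods <- purrr::map_dfr(pairs, insilico_pcr, templates = haps, ...)
    call_sex(prods, rule, sample_id = sid)
  })
}
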