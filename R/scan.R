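#' Configuration for the sex-association scan
#'
#' @param alpha Per-site significance threshold; the conventional
#'   genome-wide cutoff `5e-8` by default, used in place of an explicit
#'   multiple-testing correction. Significance is strict (`p < alpha`).
#' @param hwe_threshold Sites with an exact Hardy-Weinberg p below this are
#'   filtered out (default `1e-4`), removing call artefacts such as
#'   paralog-collapse heterozygote excess.
#' @param hwe_scope Stratum on which the HWE filter is computed. Default
#'   `"females_only"`: the homogametic sex is the natural control stratum in
#'   an XY system — an all-heterozygous male stratum at a genuinely
#'   sex-linked site is maximally out of HWE and must not disqualify it.
#' @param min_call_fraction Minimum fraction of genotyped (non-missing)
#'   samples required in each sex for a site to be classified or called
#'   significant (default 0.8, tolerating e.g. one missing male out of 15).
#' @return A `scan_config` list.
#' @export
scan_config <- function(alpha = 5e-8, hwe_threshold = 1e-4,
                        hwe_scope = c("females_only", "males_only",
                                      "all_samples", "none"),
                        min_call_fraction = 0.8) {
  hwe_scope <- match.arg(hwe_scope)
  stopifnot(.is_prob(alpha), alpha > 0, alpha < 1,
            .is_prob(hwe_threshold), hwe_threshold < 1,
            .is_prob(min_call_fraction), min_call_fraction > 0)
  structure(list(alpha = alpha, hwe_threshold = hwe_threshold,
                 hwe_scope = hwe_scope,
                 min_call_fraction = min_call_fraction),
            class = "scan_config")
}

#' Per-site sex-by-genotype table
#'
#' Tallies the 2-by-3 contingency table (sex by hom-ref/het/hom-alt) at one
#' site. Missing calls and unknown-sex samples are excluded from the
#' counts.
#'
#' @param gm A [genotype_matrix()].
#' @param site_index Row index of the site.
#' @return A named list with integer vectors `female` and `male`, each
#'   `(hom_ref, het, hom_alt)`.
#' @export
genotype_table <- function(gm, site_index) {
  stopifnot(site_index >= 1, site_index <= nrow(gm$sites))
  row <- gm$calls[site_index, ]
  tab <- function(sex) {
    g <- row[gm$samples$sex == sex]
    c(hom_ref = sum(g == 0L, na.rm = TRUE),
      het = sum(g == 1L, na.rm = TRUE),
      hom_alt = sum(g == 2L, na.rm = TRUE))
  }
  list(female = tab("female"), male = tab("male"))
}

# vectorised per-site counts for all sites: returns tibble f0,f1,f2,m0,m1,m2
.sex_counts <- function(gm) {
  count_sex <- function(sex) {
    m <- gm$calls[, gm$samples$sex == sex, drop = FALSE]
    cbind(rowSums(m == 0L, na.rm = TRUE),
          rowSums(m == 1L, na.rm = TRUE),
          rowSums(m == 2L, na.rm = TRUE))
  }
  f <- count_sex("female"); m <- count_sex("male")
  tibble(f_hom_ref = f[, 1], f_het = f[, 2], f_hom_alt = f[, 3],
         m_hom_ref = m[, 1], m_het = m[, 2], m_hom_alt = m[, 3])
}

#' Exact test of a 2-by-3 sex-by-genotype table
#'
#' Two-sided exact p for independence of sex and genotype class, as in a
#' genotypic case/control association test: all 2-by-3 tables with the
#' observed margins are enumerated and the hypergeometric probabilities of
#' those no more probable than the observed table (within relative
#' tolerance `rel_tol`, absorbing floating error of the log-space sums) are
#' summed.
#'
#' For a fully sex-specific site — all `a` females in one homozygous class,
#' all `b` males heterozygous — the observed table is a least-probable
#' table for its margins, so the p-value collapses to the closed form
#' `1 / choose(a + b, a)` when `a != b` (with 16 females and 15 males,
#' `3.33e-9`), and `2 / choose(2a, a)` for a balanced cohort, where the
#' reflected table ties it exactly.
#'
#' @param female_counts,male_counts Integer vectors
#'   `(hom_ref, het, hom_alt)`; alternatively pass a 2-by-3 matrix (rows =
#'   sexes) as `female_counts`.
#' @param rel_tol Relative tolerance for the "no more probable" comparison.
#' @return The exact p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x3(c(16, 0, 0), c(0, 15, 0))   # 1 / choose(31, 16)
fisher_exact_2x3 <- function(female_counts, male_counts = NULL,
                             rel_tol = 1e-7) {
  if (is.matrix(female_counts) && is.null(male_counts)) {
    male_counts <- female_counts[2, ]
    female_counts <- female_counts[1, ]
  }
  r1 <- as.integer(female_counts); r2 <- as.integer(male_counts)
  stopifnot(length(r1) == 3L, length(r2) == 3L, all(r1 >= 0), all(r2 >= 0))
  if (sum(r1) == 0L || sum(r2) == 0L) {
    .stop("empty sex stratum", "empty_stratum")
  }
  .fisher_2x3_core(r1, r2, rel_tol)
}

# enumeration over the first row (a, b) with the third cell implied;
# probabilities in log-factorial space
.fisher_2x3_core <- function(r1, r2, rel_tol = 1e-7) {
  cs <- r1 + r2
  n1 <- sum(r1); n <- sum(cs)
  logp_obs <- sum(lchoose(cs, r1)) - lchoose(n, n1)
  a_vals <- 0:min(n1, cs[1])
  b_lo <- pmax(0L, n1 - a_vals - cs[3])
  b_hi <- pmin(n1 - a_vals, cs[2])
  len <- pmax(0L, b_hi - b_lo + 1L)
  a <- rep.int(a_vals, len)
  b <- unlist(lapply(seq_along(a_vals),
                     function(i) if (len[i] > 0) b_lo[i]:b_hi[i] else integer(0)))
  logp <- lchoose(cs[1], a) + lchoose(cs[2], b) + lchoose(cs[3], n1 - a - b) -
    lchoose(n, n1)
  min(1, sum(exp(logp[logp <= logp_obs + log1p(rel_tol)])))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided HWE p-value conditioning on the observed allele counts:
#' over all heterozygote counts compatible with the allele totals (same
#' parity), the probabilities of configurations no more probable than the
#' observed one are summed. Monomorphic input returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(10, 0, 0)   # monomorphic: 1
#' hwe_exact_p(0, 50, 0)   # extreme heterozygote excess: tiny
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(.is_count(n_hom_ref), .is_count(n_het), .is_count(n_hom_alt))
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) .stop("at least one genotyped sample required", "empty_hwe")
  nA <- 2L * n_hom_ref + n_het
  na <- 2L * n_hom_alt + n_het
  if (nA == 0L || na == 0L) return(1)
  h <- seq.int(min(nA, na) %% 2L, min(nA, na), by = 2L)
  # P(h | nA, na) = n! nA! na! 2^h / [ ((nA-h)/2)! h! ((na-h)/2)! (2n)! ]
  logp <- lfactorial(n) + lfactorial(nA) + lfactorial(na) + h * log(2) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((na - h) / 2) -
    lfactorial(2L * n)
  logp_obs <- logp[match(n_het, h)]
  min(1, sum(exp(logp[logp <= logp_obs + log1p(1e-9)])))
}

#' Classify strict sex-specific segregation
#'
#' A site segregates `male_het` when every genotyped male is heterozygous
#' and every genotyped female sits in one single homozygous class (either
#' hom-ref or hom-alt — which one depends only on which X haplotype the
#' reference individual carried); `female_het` is the mirror (ZW signal).
#' Both sexes must reach the configured per-sex call fraction; anything
#' else is `none`.
#'
#' @param female_counts,male_counts Integer `(hom_ref, het, hom_alt)`.
#' @param n_females,n_males Total samples of each sex in the cohort
#'   (denominators of the call-fraction guard).
#' @param config A [scan_config()].
#' @return `"male_het"`, `"female_het"` or `"none"`.
#' @export
classify_segregation <- function(female_counts, male_counts,
                                 n_females = sum(female_counts),
                                 n_males = sum(male_counts),
                                 config = scan_config()) {
  f <- as.integer(female_counts); m <- as.integer(male_counts)
  ok_frac <- n_females > 0 && n_males > 0 &&
    sum(f) / n_females >= config$min_call_fraction &&
    sum(m) / n_males >= config$min_call_fraction
  if (!ok_frac) return("none")
  one_hom <- function(x) (x[1] >= 1 && x[3] == 0) || (x[1] == 0 && x[3] >= 1)
  all_het <- function(x) x[2] >= 1 && x[1] == 0 && x[3] == 0
  if (all_het(m) && f[2] == 0 && one_hom(f)) return("male_het")
  if (all_het(f) && m[2] == 0 && one_hom(m)) return("female_het")
  "none"
}

# vectorised over a counts tibble
.classify_batch <- function(cts, n_f, n_m, config) {
  frac_ok <- (cts$f_hom_ref + cts$f_het + cts$f_hom_alt) / n_f >=
    config$min_call_fraction &
    (cts$m_hom_ref + cts$m_het + cts$m_hom_alt) / n_m >=
    config$min_call_fraction
  f_one_hom <- cts$f_het == 0 &
    ((cts$f_hom_ref >= 1 & cts$f_hom_alt == 0) |
       (cts$f_hom_ref == 0 & cts$f_hom_alt >= 1))
  m_one_hom <- cts$m_het == 0 &
    ((cts$m_hom_ref >= 1 & cts$m_hom_alt == 0) |
       (cts$m_hom_ref == 0 & cts$m_hom_alt >= 1))
  f_all_het <- cts$f_het >= 1 & cts$f_hom_ref == 0 & cts$f_hom_alt == 0
  m_all_het <- cts$m_het >= 1 & cts$m_hom_ref == 0 & cts$m_hom_alt == 0
  out <- rep("none", nrow(cts))
  out[frac_ok & m_all_het & f_one_hom] <- "male_het"
  out[frac_ok & f_all_het & m_one_hom] <- "female_het"
  out
}

# memoised batch p-values over a 6-column counts tibble
.fisher_batch <- function(cts, rel_tol = 1e-7) {
  key <- paste(cts$f_hom_ref, cts$f_het, cts$f_hom_alt,
               cts$m_hom_ref, cts$m_het, cts$m_hom_alt, sep = ",")
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) {
    .fisher_2x3_core(c(cts$f_hom_ref[i], cts$f_het[i], cts$f_hom_alt[i]),
                     c(cts$m_hom_ref[i], cts$m_het[i], cts$m_hom_alt[i]),
                     rel_tol)
  }, numeric(1))
  pu[match(key, key[u])]
}

.hwe_batch <- function(g0, g1, g2) {
  key <- paste(g0, g1, g2, sep = ",")
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) hwe_exact_p(g0[i], g1[i], g2[i]),
               numeric(1))
  pu[match(key, key[u])]
}

#' Genome-wide scan for sex-specific variants
#'
#' Computes, at every site, the exact 2-by-3 sex-by-genotype p-value, the
#' exact HWE p on the configured stratum, and the strict-segregation class.
#' A site is `significant` when its exact p is below `alpha`, it passes the
#' HWE filter, and both sexes reach the minimum call fraction; it is
#' `sex_specific` when additionally its segregation class is strict
#' (`male_het` or `female_het`).
#'
#' @param gm A [genotype_matrix()], already restricted to biallelic sites
#'   of the classes under test (see [filter_biallelic()]).
#' @param config A [scan_config()].
#' @return A tibble of class `sex_scan`, one row per site: site columns,
#'   per-sex genotype counts, `fisher_p`, `hwe_p`, `neg_log10_p`,
#'   `segregation`, `significant`, `sex_specific`.
#' @export
scan_genome <- function(gm, config = scan_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_f <- sum(gm$samples$sex == "female")
  n_m <- sum(gm$samples$sex == "male")
  if (n_f == 0 || n_m == 0) .stop("need genotyped samples of both sexes",
                                  "empty_stratum")
  cts <- .sex_counts(gm)
  if (nrow(cts) == 0) {
    return(structure(dplyr::bind_cols(gm$sites[0, ], cts,
                                      tibble(fisher_p = numeric(0),
                                             hwe_p = numeric(0),
                                             neg_log10_p = numeric(0),
                                             segregation = character(0),
                                             significant = logical(0),
                                             sex_specific = logical(0))),
                     class = c("sex_scan", "tbl_df", "tbl", "data.frame")))
  }
  row_f <- cts$f_hom_ref + cts$f_het + cts$f_hom_alt
  row_m <- cts$m_hom_ref + cts$m_het + cts$m_hom_alt
  if (any(row_f == 0) || any(row_m == 0)) {
    i <- which(row_f == 0 | row_m == 0)[1]
    .stop(sprintf("empty sex stratum at site %s:%d",
                  gm$sites$scaffold[i], gm$sites$pos[i]), "empty_stratum")
  }
  fisher_p <- .fisher_batch(cts)
  hwe_p <- switch(config$hwe_scope,
    females_only = .hwe_batch(cts$f_hom_ref, cts$f_het, cts$f_hom_alt),
    males_only = .hwe_batch(cts$m_hom_ref, cts$m_het, cts$m_hom_alt),
    all_samples = .hwe_batch(cts$f_hom_ref + cts$m_hom_ref,
                             cts$f_het + cts$m_het,
                             cts$f_hom_alt + cts$m_hom_alt),
    none = rep(1, nrow(cts)))
  frac_ok <- row_f / n_f >= config$min_call_fraction &
    row_m / n_m >= config$min_call_fraction
  segregation <- .classify_batch(cts, n_f, n_m, config)
  significant <- fisher_p < config$alpha & hwe_p >= config$hwe_threshold &
    frac_ok
  out <- dplyr::bind_cols(
    gm$sites, cts,
    tibble(fisher_p = fisher_p, hwe_p = hwe_p,
           neg_log10_p = -log10(fisher_p),
           segregation = segregation,
           significant = significant,
           sex_specific = significant & segregation != "none"))
  structure(out, class = c("sex_scan", class(tibble())))
}

#' Re-scan a candidate region including indels
#'
#' The genome-wide pass uses biallelic SNPs only; once a candidate
#' sex-determination region is localised, a second caller pass over that
#' window typically surfaces additional variants including indels. This
#' runs the identical statistics restricted to the window on an
#' indel-inclusive matrix.
#'
#' @param gm A [genotype_matrix()] built with SNPs and indels retained.
#' @param scaffold Scaffold of the window.
#' @param window `c(start, end)` bp, 1-based inclusive.
#' @param config A [scan_config()].
#' @return A `sex_scan` tibble over the window (possibly empty).
#' @export
rescan_region <- function(gm, scaffold, window, config = scan_config()) {
  scan_genome(subset_region(gm, scaffold, window), config)
}

#' Infer the heterogametic system from a scan
#'
#' Sex-linked variants in an XY (male-heterogametic) system are
#' heterozygous in every male and homozygous in every female; ZW is the
#' mirror. The inference simply tallies the strict-segregation classes of
#' the sex-specific sites.
#'
#' @param scan A `sex_scan` tibble from [scan_genome()].
#' @return A list: `system` (`"XY"`, `"ZW"`, or `NA` when no sex-specific
#'   site or a conflict), `n_male_het`, `n_female_het`.
#' @export
infer_heterogamety <- function(scan) {
  sig <- scan[scan$sex_specific, , drop = FALSE]
  n_mh <- sum(sig$segregation == "male_het")
  n_fh <- sum(sig$segregation == "female_het")
  system <- if (n_mh > 0 && n_fh == 0) "XY"
    else if (n_fh > 0 && n_mh == 0) "ZW"
    else NA_character_
  list(system = system, n_male_het = n_mh, n_female_het = n_fh)
}

#' Export a Manhattan table from a scan
#'
#' Cumulative genome coordinates and `-log10(p)` per site, the data behind
#' a Manhattan plot of the scan.
#'
#' @param scan A `sex_scan` tibble.
#' @return A tibble: `scaffold`, `scaffold_index`, `pos`, `cum_pos`,
#'   `neg_log10_p`, `sex_specific`.
#' @export
manhattan_table <- function(scan) {
  scaffolds <- unique(scan$scaffold)
  idx <- match(scan$scaffold, scaffolds)
  offsets <- c(0, cumsum(unname(vapply(scaffolds, function(s)
    max(scan$pos[scan$scaffold == s]), numeric(1)))))
  tibble(scaffold = scan$scaffold, scaffold_index = idx, pos = scan$pos,
         cum_pos = scan$pos + offsets[idx],
         neg_log10_p = scan$neg_log10_p,
         sex_specific = scan$sex_specific)
}
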