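#' Configuration for pairwise LD and block partitioning
#'
#' Defaults follow the published confidence-interval (Gabriel) block
#' method as implemented by the standard haplotype-block program: a pair
#' is in "strong LD" when the lower bound of the D' confidence interval is
#' at least 0.70 and the upper bound at least 0.98; it shows "strong
#' recombination" when the upper bound is below 0.90; a candidate block
#' requires at least 95% of its informative pairs in strong LD.
#'
#' @param strong_ld_low,strong_ld_high Lower/upper D' CI bounds defining
#'   strong LD.
#' @param recomb_high Upper D' CI bound below which a pair evidences
#'   recombination.
#' @param min_strong_fraction Minimum fraction of informative pairs
#'   (strong-LD or strong-recombination) inside a block that must be
#'   strong LD.
#' @param ci_mass Two-sided mass of the D' likelihood interval (0.90).
#' @param dprime_grid_step Grid step for the D' likelihood (0.001; bounds
#'   are stable to one step against a 10x finer grid).
#' @param min_maf Minimum minor-allele frequency for a marker to enter
#'   block finding (0.05; sex-linked sites in a balanced cohort sit near
#'   0.25 and are unaffected — set 0 for exactness studies).
#' @param max_pair_distance_bp Pairs farther apart are skipped
#'   (uninformative) to bound cost; far larger than any credible block.
#' @return An `ld_config` list.
#' @export
ld_config <- function(strong_ld_low = 0.70, strong_ld_high = 0.98,
                      recomb_high = 0.90, min_strong_fraction = 0.95,
                      ci_mass = 0.90, dprime_grid_step = 0.001,
                      min_maf = 0.05, max_pair_distance_bp = 5e5) {
  stopifnot(strong_ld_low > 0, strong_ld_low < strong_ld_high,
            strong_ld_high <= 1, recomb_high > 0,
            recomb_high < strong_ld_high, ci_mass > 0, ci_mass < 1)
  structure(list(strong_ld_low = strong_ld_low,
                 strong_ld_high = strong_ld_high,
                 recomb_high = recomb_high,
                 min_strong_fraction = min_strong_fraction,
                 ci_mass = ci_mass, dprime_grid_step = dprime_grid_step,
                 min_maf = min_maf,
                 max_pair_distance_bp = max_pair_distance_bp),
            class = "ld_config")
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic sites
#' from unphased diploid genotypes. Only the double heterozygote is phase
#' ambiguous; the EM starts from linkage equilibrium (products of allele
#' frequencies) and splits the double heterozygotes between the coupling
#' (AB/ab) and repulsion (Ab/aB) resolutions in proportion to the current
#' haplotype-frequency estimates, iterating to a `1e-10` fixed point
#' (at most 1000 iterations).
#'
#' @param calls_i,calls_j Integer genotype vectors (0/1/2/NA) at the two
#'   sites, in the same sample order. `A`/`B` denote the reference alleles.
#' @param tol Convergence tolerance on the largest frequency change.
#' @param max_iter Iteration cap.
#' @return A list of class `hap_freqs`: `freqs` (named `p_AB`, `p_Ab`,
#'   `p_aB`, `p_ab`), `n_informative` (samples genotyped at both sites),
#'   `counts` (3x3 joint genotype counts), `p_A`, `p_B`, `informative`
#'   (FALSE when either site is monomorphic among shared samples, in which
#'   case frequencies are still returned at the margin products).
#' @export
em_haplotype_frequencies <- function(calls_i, calls_j,
                                     tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(calls_i) == length(calls_j))
  ok <- !is.na(calls_i) & !is.na(calls_j)
  gi <- calls_i[ok]; gj <- calls_j[ok]
  n <- length(gi)
  counts <- matrix(0, 3, 3,
                   dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
  for (x in 0:2) for (y in 0:2) counts[x + 1, y + 1] <- sum(gi == x & gj == y)
  # reference-allele frequencies (A at site i, B at site j)
  p_A <- if (n > 0) sum(2 - gi) / (2 * n) else NA_real_
  p_B <- if (n > 0) sum(2 - gj) / (2 * n) else NA_real_
  informative <- n >= 2 && p_A > 0 && p_A < 1 && p_B > 0 && p_B < 1
  if (!informative) {
    f <- c(p_AB = p_A * p_B, p_Ab = p_A * (1 - p_B),
           p_aB = (1 - p_A) * p_B, p_ab = (1 - p_A) * (1 - p_B))
    return(structure(list(freqs = f, n_informative = n, counts = counts,
                          p_A = p_A, p_B = p_B, informative = FALSE),
                     class = "hap_freqs"))
  }
  # haplotype tallies fixed by single/double homozygote and single-het cells
  base <- c(
    AB = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    Ab = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    aB = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    ab = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3])
  ndh <- counts[2, 2]
  f <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  for (iter in seq_len(max_iter)) {
    coup <- f[1] * f[4]; rep_ <- f[2] * f[3]
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    new_f <- (base + ndh * c(w, 1 - w, 1 - w, w)) / (2 * n)
    if (max(abs(new_f - f)) < tol) { f <- new_f; break }
    f <- new_f
  }
  names(f) <- c("p_AB", "p_Ab", "p_aB", "p_ab")
  structure(list(freqs = f, n_informative = n, counts = counts,
                 p_A = p_A, p_B = p_B, informative = TRUE),
            class = "hap_freqs")
}

# expected 3x3 genotype-class probabilities from haplotype frequencies
# (random union of haplotypes); vectorised over haplotype-frequency vectors
# — returns a length(hAB) x 9 matrix, row-major in the genotype at site i
.geno_probs_3x3 <- function(hAB, hAb, haB, hab) {
  cbind(hAB^2, 2 * hAB * hAb, hAb^2,
        2 * hAB * haB, 2 * hAB * hab + 2 * hAb * haB, 2 * hAb * hab,
        haB^2, 2 * haB * hab, hab^2)
}

# multinomial log-likelihood of the 3x3 genotype counts under each
# haplotype-frequency vector
.geno_loglik <- function(counts, hAB, hAb, haB, hab) {
  pr <- .geno_probs_3x3(hAB, hAb, haB, hab)
  nv <- as.vector(t(counts))
  nz <- nv > 0
  drop(log(pmax(pr[, nz, drop = FALSE], 1e-300)) %*% nv[nz])
}

#' Pairwise linkage disequilibrium statistics
#'
#' From EM haplotype frequencies: the raw disequilibrium
#' `D = p_AB - p_A p_B`, the normalised `D' = |D| / D_max`, `r^2`, the
#' `LOD` (log10 likelihood ratio of the fitted haplotype frequencies
#' against linkage equilibrium, on the genotype data), and a likelihood
#' interval for `D'` obtained by profiling the genotype likelihood over a
#' `D'` grid with allele frequencies held at their MLE. The pair class used
#' by block finding is assigned from the CI bounds.
#'
#' @param freqs A `hap_freqs` object from [em_haplotype_frequencies()].
#' @param config An [ld_config()].
#' @return A one-row tibble: `D`, `d_prime`, `r2`, `lod`, `ci_low`,
#'   `ci_high`, `pair_class` (`strong_ld` / `strong_recombination` /
#'   `other` / `uninformative`), `n_informative`.
#' @export
pairwise_ld <- function(freqs, config = ld_config()) {
  stopifnot(inherits(freqs, "hap_freqs"))
  st <- .pair_stats(freqs, config)
  tibble(D = st$D, d_prime = st$d_prime, r2 = st$r2, lod = st$lod,
         ci_low = st$ci_low, ci_high = st$ci_high,
         pair_class = st$pair_class, n_informative = freqs$n_informative)
}

# numeric core shared by pairwise_ld() and the block scan
.pair_stats <- function(freqs, config) {
  if (!freqs$informative) {
    return(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                lod = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                pair_class = "uninformative"))
  }
  f <- freqs$freqs
  p_A <- f[["p_AB"]] + f[["p_Ab"]]; p_B <- f[["p_AB"]] + f[["p_aB"]]
  D <- f[["p_AB"]] - p_A * p_B
  d_max <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
           else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  d_prime <- if (d_max > 0) min(1, abs(D) / d_max) else 0
  # EM leaves O(tol) residue in an emptied haplotype cell; snap to the
  # zero-cell identity d' = 1
  if (d_prime > 1 - 1e-9) d_prime <- 1
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  ll1 <- .geno_loglik(freqs$counts, f[["p_AB"]], f[["p_Ab"]],
                      f[["p_aB"]], f[["p_ab"]])
  ll0 <- .geno_loglik(freqs$counts, p_A * p_B, p_A * (1 - p_B),
                      (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  lod <- (ll1 - ll0) / log(10)
  # D' likelihood on a grid, D carrying the MLE sign
  grid <- seq(0, 1, by = config$dprime_grid_step)
  Dg <- (if (D >= 0) 1 else -1) * grid * d_max
  ll <- .geno_loglik(freqs$counts,
                     pmax(p_A * p_B + Dg, 0),
                     pmax(p_A * (1 - p_B) - Dg, 0),
                     pmax((1 - p_A) * p_B - Dg, 0),
                     pmax((1 - p_A) * (1 - p_B) + Dg, 0))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  tail_mass <- (1 - config$ci_mass) / 2
  cum_lo <- cumsum(w)
  cum_hi <- rev(cumsum(rev(w)))
  ci_low <- grid[which(cum_lo > tail_mass)[1]]
  ci_high <- grid[tail(which(cum_hi > tail_mass), 1)]
  pair_class <- if (ci_low >= config$strong_ld_low &&
                    ci_high >= config$strong_ld_high) "strong_ld"
    else if (ci_high < config$recomb_high) "strong_recombination"
    else "other"
  list(D = D, d_prime = d_prime, r2 = r2, lod = lod,
       ci_low = ci_low, ci_high = ci_high, pair_class = pair_class)
}

#' All pairwise LD statistics on a scaffold
#'
#' @param gm A [genotype_matrix()].
#' @param scaffold Scaffold name.
#' @param config An [ld_config()].
#' @param window Optional `c(start, end)` bp restriction.
#' @return A tibble with one row per eligible marker pair within
#'   `max_pair_distance_bp`: `pos_i`, `pos_j`, and the [pairwise_ld()]
#'   columns. Markers below `min_maf` (among genotyped samples) are
#'   excluded.
#' @export
scaffold_pairwise_ld <- function(gm, scaffold, config = ld_config(),
                                 window = NULL) {
  sub <- subset_region(gm, scaffold, window)
  elig <- .eligible_markers(sub, config)
  pos <- sub$sites$pos[elig]
  idx <- which(elig)
  if (length(idx) < 2) {
    return(tibble(pos_i = integer(0), pos_j = integer(0), D = numeric(0),
                  d_prime = numeric(0), r2 = numeric(0), lod = numeric(0),
                  ci_low = numeric(0), ci_high = numeric(0),
                  pair_class = character(0), n_informative = integer(0)))
  }
  pairs <- tidyr::expand_grid(a = seq_along(idx), b = seq_along(idx)) |>
    dplyr::filter(.data$a < .data$b) |>
    dplyr::filter(pos[.data$b] - pos[.data$a] <= config$max_pair_distance_bp)
  stats <- lapply(seq_len(nrow(pairs)), function(k) {
    fr <- em_haplotype_frequencies(sub$calls[idx[pairs$a[k]], ],
                                   sub$calls[idx[pairs$b[k]], ])
    st <- .pair_stats(fr, config)
    st$n_informative <- fr$n_informative
    st
  })
  dplyr::bind_cols(
    tibble(pos_i = pos[pairs$a], pos_j = pos[pairs$b]),
    tibble(D = vapply(stats, `[[`, 0, "D"),
           d_prime = vapply(stats, `[[`, 0, "d_prime"),
           r2 = vapply(stats, `[[`, 0, "r2"),
           lod = vapply(stats, `[[`, 0, "lod"),
           ci_low = vapply(stats, `[[`, 0, "ci_low"),
           ci_high = vapply(stats, `[[`, 0, "ci_high"),
           pair_class = vapply(stats, `[[`, "", "pair_class"),
           n_informative = vapply(stats, `[[`, 0L, "n_informative")))
}

.eligible_markers <- function(gm, config) {
  if (nrow(gm$sites) == 0) return(logical(0))
  alt_count <- rowSums(gm$calls, na.rm = TRUE)
  n_called <- rowSums(!is.na(gm$calls))
  af <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  !is.na(maf) & maf >= config$min_maf
}

#' Partition a scaffold into LD blocks (confidence-interval method)
#'
#' Candidate blocks are marker intervals whose endpoint pair is in strong
#' LD and in which at least `min_strong_fraction` of the informative pairs
#' (strong-LD or strong-recombination) are strong LD. Candidates are
#' ranked by bp span (descending; ties broken by more markers, then
#' smaller start) and accepted greedily without overlap.
#'
#' @param gm A [genotype_matrix()].
#' @param scaffold Scaffold to partition.
#' @param config An [ld_config()].
#' @param window Optional `c(start, end)` bp restriction; all eligible
#'   markers in the window participate, not only sex-specific ones.
#' @param pairs Optional precomputed [scaffold_pairwise_ld()] tibble for
#'   the same scaffold/window (avoids recomputation).
#' @return A tibble of class `ld_blocks`: `scaffold`, `first_pos`,
#'   `last_pos`, `span_bp`, `n_markers`, `member_pos` (list column of
#'   marker positions).
#' @export
gabriel_blocks <- function(gm, scaffold, config = ld_config(),
                           window = NULL, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- scaffold_pairwise_ld(gm, scaffold, config, window)
  }
  empty <- tibble(scaffold = character(0), first_pos = integer(0),
                  last_pos = integer(0), span_bp = integer(0),
                  n_markers = integer(0), member_pos = list())
  if (nrow(pairs) == 0) return(structure(empty, class = c("ld_blocks", class(tibble()))))
  pos <- sort(unique(c(pairs$pos_i, pairs$pos_j)))
  m <- length(pos)
  cls <- matrix(NA_character_, m, m)
  ia <- match(pairs$pos_i, pos); ib <- match(pairs$pos_j, pos)
  cls[cbind(ia, ib)] <- pairs$pair_class
  cls[cbind(ib, ia)] <- pairs$pair_class
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      if (is.na(cls[i, j]) || cls[i, j] != "strong_ld") next
      sub <- cls[i:j, i:j]
      inner <- sub[upper.tri(sub)]
      n_strong <- sum(inner == "strong_ld", na.rm = TRUE)
      n_recomb <- sum(inner == "strong_recombination", na.rm = TRUE)
      n_inf <- n_strong + n_recomb
      if (n_inf == 0) next
      if (n_strong / n_inf >= config$min_strong_fraction) {
        cand[[length(cand) + 1]] <- list(i = i, j = j)
      }
    }
  }
  if (length(cand) == 0) return(structure(empty, class = c("ld_blocks", class(tibble()))))
  cd <- tibble(i = vapply(cand, `[[`, 0L, "i"),
               j = vapply(cand, `[[`, 0L, "j")) |>
    dplyr::mutate(first_pos = pos[.data$i], last_pos = pos[.data$j],
                  span_bp = .data$last_pos - .data$first_pos + 1L,
                  n_markers = .data$j - .data$i + 1L) |>
    dplyr::arrange(dplyr::desc(.data$span_bp), dplyr::desc(.data$n_markers),
                   .data$first_pos)
  taken <- rep(FALSE, m)
  keep <- logical(nrow(cd))
  for (k in seq_len(nrow(cd))) {
    rng <- cd$i[k]:cd$j[k]
    if (!any(taken[rng])) { keep[k] <- TRUE; taken[rng] <- TRUE }
  }
  acc <- cd[keep, , drop = FALSE] |>
    dplyr::arrange(.data$first_pos)
  out <- tibble(scaffold = rep(scaffold, nrow(acc)),
                first_pos = acc$first_pos, last_pos = acc$last_pos,
                span_bp = acc$span_bp, n_markers = acc$n_markers,
                member_pos = purrr::map2(acc$i, acc$j, function(a, b) pos[a:b]))
  structure(out, class = c("ld_blocks", class(tibble())))
}

#' Inclusive bp span of a block
#'
#' Block and region sizes throughout the pipeline use the 1-based
#' inclusive convention `last - first + 1`.
#'
#' @param first_pos,last_pos Block bounds in bp, 1-based.
#' @return Integer span in bp.
#' @export
#' @examples
#' block_span(3723703, 3726876)  # 3174
block_span <- function(first_pos, last_pos) {
  if (any(last_pos < first_pos)) {
    .stop("last_pos must be >= first_pos", "bad_span")
  }
  as.integer(last_pos - first_pos + 1)
}
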