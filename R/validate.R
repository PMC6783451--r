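#' Parameter-recovery evaluation on one simulated cohort
#'
#' Runs the full discovery chain — simulate, biallelic-SNP filter, scan,
#' LD blocks around the candidate region, per-scaffold summary, marker
#' region selection — on a cohort simulated from `config`, and scores it
#' against the truth set.
#'
#' @param config A [cohort_config()] (its `seed` drives the cohort).
#' @param scan_cfg,ld_cfg Scan and LD configurations.
#' @param ld_margin_bp Window margin around the sex-specific region for
#'   block finding.
#' @return A one-row tibble: `seed`, `n_sex_specific`, `bounds_exact`
#'   (detected region bounds equal the planted core's first/last
#'   positions on the planted scaffold), `scaffold_picked` (marker-region
#'   selection chose the planted scaffold), `n_background_fp`
#'   (sex-specific calls at truth-class background sites).
#' @export
recover_region <- function(config, scan_cfg = scan_config(),
                           ld_cfg = ld_config(), ld_margin_bp = 10000L) {
  sim <- simulate_cohort(config, reference = FALSE)
  gm <- filter_biallelic(sim$gm, "snp", quiet = TRUE)
  scan <- scan_genome(gm, scan_cfg)
  truth <- sim$truth
  cls <- truth$sites$site_class[match(
    paste(scan$scaffold, scan$pos),
    paste(truth$sites$scaffold, truth$sites$pos))]
  n_fp <- sum(scan$sex_specific & cls == "background")
  sig <- scan[scan$sex_specific, , drop = FALSE]
  on_sd <- sig[sig$scaffold == truth$region$scaffold, , drop = FALSE]
  bounds_exact <- nrow(sig) > 0 && nrow(on_sd) == nrow(sig) &&
    min(on_sd$pos) == truth$region$first_core_pos &&
    max(on_sd$pos) == truth$region$last_core_pos
  picked <- FALSE
  if (nrow(on_sd) > 0) {
    rng <- range(on_sd$pos)
    blocks <- gabriel_blocks(gm, truth$region$scaffold, ld_cfg,
                             window = c(max(1L, rng[1] - ld_margin_bp),
                                        rng[2] + ld_margin_bp))
    summ <- summarize_scaffolds(scan, blocks)
    mr <- select_marker_region(summ, scan)
    picked <- isTRUE(mr$found) && mr$scaffold == truth$region$scaffold
  }
  tibble(seed = config$seed, n_sex_specific = nrow(sig),
         bounds_exact = bounds_exact, scaffold_picked = picked,
         n_background_fp = n_fp)
}
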