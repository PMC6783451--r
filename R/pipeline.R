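#' Run the discovery pipeline end to end
#'
#' Orchestrates scan -> LD blocks -> per-scaffold report -> marker-region
#' selection (and optionally the in-silico assay) on either a VCF + sex
#' map on disk or an in-memory genotype matrix, writing every stage's
#' table plus a run log into `out_dir`. Deterministic given inputs and
#' configuration.
#'
#' @param gm A [genotype_matrix()], or `NULL` to read from `vcf` +
#'   `sex_map`.
#' @param out_dir Output directory (created).
#' @param vcf,sex_map Input paths (used when `gm` is `NULL`).
#' @param scan_cfg A [scan_config()].
#' @param ld_cfg An [ld_config()].
#' @param min_sites Eligibility bound for [select_marker_region()].
#' @param ld_margin_bp LD blocks are computed over each candidate
#'   scaffold's sex-specific region extended by this margin on both sides
#'   (default 10 kb), so non-sex-specific markers flanking the region can
#'   participate in blocks.
#' @param scaffold_sizes Optional named scaffold lengths for the report.
#' @param assay Optional assay stage: a list with `ref_seqs` (named
#'   scaffold sequences or a FASTA path), `pairs` (a [primer_pair()] or
#'   list of them), `rule` (an [assay_rule()]), and optionally `window`
#'   (`c(start, end)`; defaults to the selected block bounds). Calls are
#'   written to `assay_calls.tsv` and accuracy to `assay_accuracy.json`.
#' @return Invisibly, a list with `scan`, `blocks`, `summary`, `region`,
#'   `heterogamety`, optionally `assay`, and the written `paths`.
#' @export
run_pipeline <- function(gm = NULL, out_dir, vcf = NULL, sex_map = NULL,
                         scan_cfg = scan_config(), ld_cfg = ld_config(),
                         min_sites = 10, ld_margin_bp = 10000L,
                         scaffold_sizes = NULL, assay = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  if (is.null(gm)) {
    if (is.null(vcf) || is.null(sex_map)) {
      .stop("either `gm` or both `vcf` and `sex_map` must be given",
            "bad_pipeline_input")
    }
    samples <- read_sex_map(sex_map, quiet = TRUE)
    gm <- read_vcf(vcf, samples)
  }
  n_in <- nrow(gm$sites)
  gm_snp <- filter_biallelic(gm, "snp", quiet = TRUE)
  say("input sites: %d; biallelic SNPs retained: %d (dropped %d)",
      n_in, nrow(gm_snp$sites), n_in - nrow(gm_snp$sites))

  scan <- scan_genome(gm_snp, scan_cfg)
  say("sex-specific sites: %d of %d (alpha = %g)",
      sum(scan$sex_specific), nrow(scan), scan_cfg$alpha)
  het <- infer_heterogamety(scan)
  say("heterogamety: %s (male_het = %d, female_het = %d)",
      het$system %||% "undetermined", het$n_male_het, het$n_female_het)

  # LD blocks around each candidate scaffold's sex-specific region
  cand <- scan |>
    dplyr::filter(.data$sex_specific) |>
    dplyr::count(.data$scaffold) |>
    dplyr::filter(.data$n > min_sites)
  ld_pairs <- purrr::map_dfr(cand$scaffold, function(s) {
    rng <- range(scan$pos[scan$sex_specific & scan$scaffold == s])
    win <- c(max(1L, rng[1] - ld_margin_bp), rng[2] + ld_margin_bp)
    dplyr::mutate(scaffold_pairwise_ld(gm_snp, s, ld_cfg, window = win),
                  scaffold = s, .before = 1)
  })
  blocks <- purrr::map_dfr(cand$scaffold, function(s) {
    gabriel_blocks(gm_snp, s, ld_cfg,
                   pairs = ld_pairs[ld_pairs$scaffold == s, -1])
  })
  say("LD blocks found on %d candidate scaffold(s): %d",
      nrow(cand), nrow(blocks))

  summary <- summarize_scaffolds(scan, blocks, scaffold_sizes)
  region <- select_marker_region(summary, scan, min_sites = min_sites)
  if (isTRUE(region$found)) {
    say("marker region: %s:%d-%d (%d bp), %d sex-specific site(s) in block",
        region$scaffold, region$block_start, region$block_end,
        region$block_span_bp, nrow(region$sites))
  } else {
    say("no marker region: %s", region$reason)
  }

  paths <- c(
    associations = file.path(out_dir, "associations.tsv"),
    manhattan = file.path(out_dir, "manhattan.tsv"),
    ld_pairs = file.path(out_dir, "ld_pairs.tsv"),
    blocks = file.path(out_dir, "ld_blocks.tsv"),
    summary = file.path(out_dir, "scaffold_summary.tsv"),
    region = file.path(out_dir, "marker_region.json"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(
    list(scan = unclass(scan_cfg), ld = unclass(ld_cfg),
         min_sites = min_sites, ld_margin_bp = ld_margin_bp),
    paths[["config"]], auto_unbox = TRUE, digits = NA)
  readr::write_tsv(format_associations(scan), paths[["associations"]])
  readr::write_tsv(manhattan_table(scan), paths[["manhattan"]])
  readr::write_tsv(ld_pairs, paths[["ld_pairs"]])
  readr::write_tsv(dplyr::select(blocks, -"member_pos"), paths[["blocks"]])
  readr::write_tsv(summary, paths[["summary"]])
  jsonlite::write_json(glance(region), paths[["region"]],
                       auto_unbox = TRUE, digits = NA)

  assay_res <- NULL
  if (!is.null(assay) && isTRUE(region$found)) {
    ref_seqs <- if (is.character(assay$ref_seqs) &&
                      length(assay$ref_seqs) == 1 &&
                      file.exists(assay$ref_seqs)) {
      read_reference(assay$ref_seqs)
    } else assay$ref_seqs
    win <- assay$window %||% c(region$block_start, region$block_end)
    calls <- run_assay(gm, ref_seqs, region$scaffold, win,
                       assay$pairs, assay$rule)
    acc <- assay_accuracy(calls, gm$samples)
    say("assay: accuracy %.3f over %d samples (%d undetermined)",
        acc$accuracy, acc$n, acc$n_undetermined)
    paths[["assay_calls"]] <- file.path(out_dir, "assay_calls.tsv")
    paths[["assay_accuracy"]] <- file.path(out_dir, "assay_accuracy.json")
    readr::write_tsv(
      dplyr::mutate(calls,
                    products = purrr::map_chr(.data$products, paste,
                                              collapse = ";")),
      paths[["assay_calls"]])
    jsonlite::write_json(as.list(acc), paths[["assay_accuracy"]],
                         auto_unbox = TRUE, digits = NA)
    assay_res <- list(calls = calls, accuracy = acc)
  }
  writeLines(log_lines, paths[["log"]])
  invisible(list(scan = scan, blocks = blocks, summary = summary,
                 region = region, heterogamety = het, assay = assay_res,
                 paths = paths))
}

#' Format a scan as the association report table
#'
#' Per-sex genotype counts rendered in `hom_ref/het/hom_alt` style.
#'
#' @param scan A `sex_scan` tibble.
#' @return A tibble: scaffold, position, alleles, `females`/`males` count
#'   strings, p-values, segregation, significance.
#' @export
format_associations <- function(scan) {
  tibble(scaffold = scan$scaffold, pos = scan$pos, ref = scan$ref,
         alt = scan$alt,
         females = paste(scan$f_hom_ref, scan$f_het, scan$f_hom_alt,
                         sep = "/"),
         males = paste(scan$m_hom_ref, scan$m_het, scan$m_hom_alt,
                       sep = "/"),
         fisher_p = scan$fisher_p, hwe_p = scan$hwe_p,
         segregation = scan$segregation,
         significant = scan$significant,
         sex_specific = scan$sex_specific)
}
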