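#' Per-scaffold summary of sex-specific variation
#'
#' Aggregates a scan into one row per scaffold carrying at least one
#' sex-specific site: total (post-filter) site count, sex-specific count,
#' the sex-specific region bounds (first/last sex-specific position,
#' inclusive size), and — where LD blocks were computed — the block count
#' and the maximum block.
#'
#' @param scan A `sex_scan` tibble from [scan_genome()].
#' @param blocks Optional `ld_blocks` tibble ([gabriel_blocks()] output,
#'   possibly row-bound across scaffolds).
#' @param scaffold_sizes Optional named vector of scaffold lengths (bp).
#' @return A tibble: `scaffold`, `scaffold_size_bp`, `n_total_sites`,
#'   `n_sex_specific`, `region_start`, `region_end`, `region_size_bp`,
#'   `n_ld_blocks`, `max_block_span_bp`, `max_block_start`,
#'   `max_block_end`.
#' @export
summarize_scaffolds <- function(scan, blocks = NULL, scaffold_sizes = NULL) {
  totals <- scan |>
    dplyr::count(.data$scaffold, name = "n_total_sites")
  sig <- scan |>
    dplyr::filter(.data$sex_specific)
  if (nrow(sig) > 0) {
    sig <- sig |>
      dplyr::group_by(.data$scaffold) |>
      dplyr::summarise(n_sex_specific = dplyr::n(),
                       region_start = min(.data$pos),
                       region_end = max(.data$pos), .groups = "drop")
  }
  if (nrow(sig) == 0) {
    return(tibble(scaffold = character(0), scaffold_size_bp = integer(0),
                  n_total_sites = integer(0), n_sex_specific = integer(0),
                  region_start = integer(0), region_end = integer(0),
                  region_size_bp = integer(0), n_ld_blocks = integer(0),
                  max_block_span_bp = integer(0),
                  max_block_start = integer(0), max_block_end = integer(0)))
  }
  out <- sig |>
    dplyr::left_join(totals, by = "scaffold") |>
    dplyr::mutate(region_size_bp = block_span(.data$region_start,
                                              .data$region_end))
  if (!is.null(blocks) && nrow(blocks) > 0) {
    bsum <- blocks |>
      dplyr::group_by(.data$scaffold) |>
      dplyr::summarise(
        n_ld_blocks = dplyr::n(),
        max_block_span_bp = max(.data$span_bp),
        max_block_start = .data$first_pos[which.max(.data$span_bp)],
        max_block_end = .data$last_pos[which.max(.data$span_bp)],
        .groups = "drop")
    out <- dplyr::left_join(out, bsum, by = "scaffold")
  } else {
    out <- dplyr::mutate(out, n_ld_blocks = NA_integer_,
                         max_block_span_bp = NA_integer_,
                         max_block_start = NA_integer_,
                         max_block_end = NA_integer_)
  }
  size <- if (is.null(scaffold_sizes)) NA_integer_
    else as.integer(scaffold_sizes[out$scaffold])
  out |>
    dplyr::mutate(scaffold_size_bp = size) |>
    dplyr::select("scaffold", "scaffold_size_bp", "n_total_sites",
                  "n_sex_specific", "region_start", "region_end",
                  "region_size_bp", "n_ld_blocks", "max_block_span_bp",
                  "max_block_start", "max_block_end") |>
    dplyr::arrange(.data$scaffold)
}

#' Select the marker region for assay design
#'
#' Among scaffolds carrying more than `min_sites` sex-specific variants
#' (strictly), selects the one whose maximum LD block spans the most bp —
#' the block where recombination is most extensively suppressed and hence
#' the natural target for diagnostic markers. Ties are broken by the
#' number of sex-specific sites inside the block, then by scaffold name.
#'
#' @param summaries Tibble from [summarize_scaffolds()] (block columns
#'   required for eligible scaffolds).
#' @param scan The `sex_scan` tibble the summaries came from.
#' @param min_sites Strict lower bound on `n_sex_specific` for
#'   eligibility (default 10, i.e. "more than 10").
#' @param metric `"block_span"` (default) or `"n_sites"` (most
#'   sex-specific sites first, span as tie-break).
#' @return A list of class `marker_region`: `found`, `scaffold`,
#'   `block_start`, `block_end`, `block_span_bp`, `sites` (tibble of
#'   sex-specific sites inside the block) and `region_sites` (all
#'   sex-specific sites on the scaffold). When no scaffold is eligible,
#'   `found = FALSE`.
#' @export
select_marker_region <- function(summaries, scan, min_sites = 10,
                                 metric = c("block_span", "n_sites")) {
  metric <- match.arg(metric)
  if (nrow(summaries) == 0) {
    return(structure(list(found = FALSE, reason = "no scaffold summaries"),
                     class = "marker_region"))
  }
  elig <- summaries |>
    dplyr::filter(.data$n_sex_specific > min_sites,
                  !is.na(.data$max_block_span_bp))
  if (nrow(elig) == 0) {
    return(structure(list(found = FALSE,
                          reason = sprintf(
                            "no scaffold with > %d sex-specific sites and an LD block",
                            min_sites)),
                     class = "marker_region"))
  }
  n_in_block <- purrr::pmap_int(
    list(elig$scaffold, elig$max_block_start, elig$max_block_end),
    function(s, a, b) sum(scan$sex_specific & scan$scaffold == s &
                            scan$pos >= a & scan$pos <= b))
  elig$n_sites_in_block <- n_in_block
  ord <- if (metric == "block_span") {
    order(-elig$max_block_span_bp, -elig$n_sites_in_block, elig$scaffold)
  } else {
    order(-elig$n_sex_specific, -elig$max_block_span_bp, elig$scaffold)
  }
  top <- elig[ord[1], ]
  in_block <- scan |>
    dplyr::filter(.data$sex_specific, .data$scaffold == top$scaffold,
                  .data$pos >= top$max_block_start,
                  .data$pos <= top$max_block_end)
  on_scaffold <- scan |>
    dplyr::filter(.data$sex_specific, .data$scaffold == top$scaffold)
  structure(list(found = TRUE, scaffold = top$scaffold,
                 block_start = top$max_block_start,
                 block_end = top$max_block_end,
                 block_span_bp = top$max_block_span_bp,
                 sites = in_block, region_sites = on_scaffold),
            class = "marker_region")
}

#' @export
print.marker_region <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<marker_region> no marker region:", x$reason %||% "", "\n")
  } else {
    cat(sprintf(
      "<marker_region> %s:%d-%d (%d bp), %d sex-specific site(s) in block, %d in region\n",
      x$scaffold, x$block_start, x$block_end, x$block_span_bp,
      nrow(x$sites), nrow(x$region_sites)))
  }
  invisible(x)
}

#' Tidy the sites of a marker region
#'
#' @param x A `marker_region`.
#' @param ... Unused.
#' @return Tibble of the sex-specific sites inside the selected block, with
#'   an `in_block` flag for region sites outside it.
#' @export
tidy.marker_region <- function(x, ...) {
  if (!isTRUE(x$found)) return(tibble())
  x$region_sites |>
    dplyr::mutate(in_block = .data$pos >= x$block_start &
                    .data$pos <= x$block_end)
}

#' One-row summary of a marker region
#'
#' Reports both the in-block and in-region sex-specific counts: block
#' bounds and region bounds need not coincide (block endpoints may be
#' non-sex-specific markers), so both tallies are kept.
#'
#' @param x A `marker_region`.
#' @param ... Unused.
#' @export
glance.marker_region <- function(x, ...) {
  if (!isTRUE(x$found)) return(tibble(found = FALSE))
  tibble(found = TRUE, scaffold = x$scaffold,
         block_start = x$block_start, block_end = x$block_end,
         block_span_bp = x$block_span_bp,
         n_sites_in_block = nrow(x$sites),
         n_sites_in_region = nrow(x$region_sites))
}
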