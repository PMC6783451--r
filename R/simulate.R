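#' Configuration for a synthetic resequencing cohort
#'
#' Describes a cohort with the exact statistical structure the scan
#' assumes: a modest wild-caught cohort genotyped genome-wide (defaults 15
#' males and 16 females, matching a realistic resequencing study of a
#' species without sexual dimorphism), a background of sites in
#' Hardy-Weinberg equilibrium independent of sex, and one planted
#' sex-determination region — a recombination-suppressed core where the
#' heterogametic sex is uniformly heterozygous and the homogametic sex
#' uniformly homozygous-reference, with leaky flanks emulating the
#' partially associated shoulders seen outside a fully suppressed core.
#'
#' @param n_males,n_females Cohort composition (defaults 15 and 16).
#' @param scaffolds Named integer vector of scaffold lengths in bp.
#' @param n_background_sites Total background SNPs, allocated to scaffolds
#'   proportionally to length.
#' @param maf_beta `c(shape1, shape2)` of the Beta distribution background
#'   minor-allele frequencies are drawn from (default `c(1, 3)`, skewed to
#'   rare as in site-frequency spectra), truncated to `maf_range`.
#' @param maf_range Truncation bounds (default `c(0.05, 0.5)` so background
#'   sites survive downstream MAF filters).
#' @param sd_scaffold,sd_start Scaffold and start of the planted region.
#' @param n_core_sites Strictly segregating core sites (default 30).
#' @param core_spacing_bp Mean spacing between core sites (default 200 bp,
#'   giving a few-kb core like real sex-determination blocks).
#' @param n_flank_sites Flank sites on each side of the core (default 0:
#'   the default cohort is the parameter-recovery condition, where the
#'   planted truth region is the core alone; set a positive count to add
#'   the partially associated shoulder).
#' @param flank_leak_prob Probability a flank site behaves as background in
#'   a given male rather than heterozygous (default 0.3).
#' @param missing_rate Per-call missing probability.
#' @param error_rate Per-call probability of resampling one of the two
#'   wrong genotype classes uniformly.
#' @param system `"XY"` (male heterogametic) or `"ZW"` (mirror).
#' @param core_indel Plant an 8-bp deletion as one core site (an assay
#'   fixture for size-dimorphism designs).
#' @param seed Master seed; all randomness derives from it through
#'   documented phase substreams (positions/alleles, genotypes, errors,
#'   missingness, reference).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_males = 15L, n_females = 16L,
                          scaffolds = setNames(rep(1e6L, 5),
                                               sprintf("scaffold_%02d", 1:5)),
                          n_background_sites = 10000L,
                          maf_beta = c(1, 3), maf_range = c(0.05, 0.5),
                          sd_scaffold = "scaffold_03", sd_start = 400000L,
                          n_core_sites = 30L, core_spacing_bp = 200L,
                          n_flank_sites = 0L, flank_leak_prob = 0.3,
                          missing_rate = 0.02, error_rate = 0,
                          system = c("XY", "ZW"), core_indel = FALSE,
                          seed = 1L) {
  system <- match.arg(system)
  stopifnot(.is_count(n_males), .is_count(n_females), n_males >= 1,
            n_females >= 1, .is_count(n_background_sites),
            .is_prob(missing_rate), .is_prob(error_rate),
            .is_prob(flank_leak_prob), n_core_sites >= 1,
            sd_scaffold %in% names(scaffolds))
  cfg <- structure(list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    scaffolds = scaffolds, n_background_sites = as.integer(n_background_sites),
    maf_beta = maf_beta, maf_range = maf_range,
    sd_scaffold = sd_scaffold, sd_start = as.integer(sd_start),
    n_core_sites = as.integer(n_core_sites),
    core_spacing_bp = as.integer(core_spacing_bp),
    n_flank_sites = as.integer(n_flank_sites),
    flank_leak_prob = flank_leak_prob,
    missing_rate = missing_rate, error_rate = error_rate,
    system = system, core_indel = isTRUE(core_indel),
    seed = as.integer(seed)), class = "cohort_config")
  cfg
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file whose keys mirror [cohort_config()] arguments
#'   (`scaffolds` as a name-to-length map).
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scaffolds)) y$scaffolds <- unlist(y$scaffolds)
  do.call(cohort_config, y)
}

.rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

.other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a cohort with a planted sex-determination region
#'
#' Background sites draw an allele frequency from the truncated Beta and
#' genotypes under Hardy-Weinberg independently of sex. Core sites make
#' every heterogametic-sex sample heterozygous and every other sample
#' homozygous reference. Flank sites behave like core in each
#' heterogametic sample with probability `1 - flank_leak_prob`, otherwise
#' like background. Genotyping error is applied first, then missingness,
#' call by call. Reference scaffolds are uniform random sequence carrying
#' the planted reference alleles.
#'
#' @param config A [cohort_config()].
#' @param reference Generate reference scaffold sequences (`TRUE` by
#'   default; skip for large parameter-recovery sweeps that never touch
#'   sequence).
#' @return A list: `gm` (a [genotype_matrix()]), `ref` (named character
#'   vector of scaffold sequences, or `NULL`), `truth` (a `truth_set`:
#'   `region`, per-site `site_class`, `system`, per-sample sex).
#' @export
simulate_cohort <- function(config, reference = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n_s <- config$n_males + config$n_females
  samples <- tibble(
    sample_id = c(sprintf("F%02d", seq_len(config$n_females)),
                  sprintf("M%02d", seq_len(config$n_males))),
    sex = c(rep("female", config$n_females), rep("male", config$n_males)))

  # --- phase 1: site positions and alleles ---------------------------------
  set.seed(.sub_seed(config$seed, 1L))
  core_gap <- 1L + stats::rpois(config$n_core_sites - 1L,
                                config$core_spacing_bp - 1L)
  core_pos <- config$sd_start + c(0L, cumsum(core_gap))
  flank_gap_l <- 1L + stats::rpois(config$n_flank_sites, config$core_spacing_bp - 1L)
  flank_gap_r <- 1L + stats::rpois(config$n_flank_sites, config$core_spacing_bp - 1L)
  flank_pos <- sort(c(config$sd_start - rev(cumsum(flank_gap_l)),
                      max(core_pos) + cumsum(flank_gap_r)))
  region_pos <- sort(c(core_pos, flank_pos))
  sd_len <- config$scaffolds[[config$sd_scaffold]]
  if (min(region_pos) < 1L || max(region_pos) > sd_len) {
    .stop("planted region overflows its scaffold", "region_overflow")
  }
  n_bg <- stats::rmultinom(1, config$n_background_sites,
                           config$scaffolds / sum(config$scaffolds))[, 1]
  bg <- purrr::imap_dfr(as.list(n_bg), function(k, nm) {
    p <- sort(sample.int(config$scaffolds[[nm]], k))
    tibble(scaffold = nm, pos = p)
  })
  # background sites may not collide with planted ones
  bg <- bg[!(bg$scaffold == config$sd_scaffold & bg$pos %in% region_pos), ]
  region <- tibble(scaffold = config$sd_scaffold, pos = region_pos)
  sites <- dplyr::bind_rows(bg, region) |>
    dplyr::arrange(factor(.data$scaffold, names(config$scaffolds)), .data$pos)
  site_class <- rep("background", nrow(sites))
  site_class[sites$scaffold == config$sd_scaffold &
               sites$pos %in% core_pos] <- "core"
  site_class[sites$scaffold == config$sd_scaffold &
               sites$pos %in% flank_pos] <- "flank"
  ref <- .rand_bases(nrow(sites))
  alt <- .other_base(ref)
  if (config$core_indel) {
    i <- which(site_class == "core")[ceiling(config$n_core_sites / 2)]
    # an 8-bp deletion: ref spans 9 bases, alt keeps the first
    ref[i] <- paste0(ref[i], paste(.rand_bases(8L), collapse = ""))
    alt[i] <- substr(ref[i], 1, 1)
  }
  maf <- stats::qbeta(stats::runif(nrow(sites),
                                   stats::pbeta(config$maf_range[1],
                                                config$maf_beta[1], config$maf_beta[2]),
                                   stats::pbeta(config$maf_range[2],
                                                config$maf_beta[1], config$maf_beta[2])),
                      config$maf_beta[1], config$maf_beta[2])

  # --- phase 2: genotypes --------------------------------------------------
  set.seed(.sub_seed(config$seed, 2L))
  n_sites <- nrow(sites)
  calls <- matrix(rbinom(n_sites * n_s, 2L, rep(maf, n_s)),
                  nrow = n_sites, ncol = n_s)
  het_sex <- if (config$system == "XY") "male" else "female"
  het_cols <- which(samples$sex == het_sex)
  hom_cols <- which(samples$sex != het_sex)
  core_rows <- which(site_class == "core")
  flank_rows <- which(site_class == "flank")
  calls[core_rows, het_cols] <- 1L
  calls[core_rows, hom_cols] <- 0L
  if (length(flank_rows)) {
    calls[flank_rows, hom_cols] <- 0L
    leak <- matrix(runif(length(flank_rows) * length(het_cols)) <
                     config$flank_leak_prob,
                   nrow = length(flank_rows))
    fl <- matrix(1L, nrow = length(flank_rows), ncol = length(het_cols))
    if (any(leak)) {
      bgdraw <- matrix(rbinom(length(flank_rows) * length(het_cols), 2L,
                              rep(maf[flank_rows], length(het_cols))),
                       nrow = length(flank_rows))
      fl[leak] <- bgdraw[leak]
    }
    calls[flank_rows, het_cols] <- fl
  }

  # --- phase 3: genotyping error (uniform over the two wrong classes) ------
  set.seed(.sub_seed(config$seed, 3L))
  if (config$error_rate > 0) {
    err <- which(runif(length(calls)) < config$error_rate)
    if (length(err)) {
      shift <- sample.int(2L, length(err), replace = TRUE)
      calls[err] <- (calls[err] + shift) %% 3L
    }
  }

  # --- phase 4: missingness ------------------------------------------------
  set.seed(.sub_seed(config$seed, 4L))
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  sites$ref <- ref; sites$alt <- alt
  gm <- genotype_matrix(sites, samples, calls)

  # --- phase 5: reference sequence -----------------------------------------
  ref_seqs <- NULL
  if (reference) {
    set.seed(.sub_seed(config$seed, 5L))
    ref_seqs <- vapply(names(config$scaffolds), function(nm) {
      paste(.rand_bases(config$scaffolds[[nm]]), collapse = "")
    }, character(1))
    for (i in seq_len(nrow(sites))) {
      s <- sites$scaffold[i]
      ref_seqs[[s]] <- paste0(
        substr(ref_seqs[[s]], 1L, sites$pos[i] - 1L), sites$ref[i],
        substr(ref_seqs[[s]], sites$pos[i] + nchar(sites$ref[i]),
               nchar(ref_seqs[[s]])))
    }
  }

  truth <- structure(list(
    region = list(scaffold = config$sd_scaffold,
                  first_core_pos = min(core_pos),
                  last_core_pos = max(core_pos)),
    sites = tibble(scaffold = sites$scaffold, pos = sites$pos,
                   site_class = site_class),
    system = config$system,
    samples = samples), class = "truth_set")
  list(gm = gm, ref = ref_seqs, truth = truth)
}

#' Write a truth set to JSON
#'
#' @param truth A `truth_set` from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    region = truth$region,
    sites = truth$sites,
    system = truth$system,
    samples = truth$samples), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth set from JSON
#'
#' @param path JSON written by [write_truth()].
#' @return A `truth_set`.
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    region = as.list(j$region),
    sites = as_tibble(j$sites) |>
      dplyr::mutate(pos = as.integer(.data$pos)),
    system = j$system,
    samples = as_tibble(j$samples)), class = "truth_set")
}

#' Write all artefacts of a simulated cohort
#'
#' Emits the VCF, the sex map, the truth JSON and (when present) the
#' reference FASTA into a directory. Deterministic given the cohort seed:
#' the same configuration writes byte-identical files.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param contig_lengths Optional named scaffold lengths for the VCF header.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir, contig_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             sex_map = file.path(dir, "sex_map.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths[["vcf"]], contig_lengths)
  write_sex_map(sim$gm$samples, paths[["sex_map"]])
  write_truth(sim$truth, paths[["truth"]])
  if (!is.null(sim$ref)) {
    paths[["fasta"]] <- file.path(dir, "reference.fa")
    write_reference(sim$ref, paths[["fasta"]])
  }
  invisible(paths)
}
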