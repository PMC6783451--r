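#' Read a sample-to-sex map
#'
#' Parses the two-column TSV linking resequenced individuals to phenotypic
#' sex (as diagnosed, e.g., by gonad inspection). Accepted sex tokens are
#' `F`/`female`, `M`/`male`, `U`/`unknown`, case-insensitive. A header line
#' is detected and skipped when its second field is not a recognised token.
#'
#' @param path Path to a TSV with columns `sample_id` and `sex`.
#' @param quiet Suppress the per-sex tally message.
#' @return A tibble with columns `sample_id` and `sex`
#'   (`female`/`male`/`unknown`). Unknown-sex samples are retained but are
#'   excluded from all sex-contrast computations downstream.
#' @export
read_sex_map <- function(path, quiet = FALSE) {
  raw <- readr::read_tsv(path, col_names = c("sample_id", "sex"),
                         col_types = "cc", progress = FALSE)
  norm <- .normalize_sex(raw$sex)
  if (nrow(raw) > 0 && is.na(norm[1])) {
    raw <- raw[-1, , drop = FALSE]  # header row
    norm <- norm[-1]
  }
  bad <- which(is.na(norm))
  if (length(bad)) {
    .stop(sprintf("unrecognized sex token '%s' at row %d of %s",
                  raw$sex[bad[1]], bad[1], path), "bad_sex_token")
  }
  if (anyDuplicated(raw$sample_id)) {
    dup <- raw$sample_id[duplicated(raw$sample_id)][1]
    .stop(paste0("duplicate sample_id ", dup), "duplicate_sample")
  }
  out <- tibble(sample_id = raw$sample_id, sex = norm)
  if (!quiet) {
    inform(sprintf("read_sex_map: %d females, %d males, %d unknown",
                   sum(norm == "female"), sum(norm == "male"),
                   sum(norm == "unknown")))
  }
  out
}

.normalize_sex <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("f", "female")] <- "female"
  out[key %in% c("m", "male")] <- "male"
  out[key %in% c("u", "unknown")] <- "unknown"
  out
}

#' Write a sample-to-sex map TSV
#'
#' @param samples Tibble with `sample_id`, `sex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sex_map <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "sex")], path, col_names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT subfield of a VCF v4.2 (as emitted by standard joint
#' genotypers) for the samples named in the sex map. Unphased and phased
#' separators are both accepted; phase is discarded because every
#' downstream computation (the exact tests, the two-locus EM) works on
#' unphased genotypes. Half-missing calls (e.g. `./1`) are mapped to
#' missing. FILTER and QUAL are ignored.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @param samples Tibble from [read_sex_map()]; every `sample_id` must be
#'   present in the VCF header.
#' @return A [genotype_matrix()] with sites in file order. Genotypes that
#'   reference an allele index greater than 1 are set to `NA` at this stage;
#'   such (multiallelic) sites are expected to be removed by
#'   [filter_biallelic()] before any scan.
#' @export
read_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(samples$sample_id, vcf_samples)
  if (length(missing_samples)) {
    .stop(paste0("sex-map sample(s) absent from VCF: ",
                 paste(missing_samples, collapse = ", ")), "missing_sample")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, samples$sample_id, drop = FALSE]
  calls <- .encode_gt(gt)
  # a GT referencing allele index >= 2 at a biallelic record is malformed;
  # at multiallelic records it becomes NA and the site falls to the filter
  high_idx <- matrix(grepl("[2-9]", as.vector(gt)), nrow = nrow(gt))
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(high_idx[biallelic, , drop = FALSE])) {
    bad <- which(biallelic & rowSums(high_idx) > 0)[1]
    .stop(sprintf("GT allele index >= 2 at biallelic site %s:%s",
                  fix$CHROM[bad], fix$POS[bad]), "bad_gt_index")
  }
  sites <- tibble(
    scaffold = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  genotype_matrix(sites, samples, calls)
}

# "0/0"->0, "0/1"/"1/0"->1, "1/1"->2; '|' treated as '/'; any '.' or an
# allele index >= 2 -> NA
.encode_gt <- function(gt) {
  dims <- dim(gt)
  g <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  out <- rep(NA_integer_, length(g))
  out[g == "0/0"] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g == "1/1"] <- 2L
  matrix(out, nrow = dims[1], ncol = dims[2])
}

#' Write a genotype matrix as a VCF v4.2
#'
#' Emits a minimal plain-text VCF carrying GT only, with one `##contig`
#' line per scaffold. Round-trips exactly through [read_vcf()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (plain text).
#' @param contig_lengths Optional named integer vector of scaffold lengths
#'   for the `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  scaffolds <- unique(gm$sites$scaffold)
  contig <- if (is.null(contig_lengths)) {
    sprintf("##contig=<ID=%s>", scaffolds)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", scaffolds,
            as.integer(contig_lengths[scaffolds]))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sexmarkr",
    contig,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = nrow(gm$calls))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(
    gm$sites$scaffold, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    ".", ".", ".", "GT",
    apply(gt_str, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read reference scaffolds from FASTA
#'
#' @param path FASTA path.
#' @return A named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write reference scaffolds to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path, width = 80L)
  invisible(path)
}
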