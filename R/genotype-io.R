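#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into alternate-allele dosages. Only biallelic SNP
#' records are kept; multi-allelic or indel records are skipped with a
#' warning (splitting them would make dosages ambiguous). `./.` (or `.`)
#' becomes a missing value. Phasing separators (`|`) are accepted.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path), call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warning(sprintf("skipping %d non-biallelic-SNP record(s)", sum(!snp)),
            call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in VCF", call. = FALSE)
  dos <- gt_to_dosage(gt)  # variants x samples
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, sample_ids = colnames(gt))
}

# GT strings (variants x samples) -> numeric dosage matrix
gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean == "0/0"] <- 0
  d[clean %in% c("0/1", "1/0")] <- 1
  d[clean == "1/1"] <- 2
  known <- is.na(gt) | clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(!known)) stop("malformed GT field(s) in VCF", call. = FALSE)
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits minimal VCFv4.2 with a GT FORMAT field; missing dosages become
#' `./.` and dosage 1 becomes the unphased heterozygote `0/1`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haploscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_variants(gm)), function(j) {
    d <- gm$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(gm$variants$chrom[j], gm$variants$pos[j], gm$variants$id[j],
            gm$variants$ref[j], gm$variants$alt[j], ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Marker filter specification
#'
#' Defaults follow the usual post-calling filters for a landrace panel:
#' markers present in at least 90% of genotypes with minor allele frequency
#' of at least 3%.
#'
#' @param min_call_rate minimum fraction of non-missing genotypes.
#' @param min_maf minimum minor allele frequency (computed on alleles of
#'   non-missing genotypes only).
#' @return a list of class `variant_filter_spec`.
#' @export
variant_filter_spec <- function(min_call_rate = 0.90, min_maf = 0.03) {
  assert_fraction(min_call_rate, "min_call_rate")
  assert_fraction(min_maf, "min_maf")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf),
            class = "variant_filter_spec")
}

#' Filter variants on call rate and minor allele frequency
#'
#' Retains variants with call rate >= `min_call_rate` and MAF >= `min_maf`
#' ("at least": ties at either threshold are kept).
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [variant_filter_spec()].
#' @return the filtered [genotype_matrix()].
#' @export
filter_variants <- function(gm, spec = variant_filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), n_variants(gm) > 0)
  st <- variant_stats(gm)
  keep <- !is.na(st$maf) & st$call_rate >= spec$min_call_rate &
    st$maf >= spec$min_maf
  if (!any(keep)) {
    stop("variant filter removed every marker; thresholds look over-aggressive",
         call. = FALSE)
  }
  subset_variants(gm, keep)
}

#' Windowed SNP density per chromosome
#'
#' @param gm a [genotype_matrix()].
#' @param window_bp window width in bp.
#' @return data.frame with `chrom`, `window_start`, `window_end`, `count`;
#'   attribute `"totals"` holds per-chromosome totals.
#' @export
snp_density <- function(gm, window_bp = 1e6) {
  stopifnot(window_bp > 0)
  out <- lapply(unique(gm$variants$chrom), function(ch) {
    pos <- gm$variants$pos[gm$variants$chrom == ch]
    nbin <- ceiling(max(pos) / window_bp)
    bin <- pmin(ceiling(pos / window_bp), nbin)
    cnt <- tabulate(bin, nbins = nbin)
    data.frame(chrom = ch,
               window_start = (seq_len(nbin) - 1) * window_bp + 1,
               window_end = seq_len(nbin) * window_bp,
               count = cnt, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "totals") <- tapply(res$count, res$chrom, sum)
  res
}

#' Export dosages as a tab-separated table (samples in rows)
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(gm, path) {
  df <- data.frame(sample = gm$sample_ids, gm$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
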