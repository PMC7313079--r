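#' Construct a genotype matrix
#'
#' The central container of the package: a samples x variants matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for missing) together with
#' variant coordinates. All variants are biallelic SNPs and positions are
#' 1-based (VCF convention) and strictly increasing within a chromosome.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per variant, in column order of `dosages`).
#' @param sample_ids character vector of sample labels; defaults to the
#'   rownames of `dosages` or `S1..Sn`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("`dosages` must be numeric", call. = FALSE)
  storage.mode(dosages) <- "double"
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("`variants` needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table and dosage matrix dimensions disagree", call. = FALSE)
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("positions not strictly increasing on chromosome %s", ch),
           call. = FALSE)
    }
  }
  sample_ids <- sample_ids %||% rownames(dosages) %||%
    paste0("S", seq_len(nrow(dosages)))
  rownames(dosages) <- sample_ids
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(round(variants$pos))
  variants$id <- paste0(variants$chrom, ":", variants$pos)
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d biallelic SNPs on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))
  ))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.2f%%; chromosomes: %s\n", 100 * miss,
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix by variant index
#' @param gm a [genotype_matrix()].
#' @param j integer or logical index over variants.
#' @return a new `genotype_matrix`.
#' @export
subset_variants <- function(gm, j) {
  genotype_matrix(gm$dosages[, j, drop = FALSE],
                  gm$variants[j, , drop = FALSE],
                  sample_ids = gm$sample_ids)
}

#' Per-variant minor allele frequency and call rate
#'
#' MAF is computed on allele counts from non-missing genotypes only.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `id`, `call_rate`, `maf`.
#' @export
variant_stats <- function(gm) {
  dos <- gm$dosages
  n <- nrow(dos)
  called <- colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  data.frame(
    id = gm$variants$id,
    call_rate = called / n,
    maf = pmin(p, 1 - p),
    stringsAsFactors = FALSE
  )
}
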