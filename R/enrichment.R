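#' Drop small haploblocks before enrichment testing
#'
#' Retains blocks with strictly more than `min_snps_exclusive` member SNPs
#' (the default keeps blocks of 7+ SNPs).
#'
#' @param hb a `haploblock_set`.
#' @param min_snps_exclusive exclusive lower bound on member count.
#' @return the filtered `haploblock_set`.
#' @export
filter_blocks <- function(hb, min_snps_exclusive = 6L) {
  keep <- hb$blocks$n_snps > min_snps_exclusive
  structure(list(blocks = hb$blocks[keep, , drop = FALSE],
                 members = hb$members[hb$blocks$block_id[keep]]),
            class = "haploblock_set")
}

#' Rank SNPs by GWAS p-value for set enrichment
#'
#' SNPs are ordered by increasing genomic-control-adjusted p-value (most
#' significant first), with ties broken by genomic coordinate. The rank
#' statistic is `-log10(p)` capped at 300.
#'
#' @param gwas a `gwas_result` with a finite p-value for every panel SNP.
#' @param cap cap on the rank statistic.
#' @return object of class `ranked_snps`: data.frame in rank order with
#'   `id`, `chrom`, `pos`, `p`, `stat`, `orig_index` (position of each SNP
#'   in the GWAS input, used to map block members onto ranks).
#' @export
rank_snps <- function(gwas, cap = 300) {
  p <- gwas$p_gc
  if (any(!is.finite(p))) {
    stop("every SNP needs a finite p-value before ranking", call. = FALSE)
  }
  ord <- order(p, match(gwas$chrom, unique(gwas$chrom)), gwas$pos)
  out <- data.frame(id = gwas$id[ord], chrom = gwas$chrom[ord],
                    pos = gwas$pos[ord], p = p[ord],
                    stat = pmin(-log10(p[ord]), cap),
                    orig_index = ord, stringsAsFactors = FALSE)
  class(out) <- c("ranked_snps", "data.frame")
  out
}

#' GSEA-style enrichment score of a SNP set over a ranking
#'
#' Walks the ranked SNP list accumulating `stat^alpha / sum(stat^alpha)` at
#' every member of the set ("hit") and `-1 / (N - |set|)` at every
#' non-member; the enrichment score is the running-sum value of maximal
#' absolute deviation from zero (signed). `alpha = 0` gives the unweighted
#' Kolmogorov-Smirnov-type statistic. If every hit has zero statistic the
#' hits fall back to equal weights.
#'
#' @param ranked a [rank_snps()] result.
#' @param members integer variant indices (positions in the original GWAS
#'   table) forming the set.
#' @param alpha weight exponent on the rank statistic (default 1).
#' @return the enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, members, alpha = 1) {
  N <- nrow(ranked)
  pos <- sort(match(members, ranked$orig_index))
  if (any(is.na(pos))) stop("set members missing from the ranking",
                            call. = FALSE)
  s <- length(pos)
  if (s == 0 || s >= N) {
    stop("set must be a non-empty proper subset of the panel", call. = FALSE)
  }
  w <- ranked$stat[pos]^alpha
  if (sum(w) == 0) w <- rep(1, s)
  es_from_positions(matrix(pos, nrow = 1), matrix(w, nrow = 1), N)[1]
}

# vectorized ES over many same-size sets: pos and w are n_sets x s matrices
# with row-sorted positions; returns the signed maximal deviation per set
es_from_positions <- function(pos, w, N) {
  s <- ncol(pos)
  miss_step <- 1 / (N - s)
  sumw <- rowSums(w)
  zero <- sumw == 0
  if (any(zero)) { w[zero, ] <- 1; sumw[zero] <- s }
  cw <- w
  if (s > 1) for (k in 2:s) cw[, k] <- cw[, k - 1] + w[, k]
  hi <- rep(-Inf, nrow(pos))
  lo <- rep(Inf, nrow(pos))
  for (k in seq_len(s)) {
    after <- cw[, k] / sumw - (pos[, k] - k) * miss_step
    before <- (cw[, k] - w[, k]) / sumw - (pos[, k] - k) * miss_step
    hi <- pmax(hi, after)
    lo <- pmin(lo, before)
  }
  # the walk ends at 0, so the extremes are attained at hit boundaries
  hi <- pmax(hi, 0)
  lo <- pmin(lo, 0)
  ifelse(abs(hi) >= abs(lo), hi, lo)
}

#' Permutation test of haploblock enrichment for one trait
#'
#' The null draws random SNP sets of matched size from the panel without
#' replacement (equivalently, permuting set labels over the fixed ranking).
#' One shared permutation stream per trait is reused across blocks by
#' size-stratified lookup. P-values are positive-tail only,
#' `p = (1 + #[null es >= observed es]) / (n_perm + 1)`, BH-adjusted across
#' blocks within the trait; a block is significant when its enrichment
#' score is positive and `q < fdr`.
#'
#' @param ranked a [rank_snps()] result.
#' @param hb a `haploblock_set` (pre-filtered, see [filter_blocks()]).
#' @param n_perm number of permutations (default 100000).
#' @param seed integer seed for the permutation stream.
#' @param alpha weight exponent, see [enrichment_score()].
#' @param fdr significance threshold on the q-value (default 0.05).
#' @param trait trait label recorded in the result.
#' @return data.frame of class `enrichment_result` with `trait`, `block_id`,
#'   `n_snps`, `es`, `p_perm`, `q`, `significant`.
#' @export
permutation_test <- function(ranked, hb, n_perm = 1e5, seed = 1L,
                             alpha = 1, fdr = 0.05, trait = "trait") {
  stopifnot(inherits(hb, "haploblock_set"), n_perm >= 100)
  N <- nrow(ranked)
  ids <- hb$blocks$block_id
  sizes <- hb$blocks$n_snps
  if (any(sizes >= N)) stop("a block spans the whole panel", call. = FALSE)
  if (length(ids) == 0) {
    out <- data.frame(trait = character(), block_id = character(),
                      n_snps = integer(), es = numeric(), p_perm = numeric(),
                      q = numeric(), significant = logical())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  es_obs <- vapply(ids, function(b) {
    enrichment_score(ranked, hb$members[[b]], alpha = alpha)
  }, numeric(1))

  set.seed(child_seed(seed, paste0("perm-", trait)))
  stat <- ranked$stat
  p_perm <- numeric(length(ids))
  for (s in sort(unique(sizes))) {
    P <- t(vapply(seq_len(n_perm),
                  function(i) sort.int(sample.int(N, s)),
                  integer(s)))
    if (s == 1L) P <- matrix(P, ncol = 1L)
    W <- matrix(stat[P], nrow = n_perm)^alpha
    null_es <- es_from_positions(P, W, N)
    for (k in which(sizes == s)) {
      p_perm[k] <- (1 + sum(null_es >= es_obs[k])) / (n_perm + 1)
    }
  }
  q <- bh_fdr(p_perm)
  out <- data.frame(trait = trait, block_id = ids, n_snps = sizes,
                    es = unname(es_obs), p_perm = p_perm, q = q,
                    significant = es_obs > 0 & q < fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Run the enrichment test for several traits over one block list
#'
#' @param gwas_list named list of `gwas_result` objects (one per trait).
#' @param hb a pre-filtered `haploblock_set`.
#' @param n_perm,seed,alpha,fdr see [permutation_test()].
#' @param fdr_scope `"within_trait"` (default: BH across blocks separately
#'   per trait, mirroring the per-trait GWAS FDR convention) or `"global"`
#'   (BH across all block-trait pairs at once).
#' @return a combined `enrichment_result` data.frame.
#' @export
block_enrichment <- function(gwas_list, hb, n_perm = 1e5, seed = 1L,
                             alpha = 1, fdr = 0.05,
                             fdr_scope = c("within_trait", "global")) {
  stopifnot(is.list(gwas_list), !is.null(names(gwas_list)))
  fdr_scope <- match.arg(fdr_scope)
  res <- lapply(names(gwas_list), function(tr) {
    permutation_test(rank_snps(gwas_list[[tr]]), hb, n_perm = n_perm,
                     seed = seed, alpha = alpha, fdr = fdr, trait = tr)
  })
  out <- do.call(rbind, res)
  if (fdr_scope == "global" && nrow(out)) {
    out$q <- bh_fdr(out$p_perm)
    out$significant <- out$es > 0 & out$q < fdr
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Significantly enriched block sets per trait
#'
#' @param results an `enrichment_result` covering one or more traits (all
#'   computed on the same block list).
#' @return named list mapping each trait to the character vector of its
#'   significantly enriched block ids (possibly empty).
#' @export
enriched_sets_by_trait <- function(results) {
  traits <- unique(results$trait)
  out <- lapply(traits, function(tr) {
    r <- results[results$trait == tr, ]
    r$block_id[r$significant]
  })
  names(out) <- traits
  out
}
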