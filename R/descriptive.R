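#' Spearman correlation matrix of a trait table
#'
#' Rank correlation with average ranks for ties, on pairwise-complete
#' observations. Entries supported by fewer than `min_pairs` complete pairs,
#' or involving a constant column, are reported as `NA` and flagged.
#' Threshold flags mark the conventional levels used when reading
#' correlation heatmaps for variable groups.
#'
#' @param table data.frame of numeric traits (samples in rows).
#' @param min_pairs minimum complete pairs per entry (default 3).
#' @param thresholds levels at which `|r|` flags are reported.
#' @return list of class `correlation_matrix` with `r` (matrix), `n`
#'   (pairwise counts), `undefined` (logical matrix) and `flags` (list of
#'   logical matrices `|r| > t`).
#' @export
spearman_matrix <- function(table, min_pairs = 3L,
                            thresholds = c(0.4, 0.7, 0.9)) {
  X <- as.matrix(table)
  stopifnot(is.numeric(X))
  k <- ncol(X)
  n <- crossprod(!is.na(X))
  suppressWarnings(
    r <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  )
  undef <- is.na(r) | n < min_pairs
  r[n < min_pairs] <- NA
  diag(undef) <- FALSE
  flags <- lapply(thresholds, function(t) !is.na(r) & abs(r) > t)
  names(flags) <- paste0("gt_", thresholds)
  structure(list(r = r, n = n, undefined = undef, flags = flags),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d variables (Spearman, pairwise complete)\n",
              ncol(x$r)))
  invisible(x)
}

#' Nucleotide diversity from polymorphic sites, per chromosome and group
#'
#' Per-site diversity within a group is the unbiased expected
#' heterozygosity `pi = n / (n - 1) * 2 p (1 - p)`, with `n` the number of
#' non-missing alleles and `p` the alternate allele frequency in the group.
#' Sites monomorphic within a group are excluded from that group's mean, so
#' the value is a mean over polymorphic sites (which overestimates per-bp
#' diversity but supports between-group comparison).
#'
#' @param gm a [genotype_matrix()].
#' @param groups character/factor of group labels, one per sample.
#' @return data.frame with `chrom`, `group`, `pi` (mean over polymorphic
#'   sites) and `n_sites` (polymorphic site count).
#' @export
site_pi <- function(gm, groups) {
  stopifnot(length(groups) == n_samples(gm))
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    dos <- gm$dosages[groups == g, , drop = FALSE]
    called <- colSums(!is.na(dos))
    if (all(called < 2)) {
      stop(sprintf("group %s has fewer than 2 genotyped samples at every site", g),
           call. = FALSE)
    }
    n_allele <- 2 * called
    p <- ifelse(called > 0, colSums(dos, na.rm = TRUE) / n_allele, NA)
    poly <- !is.na(p) & p > 0 & p < 1 & n_allele >= 2
    pi_site <- ifelse(poly, n_allele / (n_allele - 1) * 2 * p * (1 - p), NA)
    for (ch in unique(gm$variants$chrom)) {
      sel <- poly & gm$variants$chrom == ch
      out[[paste(ch, g)]] <- data.frame(
        chrom = ch, group = g,
        pi = if (any(sel)) mean(pi_site[sel]) else NA_real_,
        n_sites = sum(sel), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise Mann-Whitney-Wilcoxon group comparisons
#'
#' For every pair of groups, a two-sided rank-sum test of the values.
#' When the combined sample size is at most `exact_max` the p-value is
#' computed by exhaustive enumeration of all group assignments (handling
#' ties through average ranks, two-sided via distance of U from its mean);
#' larger pairs use the normal approximation with tie correction (through
#' [stats::wilcox.test()]).
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param exact_max maximum combined size for the exact method (default 20).
#' @return data.frame with `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p`,
#'   `method`.
#' @export
mann_whitney_groups <- function(values, groups, exact_max = 20L) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  glev <- unique(groups)
  sizes <- table(groups)
  if (length(glev) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least two values",
                           call. = FALSE)
  pairs <- utils::combn(glev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    x <- values[groups == ga]; y <- values[groups == gb]
    n1 <- length(x); n2 <- length(y)
    rk <- rank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (n1 + n2 <= exact_max) {
      p <- mw_exact_p(x, y)
      method <- "exact"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      p <- wt$p.value
      method <- "normal"
    }
    data.frame(group_a = ga, group_b = gb, n_a = n1, n_b = n2, U = U,
               p = p, method = method, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# assignments; ties handled by average ranks, two-sidedness by |U - n1 n2/2|
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  mu <- n1 * n2 / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
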