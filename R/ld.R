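#' Pairwise linkage disequilibrium (r-squared) between dosage columns
#'
#' r-squared is the squared Pearson correlation of alternate-allele dosages
#' over pairwise-complete samples (composite LD on genotypes, the natural
#' choice for a highly selfing panel where dosage r2 tracks haplotype r2).
#' Pairs with fewer than `min_n` complete samples, or with a column
#' monomorphic among the complete samples, are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param scope `"intra_chromosomal"` (all same-chromosome pairs, with
#'   physical distance) or `"unlinked"` (pairs on different chromosomes,
#'   subsampled to `max_pairs`).
#' @param max_pairs maximum number of unlinked pairs to sample.
#' @param seed seed for the unlinked-pair subsample.
#' @param min_n minimum pairwise-complete sample count (default 20).
#' @return data.frame with columns `i`, `j` (variant indices, `i < j`),
#'   `same_chromosome`, `distance_bp` (`NA` for unlinked), `r2`, `n_used`.
#' @export
pairwise_r2 <- function(gm, scope = c("intra_chromosomal", "unlinked"),
                        max_pairs = 1e5, seed = 1L, min_n = 20L) {
  scope <- match.arg(scope)
  stopifnot(inherits(gm, "genotype_matrix"), n_variants(gm) >= 2)
  dos <- gm$dosages
  chrom <- gm$variants$chrom
  if (scope == "intra_chromosomal") {
    out <- lapply(unique(chrom), function(ch) {
      idx <- which(chrom == ch)
      if (length(idx) < 2) return(NULL)
      x <- dos[, idx, drop = FALSE]
      suppressWarnings(C <- stats::cor(x, use = "pairwise.complete.obs"))
      N <- crossprod(!is.na(x))
      ut <- which(upper.tri(C), arr.ind = TRUE)
      r2 <- C[ut]^2
      n_used <- N[ut]
      keep <- !is.na(r2) & n_used >= min_n
      pos <- gm$variants$pos[idx]
      data.frame(
        i = idx[ut[keep, 1]], j = idx[ut[keep, 2]],
        same_chromosome = TRUE,
        distance_bp = abs(pos[ut[keep, 2]] - pos[ut[keep, 1]]),
        r2 = r2[keep], n_used = n_used[keep]
      )
    })
    res <- do.call(rbind, out)
  } else {
    if (length(unique(chrom)) < 2) {
      stop("unlinked scope needs at least two chromosomes", call. = FALSE)
    }
    set.seed(child_seed(seed, "unlinked-pairs"))
    nv <- n_variants(gm)
    # rejection-sample cross-chromosome pairs
    total_cross <- (nv^2 - sum(table(chrom)^2)) / 2
    want <- as.integer(min(max_pairs, total_cross))
    a <- integer(0); b <- integer(0)
    while (length(a) < want) {
      k <- (want - length(a)) * 2L
      i <- sample.int(nv, k, replace = TRUE)
      j <- sample.int(nv, k, replace = TRUE)
      ok <- chrom[i] != chrom[j]
      ii <- pmin(i[ok], j[ok]); jj <- pmax(i[ok], j[ok])
      key <- paste(ii, jj)
      new <- !duplicated(key) & !(key %in% paste(a, b))
      a <- c(a, ii[new]); b <- c(b, jj[new])
    }
    a <- a[seq_len(want)]; b <- b[seq_len(want)]
    r2 <- numeric(want); n_used <- integer(want)
    for (k in seq_len(want)) {
      x <- dos[, a[k]]; y <- dos[, b[k]]
      cc <- !is.na(x) & !is.na(y)
      n_used[k] <- sum(cc)
      if (n_used[k] >= min_n && stats::var(x[cc]) > 0 && stats::var(y[cc]) > 0) {
        r2[k] <- stats::cor(x[cc], y[cc])^2
      } else {
        r2[k] <- NA_real_
      }
    }
    keep <- !is.na(r2)
    res <- data.frame(i = a[keep], j = b[keep], same_chromosome = FALSE,
                      distance_bp = NA_real_, r2 = r2[keep],
                      n_used = n_used[keep])
  }
  if (is.null(res)) res <- data.frame(i = integer(), j = integer(),
                                      same_chromosome = logical(),
                                      distance_bp = numeric(), r2 = numeric(),
                                      n_used = integer())
  rownames(res) <- NULL
  res
}

#' Critical r-squared from the unlinked distribution
#'
#' The critical value separating background association from real physical
#' linkage, taken from the distribution of r2 between markers on different
#' chromosomes. The parametric mode returns `mean + z(percentile) * sd`
#' (normal approximation of the upper tail); the empirical mode returns the
#' sample quantile.
#'
#' @param unlinked data.frame from [pairwise_r2()] with `scope = "unlinked"`,
#'   or a numeric vector of unlinked r2 values.
#' @param percentile upper-tail probability point (default 0.95).
#' @param mode `"parametric_normal"` or `"empirical"`.
#' @return the critical r2, with attribute `"mode"`.
#' @export
unlinked_critical_r2 <- function(unlinked, percentile = 0.95,
                                 mode = c("parametric_normal", "empirical")) {
  mode <- match.arg(mode)
  r2 <- if (is.data.frame(unlinked)) unlinked$r2 else as.numeric(unlinked)
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0) stop("no unlinked r2 values supplied", call. = FALSE)
  if (length(r2) < 100) {
    warning("fewer than 100 unlinked pairs; critical value is unstable",
            call. = FALSE)
  }
  val <- if (mode == "parametric_normal") {
    mean(r2) + stats::qnorm(percentile) * stats::sd(r2)
  } else {
    unname(stats::quantile(r2, percentile, type = 7))
  }
  if (length(r2) == 1 || stats::sd(r2) == 0) val <- r2[1]
  structure(val, mode = mode)
}

#' Fit the LD decay curve and locate the linkage range
#'
#' Second-degree local regression (LOESS) of intra-chromosomal r2 on
#' physical distance. The decay range is the smallest distance at which the
#' fitted curve first drops to or below the critical r2 (linear
#' interpolation between evaluation points); `NA` with `crossed = FALSE`
#' when the curve never crosses.
#'
#' @param intra data.frame from [pairwise_r2()] (intra-chromosomal scope).
#' @param critical_r2 threshold for real physical linkage.
#' @param loess_span LOESS span (default 0.3).
#' @param n_eval number of evaluation points of the fitted curve.
#' @param max_points above this pair count the pairs are aggregated into
#'   equal-count distance bins (mean distance, mean r2, count as weight)
#'   before fitting, keeping the LOESS cost bounded on dense panels.
#' @return object of class `ld_decay_fit`: list with `curve`
#'   (distance_bp, r2_fit), `critical_r2`, `decay_range_bp`, `crossed`.
#' @export
fit_ld_decay <- function(intra, critical_r2, loess_span = 0.3,
                         n_eval = 400L, max_points = 20000L) {
  d <- intra$distance_bp
  r2 <- intra$r2
  ok <- !is.na(d) & !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (length(unique(d)) < 2) {
    stop("LD decay fit needs pairs spanning more than one distance",
         call. = FALSE)
  }
  if (length(d) < 50) {
    warning("fewer than 50 intra-chromosomal pairs; decay fit is unstable",
            call. = FALSE)
  }
  n_pairs_in <- length(d)
  w <- rep(1, length(d))
  if (length(d) > max_points) {
    ord <- order(d)
    bins <- ceiling(seq_along(ord) / ceiling(length(ord) / 2000))
    d_binned <- tapply(d[ord], bins, mean)
    r2_binned <- tapply(r2[ord], bins, mean)
    w <- as.numeric(tapply(r2[ord], bins, length))
    d <- as.numeric(d_binned); r2 <- as.numeric(r2_binned)
  }
  fit <- stats::loess(r2 ~ d, degree = 2, span = loess_span, weights = w,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(d), max(d), length.out = n_eval)
  yhat <- stats::predict(fit, newdata = data.frame(d = grid))
  below <- which(yhat <= critical_r2)
  if (length(below) == 0) {
    cross <- NA_real_; crossed <- FALSE
  } else {
    k <- below[1]
    crossed <- TRUE
    if (k == 1) {
      cross <- grid[1]
    } else {
      # linear interpolation between the bracketing evaluation points
      x0 <- grid[k - 1]; x1 <- grid[k]
      y0 <- yhat[k - 1]; y1 <- yhat[k]
      cross <- x0 + (critical_r2 - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  structure(list(
    curve = data.frame(distance_bp = grid, r2_fit = yhat),
    critical_r2 = critical_r2,
    decay_range_bp = cross,
    crossed = crossed,
    span = loess_span,
    n_pairs = n_pairs_in
  ), class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit (LOESS degree 2, span %.2f) on %d pairs\n",
              x$span, x$n_pairs))
  if (x$crossed) {
    cat(sprintf("  fitted curve crosses r2 = %.3f at %.0f bp\n",
                x$critical_r2, x$decay_range_bp))
  } else {
    cat(sprintf("  fitted curve never drops to r2 = %.3f\n", x$critical_r2))
  }
  invisible(x)
}
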