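#' Single-locus mixed-model association scan
#'
#' Fits, for one quantitative trait (ordinal traits enter as integer
#' scores), the single-locus linear mixed model
#' `y = X beta + g + e`, `g ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`,
#' where `K = Z Z' / m` is the realized relationship matrix from
#' standardized dosages. The model is spectrally transformed: with
#' `K = U S U'` the rotated data have diagonal covariance
#' `sigma2_g (S + delta)`, `delta = sigma2_e / sigma2_g`. `delta` is
#' estimated once per trait by maximizing the REML profile likelihood over
#' `log delta` (grid search then local refinement), and each candidate SNP
#' is then tested by a Wald test in the rotated generalized least squares
#' fit with the SNP added to the fixed effects. One global `K` is used for
#' all SNPs (no leave-one-chromosome-out). Missing dosages are mean-imputed
#' per variant; samples with a missing trait value are dropped.
#'
#' Association statistics are 1-df Wald chi-squares; they are deflated by
#' the genomic-control inflation factor when `lambda > 1` and
#' Benjamini-Hochberg q-values are computed from the adjusted p-values.
#'
#' @param gm a [genotype_matrix()].
#' @param trait numeric vector (length = samples), `NA` allowed.
#' @param covariates a `covariate_set`, a plain numeric matrix, or `NULL`.
#' @param method `"lmm"` (default) or `"ols"` (covariate-only least squares).
#' @param trait_name label stored in the result.
#' @param delta optional fixed value of `sigma2_e / sigma2_g` overriding the
#'   REML estimate (mainly for testing limits).
#' @return object of class `gwas_result`: data.frame with `chrom`, `pos`,
#'   `id`, `beta`, `se`, `stat`, `p_raw`, `p_gc`, `q`; attributes
#'   `lambda_gc`, `delta`, `method`, `trait`.
#' @export
gwas_scan <- function(gm, trait, covariates = NULL,
                      method = c("lmm", "ols"), trait_name = "trait",
                      delta = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "genotype_matrix"))
  n_all <- n_samples(gm)
  if (length(trait) != n_all) {
    stop("trait length does not match the sample count", call. = FALSE)
  }
  C <- if (inherits(covariates, "covariate_set")) covariates$matrix
       else covariates
  keep <- !is.na(trait)
  y <- as.numeric(trait[keep])
  dos <- impute_dosages(gm$dosages)[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, sum(keep)),
             if (!is.null(C)) C[keep, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient covariates; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- length(y)
  p <- ncol(X)
  m <- ncol(dos)

  if (method == "lmm") {
    sds <- apply(dos, 2, stats::sd)
    Zs <- scale(dos[, sds > 0, drop = FALSE])
    K <- tcrossprod(Zs) / ncol(Zs)
    ee <- eigen(K, symmetric = TRUE)
    U <- ee$vectors
    S <- pmax(ee$values, 0)
    yr <- crossprod(U, y)
    Xr <- crossprod(U, X)
    if (is.null(delta)) delta <- reml_delta(yr, Xr, S)
    d <- S + delta
    Gr <- crossprod(U, dos)
  } else {
    d <- rep(1, n)
    yr <- y; Xr <- X; Gr <- dos
    delta <- NA_real_
  }

  w <- 1 / d
  sw <- sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  Gw <- Gr * sw
  # residualize trait and all SNPs on the fixed covariates under the
  # rotated weights (equivalent to including them in each per-SNP fit)
  XtXi <- solve(crossprod(Xw))
  Py <- yw - Xw %*% (XtXi %*% crossprod(Xw, yw))
  PG <- Gw - Xw %*% (XtXi %*% crossprod(Xw, Gw))
  gg <- colSums(PG^2)
  gy <- drop(crossprod(PG, Py))
  yy <- sum(Py^2)
  dof <- n - p - 1L
  beta <- ifelse(gg > 1e-12, gy / gg, NA_real_)
  rss <- yy - ifelse(gg > 1e-12, gy^2 / gg, 0)
  sigma2 <- rss / dof
  se <- ifelse(gg > 1e-12, sqrt(sigma2 / gg), NA_real_)
  stat <- ifelse(is.na(beta), 0, (beta / se)^2)
  p_raw <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)

  gc <- genomic_control(stat)
  q <- bh_fdr(gc$p_adj)

  res <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                    id = gm$variants$id, beta = beta, se = se, stat = stat,
                    p_raw = p_raw, p_gc = gc$p_adj, q = q,
                    stringsAsFactors = FALSE)
  attr(res, "lambda_gc") <- gc$lambda
  attr(res, "delta") <- delta
  attr(res, "method") <- method
  attr(res, "trait") <- trait_name
  class(res) <- c("gwas_result", "data.frame")
  res
}

# REML profile likelihood maximization over log(delta) in [-10, 10]
reml_delta <- function(yr, Xr, S, grid_n = 41L) {
  ll <- function(logd) reml_loglik(exp(logd), yr, Xr, S)
  grid <- seq(-10, 10, length.out = grid_n)
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  exp(opt$maximum)
}

reml_loglik <- function(delta, yr, Xr, S) {
  d <- S + delta
  n <- length(yr); p <- ncol(Xr)
  w <- 1 / d
  XtWX <- crossprod(Xr * sqrt(w))
  XtWy <- crossprod(Xr, yr * w)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 * w)
  sg2 <- rss / (n - p)
  ldetA <- 2 * sum(log(diag(R)))
  ldetX <- determinant(crossprod(Xr), logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi * sg2) + sum(log(d)) + ldetA - ldetX +
            (n - p))
}

#' @export
print.gwas_result <- function(x, n = 6L, ...) {
  cat(sprintf("gwas_result (%s, trait %s): %d variants, lambda_GC = %.3f\n",
              attr(x, "method"), attr(x, "trait"), nrow(x),
              attr(x, "lambda_gc")))
  cat(sprintf("  significant at FDR 0.05: %d\n", sum(x$q < 0.05)))
  if (nrow(x) > 0) {
    top <- as.data.frame(x)[order(x$p_gc)[seq_len(min(n, nrow(x)))],
                            c("id", "beta", "se", "p_gc", "q")]
    cat(sprintf("  top %d of %d variants by adjusted p:\n", nrow(top),
                nrow(x)))
    print(top, digits = 3)
  }
  invisible(x)
}

#' Genomic-control adjustment of 1-df chi-square statistics
#'
#' The inflation factor is the ratio of the observed median statistic to the
#' median of the chi-square(1) distribution. When `lambda > 1` the
#' statistics are deflated by `lambda` and p-values recomputed; otherwise
#' they pass through unchanged.
#'
#' @param statistics non-negative 1-df chi-square statistics.
#' @return list with `lambda`, `stat_adj`, `p_adj`.
#' @export
genomic_control <- function(statistics) {
  if (length(statistics) == 0) stop("no statistics supplied", call. = FALSE)
  if (any(statistics < 0, na.rm = TRUE)) {
    stop("chi-square statistics must be non-negative", call. = FALSE)
  }
  lambda <- stats::median(statistics, na.rm = TRUE) / stats::qchisq(0.5, 1)
  stat_adj <- if (lambda > 1) statistics / lambda else statistics
  p_adj <- stats::pchisq(stat_adj, df = 1, lower.tail = FALSE)
  p_adj <- pmin(pmax(p_adj, .Machine$double.xmin), 1)
  list(lambda = lambda, stat_adj = stat_adj, p_adj = p_adj)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1
#' and mapped back to input order (delegates to [stats::p.adjust()], which
#' implements exactly this).
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Write a GWAS result as a tab-separated table
#' @param gwas a `gwas_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
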