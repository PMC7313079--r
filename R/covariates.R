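#' Genotype principal components as structure covariates
#'
#' Dosages are mean-imputed per variant, centered and scaled to unit
#' variance, and the top axes of the sample covariance are returned as the
#' usual population-structure covariates for association testing.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (default 8).
#' @return object of class `covariate_set`: list with `matrix` (samples x k,
#'   centered scores), `source`, `variance_explained` (all-axis fractions).
#' @export
genotype_pca <- function(gm, k = 8L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k >= min(n_samples(gm), n_variants(gm))) {
    stop("k must be smaller than both sample and variant counts", call. = FALSE)
  }
  dos <- impute_dosages(gm$dosages)
  sds <- apply(dos, 2, stats::sd)
  poly <- sds > 0
  if (!any(poly)) stop("all variants are monomorphic; PCA undefined",
                       call. = FALSE)
  Z <- scale(dos[, poly, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- scale(scores, center = TRUE, scale = FALSE)
  rownames(scores) <- gm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(matrix = scores, source = "genotype_pca",
                 variance_explained = ve),
            class = "covariate_set")
}

#' Geographic principal coordinates as covariates
#'
#' Classical metric scaling (double-centering and eigendecomposition) of the
#' great-circle (haversine) distance matrix between collection sites.
#' Axes with non-positive eigenvalues are discarded and reported.
#'
#' @param coords data.frame with columns `lat` and `lon` (decimal degrees).
#' @param k number of axes to keep (default 2).
#' @return a `covariate_set` with `variance_explained` computed over the
#'   positive eigenvalues and attribute `n_negative_eigenvalues`.
#' @export
geographic_pcoa <- function(coords, k = 2L) {
  stopifnot(all(c("lat", "lon") %in% names(coords)))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    stop("coordinates out of lat/lon range", call. = FALSE)
  }
  D <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = geosphere::distHaversine)
  if (all(D == 0)) stop("all coordinates identical: distance matrix is zero",
                        call. = FALSE)
  mds <- stats::cmdscale(D, k = min(k, nrow(D) - 1L), eig = TRUE)
  eig <- mds$eig
  pos <- eig > 1e-8 * max(eig)
  keep <- seq_len(min(k, sum(pos[seq_len(ncol(mds$points))])))
  scores <- mds$points[, keep, drop = FALSE]
  scores <- scale(scores, center = TRUE, scale = FALSE)
  rownames(scores) <- coords$sample %||% rownames(coords)
  colnames(scores) <- paste0("PCo", keep)
  structure(list(matrix = scores, source = "geographic_pcoa",
                 variance_explained = pmax(eig, 0) / sum(pmax(eig, 0)),
                 eigenvalues = eig),
            class = "covariate_set")
}

#' Merge covariate sets column-wise
#' @param ... `covariate_set` objects over the same samples.
#' @return a merged `covariate_set` with `source = "merged"`.
#' @export
merge_covariates <- function(...) {
  sets <- list(...)
  mats <- lapply(sets, function(s) s$matrix)
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("covariate sets differ in sample count",
                           call. = FALSE)
  structure(list(matrix = do.call(cbind, mats), source = "merged",
                 variance_explained = NULL),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf("covariate_set (%s): %d samples x %d axes\n", x$source,
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$variance_explained)) {
    k <- ncol(x$matrix)
    cat(sprintf("  variance explained by kept axes: %.1f%%\n",
                100 * sum(x$variance_explained[seq_len(k)])))
  }
  invisible(x)
}
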