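#' Sorensen-Dice similarity of two enriched-block sets
#'
#' `2 |a intersect b| / (|a| + |b|)`; the sum of blocks enriched for both
#' traits, doubly counted, normalized by the total enriched blocks of the
#' two traits. Two empty sets score 0 by convention.
#'
#' @param set_a,set_b character vectors of block ids.
#' @return a score in `[0, 1]`.
#' @export
dice_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  tot <- length(set_a) + length(set_b)
  if (tot == 0) return(0)
  2 * length(intersect(set_a, set_b)) / tot
}

#' Trait-by-trait similarity matrix of enriched haploblock sets
#'
#' @param sets named list mapping traits to enriched block id sets (as from
#'   [enriched_sets_by_trait()]).
#' @return object of class `similarity_matrix`: list with `matrix`
#'   (symmetric, unit diagonal for traits with at least one enriched block,
#'   0 diagonal flag for empty-set traits) and `empty_traits`.
#' @export
similarity_matrix <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2)
  traits <- names(sets)
  k <- length(traits)
  M <- matrix(0, k, k, dimnames = list(traits, traits))
  for (a in seq_len(k)) {
    for (b in a:k) {
      M[a, b] <- M[b, a] <- dice_similarity(sets[[a]], sets[[b]])
    }
  }
  structure(list(matrix = M,
                 empty_traits = traits[lengths(sets) == 0]),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d traits (%d with no enriched blocks)\n",
              nrow(x$matrix), length(x$empty_traits)))
  invisible(x)
}

#' Bi-cluster traits by shared enriched haploblocks
#'
#' Agglomerative hierarchical clustering (average linkage) on the
#' dissimilarity `1 - score`; since rows and columns index the same traits,
#' a single clustering supplies both orderings of the heatmap. The leaf
#' order is made deterministic by tie-breaking on trait label.
#'
#' @param sim a [similarity_matrix()] (or a symmetric numeric matrix).
#' @param height_cut optional dendrogram height at which to cut flat groups
#'   (default 0.5 on the dissimilarity scale).
#' @return list of class `trait_biclust`: `hclust` object, `order` (leaf
#'   ordering), `groups` (named integer vector of flat cluster labels) and
#'   the reordered similarity matrix.
#' @export
bicluster <- function(sim, height_cut = 0.5) {
  M <- if (inherits(sim, "similarity_matrix")) sim$matrix else as.matrix(sim)
  if (!isSymmetric(unname(M), tol = 1e-12)) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  # stable label order so that equal-height merges are reproducible
  M <- M[order(rownames(M)), order(colnames(M))]
  D <- stats::as.dist(1 - M)
  hc <- stats::hclust(D, method = "average")
  groups <- stats::cutree(hc, h = height_cut)
  structure(list(hclust = hc, order = hc$labels[hc$order],
                 groups = groups,
                 matrix = M[hc$order, hc$order]),
            class = "trait_biclust")
}

#' @export
print.trait_biclust <- function(x, ...) {
  cat(sprintf("trait_biclust: %d traits in %d flat group(s)\n",
              length(x$groups), length(unique(x$groups))))
  invisible(x)
}

#' Export a similarity matrix and dendrogram
#'
#' Writes the matrix as TSV, a long-format `(trait_a, trait_b, score)` table
#' for heatmap plotting, and the dendrogram in Newick format.
#'
#' @param sim a `similarity_matrix`.
#' @param bic a `trait_biclust` (for the dendrogram; optional).
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_similarity <- function(sim, bic = NULL, prefix) {
  paths <- character(0)
  p1 <- paste0(prefix, "_matrix.tsv")
  utils::write.table(sim$matrix, p1, sep = "\t", quote = FALSE,
                     col.names = NA)
  paths <- c(paths, p1)
  M <- sim$matrix
  long <- data.frame(trait_a = rownames(M)[row(M)],
                     trait_b = colnames(M)[col(M)],
                     score = as.vector(M))
  p2 <- paste0(prefix, "_long.tsv")
  utils::write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p2)
  if (!is.null(bic)) {
    p3 <- paste0(prefix, "_dendrogram.nwk")
    phy <- hclust_to_newick(bic$hclust)
    writeLines(phy, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

# minimal hclust -> Newick conversion (labels assumed Newick-safe)
hclust_to_newick <- function(hc) {
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    left <- build(hc$merge[i, 1])
    right <- build(hc$merge[i, 2])
    hl <- if (hc$merge[i, 1] < 0) hc$height[i] else
      hc$height[i] - hc$height[hc$merge[i, 1]]
    hr <- if (hc$merge[i, 2] < 0) hc$height[i] else
      hc$height[i] - hc$height[hc$merge[i, 2]]
    sprintf("(%s:%g,%s:%g)", left, hl, right, hr)
  }
  paste0(build(nrow(hc$merge)), ";")
}
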