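#' Partition chromosomes into haploblocks from |D'| confidence intervals
#'
#' Implements the confidence-interval block definition: a candidate block is
#' a contiguous run of markers whose outermost pair is in strong LD and in
#' which at least `informative_fraction` of the informative pairs (strong-LD
#' or recombination; uninformative pairs are ignored) are strong LD.
#' Candidates are accepted greedily by descending marker count (ties: longer
#' physical span, then leftmost start), discarding any candidate that
#' overlaps an accepted block. Haploview's separate rules for 2-4 marker
#' blocks are collapsed into the single fraction rule. Block search is
#' limited to `max_block_span_bp` to bound the pairwise evaluation.
#'
#' @param gm a [genotype_matrix()].
#' @param max_block_span_bp maximum physical span of a block (default 500 kb,
#'   the usual search window).
#' @param informative_fraction minimum fraction of informative pairs in
#'   strong LD (default 0.95).
#' @param grid_step,ci_mass,min_n passed to the |D'| CI computation.
#' @param maf_floor optional per-pair minor-allele-frequency floor applied
#'   before classification (0 = off; Haploview's own default would be 0.05).
#' @return object of class `haploblock_set`: list with `blocks` (data.frame
#'   `block_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`) and `members`
#'   (named list of global variant index vectors, contiguous in the
#'   chromosome's marker order).
#' @export
partition_haploblocks <- function(gm, max_block_span_bp = 5e5,
                                  informative_fraction = 0.95,
                                  grid_step = 0.001, ci_mass = 0.90,
                                  min_n = 20L, maf_floor = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  st <- variant_stats(gm)
  blocks <- list(); members <- list()
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    m <- length(idx)
    if (m < 2) next
    pos <- gm$variants$pos[idx]
    dos <- gm$dosages[, idx, drop = FALSE]

    # classify pairs within the span window: 1 strong, -1 recombination,
    # 0 uninformative
    cls <- matrix(0L, m, m)
    for (a in seq_len(m - 1)) {
      jmax <- a
      while (jmax < m && pos[jmax + 1] - pos[a] <= max_block_span_bp) {
        jmax <- jmax + 1
      }
      if (jmax == a) next
      for (b in (a + 1):jmax) {
        if (maf_floor > 0 &&
            (is.na(st$maf[idx[a]]) || is.na(st$maf[idx[b]]) ||
             st$maf[idx[a]] < maf_floor || st$maf[idx[b]] < maf_floor)) next
        ci <- dprime_ci_counts(pair_counts(dos[, a], dos[, b]),
                               grid_step = grid_step, ci_mass = ci_mass,
                               min_n = min_n, strict = FALSE)
        cls[a, b] <- switch(ci$class, strong_ld = 1L, recombination = -1L, 0L)
      }
    }

    # candidate runs [a, b]: outermost pair strong, informative fraction met
    SC <- apply(cls == 1L, 2, cumsum)    # column-wise cumulative strong
    IC <- apply(cls != 0L, 2, cumsum)    # column-wise cumulative informative
    cand <- list()
    for (a in seq_len(m - 1)) {
      n_str <- 0; n_inf <- 0
      b <- a
      repeat {
        b <- b + 1
        if (b > m || pos[b] - pos[a] > max_block_span_bp) break
        # pairs (k, b) for k in a..(b-1)
        add_str <- SC[b - 1, b] - if (a > 1) SC[a - 1, b] else 0
        add_inf <- IC[b - 1, b] - if (a > 1) IC[a - 1, b] else 0
        n_str <- n_str + add_str
        n_inf <- n_inf + add_inf
        if (cls[a, b] == 1L && n_inf > 0 &&
            n_str / n_inf >= informative_fraction) {
          cand[[length(cand) + 1L]] <- c(a = a, b = b,
                                         size = b - a + 1L,
                                         span = pos[b] - pos[a])
        }
      }
    }
    if (!length(cand)) next
    cd <- do.call(rbind, cand)
    cd <- cd[order(-cd[, "size"], -cd[, "span"], cd[, "a"]), , drop = FALSE]
    taken <- rep(FALSE, m)
    acc <- list()
    for (r in seq_len(nrow(cd))) {
      a <- cd[r, "a"]; b <- cd[r, "b"]
      if (!any(taken[a:b])) {
        taken[a:b] <- TRUE
        acc[[length(acc) + 1L]] <- c(a, b)
      }
    }
    acc <- acc[order(vapply(acc, `[`, numeric(1), 1))]
    for (k in seq_along(acc)) {
      a <- acc[[k]][1]; b <- acc[[k]][2]
      bid <- sprintf("%s_B%d", ch, k)
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom = ch, start_bp = pos[a], end_bp = pos[b],
        n_snps = b - a + 1L, stringsAsFactors = FALSE
      )
      members[[bid]] <- idx[a:b]
    }
  }
  tab <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(), n_snps = integer())
  rownames(tab) <- NULL
  structure(list(blocks = tab, members = members), class = "haploblock_set")
}

#' @export
print.haploblock_set <- function(x, ...) {
  cat(sprintf("haploblock_set: %d block(s), %d SNPs total\n",
              nrow(x$blocks), sum(x$blocks$n_snps)))
  if (nrow(x$blocks)) {
    cat(sprintf("  mean SNPs per block: %.1f\n", mean(x$blocks$n_snps)))
  }
  invisible(x)
}

#' Build a haploblock set from explicit member lists
#'
#' Useful for analyzing designated (e.g. planted) blocks without running
#' the partitioner.
#'
#' @param gm a [genotype_matrix()].
#' @param members named list of global variant index vectors.
#' @return a `haploblock_set`.
#' @export
haploblock_set <- function(gm, members) {
  stopifnot(is.list(members), !is.null(names(members)))
  tab <- do.call(rbind, lapply(names(members), function(bid) {
    idx <- members[[bid]]
    data.frame(block_id = bid, chrom = gm$variants$chrom[idx[1]],
               start_bp = min(gm$variants$pos[idx]),
               end_bp = max(gm$variants$pos[idx]),
               n_snps = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(blocks = tab, members = members), class = "haploblock_set")
}

#' Write haploblocks as text (one block per line) or BED
#'
#' The text format lists chromosome, 1-based closed interval and marker
#' indices; BED output converts to 0-based half-open intervals.
#'
#' @param hb a `haploblock_set`.
#' @param path output path.
#' @param format `"text"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(hb, path, format = c("text", "bed")) {
  format <- match.arg(format)
  b <- hb$blocks
  if (format == "text") {
    lines <- vapply(seq_len(nrow(b)), function(k) {
      paste(b$chrom[k], b$start_bp[k], b$end_bp[k],
            paste(hb$members[[b$block_id[k]]], collapse = ","),
            sep = "\t")
    }, character(1))
  } else {
    lines <- vapply(seq_len(nrow(b)), function(k) {
      paste(b$chrom[k], b$start_bp[k] - 1L, b$end_bp[k], b$block_id[k],
            sep = "\t")
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}
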