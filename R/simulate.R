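#' Simulation configuration for a synthetic landrace panel
#'
#' Describes the panel the generator produces: a largely homozygous
#' (selfing) accession collection scored on biallelic SNPs spread over
#' several chromosomes with uneven marker density, with designated
#' founder-haplotype blocks (regions of strong LD), geographic group
#' structure and uniform missingness.
#'
#' Within each planted block every gamete carries one of a small pool of
#' founder haplotypes, so markers inside a block are in strong mutual LD;
#' between blocks (and for background markers) gametes recombine freely.
#' Group structure enters through group-specific founder-haplotype and
#' background allele frequencies (Balding-Nichols style differentiation).
#'
#' @param n_samples number of accessions.
#' @param chromosomes data.frame with columns `name`, `length_bp`, `n_snps`.
#'   The default emulates an eight-chromosome panel of 2579 SNPs with
#'   strongly uneven density (from 91 markers on the shortest chromosome to
#'   792 on the densest one).
#' @param blocks data.frame of planted blocks with columns `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_founders`. Blocks must not overlap
#'   within a chromosome. `NULL` plants the default 40 blocks (five per
#'   chromosome, 10 SNPs each, 4 founder haplotypes).
#' @param selfing_inbreeding probability that an accession is fully
#'   homozygous (its two gametes are copies). Default 0.95, typical of a
#'   predominantly self-fertilizing crop.
#' @param missing_rate per-cell probability of a missing genotype.
#' @param n_groups number of geographic groups (default 6).
#' @param group_fst differentiation of allele/founder frequencies between
#'   groups (Balding-Nichols F, default 0.15).
#' @param seed integer seed; all generator stages derive child seeds from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 400,
                       chromosomes = default_chromosomes(),
                       blocks = NULL,
                       selfing_inbreeding = 0.95,
                       missing_rate = 0.03,
                       n_groups = 6,
                       group_fst = 0.15,
                       seed = 1L) {
  assert_fraction(selfing_inbreeding, "selfing_inbreeding")
  assert_fraction(missing_rate, "missing_rate")
  assert_fraction(group_fst, "group_fst")
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "length_bp", "n_snps") %in% names(chromosomes)),
            all(chromosomes$n_snps >= 1), n_samples >= 2, n_groups >= 1)
  if (is.null(blocks)) blocks <- default_blocks(chromosomes)
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("chrom", "start_bp", "end_bp", "n_snps", "n_founders") %in%
                  names(blocks)))
  # planted blocks must not overlap within a chromosome
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    b <- b[order(b$start_bp), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start_bp[-1] <= b$end_bp[-nrow(b)])) {
      stop(sprintf("planted blocks overlap on chromosome %s", ch),
           call. = FALSE)
    }
    if (!ch %in% chromosomes$name) {
      stop(sprintf("block chromosome %s not in chromosome table", ch),
           call. = FALSE)
    }
  }
  if (any(blocks$n_founders > 2^blocks$n_snps)) {
    stop("a block requests more founder haplotypes than 2^n_snps distinct ones",
         call. = FALSE)
  }
  per_chr_block_snps <- tapply(blocks$n_snps, blocks$chrom, sum)
  for (ch in names(per_chr_block_snps)) {
    tot <- chromosomes$n_snps[chromosomes$name == ch]
    if (per_chr_block_snps[[ch]] > tot) {
      stop(sprintf("planted blocks on %s exceed the chromosome's SNP count", ch),
           call. = FALSE)
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), chromosomes = chromosomes,
    blocks = blocks, selfing_inbreeding = selfing_inbreeding,
    missing_rate = missing_rate, n_groups = as.integer(n_groups),
    group_fst = group_fst, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default chromosome table (uneven SNP density over eight chromosomes)
#' @return data.frame with `name`, `length_bp`, `n_snps` (2579 SNPs total).
#' @export
default_chromosomes <- function() {
  data.frame(
    name = paste0("Ca", 1:8),
    length_bp = c(48.36e6, 36.63e6, 39.99e6, 49.19e6,
                  48.17e6, 59.46e6, 48.96e6, 16.48e6),
    n_snps = c(300L, 280L, 320L, 792L, 270L, 316L, 210L, 91L),
    stringsAsFactors = FALSE
  )
}

#' Default planted blocks: five per chromosome, 10 SNPs, 4 founders
#' @param chromosomes chromosome table as in [sim_config()].
#' @param per_chrom number of blocks per chromosome.
#' @param n_snps SNPs per block.
#' @param n_founders founder haplotypes per block.
#' @param span_bp physical span of each block.
#' @return data.frame of blocks.
#' @export
default_blocks <- function(chromosomes, per_chrom = 5L, n_snps = 10L,
                           n_founders = 4L, span_bp = 4e5) {
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    len <- chromosomes$length_bp[i]
    starts <- round(seq(0.08, 0.88, length.out = per_chrom) * len)
    data.frame(chrom = chromosomes$name[i], start_bp = starts,
               end_bp = starts + span_bp, n_snps = n_snps,
               n_founders = n_founders, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# distinct random founder haplotypes (n_f x m 0/1 matrix), each column
# polymorphic across founders where n_f >= 2
draw_founders <- function(n_f, m) {
  if (n_f == 1L) return(matrix(rbinom(m, 1, 0.5), nrow = 1L))
  for (attempt in 1:50) {
    H <- matrix(rbinom(n_f * m, 1, 0.5), nrow = n_f)
    # force every site polymorphic among founders
    const <- which(apply(H, 2, function(x) all(x == x[1])))
    for (j in const) H[sample.int(n_f, 1L), j] <- 1L - H[1L, j]
    if (!anyDuplicated(apply(H, 1, paste, collapse = ""))) return(H)
  }
  stop("could not draw distinct founder haplotypes", call. = FALSE)
}

# Dirichlet draw via gamma
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Simulate genotypes with planted founder-haplotype blocks
#'
#' Each accession is built from two gametes. A gamete carries, for every
#' planted block, one founder haplotype drawn with group-specific
#' frequencies, and an independent allele at every background SNP with
#' group-specific frequency. With probability `selfing_inbreeding` the
#' second gamete is a copy of the first, producing a fully homozygous
#' accession; dosage is the sum of the two gametes. Missing genotypes are
#' masked uniformly at random.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (planted block boundaries and member indices, per-sample
#'   group labels, founder pools).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "simulate-genotypes"))
  n <- config$n_samples
  ng <- config$n_groups
  # contiguous group blocks, sizes within 1 of equal
  groups <- paste0("G", sort(rep_len(seq_len(ng), n)))
  fst <- max(config$group_fst, 1e-6)
  conc <- (1 - fst) / fst

  dos_chunks <- list()
  var_chunks <- list()
  truth_blocks <- list()
  col_offset <- 0L

  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes$name[i]
    len <- config$chromosomes$length_bp[i]
    m_total <- config$chromosomes$n_snps[i]
    cb <- config$blocks[config$blocks$chrom == ch, , drop = FALSE]
    cb <- cb[order(cb$start_bp), , drop = FALSE]
    m_block <- if (nrow(cb)) sum(cb$n_snps) else 0L
    m_bg <- m_total - m_block

    # background positions avoid planted block intervals so inferred block
    # membership can be compared against ground truth exactly
    pos_bg <- integer(0)
    if (m_bg > 0) {
      repeat {
        cand <- sort(sample.int(len, m_bg * 2L))
        if (nrow(cb)) {
          inside <- rep(FALSE, length(cand))
          for (b in seq_len(nrow(cb))) {
            inside <- inside | (cand >= cb$start_bp[b] & cand <= cb$end_bp[b])
          }
          cand <- cand[!inside]
        }
        cand <- unique(cand)
        if (length(cand) >= m_bg) { pos_bg <- sort(sample(cand, m_bg)); break }
      }
    }

    # per-block founder pools and positions
    gam1 <- matrix(0L, n, 0L); gam2 <- matrix(0L, n, 0L)
    pos_all <- integer(0)
    planted <- rep(NA_character_, 0L)

    selfed <- rbinom(n, 1, config$selfing_inbreeding) == 1L

    blocks_here <- list()
    if (nrow(cb)) {
      for (b in seq_len(nrow(cb))) {
        m <- cb$n_snps[b]
        pos_b <- round(seq(cb$start_bp[b], cb$end_bp[b], length.out = m))
        pos_b <- pos_b + seq_len(m) - 1L  # break accidental ties
        H <- draw_founders(cb$n_founders[b], m)
        w <- rdirichlet1(rep(1.5, cb$n_founders[b]))
        freq_g <- do.call(rbind, lapply(seq_len(ng),
                                        function(g) rdirichlet1(w * conc)))
        g_idx <- match(groups, paste0("G", seq_len(ng)))
        pick <- function() {
          idx <- integer(n)
          for (g in seq_len(ng)) {
            sel <- g_idx == g
            if (any(sel)) {
              idx[sel] <- sample.int(cb$n_founders[b], sum(sel), replace = TRUE,
                                     prob = freq_g[g, ])
            }
          }
          idx
        }
        i1 <- pick(); i2 <- pick()
        gb1 <- H[i1, , drop = FALSE]
        gb2 <- H[i2, , drop = FALSE]
        gb2[selfed, ] <- gb1[selfed, ]
        gam1 <- cbind(gam1, gb1); gam2 <- cbind(gam2, gb2)
        pos_all <- c(pos_all, pos_b)
        bid <- sprintf("%s_B%d", ch, b)
        planted <- c(planted, rep(bid, m))
        blocks_here[[bid]] <- list(
          block_id = bid, chrom = ch,
          start_bp = min(pos_b), end_bp = max(pos_b),
          n_founders = cb$n_founders[b], founders = H, positions = pos_b
        )
      }
    }
    if (m_bg > 0) {
      p0 <- runif(m_bg, 0.08, 0.92)
      pg <- matrix(0, ng, m_bg)
      for (g in seq_len(ng)) {
        pg[g, ] <- rbeta(m_bg, p0 * conc, (1 - p0) * conc)
      }
      g_idx <- match(groups, paste0("G", seq_len(ng)))
      pmat <- pg[g_idx, , drop = FALSE]
      gb1 <- matrix(rbinom(n * m_bg, 1, pmat), n, m_bg)
      gb2 <- matrix(rbinom(n * m_bg, 1, pmat), n, m_bg)
      gb2[selfed, ] <- gb1[selfed, ]
      gam1 <- cbind(gam1, gb1); gam2 <- cbind(gam2, gb2)
      pos_all <- c(pos_all, pos_bg)
      planted <- c(planted, rep(NA_character_, m_bg))
    }

    ord <- order(pos_all)
    # guard against residual position ties
    pos_sorted <- pos_all[ord]
    dup <- duplicated(pos_sorted)
    while (any(dup)) { pos_sorted[dup] <- pos_sorted[dup] + 1L
                       o2 <- order(pos_sorted); pos_sorted <- pos_sorted[o2]
                       ord <- ord[o2]; dup <- duplicated(pos_sorted) }
    dos <- (gam1 + gam2)[, ord, drop = FALSE]
    ra <- t(vapply(seq_along(pos_sorted), function(k) sample(bases, 2L),
                   character(2)))
    var_chunks[[ch]] <- data.frame(
      chrom = ch, pos = pos_sorted, ref = ra[, 1], alt = ra[, 2],
      stringsAsFactors = FALSE
    )
    dos_chunks[[ch]] <- dos

    pl_sorted <- planted[ord]
    for (bid in names(blocks_here)) {
      blocks_here[[bid]]$member_idx <- col_offset + which(pl_sorted == bid)
    }
    truth_blocks <- c(truth_blocks, blocks_here)
    col_offset <- col_offset + m_total
  }

  dosages <- do.call(cbind, dos_chunks)
  variants <- do.call(rbind, var_chunks)
  rownames(variants) <- NULL
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(dosages)) < config$missing_rate,
                   nrow(dosages), ncol(dosages))
    dosages[mask] <- NA
  }
  gm <- genotype_matrix(dosages, variants)

  block_table <- do.call(rbind, lapply(truth_blocks, function(b) {
    data.frame(block_id = b$block_id, chrom = b$chrom, start_bp = b$start_bp,
               end_bp = b$end_bp, n_snps = length(b$member_idx),
               n_founders = b$n_founders, stringsAsFactors = FALSE)
  }))
  rownames(block_table) <- NULL
  names(groups) <- gm$sample_ids
  truth <- list(
    blocks = block_table,
    block_members = lapply(truth_blocks, function(b) b$member_idx),
    groups = groups,
    founders = lapply(truth_blocks, function(b) b$founders)
  )
  list(genotypes = gm, truth = truth)
}

#' Specify a simulated trait
#'
#' A trait is the sum of a causal component (planted-block SNPs with fixed
#' per-SNP effects), a polygenic background (many small random effects) and
#' Gaussian noise, with each component rescaled to its configured share of
#' the total variance: the causal component contributes
#' `heritability * (1 - polygenic_share)`, the polygenic component
#' `heritability * polygenic_share`, and noise `1 - heritability`.
#'
#' @param name trait label.
#' @param causal_blocks character vector of planted block ids whose member
#'   SNPs are causal (resolved against the generator's ground truth), or
#'   `NULL` for a trait with no localized signal.
#' @param causal_snps integer variant indices used directly instead of
#'   block ids (optional).
#' @param effects per-SNP effect sizes, recycled over the causal SNPs.
#' @param heritability total genetic variance fraction in `[0, 1]`.
#' @param polygenic_share fraction of the genetic variance from background
#'   SNPs rather than the causal set.
#' @param type `"quantitative"` or `"ordinal"`.
#' @param n_levels number of ordinal categories (equal-probability bins on
#'   the latent scale).
#' @return a list of class `trait_spec`.
#' @export
trait_spec <- function(name, causal_blocks = NULL, causal_snps = NULL,
                       effects = 1, heritability = 0.5,
                       polygenic_share = 0.2,
                       type = c("quantitative", "ordinal"), n_levels = 5L) {
  assert_fraction(heritability, "heritability")
  assert_fraction(polygenic_share, "polygenic_share")
  type <- match.arg(type)
  structure(list(name = name, causal_blocks = causal_blocks,
                 causal_snps = causal_snps, effects = effects,
                 heritability = heritability,
                 polygenic_share = polygenic_share, type = type,
                 n_levels = as.integer(n_levels)),
            class = "trait_spec")
}

#' Simulate traits over a genotype panel
#'
#' @param gm a [genotype_matrix()].
#' @param specs list of [trait_spec()] objects.
#' @param truth generator ground truth (needed when specs reference planted
#'   block ids).
#' @param n_polygenic number of background SNPs in the polygenic term.
#' @param seed integer seed.
#' @return data.frame of traits (samples in rows) with attribute
#'   `"ground_truth"`: per-trait causal indices and realized variance
#'   components.
#' @export
simulate_traits <- function(gm, specs, truth = NULL, n_polygenic = 200L,
                            seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  if (any(colSums(!is.na(gm$dosages)) == 0)) {
    stop("genotype matrix has all-missing variants", call. = FALSE)
  }
  set.seed(child_seed(seed, "simulate-traits"))
  n <- n_samples(gm)
  dos <- impute_dosages(gm$dosages)
  out <- matrix(NA_real_, n, length(specs))
  info <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    idx <- sp$causal_snps
    if (!is.null(sp$causal_blocks)) {
      if (is.null(truth)) stop("`truth` required to resolve causal blocks",
                               call. = FALSE)
      idx <- c(idx, unlist(truth$block_members[sp$causal_blocks],
                           use.names = FALSE))
    }
    idx <- unique(as.integer(idx))
    if (any(idx < 1 | idx > n_variants(gm))) {
      stop("causal SNP index outside the genotype matrix", call. = FALSE)
    }
    v_causal <- sp$heritability * (1 - sp$polygenic_share)
    v_poly <- sp$heritability * sp$polygenic_share
    v_noise <- 1 - sp$heritability
    if (v_causal > 0 && length(idx) == 0) {
      stop(sprintf("trait %s: positive causal variance but no causal SNPs",
                   sp$name), call. = FALSE)
    }
    g_causal <- rep(0, n)
    if (length(idx)) {
      beta <- rep_len(sp$effects, length(idx))
      g_causal <- drop(dos[, idx, drop = FALSE] %*% beta)
      g_causal <- scale_to_var(g_causal, v_causal)
    }
    g_poly <- rep(0, n)
    if (v_poly > 0) {
      bg <- setdiff(seq_len(n_variants(gm)), idx)
      bg <- sample(bg, min(n_polygenic, length(bg)))
      g_poly <- drop(dos[, bg, drop = FALSE] %*% rnorm(length(bg)))
      g_poly <- scale_to_var(g_poly, v_poly)
    }
    eps <- scale_to_var(rnorm(n), v_noise)
    y <- g_causal + g_poly + eps
    if (sp$type == "ordinal") {
      br <- quantile(y, probs = seq(0, 1, length.out = sp$n_levels + 1L))
      br[1] <- -Inf; br[length(br)] <- Inf
      y <- as.integer(cut(y, breaks = br, labels = FALSE,
                          include.lowest = TRUE))
    }
    out[, k] <- y
    info[[k]] <- list(name = sp$name, causal_snps = idx,
                      components = c(causal = v_causal, polygenic = v_poly,
                                     noise = v_noise))
  }
  traits <- as.data.frame(out)
  names(traits) <- vapply(specs, function(s) s$name, character(1))
  rownames(traits) <- gm$sample_ids
  attr(traits, "ground_truth") <- info
  traits
}

# center a component and rescale to an exact sample variance
scale_to_var <- function(x, v) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) {
    if (v > 0) stop("component has zero variance but a positive target",
                    call. = FALSE)
    return(x)
  }
  x * sqrt(v) / s
}

#' Simulate collection-site geography and bioclimatic covariates
#'
#' Accessions of the same geographic group receive jittered coordinates
#' around a group centroid. Bioclimatic variables are organized into
#' correlation blocks: variables in a block share a group-level mean shift
#' and a per-sample latent factor, giving high mutual (Spearman)
#' correlation within a block and near-zero correlation across blocks.
#'
#' @param truth generator ground truth carrying per-sample group labels.
#' @param n_bioclim number of bioclimatic variables (default 19).
#' @param correlation_blocks list of integer vectors partitioning
#'   `1:n_bioclim` (default: five blocks of sizes 4,4,4,4,3).
#' @param within_cor target within-block correlation of the latent factors.
#' @param jitter_deg s.d. (degrees) of coordinate jitter around centroids.
#' @param group_sd s.d. of group-level mean shifts of bioclim variables.
#' @param seed integer seed.
#' @return list with `coords` (sample, lat, lon, group) and `bioclim`
#'   (samples x variables data.frame, `BIO1..BIOk`).
#' @export
simulate_geography_bioclim <- function(truth, n_bioclim = 19L,
                                       correlation_blocks = NULL,
                                       within_cor = 0.9, jitter_deg = 1.5,
                                       group_sd = 1, seed = 1L) {
  groups <- truth$groups
  glev <- unique(groups)
  ng <- length(glev)
  if (ng < 2) stop("group-structured geography needs at least 2 groups",
                   call. = FALSE)
  assert_fraction(within_cor, "within_cor")
  set.seed(child_seed(seed, "simulate-geography"))
  n <- length(groups)
  if (is.null(correlation_blocks)) {
    sizes <- rep(floor(n_bioclim / 5), 5)
    sizes[seq_len(n_bioclim - sum(sizes))] <- sizes[seq_len(n_bioclim - sum(sizes))] + 1L
    correlation_blocks <- split(seq_len(n_bioclim), rep(seq_along(sizes), sizes))
  }
  stopifnot(setequal(unlist(correlation_blocks), seq_len(n_bioclim)))

  # six fixed centroids in historic cultivation centers; random otherwise
  fixed <- matrix(c(39.0, 35.0,   # Anatolia
                    22.0, 79.0,   # India
                    9.0, 39.0,    # Ethiopian highlands
                    32.0, -6.0,   # Morocco
                    34.0, 36.0,   # Levant
                    41.0, 64.0),  # Central Asia
                  ncol = 2, byrow = TRUE)
  if (ng <= 6) {
    cent <- fixed[seq_len(ng), , drop = FALSE]
  } else {
    cent <- cbind(runif(ng, -35, 55), runif(ng, -15, 90))
  }
  gi <- match(groups, glev)
  lat <- cent[gi, 1] + rnorm(n, 0, jitter_deg)
  lon <- cent[gi, 2] + rnorm(n, 0, jitter_deg)
  coords <- data.frame(sample = names(groups) %||% paste0("S", seq_len(n)),
                       lat = lat, lon = lon, group = groups,
                       stringsAsFactors = FALSE)

  bio <- matrix(NA_real_, n, n_bioclim)
  for (b in seq_along(correlation_blocks)) {
    vars <- correlation_blocks[[b]]
    mu_g <- rnorm(ng, 0, group_sd)
    f <- rnorm(n)
    for (v in vars) {
      e <- rnorm(n)
      bio[, v] <- mu_g[gi] + sqrt(within_cor) * f + sqrt(1 - within_cor) * e
    }
  }
  bioclim <- as.data.frame(bio)
  names(bioclim) <- paste0("BIO", seq_len(n_bioclim))
  rownames(bioclim) <- coords$sample
  list(coords = coords, bioclim = bioclim)
}
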