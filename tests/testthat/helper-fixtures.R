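# Small fixture builders shared across tests. Everything is generated in
# code; no binary fixtures.

# deterministic tiny genotype matrix built by hand
tiny_gm <- function() {
  dos <- rbind(
    S1 = c(0, 0, 2, 1, 0),
    S2 = c(1, 0, 2, 1, 2),
    S3 = c(2, NA, 0, 1, 2),
    S4 = c(2, 2, 0, 0, NA)
  )
  variants <- data.frame(
    chrom = c("Ca1", "Ca1", "Ca1", "Ca2", "Ca2"),
    pos = c(100L, 500L, 900L, 200L, 700L),
    ref = "A", alt = "G"
  )
  genotype_matrix(dos, variants)
}

# a genotype matrix from explicit dosage columns on one chromosome
gm_from_columns <- function(..., chrom = "Ca1", spacing = 1000L) {
  cols <- list(...)
  dos <- do.call(cbind, cols)
  variants <- data.frame(chrom = chrom,
                         pos = spacing * seq_along(cols),
                         ref = "A", alt = "G")
  genotype_matrix(dos, variants)
}

# small simulated panel with planted blocks, reused by several suites
small_panel <- function(seed = 1, n = 200, n_groups = 2, missing_rate = 0.02,
                        n_founders = 3, block_snps = 8, bg_snps = 30,
                        per_chrom = 2, n_chrom = 2, selfing = 0.95) {
  chroms <- data.frame(name = paste0("Ca", seq_len(n_chrom)),
                       length_bp = 8e6,
                       n_snps = per_chrom * block_snps + bg_snps)
  starts <- round(seq(0.15, 0.7, length.out = per_chrom) * 8e6)
  blocks <- do.call(rbind, lapply(chroms$name, function(ch) {
    data.frame(chrom = ch, start_bp = starts, end_bp = starts + 3e5,
               n_snps = block_snps, n_founders = n_founders)
  }))
  cfg <- sim_config(n_samples = n, chromosomes = chroms, blocks = blocks,
                    selfing_inbreeding = selfing,
                    missing_rate = missing_rate, n_groups = n_groups,
                    seed = seed)
  simulate_genotypes(cfg)
}

# simple column-mean imputation for test-side computations
impute_dos <- function(m) {
  m <- as.matrix(m)
  cm <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- cm[idx[, 2]]
  m
}

# brute-force GSEA running sum: the independent oracle for enrichment_score
walk_es <- function(stat, hit_ranks, alpha = 1) {
  N <- length(stat)
  s <- length(hit_ranks)
  w <- stat[hit_ranks]^alpha
  if (sum(w) == 0) w <- rep(1, s)
  running <- 0
  best <- 0
  for (r in seq_len(N)) {
    if (r %in% hit_ranks) {
      running <- running + w[match(r, hit_ranks)] / sum(w)
    } else {
      running <- running - 1 / (N - s)
    }
    if (abs(running) > abs(best) ||
        (abs(running) == abs(best) && running > best)) {
      # positive deviation preferred on an exact tie, as in the package
      best <- running
    }
  }
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# best Jaccard of each planted block against a set of inferred member lists
block_jaccards <- function(truth_members, inferred_members) {
  vapply(truth_members, function(tm) {
    if (!length(inferred_members)) return(0)
    max(vapply(inferred_members, function(im) {
      length(intersect(tm, im)) / length(union(tm, im))
    }, numeric(1)))
  }, numeric(1))
}

# write a small VCF fixture as text lines
write_fixture_vcf <- function(path, records,
                              samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
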