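test_that("pairwise r2 matches direct Pearson computation", {
  x <- c(2, 2, 0, 0, 2, 0, 1, 1)
  y <- c(2, 0, 0, 2, 2, 0, 1, 1)
  gm <- gm_from_columns(x, y)
  r <- pairwise_r2(gm, "intra_chromosomal", min_n = 5)
  expect_equal(r$r2, stats::cor(x, y)^2)
  expect_equal(r$distance_bp, 1000)
  expect_equal(r$n_used, 8)

  gm_id <- gm_from_columns(x, x)
  expect_equal(pairwise_r2(gm_id, min_n = 5)$r2, 1)

  # constructed zero-covariance pair
  a <- c(0, 0, 2, 2)
  b <- c(0, 2, 0, 2)
  expect_equal(pairwise_r2(gm_from_columns(a, b), min_n = 4)$r2, 0)
})

test_that("r2 is invariant to swapping ref/alt labels", {
  x <- c(2, 2, 0, 0, 2, 0, 1, 1)
  y <- c(2, 0, 0, 2, 2, 0, 1, 1)
  r1 <- pairwise_r2(gm_from_columns(x, y), min_n = 5)$r2
  r2 <- pairwise_r2(gm_from_columns(2 - x, y), min_n = 5)$r2
  expect_equal(r1, r2)
})

test_that("unlinked pairs are cross-chromosome and capped", {
  p <- small_panel(seed = 31, n = 100)
  u <- pairwise_r2(p$genotypes, "unlinked", max_pairs = 200, seed = 3)
  expect_lte(nrow(u), 200)
  chrom <- p$genotypes$variants$chrom
  expect_true(all(chrom[u$i] != chrom[u$j]))
  gm1 <- subset_variants(p$genotypes,
                         p$genotypes$variants$chrom == "Ca1")
  expect_error(pairwise_r2(gm1, "unlinked"), "two chromosomes")
})

test_that("critical r2 agrees with the direct tail formula", {
  expect_warning(c1 <- unlinked_critical_r2(rep(0.12, 30)), "fewer than 100")
  expect_equal(as.numeric(c1), 0.12)
  suppressWarnings(
    c2 <- unlinked_critical_r2(rep(0.12, 30), mode = "empirical"))
  expect_equal(as.numeric(c2), 0.12)

  set.seed(10)
  r2 <- stats::rbeta(10000, 1, 20)
  par <- unlinked_critical_r2(r2, percentile = 0.95)
  expect_equal(as.numeric(par),
               mean(r2) + stats::qnorm(0.95) * stats::sd(r2))
  emp <- unlinked_critical_r2(r2, mode = "empirical")
  expect_equal(as.numeric(emp), unname(stats::quantile(r2, 0.95)))
  expect_error(unlinked_critical_r2(numeric(0)), "no unlinked")
})

test_that("LOESS decay crossing matches the analytic exponential decay", {
  set.seed(4)
  d0 <- 2e5
  d <- runif(2000, 0, 1e6)
  r2 <- pmin(pmax(0.8 * exp(-d / d0) + rnorm(2000, 0, 0.02), 0), 1)
  fit <- fit_ld_decay(data.frame(distance_bp = d, r2 = r2),
                      critical_r2 = 0.16)
  analytic <- d0 * log(0.8 / 0.16)
  expect_true(fit$crossed)
  expect_lt(abs(fit$decay_range_bp - analytic) / analytic, 0.10)
  expect_equal(fit$critical_r2, 0.16)
})

test_that("a curve that never reaches the threshold is flagged", {
  set.seed(5)
  d <- runif(300, 0, 1e6)
  r2 <- pmin(pmax(0.6 + rnorm(300, 0, 0.01), 0), 1)
  fit <- fit_ld_decay(data.frame(distance_bp = d, r2 = r2),
                      critical_r2 = 0.16)
  expect_false(fit$crossed)
  expect_true(is.na(fit$decay_range_bp))
  expect_error(fit_ld_decay(data.frame(distance_bp = rep(100, 60),
                                       r2 = runif(60)), 0.16),
               "more than one distance")
})

test_that("complete association gives |D'| = 1 and strong LD", {
  x <- rep(c(0, 2), each = 25)
  gm <- gm_from_columns(x, x)
  ci <- dprime_ci(gm, 1, 2)
  expect_equal(ci$dprime, 1)
  expect_equal(ci$class, "strong_ld")
  expect_gte(ci$ci_high, 0.98)
  # CI contains the point estimate
  expect_true(ci$ci_low <= ci$dprime && ci$dprime <= ci$ci_high)
})

test_that("independent common loci are classified as recombination", {
  set.seed(8)
  n_recomb <- 0
  for (rep in 1:10) {
    x <- rbinom(500, 2, 0.5)
    y <- rbinom(500, 2, 0.5)
    ci <- dprime_ci(gm_from_columns(x, y), 1, 2)
    if (ci$class == "recombination") n_recomb <- n_recomb + 1
  }
  expect_gte(n_recomb, 6)
})

test_that("|D'| is invariant to allele relabeling and needs polymorphism", {
  set.seed(9)
  x <- rbinom(100, 2, 0.4)
  y <- ifelse(x > 0, pmin(x + rbinom(100, 1, 0.2), 2), rbinom(100, 2, 0.1))
  c1 <- dprime_ci(gm_from_columns(x, y), 1, 2)
  c2 <- dprime_ci(gm_from_columns(2 - x, y), 1, 2)
  expect_equal(c1$dprime, c2$dprime, tolerance = 1e-9)
  expect_error(dprime_ci(gm_from_columns(rep(0, 50), x[1:50]), 1, 2),
               "monomorphic")
})

test_that("planted founder blocks are recovered exactly", {
  chroms <- data.frame(name = "Ca1", length_bp = 4e6, n_snps = 22)
  blocks <- data.frame(chrom = "Ca1", start_bp = c(5e5, 2.5e6),
                       end_bp = c(8e5, 2.8e6), n_snps = 6, n_founders = 3)
  cfg <- sim_config(n_samples = 400, chromosomes = chroms, blocks = blocks,
                    missing_rate = 0, n_groups = 1, seed = 17)
  p <- simulate_genotypes(cfg)
  hb <- partition_haploblocks(p$genotypes)
  expect_equal(nrow(hb$blocks), 2)
  expect_setequal(hb$members[[1]], p$truth$block_members$Ca1_B1)
  expect_setequal(hb$members[[2]], p$truth$block_members$Ca1_B2)
})

test_that("degenerate chromosomes and overlap invariants hold", {
  # single-variant chromosome yields no blocks
  gm1 <- gm_from_columns(rbinom(50, 2, 0.5))
  expect_equal(nrow(partition_haploblocks(gm1)$blocks), 0)

  p <- small_panel(seed = 33, n = 250)
  hb <- partition_haploblocks(p$genotypes)
  for (ch in unique(hb$blocks$chrom)) {
    b <- hb$blocks[hb$blocks$chrom == ch, ]
    b <- b[order(b$start_bp), ]
    if (nrow(b) > 1) {
      expect_true(all(b$start_bp[-1] > b$end_bp[-nrow(b)]))
    }
  }
  for (bid in hb$blocks$block_id) {
    m <- hb$members[[bid]]
    expect_equal(m, seq(min(m), max(m)))  # contiguous in marker order
  }
})

test_that("block partitioning is invariant to sample order", {
  p <- small_panel(seed = 34, n = 150)
  gm <- p$genotypes
  perm <- sample(n_samples(gm))
  gm_perm <- genotype_matrix(gm$dosages[perm, ], gm$variants,
                             sample_ids = gm$sample_ids[perm])
  h1 <- partition_haploblocks(gm)
  h2 <- partition_haploblocks(gm_perm)
  expect_identical(h1$blocks, h2$blocks)
  expect_identical(h1$members, h2$members)
})
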