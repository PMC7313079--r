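test_that("genotype PCA separates simulated groups and conserves variance", {
  # two strongly differentiated groups built directly from allele frequencies
  set.seed(41)
  n_half <- 60; m <- 80
  p1 <- runif(m, 0.05, 0.3); p2 <- runif(m, 0.7, 0.95)
  dos <- rbind(
    matrix(rbinom(n_half * m, 2, rep(p1, each = n_half)), n_half, m),
    matrix(rbinom(n_half * m, 2, rep(p2, each = n_half)), n_half, m)
  )
  gm <- genotype_matrix(dos, data.frame(chrom = "Ca1", pos = 1:m * 100,
                                        ref = "A", alt = "G"))
  cov <- genotype_pca(gm, k = 4)
  expect_equal(sum(cov$variance_explained), 1)
  g <- rep(c("G1", "G2"), each = n_half)
  pc1 <- cov$matrix[, 1]
  between <- (mean(pc1[g == "G1"]) - mean(pc1[g == "G2"]))^2
  within <- mean(tapply(pc1, g, stats::var))
  expect_gt(between / within, 10)
})

test_that("duplicated samples get identical PCA scores", {
  set.seed(42)
  dos <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30)
  dos <- rbind(dos, dos[1, ])
  variants <- data.frame(chrom = "Ca1", pos = 1:30 * 100, ref = "A", alt = "G")
  gm <- genotype_matrix(dos, variants)
  cov <- genotype_pca(gm, k = 3)
  expect_equal(cov$matrix[1, ], cov$matrix[21, ], tolerance = 1e-9)
})

test_that("geographic PCoA embeds simple configurations exactly", {
  # three pairwise-equidistant points (small equilateral triangle)
  r <- 0.5
  coords <- data.frame(
    lat = c(r, -r / 2, -r / 2),
    lon = c(0, r * sqrt(3) / 2, -r * sqrt(3) / 2)
  )
  pc <- geographic_pcoa(coords, k = 2)
  ev <- pc$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 0.01)
  expect_true(all(ev[1:2] > 0))
  D_in <- geosphere::distm(cbind(coords$lon, coords$lat))
  D_out <- as.matrix(stats::dist(pc$matrix))
  expect_equal(D_out, unname(D_in), tolerance = 1e-4 * max(D_in),
               ignore_attr = TRUE)

  # two points: a single informative axis whose separation is the distance
  two <- data.frame(lat = c(10, 12), lon = c(30, 30))
  pc2 <- geographic_pcoa(two, k = 2)
  d <- geosphere::distHaversine(c(30, 10), c(30, 12))
  expect_equal(unname(abs(diff(pc2$matrix[, 1]))), d, tolerance = 1e-6)

  expect_error(geographic_pcoa(data.frame(lat = c(1, 1), lon = c(2, 2))),
               "identical")
  expect_equal(formals(geographic_pcoa)$k, 2L)
})

test_that("a strong planted SNP is the top GWAS hit", {
  p <- small_panel(seed = 43, n = 400, bg_snps = 60)
  gm <- p$genotypes
  set.seed(7)
  snp <- impute_dos(gm$dosages[, 40, drop = FALSE])[, 1]
  g <- scale(snp)[, 1] * sqrt(0.2)
  y <- g + rnorm(400, 0, sqrt(0.8))
  res <- gwas_scan(gm, y, genotype_pca(gm, 4))
  expect_equal(which.min(res$p_gc), 40)
  expect_lt(res$q[40], 0.05)
})

test_that("covariate-aligned traits yield no hits after adjustment", {
  p <- small_panel(seed = 44, n = 300)
  gm <- p$genotypes
  cov <- genotype_pca(gm, k = 4)
  set.seed(9)
  y <- cov$matrix[, 1] * 3 + rnorm(300, 0, 0.5)
  res <- gwas_scan(gm, y, cov)
  expect_equal(sum(res$q < 0.05), 0)
})

test_that("the LMM collapses to OLS in the large-delta limit", {
  p <- small_panel(seed = 45, n = 120)
  gm <- p$genotypes
  set.seed(11)
  y <- rnorm(120)
  cov <- genotype_pca(gm, k = 2)
  lmm <- gwas_scan(gm, y, cov, method = "lmm", delta = 1e8)
  ols <- gwas_scan(gm, y, cov, method = "ols")
  expect_equal(lmm$beta, ols$beta, tolerance = 1e-6)
  expect_equal(lmm$stat, ols$stat, tolerance = 1e-5)
})

test_that("p-values are invariant to a consistent sample permutation", {
  p <- small_panel(seed = 46, n = 150)
  gm <- p$genotypes
  set.seed(13)
  y <- rnorm(150)
  cov <- genotype_pca(gm, k = 3)
  res1 <- gwas_scan(gm, y, cov)
  perm <- sample(150)
  gm2 <- genotype_matrix(gm$dosages[perm, ], gm$variants,
                         sample_ids = gm$sample_ids[perm])
  res2 <- gwas_scan(gm2, y[perm], cov$matrix[perm, , drop = FALSE])
  expect_equal(res1$p_raw, res2$p_raw, tolerance = 1e-6)
})

test_that("structure covariates pull lambda toward 1 under confounding", {
  hits <- 0
  for (seed in 1:10) {
    p <- small_panel(seed = 100 + seed, n = 200, n_groups = 2)
    gm <- p$genotypes
    set.seed(seed)
    y <- as.numeric(p$truth$groups == "G1") * 2 + rnorm(200)
    l_without <- attr(gwas_scan(gm, y, NULL, method = "ols"), "lambda_gc")
    l_with <- attr(gwas_scan(gm, y, genotype_pca(gm, 4), method = "ols"),
                   "lambda_gc")
    if (abs(l_with - 1) < abs(l_without - 1)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("rank-deficient covariates are reported by name", {
  p <- small_panel(seed = 47, n = 80)
  cov <- genotype_pca(p$genotypes, k = 2)
  X <- cbind(cov$matrix, dup = cov$matrix[, 1])
  expect_error(gwas_scan(p$genotypes, rnorm(80), X), "dup")
})

test_that("genomic control follows the median-ratio definition", {
  stats0 <- c(rep(0.2, 5), rep(stats::qchisq(0.5, 1), 1), rep(1.5, 5))
  gc <- genomic_control(stats0)
  expect_equal(gc$lambda, 1)
  expect_identical(gc$stat_adj, stats0)

  set.seed(20)
  s <- stats::rchisq(5000, 1)
  g1 <- genomic_control(s)
  g2 <- genomic_control(2 * s)
  expect_equal(g2$lambda, 2 * g1$lambda)
  if (g1$lambda > 1) {
    # doubling every statistic doubles lambda and leaves the adjusted
    # statistics unchanged
    expect_equal(g2$stat_adj, g1$stat_adj)
  } else {
    expect_equal(g2$stat_adj, 2 * s / g2$lambda)
  }
  expect_error(genomic_control(c(-1, 1)), "non-negative")
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(21)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0, 0.5)), "\\(0, 1\\]")
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})
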