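test_that("generator is deterministic for a fixed seed", {
  p1 <- small_panel(seed = 5)
  p2 <- small_panel(seed = 5)
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$truth$blocks, p2$truth$blocks)

  t1 <- simulate_traits(p1$genotypes,
                        trait_spec("t", causal_blocks = "Ca1_B1"),
                        truth = p1$truth, seed = 9)
  t2 <- simulate_traits(p2$genotypes,
                        trait_spec("t", causal_blocks = "Ca1_B1"),
                        truth = p2$truth, seed = 9)
  expect_identical(t1, t2)

  g1 <- simulate_geography_bioclim(p1$truth, seed = 3)
  g2 <- simulate_geography_bioclim(p2$truth, seed = 3)
  expect_identical(g1, g2)
})

test_that("full selfing yields only homozygous dosages", {
  p <- small_panel(seed = 2, selfing = 1, missing_rate = 0)
  expect_true(all(p$genotypes$dosages %in% c(0, 2)))
})

test_that("single-founder blocks are monomorphic; two founders give r2 = 1", {
  p1 <- small_panel(seed = 3, n_founders = 1, missing_rate = 0)
  idx <- p1$truth$block_members$Ca1_B1
  block <- p1$genotypes$dosages[, idx]
  expect_true(all(apply(block, 2, function(x) length(unique(x)) == 1)))

  p2 <- small_panel(seed = 4, n_founders = 2, missing_rate = 0, n = 150)
  idx <- p2$truth$block_members$Ca1_B1
  block <- p2$genotypes$dosages[, idx]
  poly <- apply(block, 2, stats::sd) > 0
  r2 <- stats::cor(block[, poly])^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("unsatisfiable founder diversity is rejected", {
  chroms <- data.frame(name = "Ca1", length_bp = 1e6, n_snps = 5)
  blocks <- data.frame(chrom = "Ca1", start_bp = 1e5, end_bp = 3e5,
                       n_snps = 2, n_founders = 5)
  expect_error(sim_config(chromosomes = chroms, blocks = blocks),
               "founder")
})

test_that("planted blocks show more LD within than between", {
  for (seed in 1:3) {
    p <- small_panel(seed = seed, n = 250)
    gm <- p$genotypes
    members <- p$truth$block_members
    within <- unlist(lapply(members, function(ix) {
      r <- stats::cor(impute_dos(gm$dosages[, ix]))^2
      r[upper.tri(r)]
    }))
    b1 <- members[[1]]; b2 <- members[[2]]
    between <- stats::cor(impute_dos(gm$dosages[, b1]),
                          impute_dos(gm$dosages[, b2]))^2
    expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
  }
})

test_that("trait variance components are realized at large n", {
  p <- small_panel(seed = 6, n = 2000)
  tr <- simulate_traits(p$genotypes,
                        trait_spec("t", causal_blocks = "Ca1_B1",
                                   heritability = 0.5,
                                   polygenic_share = 0.2),
                        truth = p$truth, seed = 1)
  expect_lt(abs(stats::var(tr$t) - 1), 0.05)
})

test_that("realized R2 on the causal set matches the heritability target", {
  r2 <- replicate(50, {
    p <- small_panel(seed = sample.int(1e6, 1), n = 400, bg_snps = 15,
                     per_chrom = 1, n_chrom = 1)
    tr <- simulate_traits(p$genotypes,
                          trait_spec("t", causal_blocks = "Ca1_B1",
                                     heritability = 0.5,
                                     polygenic_share = 0),
                          truth = p$truth, seed = sample.int(1e6, 1))
    X <- impute_dos(p$genotypes$dosages[, p$truth$block_members$Ca1_B1])
    summary(stats::lm(tr$t ~ X))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.5), 0.1)
})

test_that("pure-noise traits show no association with any SNP", {
  p <- small_panel(seed = 7, n = 300)
  tr <- simulate_traits(p$genotypes,
                        trait_spec("noise", heritability = 0,
                                   polygenic_share = 0), seed = 2)
  cors <- abs(stats::cor(impute_dos(p$genotypes$dosages), tr$noise))
  # Bonferroni-style null envelope for the max absolute correlation
  crit <- stats::qnorm(1 - 0.01 / (2 * length(cors))) / sqrt(300)
  expect_lt(max(cors), crit * 1.5)
})

test_that("ordinal traits are integer scores with the requested levels", {
  p <- small_panel(seed = 8)
  tr <- simulate_traits(p$genotypes,
                        trait_spec("o", causal_blocks = "Ca1_B1",
                                   type = "ordinal", n_levels = 4),
                        truth = p$truth, seed = 5)
  expect_true(all(tr$o %in% 1:4))
  expect_equal(sort(unique(tr$o)), 1:4)
})

test_that("impossible heritability demands are rejected", {
  p <- small_panel(seed = 9, n = 60)
  expect_error(
    simulate_traits(p$genotypes,
                    trait_spec("bad", heritability = 1, polygenic_share = 0),
                    seed = 1),
    "causal")
})

test_that("bioclim correlation blocks are high within and low across", {
  p <- small_panel(seed = 10, n = 400, n_groups = 3)
  geo <- simulate_geography_bioclim(p$truth, n_bioclim = 8,
                                    correlation_blocks =
                                      list(1:4, 5:7, 8), seed = 4)
  r <- stats::cor(geo$bioclim, method = "spearman")
  within <- r[1:4, 1:4][upper.tri(diag(4))]
  expect_gt(mean(within), 0.7)
  # a singleton block is uncorrelated with the others up to group structure
  expect_lt(mean(abs(r[8, 5:7])), 0.5)
})

test_that("zero jitter collapses groups to centroid points", {
  p <- small_panel(seed = 11, n_groups = 3)
  geo <- simulate_geography_bioclim(p$truth, jitter_deg = 0, seed = 1)
  for (g in unique(geo$coords$group)) {
    sel <- geo$coords$group == g
    expect_equal(length(unique(geo$coords$lat[sel])), 1)
    expect_equal(length(unique(geo$coords$lon[sel])), 1)
  }
})

test_that("group-structured geography requires at least two groups", {
  p <- small_panel(seed = 12, n_groups = 1)
  expect_error(simulate_geography_bioclim(p$truth, seed = 1), "2 groups")
})
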