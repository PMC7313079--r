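# a ranking object built directly from a vector of p-values
ranked_from_p <- function(p, chrom = "Ca1") {
  g <- data.frame(chrom = chrom, pos = seq_along(p) * 100,
                  id = paste0(chrom, ":", seq_along(p) * 100),
                  p_gc = p, stringsAsFactors = FALSE)
  rank_snps(g)
}

test_that("block size filter is strictly exclusive", {
  gm <- small_panel(seed = 51, n = 50)$genotypes
  members <- lapply(1:10, function(s) seq_len(s))
  names(members) <- paste0("b", 1:10)
  hb <- haploblock_set(gm, members)
  out <- filter_blocks(hb)
  expect_equal(nrow(out$blocks), 4)           # sizes 7, 8, 9, 10
  expect_true(all(out$blocks$n_snps > 6))
  expect_equal(nrow(filter_blocks(haploblock_set(
    gm, list(b7 = 1:7, b6 = 1:6)))$blocks), 1)
  empty <- structure(list(blocks = hb$blocks[0, ], members = list()),
                     class = "haploblock_set")
  expect_equal(nrow(filter_blocks(empty)$blocks), 0)
})

test_that("SNP ranking is p-ascending with positional tie-breaks", {
  r <- ranked_from_p(c(0.5, 0.01, 0.5, 1))
  expect_equal(r$orig_index, c(2, 1, 3, 4))   # tie 1 vs 3 -> earlier pos first
  expect_equal(r$stat[r$p == 1], 0)
  # input order does not matter
  g <- data.frame(chrom = "Ca1", pos = c(300, 100, 400, 200),
                  id = paste0("Ca1:", c(300, 100, 400, 200)),
                  p_gc = c(0.5, 0.5, 1, 0.01))
  r2 <- rank_snps(g)
  expect_equal(r2$id, c("Ca1:200", "Ca1:100", "Ca1:300", "Ca1:400"))
  g$p_gc[2] <- NA
  expect_error(rank_snps(g), "finite p-value")
})

test_that("enrichment score matches the brute-force running sum", {
  # hand-traceable case: N = 5, hits at ranks 2 and 4, stats 5..1
  r <- ranked_from_p(10^(-c(5, 4, 3, 2, 1)))
  es <- enrichment_score(r, members = r$orig_index[c(2, 4)])
  expect_equal(es, walk_es(r$stat, c(2, 4)))
  expect_equal(es, 1 / 3)  # frozen from the 5-step walk (positive tie wins)

  # full concentration at the top gives es = 1
  es_top <- enrichment_score(r, members = r$orig_index[1:2])
  expect_equal(es_top, 1)

  # random cases against the oracle, weighted and unweighted
  set.seed(31)
  for (i in 1:25) {
    N <- sample(8:40, 1)
    s <- sample(2:min(6, N - 1), 1)
    p <- sort(runif(N))
    r <- ranked_from_p(p)
    hits <- sort(sample(N, s))
    for (a in c(0, 1, 2)) {
      expect_equal(enrichment_score(r, r$orig_index[hits], alpha = a),
                   walk_es(r$stat, hits, alpha = a))
    }
  }
})

test_that("scores stay in [-1, 1] and respect rank-preserving transforms", {
  set.seed(32)
  for (i in 1:200) {
    N <- sample(10:60, 1)
    s <- sample(2:5, 1)
    r <- ranked_from_p(sort(runif(N)))
    es <- enrichment_score(r, r$orig_index[sort(sample(N, s))])
    expect_gte(es, -1); expect_lte(es, 1)
  }
  # alpha = 0: any monotone p transform preserving order gives the same score
  p <- sort(runif(30))
  r1 <- ranked_from_p(p)
  r2 <- ranked_from_p(p^3 / 2)
  hits <- sort(sample(30, 4))
  expect_equal(enrichment_score(r1, r1$orig_index[hits], alpha = 0),
               enrichment_score(r2, r2$orig_index[hits], alpha = 0))
})

test_that("enrichment score agrees with an established GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  for (i in 1:20) {
    N <- 50
    r <- ranked_from_p(sort(runif(N)))
    hits <- sort(sample(N, 6))
    ours <- enrichment_score(r, r$orig_index[hits], alpha = 1)
    ref <- fgsea::calcGseaStat(stats = r$stat, selectedStats = hits,
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("permutation p matches exhaustive enumeration on a tiny panel", {
  set.seed(34)
  p <- sort(runif(6))
  r <- ranked_from_p(p)
  gm <- small_panel(seed = 52, n = 50)$genotypes
  # the block occupies ranks 1 and 3
  members <- r$orig_index[c(1, 3)]
  hb <- haploblock_set(gm, list(b = members))
  res <- permutation_test(r, hb, n_perm = 50000, seed = 7)
  es_obs <- enrichment_score(r, members)
  combs <- utils::combn(6, 2)
  null_es <- apply(combs, 2, function(cc) walk_es(r$stat, cc))
  exact <- mean(null_es >= es_obs)
  expect_lt(abs(res$p_perm - exact), 0.01)
})

test_that("weak observed scores give p near 1 and seeds reproduce", {
  set.seed(35)
  r <- ranked_from_p(sort(runif(40)))
  gm <- small_panel(seed = 53, n = 50)$genotypes
  hb <- haploblock_set(gm, list(worst = r$orig_index[34:40]))
  res <- permutation_test(r, hb, n_perm = 2000, seed = 11)
  expect_gt(res$p_perm, 0.9)
  res2 <- permutation_test(r, hb, n_perm = 2000, seed = 11)
  expect_identical(res$p_perm, res2$p_perm)
  expect_gte(res$p_perm, 1 / 2001)
})

test_that("global FDR pools permutation p-values across traits", {
  p <- small_panel(seed = 54, n = 150)
  gm <- p$genotypes
  tr <- simulate_traits(gm, list(
    trait_spec("t1", causal_blocks = "Ca1_B1", heritability = 0.5,
               polygenic_share = 0),
    trait_spec("t2", heritability = 0, polygenic_share = 0)),
    truth = p$truth, seed = 4)
  gl <- lapply(names(tr), function(nm) gwas_scan(gm, tr[[nm]],
                                                 genotype_pca(gm, 4),
                                                 trait_name = nm))
  names(gl) <- names(tr)
  hb <- haploblock_set(gm, p$truth$block_members)
  e_within <- block_enrichment(gl, hb, n_perm = 500, seed = 2)
  e_global <- block_enrichment(gl, hb, n_perm = 500, seed = 2,
                               fdr_scope = "global")
  expect_identical(e_within$p_perm, e_global$p_perm)
  expect_equal(e_global$q, bh_fdr(e_global$p_perm))
  expect_identical(e_global$significant,
                   e_global$es > 0 & e_global$q < 0.05)
})

test_that("significant sets collect positive-ES, low-q blocks per trait", {
  res <- data.frame(
    trait = c("t1", "t1", "t1", "t2"),
    block_id = c("b1", "b2", "b3", "b1"),
    n_snps = 7,
    es = c(0.8, -0.9, 0.5, 0.2),
    p_perm = c(0.001, 0.0001, 0.2, 0.5),
    q = c(0.003, 0.001, 0.4, 0.5),
    significant = c(TRUE, FALSE, FALSE, FALSE)
  )
  sets <- enriched_sets_by_trait(res)
  expect_equal(sets$t1, "b1")      # es > 0 and q < 0.05
  expect_equal(sets$t2, character(0))
  # negative ES is excluded no matter how small q is
  expect_false("b2" %in% sets$t1)
})
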