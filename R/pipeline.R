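#' Declarative configuration for a full pipeline run
#'
#' Exactly one of `sim` (a [sim_config()]) or `input` (named list with paths
#' `vcf`, `traits`, `coords`) must be supplied. Every stage parameter has
#' the analysis defaults: markers filtered at 90% call rate / 3% MAF,
#' haploblocks from |D'| CIs with the `[0.7, 0.98]` thresholds, GWAS with 8
#' genotype PCs (optionally plus 2 geographic PCoA axes), enrichment on
#' blocks of more than 6 SNPs with a 100,000-permutation null at FDR 0.05.
#'
#' @param sim optional [sim_config()] for a synthetic run.
#' @param input optional list of input paths (`vcf`, `traits`, `coords`).
#' @param trait_specs list of [trait_spec()] for simulated traits (ignored
#'   when reading inputs). `NULL` gives a small default set of block-linked
#'   traits.
#' @param filter a [variant_filter_spec()].
#' @param n_unlinked_pairs unlinked r2 subsample size.
#' @param loess_span LOESS span for the decay fit.
#' @param max_block_span_bp,informative_fraction block partition parameters.
#' @param n_pcs genotype PCA covariates (default 8).
#' @param use_geo_pcoa append geographic PCoA covariates.
#' @param n_pcoa number of PCoA axes (default 2).
#' @param gwas_method `"lmm"` or `"ols"`.
#' @param min_snps_exclusive block size filter before enrichment.
#' @param n_perm permutations for the enrichment null.
#' @param fdr significance threshold.
#' @param alpha enrichment weight exponent.
#' @param blocks_from `"infer"` (partition from LD) or `"planted"` (use the
#'   generator's ground-truth blocks; synthetic runs only).
#' @param height_cut dendrogram cut height for flat trait groups.
#' @param seed global seed; stages derive child seeds.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input = NULL, trait_specs = NULL,
                            filter = variant_filter_spec(),
                            n_unlinked_pairs = 1e5, loess_span = 0.3,
                            max_block_span_bp = 5e5,
                            informative_fraction = 0.95,
                            n_pcs = 8L, use_geo_pcoa = FALSE, n_pcoa = 2L,
                            gwas_method = "lmm",
                            min_snps_exclusive = 6L, n_perm = 1e5,
                            fdr = 0.05, alpha = 1,
                            blocks_from = c("infer", "planted"),
                            height_cut = 0.5, seed = 1L,
                            out_dir = tempfile("haploscan_run_")) {
  if (is.null(sim) == is.null(input)) {
    stop("supply exactly one of `sim` or `input`", call. = FALSE)
  }
  blocks_from <- match.arg(blocks_from)
  if (blocks_from == "planted" && is.null(sim)) {
    stop("planted blocks are only available for synthetic runs", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate-or-ingest, marker filtering, LD characterization
#' (pairwise r2, unlinked critical value, LOESS decay range), haploblock
#' partitioning, structure covariates and per-trait mixed-model GWAS,
#' haploblock enrichment, and trait similarity bi-clustering. Every stage
#' writes its tables under `out_dir` and the run finishes with a JSON
#' manifest of artifacts and resolved parameters. A stage failure aborts
#' with the stage name; artifacts of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `artifacts`, `parameters`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  note <- function(name, path) artifacts[[name]] <<- path
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  ## --- input -------------------------------------------------------------
  truth <- NULL
  stage("input", {
    if (!is.null(config$sim)) {
      simc <- config$sim
      simc$seed <- child_seed(seed, "simulate")
      panel <- simulate_genotypes(simc)
      gm0 <- panel$genotypes
      truth <- panel$truth
      specs <- config$trait_specs %||% default_trait_specs(truth)
      traits <- simulate_traits(gm0, specs, truth = truth,
                                seed = child_seed(seed, "traits"))
      geo <- simulate_geography_bioclim(truth,
                                        seed = child_seed(seed, "geo"))
      coords <- geo$coords
      traits <- cbind(traits, geo$bioclim)
      note("vcf", write_vcf(gm0, file.path(config$out_dir, "genotypes.vcf")))
      tp <- file.path(config$out_dir, "traits.tsv")
      utils::write.table(data.frame(sample = rownames(traits), traits),
                         tp, sep = "\t", quote = FALSE, row.names = FALSE)
      note("traits", tp)
      cp <- file.path(config$out_dir, "coords.tsv")
      utils::write.table(coords, cp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("coords", cp)
      gp <- file.path(config$out_dir, "ground_truth.json")
      jsonlite::write_json(list(
        blocks = truth$blocks,
        block_members = truth$block_members,
        groups = as.list(truth$groups),
        trait_truth = lapply(attr(traits, "ground_truth") %||% list(),
                             function(i) i[c("name", "causal_snps")])
      ), gp, auto_unbox = TRUE, digits = NA)
      note("ground_truth", gp)
    } else {
      gm0 <- read_vcf(config$input$vcf)
      tr <- utils::read.delim(config$input$traits, check.names = FALSE)
      rownames(tr) <- tr[[1]]
      traits <- tr[gm0$sample_ids, -1, drop = FALSE]
      coords <- utils::read.delim(config$input$coords)
    }
  })

  ## --- filter ------------------------------------------------------------
  gm <- stage("filter", filter_variants(gm0, config$filter))
  note("dosages", write_dosage_table(
    gm, file.path(config$out_dir, "dosages_filtered.tsv")))

  ## --- LD ----------------------------------------------------------------
  ld <- stage("ld", {
    intra <- pairwise_r2(gm, "intra_chromosomal")
    unl <- pairwise_r2(gm, "unlinked", max_pairs = config$n_unlinked_pairs,
                       seed = child_seed(seed, "unlinked"))
    crit <- unlinked_critical_r2(unl)
    decay <- fit_ld_decay(intra, critical_r2 = as.numeric(crit),
                          loess_span = config$loess_span)
    lp <- file.path(config$out_dir, "ld_intra.tsv")
    utils::write.table(intra, lp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("ld_intra", lp)
    list(intra = intra, unlinked = unl, critical = as.numeric(crit),
         decay = decay)
  })

  ## --- blocks ------------------------------------------------------------
  hb <- stage("blocks", {
    if (config$blocks_from == "planted") {
      # remap planted member indices through the filtered panel
      ids0 <- gm0$variants$id
      members <- lapply(truth$block_members, function(ix) {
        match(ids0[ix], gm$variants$id)
      })
      members <- lapply(members, function(m) m[!is.na(m)])
      members <- members[lengths(members) >= 2]
      haploblock_set(gm, members)
    } else {
      partition_haploblocks(gm, max_block_span_bp = config$max_block_span_bp,
                            informative_fraction = config$informative_fraction)
    }
  })
  note("blocks", write_blocks(hb, file.path(config$out_dir, "haploblocks.tsv")))
  note("blocks_bed", write_blocks(hb, file.path(config$out_dir,
                                                "haploblocks.bed"),
                                  format = "bed"))
  hb_big <- filter_blocks(hb, config$min_snps_exclusive)

  ## --- GWAS --------------------------------------------------------------
  gwas_list <- stage("gwas", {
    cov <- genotype_pca(gm, k = config$n_pcs)
    if (isTRUE(config$use_geo_pcoa)) {
      cov <- merge_covariates(cov, geographic_pcoa(coords, k = config$n_pcoa))
    }
    cvp <- file.path(config$out_dir, "covariates.tsv")
    utils::write.table(data.frame(sample = gm$sample_ids, cov$matrix),
                       cvp, sep = "\t", quote = FALSE, row.names = FALSE)
    note("covariates", cvp)
    num <- vapply(traits, is.numeric, logical(1))
    out <- lapply(names(traits)[num], function(tr) {
      g <- gwas_scan(gm, traits[[tr]], cov, method = config$gwas_method,
                     trait_name = tr)
      write_gwas(g, file.path(config$out_dir,
                              sprintf("gwas_%s.tsv", make.names(tr))))
      g
    })
    names(out) <- names(traits)[num]
    out
  })
  for (tr in names(gwas_list)) {
    note(paste0("gwas_", tr),
         file.path(config$out_dir, sprintf("gwas_%s.tsv", make.names(tr))))
  }

  ## --- enrichment --------------------------------------------------------
  enr <- stage("enrichment", {
    if (nrow(hb_big$blocks) == 0) {
      warning("no blocks exceed the size filter; enrichment skipped",
              call. = FALSE)
      NULL
    } else {
      e <- block_enrichment(gwas_list, hb_big, n_perm = config$n_perm,
                            seed = child_seed(seed, "perm"),
                            alpha = config$alpha, fdr = config$fdr)
      ep <- file.path(config$out_dir, "enrichment.tsv")
      utils::write.table(e, ep, sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrichment", ep)
      e
    }
  })

  ## --- similarity --------------------------------------------------------
  simres <- stage("similarity", {
    if (is.null(enr)) NULL else {
      sets <- enriched_sets_by_trait(enr)
      jp <- file.path(config$out_dir, "enriched_sets.json")
      jsonlite::write_json(sets, jp, auto_unbox = FALSE)
      note("enriched_sets", jp)
      if (length(sets) < 2) NULL else {
        sm <- similarity_matrix(sets)
        bc <- bicluster(sm, height_cut = config$height_cut)
        paths <- write_similarity(sm, bc,
                                  prefix = file.path(config$out_dir,
                                                     "similarity"))
        for (p in paths) note(basename(p), p)
        list(similarity = sm, biclust = bc, sets = sets)
      }
    }
  })

  manifest <- list(
    artifacts = artifacts,
    parameters = list(
      seed = seed,
      filter = unclass(config$filter),
      n_pcs = config$n_pcs, use_geo_pcoa = config$use_geo_pcoa,
      gwas_method = config$gwas_method,
      max_block_span_bp = config$max_block_span_bp,
      informative_fraction = config$informative_fraction,
      min_snps_exclusive = config$min_snps_exclusive,
      n_perm = config$n_perm, fdr = config$fdr, alpha = config$alpha,
      blocks_from = config$blocks_from,
      child_seeds = list(simulate = child_seed(seed, "simulate"),
                         unlinked = child_seed(seed, "unlinked"),
                         perm = child_seed(seed, "perm"))
    ),
    summary = list(
      n_samples = n_samples(gm), n_variants_raw = n_variants(gm0),
      n_variants = n_variants(gm),
      critical_r2 = ld$critical,
      decay_range_bp = ld$decay$decay_range_bp,
      n_blocks = nrow(hb$blocks),
      n_block_snps = sum(hb$blocks$n_snps),
      n_blocks_filtered = nrow(hb_big$blocks),
      lambda_gc = vapply(gwas_list, attr, numeric(1), "lambda_gc"),
      n_gwas_hits = if (length(gwas_list))
        sum(vapply(gwas_list, function(g) sum(g$q < config$fdr), numeric(1)))
        else 0,
      n_associated_snps = if (length(gwas_list))
        length(unique(unlist(lapply(gwas_list,
                                    function(g) g$id[g$q < config$fdr]))))
        else 0,
      n_enriched_pairs = if (!is.null(enr)) sum(enr$significant) else 0
    )
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$artifacts$manifest <- mp
  invisible(manifest)
}

# a small default trait set tied to planted blocks: two 3-trait pleiotropy
# groups plus a polygenic-only trait
default_trait_specs <- function(truth) {
  b <- truth$blocks$block_id
  big <- truth$blocks$block_id[truth$blocks$n_snps > 6]
  g1 <- big[seq_len(min(2, length(big)))]
  g2 <- big[seq_len(min(4, length(big)))][-seq_len(min(2, length(big)))]
  c(
    lapply(1:3, function(i) trait_spec(sprintf("traitA%d", i),
                                       causal_blocks = g1,
                                       heritability = 0.5)),
    lapply(1:3, function(i) trait_spec(sprintf("traitB%d", i),
                                       causal_blocks = g2,
                                       heritability = 0.5)),
    list(trait_spec("null_trait", heritability = 0, polygenic_share = 0))
  )
}
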