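test_that("cohort config validation rejects bad dimensions and rates", {
  expect_error(cohortConfig(n_samples = 0), "dimensions")
  expect_error(cohortConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohortConfig(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(cohortConfig(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(cohortConfig(missing_rate = 1), "missing_rate")
  expect_error(
    cohortConfig(n_variants = 10, n_genes = 5,
                 planted_effects = data.frame(variant = 11, gene = 1,
                                              beta = 1)),
    "unknown variant or gene")
})

test_that("genotype simulation honors missingness and allele frequency", {
  cfg <- cohortConfig(n_samples = 50, n_variants = 40, missing_rate = 0,
                      seed = 2)
  d <- dosageMatrix(simulateGenotypes(cfg))
  expect_false(anyNA(d))
  expect_true(all(d %in% 0:2))

  # positions strictly increasing, ids unique
  vi <- variantInfo(simulateGenotypes(cfg))
  expect_true(all(diff(vi$pos) > 0))
  expect_false(anyDuplicated(vi$id) > 0)

  # observed alt-allele frequency near the configured MAF at 4000 alleles
  # (a deep founder pool so founder sampling adds negligible variance and
  # the direct binomial bound applies)
  cfg2 <- cohortConfig(n_samples = 2000, n_variants = 20,
                       maf_range = c(0.3, 0.3), missing_rate = 0,
                       n_haplotypes_per_block = 4000, seed = 1)
  d2 <- dosageMatrix(simulateGenotypes(cfg2))
  freq <- rowMeans(d2) / 2
  expect_true(all(abs(freq - 0.3) < 0.03))
  expect_lt(abs(mean(freq) - 0.3), 0.01)
})

test_that("expression equals dosage under a pure planted effect", {
  cfg <- cohortConfig(n_samples = 30, n_variants = 5, n_genes = 3,
                      planted_effects = data.frame(variant = 2, gene = 1,
                                                   beta = 1),
                      noise_sd = 0, missing_rate = 0, baseline = 0, seed = 5)
  gd <- simulateGenotypes(cfg)
  ex <- simulateExpression(gd, cfg)
  expect_equal(unname(exprMatrix(ex)[1, ]), unname(dosageMatrix(gd)[2, ]))
  # genes without planted effects are constant when noise is off
  expect_equal(stats::sd(exprMatrix(ex)[2, ]), 0)
  expect_equal(stats::sd(exprMatrix(ex)[3, ]), 0)
})

test_that("planted OLS slope is recovered at cohort scale", {
  cfg <- cohortConfig(n_samples = 373, n_variants = 1, n_genes = 1,
                      maf_range = c(0.3, 0.3), ld_block_size = 1,
                      n_haplotypes_per_block = 100,
                      planted_effects = data.frame(variant = 1, gene = 1,
                                                   beta = 0.8),
                      noise_sd = 1, missing_rate = 0, seed = 9)
  gd <- simulateGenotypes(cfg)
  ex <- simulateExpression(gd, cfg)
  slope <- olsSlope(dosageMatrix(gd)[1, ], exprMatrix(ex)[1, ])
  expect_lt(abs(slope - 0.8), 0.15)
})

test_that("missing dosages contribute the variant mean, not NA", {
  cfg <- cohortConfig(n_samples = 100, n_variants = 4, n_genes = 2,
                      planted_effects = data.frame(variant = 1, gene = 1,
                                                   beta = 2),
                      noise_sd = 0, missing_rate = 0.3, baseline = 0, seed = 3)
  gd <- simulateGenotypes(cfg)
  ex <- simulateExpression(gd, cfg)
  expect_false(anyNA(exprMatrix(ex)))
  d <- dosageMatrix(gd)[1, ]
  filled <- ifelse(is.na(d), mean(d, na.rm = TRUE), d)
  expect_equal(unname(exprMatrix(ex)[1, ]), unname(2 * filled))
})

test_that("feature generation covers classes, strata and annotations", {
  cfg <- cohortConfig(n_samples = 20, n_variants = 100, n_genes = 10,
                      feature_density = 0.4,
                      planted_effects = data.frame(variant = c(3, 23, 43, 63, 83),
                                                   gene = 1:5, beta = 0.8),
                      annotation_hit_rate = 1, seed = 7)
  gd <- simulateGenotypes(cfg)
  fa <- simulateFeaturesAndAnnotations(gd, cfg)
  cls <- S4Vectors::mcols(fa$features)$feature_class
  expect_setequal(unique(cls), c("mirna_seed", "mirna_binding_site", "lincrna"))

  # lincRNA lengths span below / within / above the 200 bp-100 kb window
  len <- GenomicRanges::width(fa$features)[cls == "lincrna"]
  expect_gt(sum(len < 200), 0)
  expect_gt(sum(len > 200 & len < 100000), 0)
  expect_gt(sum(len > 100000), 0)

  # every planted SNP has a binding site targeting its planted gene
  vi <- variantInfo(gd)
  mc <- S4Vectors::mcols(fa$features)
  for (k in 1:5) {
    snp <- vi$id[cfg$planted_effects$variant[k]]
    gene <- sprintf("gene%04d", cfg$planted_effects$gene[k])
    ov <- bruteForceOverlap(vi[vi$id == snp, ], fa$features)
    sites <- mc$target_gene[match(ov$feature_id, mc$feature_id)]
    expect_true(gene %in% stats::na.omit(sites))
  }

  # hit rate 1 with 5 planted eQTL: at least 5 direct annotation rows
  planted_snps <- vi$id[cfg$planted_effects$variant]
  expect_gte(sum(fa$annotations$snp_id %in% planted_snps), 5)
  # plus proxy records that do NOT hit planted SNPs themselves
  expect_gt(sum(!fa$annotations$snp_id %in% planted_snps), 0)

  # precomputed table includes planted entries and decoys
  eq <- fa$precomputed_eqtl
  expect_true(all(paste(planted_snps,
                        sprintf("gene%04d", cfg$planted_effects$gene)) %in%
                    paste(eq$snp_id, eq$gene_id)))
  expect_gt(nrow(eq), 5)

  # density 0 with no planted effects: empty interval set
  cfg0 <- cohortConfig(n_samples = 20, n_variants = 50, feature_density = 0,
                       seed = 7)
  fa0 <- simulateFeaturesAndAnnotations(simulateGenotypes(cfg0), cfg0)
  expect_length(fa0$features, 0)
})

test_that("identical config and seed give byte-identical cohort files", {
  cfg <- demoConfig(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(cfg, d1)
  writeCohort(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("LD decays across block boundaries", {
  cfg <- cohortConfig(n_samples = 300, n_variants = 60, ld_block_size = 6,
                      n_haplotypes_per_block = 4, missing_rate = 0, seed = 13)
  d <- dosageMatrix(simulateGenotypes(cfg))
  blk <- ceiling(seq_len(nrow(d)) / 6)
  within <- c()
  between <- c()
  for (i in 1:(nrow(d) - 1)) {
    for (j in (i + 1):nrow(d)) {
      r2 <- ldR2(d[i, ], d[j, ])$r2
      if (is.na(r2)) next
      if (blk[i] == blk[j]) within <- c(within, r2)
      else if (abs(blk[i] - blk[j]) == 1) between <- c(between, r2)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("null cohort p-values are approximately uniform", {
  # 2000 independent null tests (block size 1, no planted effects)
  cfg <- cohortConfig(n_samples = 200, n_variants = 2000, n_genes = 2000,
                      ld_block_size = 1, n_haplotypes_per_block = 50,
                      noise_sd = 1, missing_rate = 0, seed = 17)
  gd <- simulateGenotypes(cfg)
  ex <- simulateExpression(gd, cfg)
  d <- dosageMatrix(gd)
  e <- exprMatrix(ex)
  p <- vapply(seq_len(2000),
              function(i) spearmanRho(d[i, ], e[i, ])$p, numeric(1))
  p <- p[!is.na(p)]
  ks <- unname(suppressWarnings(stats::ks.test(p, "punif")$statistic))
  expect_lt(ks, 0.05)
})
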