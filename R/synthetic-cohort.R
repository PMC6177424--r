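## Synthetic study inputs: block-LD genotypes from founder-haplotype
## resampling, expression with planted additive cis-effects, feature
## intervals, precomputed tissue-eQTL tables and clinical annotation catalogs.
## Everything is driven by a single seeded configuration so identical configs
## yield byte-identical files.

#' Configuration for a synthetic cohort
#'
#' @param n_samples,n_variants,n_genes cohort dimensions (all >= 1).
#' @param maf_range length-2 numeric in (0, 0.5]; per-site alternative-allele
#'   frequencies are drawn uniformly from this range.
#' @param ld_block_size variants per LD block; blocks are independent.
#' @param n_haplotypes_per_block founder haplotypes per block. Two founders
#'   force r2 = 1 within a block; more founders weaken within-block LD.
#' @param planted_effects data.frame with columns `variant` (index), `gene`
#'   (index), `beta` (expression units per alternative-allele copy), or NULL.
#' @param noise_sd standard deviation of Gaussian expression noise (RPKM-like
#'   units).
#' @param missing_rate fraction in \[0, 1) of genotype entries masked missing,
#'   completely at random.
#' @param feature_density fraction of variants covered by each feature class.
#' @param annotation_hit_rate fraction of planted eQTL SNPs given a clinical
#'   annotation record.
#' @param baseline baseline expression level added to every gene.
#' @param seed integer seed; identical configs produce identical cohorts.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_samples = 373L, n_variants = 300L, n_genes = 50L,
                         maf_range = c(0.05, 0.5), ld_block_size = 10L,
                         n_haplotypes_per_block = 4L, planted_effects = NULL,
                         noise_sd = 1, missing_rate = 0.02,
                         feature_density = 0.5, annotation_hit_rate = 1,
                         baseline = 5, seed = 1L) {
  if (is.null(planted_effects))
    planted_effects <- data.frame(variant = integer(), gene = integer(),
                                  beta = numeric())
  planted_effects <- as.data.frame(planted_effects)
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    n_haplotypes_per_block = as.integer(n_haplotypes_per_block),
    planted_effects = planted_effects, noise_sd = as.numeric(noise_sd),
    missing_rate = as.numeric(missing_rate),
    feature_density = as.numeric(feature_density),
    annotation_hit_rate = as.numeric(annotation_hit_rate),
    baseline = as.numeric(baseline), seed = as.integer(seed)
  )
  if (cfg$n_samples < 1L || cfg$n_variants < 1L || cfg$n_genes < 1L)
    stop("cohort dimensions must be >= 1")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[1] > cfg$maf_range[2] || cfg$maf_range[2] > 0.5)
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  if (cfg$ld_block_size < 1L || cfg$n_haplotypes_per_block < 2L)
    stop("ld_block_size >= 1 and n_haplotypes_per_block >= 2 required")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$feature_density < 0 || cfg$feature_density > 1)
    stop("feature_density must be in [0, 1]")
  if (cfg$annotation_hit_rate < 0 || cfg$annotation_hit_rate > 1)
    stop("annotation_hit_rate must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  pe <- cfg$planted_effects
  if (nrow(pe)) {
    if (!all(c("variant", "gene", "beta") %in% colnames(pe)))
      stop("planted_effects needs columns variant, gene, beta")
    if (any(pe$variant < 1 | pe$variant > cfg$n_variants) ||
        any(pe$gene < 1 | pe$gene > cfg$n_genes))
      stop("planted effect references an unknown variant or gene")
  }
  class(cfg) <- "CohortConfig"
  cfg
}

## Evaluate expr under a given RNG seed without disturbing the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.sampleIds <- function(n) sprintf("sample%04d", seq_len(n))
.geneIds <- function(n) sprintf("gene%04d", seq_len(n))

#' Simulate genotypes with block-wise LD
#'
#' Per LD block, `n_haplotypes_per_block` founder haplotypes are drawn with
#' per-site alternative-allele frequency uniform in `maf_range`; each sample's
#' two haplotypes are resampled with replacement from the block's founder
#' pool, and dosage is their sum. Entries are then masked missing
#' independently at `missing_rate`. Variants receive deterministic synthetic
#' rs-style ids and strictly increasing positions on one chromosome.
#'
#' @param config a [cohortConfig()].
#' @return A [GenotypeData-class] object.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    n <- config$n_samples
    m <- config$n_variants
    blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))
    dosage <- matrix(NA_real_, nrow = m, ncol = n)
    for (idx in blocks) {
      L <- length(idx)
      H <- config$n_haplotypes_per_block
      p <- stats::runif(L, config$maf_range[1], config$maf_range[2])
      founders <- matrix(stats::rbinom(H * L, 1L, rep(p, each = H)),
                         nrow = H, ncol = L)
      h1 <- sample.int(H, n, replace = TRUE)
      h2 <- sample.int(H, n, replace = TRUE)
      dosage[idx, ] <- t(founders[h1, , drop = FALSE] +
                         founders[h2, , drop = FALSE])
    }
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(dosage)) < config$missing_rate
      dosage[mask] <- NA_real_
    }
    rownames(dosage) <- sprintf("rs%06d", seq_len(m))
    colnames(dosage) <- .sampleIds(n)
    variants <- data.frame(
      id = rownames(dosage), chrom = "1", pos = seq_len(m) * 500L,
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
    GenotypeData(dosage, variants)
  })
}

#' Simulate expression with planted additive cis-effects
#'
#' For gene g and sample s: `baseline + sum(beta * dosage) + N(0, noise_sd)`,
#' where missing dosages contribute their variant's mean dosage. Values are
#' shifted to be non-negative; the shift is recorded in
#' `metadata(x)$nonneg_shift` (Spearman statistics are insensitive to it).
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param config a [cohortConfig()]; its sample count must match.
#' @return An [ExpressionData-class] object.
#' @export
simulateExpression <- function(genotypes, config) {
  stopifnot(inherits(config, "CohortConfig"), methods::is(genotypes, "GenotypeData"))
  d <- dosageMatrix(genotypes)
  n <- ncol(d)
  pe <- config$planted_effects
  if (nrow(pe) && (any(pe$variant > nrow(d)) || any(pe$gene > config$n_genes)))
    stop("planted effect references an unknown variant or gene")
  withSeed(config$seed + 1L, {
    expr <- matrix(config$baseline +
                     stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                   nrow = config$n_genes, ncol = n)
    if (nrow(pe)) {
      for (k in seq_len(nrow(pe))) {
        dv <- d[pe$variant[k], ]
        if (anyNA(dv)) dv[is.na(dv)] <- mean(dv, na.rm = TRUE)
        expr[pe$gene[k], ] <- expr[pe$gene[k], ] + pe$beta[k] * dv
      }
    }
    shift <- 0
    mn <- min(expr)
    if (mn < 0) {
      shift <- -mn
      expr <- expr + shift
    }
    rownames(expr) <- .geneIds(config$n_genes)
    colnames(expr) <- colnames(d)
    out <- ExpressionData(expr)
    S4Vectors::metadata(out)$nonneg_shift <- shift
    out
  })
}

#' Simulate feature intervals, precomputed eQTL and annotation catalogs
#'
#' Emits feature intervals of each class covering a `feature_density` fraction
#' of variants; binding sites carry a target gene and miRNA family (planted
#' eQTL variants are guaranteed a binding site targeting their planted gene);
#' lincRNA intervals include decoys below, within and above the 200 bp-100 kb
#' length window so the length filter is exercised. The precomputed tissue
#' eQTL table contains the planted pairs (small p) plus decoys, and the
#' annotation table covers both catalog layouts, hitting an
#' `annotation_hit_rate` fraction of planted SNPs directly plus records that
#' hit only within-block LD partners of planted SNPs.
#'
#' @param genotypes a [GenotypeData-class] from [simulateGenotypes()].
#' @param config the same [cohortConfig()].
#' @return list with `features` (`GRanges`), `precomputed_eqtl`
#'   (data.frame: snp_id, gene_id, tissue, slope, p) and `annotations`
#'   (data.frame: snp_id, source, trait_or_drug, gene).
#' @export
simulateFeaturesAndAnnotations <- function(genotypes, config) {
  stopifnot(inherits(config, "CohortConfig"), methods::is(genotypes, "GenotypeData"))
  vi <- variantInfo(genotypes)
  m <- nrow(vi)
  genes <- .geneIds(config$n_genes)
  pe <- config$planted_effects
  withSeed(config$seed + 2L, {
    k <- round(config$feature_density * m)
    pick <- function(k, must = integer()) {
      extra <- setdiff(seq_len(m), must)
      out <- must
      if (k > length(out))
        out <- c(out, sort(sample(extra, k - length(out))))
      sort(out)
    }

    feats <- list()
    if (k > 0 || nrow(pe)) {
      ## miRNA seeds: short (7 bp) intervals centered on the variant
      si <- pick(k)
      if (length(si))
        feats$seed <- data.frame(
          chrom = vi$chrom[si], start = vi$pos[si] - 4L, end = vi$pos[si] + 3L,
          feature_id = sprintf("seed%04d", seq_along(si)),
          feature_class = "mirna_seed", strand = "+",
          target_gene = NA_character_,
          mirna_family = sprintf("miR-%d", 100L + seq_along(si))
        )
      ## binding sites: planted variants always get a site targeting their gene
      bi <- pick(k, must = unique(pe$variant))
      if (length(bi)) {
        tg <- genes[1L + (bi %% config$n_genes)]
        if (nrow(pe)) {
          hit <- match(pe$variant, bi)
          tg[hit] <- genes[pe$gene]
        }
        feats$bs <- data.frame(
          chrom = vi$chrom[bi], start = vi$pos[bi] - 3L, end = vi$pos[bi] + 4L,
          feature_id = sprintf("site%04d", seq_along(bi)),
          feature_class = "mirna_binding_site", strand = "+",
          target_gene = tg,
          mirna_family = sprintf("miR-%d-5p", 200L + seq_along(bi))
        )
      }
      ## lincRNAs: length 800 (inside the 200 bp-100 kb window), one per
      ## chosen variant
      li <- pick(k)
      if (length(li))
        feats$linc <- data.frame(
          chrom = vi$chrom[li], start = pmax(0L, vi$pos[li] - 400L),
          end = pmax(0L, vi$pos[li] - 400L) + 800L,
          feature_id = sprintf("linc%04d", seq_along(li)),
          feature_class = "lincrna", strand = "+",
          target_gene = NA_character_, mirna_family = NA_character_
        )
    }
    ## decoy lincRNAs in the three length strata (below / within / above the
    ## 200 bp-100 kb window), placed beyond the variant positions
    far <- max(vi$pos) + 10000L
    if (k > 0 || nrow(pe)) feats$decoy <- data.frame(
      chrom = "1",
      ## lengths: 150 (below), 200 and 100000 (boundaries), 3000 (within),
      ## 150000 (above)
      start = far + c(0L, 1000L, 2000L, 200000L, 500000L),
      end = far + c(150L, 1200L, 5000L, 300000L, 650000L),
      feature_id = sprintf("linc_decoy%02d", 1:5),
      feature_class = "lincrna", strand = "+",
      target_gene = NA_character_, mirna_family = NA_character_
    )
    features <- if (length(feats)) {
      fdf <- do.call(rbind, feats)
      featureIntervals(
        chrom = fdf$chrom, start = fdf$start, end = fdf$end,
        feature_id = fdf$feature_id, feature_class = fdf$feature_class,
        strand = fdf$strand, target_gene = fdf$target_gene,
        mirna_family = fdf$mirna_family
      )
    } else {
      featureIntervals(character(), integer(), integer(), character(),
                       character())
    }

    ## precomputed tissue-eQTL: planted pairs with tiny p, plus decoys
    tissues <- c("thyroid", "testis")
    eq <- list()
    if (nrow(pe))
      eq$planted <- data.frame(
        snp_id = vi$id[pe$variant], gene_id = genes[pe$gene],
        tissue = tissues[1L + (seq_len(nrow(pe)) %% 2L)],
        slope = pe$beta, p = 1e-8
      )
    nd <- max(10L, nrow(pe))
    dv <- sample.int(m, nd, replace = TRUE)
    dg <- sample.int(config$n_genes, nd, replace = TRUE)
    keep <- !(paste(dv, dg) %in% paste(pe$variant, pe$gene))
    eq$decoy <- data.frame(
      snp_id = vi$id[dv[keep]], gene_id = genes[dg[keep]],
      tissue = sample(tissues, sum(keep), replace = TRUE),
      slope = stats::rnorm(sum(keep), sd = 0.2),
      p = stats::runif(sum(keep), 0.2, 1)
    )
    precomputed <- do.call(rbind, eq)
    rownames(precomputed) <- NULL

    ## clinical annotations: direct hits on planted SNPs at annotation_hit_rate,
    ## alternating catalog layouts, plus records hitting only within-block LD
    ## partners of planted SNPs (exercises the indirect join)
    ann <- list()
    if (nrow(pe)) {
      nhit <- ceiling(config$annotation_hit_rate * nrow(pe))
      if (nhit > 0) {
        hi <- seq_len(nhit)
        ann$direct <- data.frame(
          snp_id = vi$id[pe$variant[hi]],
          source = rep(c("gwas", "pharmgkb"), length.out = nhit),
          trait_or_drug = sprintf("trait_%s", genes[pe$gene[hi]]),
          gene = genes[pe$gene[hi]]
        )
      }
      ## proxy-only records: annotate the strongest same-block LD partner of
      ## each planted SNP (never a planted SNP itself, never a site with
      ## undefined LD)
      dos <- dosageMatrix(genotypes)
      blk <- function(v) ceiling(v / config$ld_block_size)
      proxies <- vapply(pe$variant, function(v) {
        cand <- setdiff(which(blk(seq_len(m)) == blk(v)), pe$variant)
        if (!length(cand)) return(NA_integer_)
        r2s <- vapply(cand, function(j) ldR2(dos[v, ], dos[j, ])$r2,
                      numeric(1))
        if (all(is.na(r2s))) return(NA_integer_)
        cand[which.max(r2s)]
      }, integer(1))
      ok <- !is.na(proxies)
      if (any(ok))
        ann$proxy <- data.frame(
          snp_id = vi$id[proxies[ok]],
          source = "gwas",
          trait_or_drug = sprintf("proxy_trait_%02d", which(ok)),
          gene = NA_character_
        )
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(snp_id = character(), source = character(),
                 trait_or_drug = character(), gene = character())
    annotations <- unique(annotations)
    rownames(annotations) <- NULL

    list(features = features, precomputed_eqtl = precomputed,
         annotations = annotations)
  })
}

#' Generate a complete synthetic cohort and write it to disk
#'
#' Runs the three simulators and writes every pipeline input in its standard
#' external format: genotypes as minimal VCF v4.2, expression and features as
#' TSV, the precomputed tissue-eQTL table and both annotation-catalog layouts
#' as TSV. Identical configs produce byte-identical files.
#'
#' @param config a [cohortConfig()].
#' @param dir output directory (created if missing).
#' @return Named list of file paths plus the in-memory objects (invisible
#'   components `genotypes`, `expression`, `features`, `precomputed_eqtl`,
#'   `annotations`).
#' @export
writeCohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gd <- simulateGenotypes(config)
  ex <- simulateExpression(gd, config)
  fa <- simulateFeaturesAndAnnotations(gd, config)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    features = file.path(dir, "features.tsv"),
    precomputed_eqtl = file.path(dir, "eqtl_tissues.tsv"),
    gwas = file.path(dir, "annotations_gwas.tsv"),
    pharmgkb = file.path(dir, "annotations_pharmgkb.tsv")
  )
  writeGenotypesVcf(gd, paths$vcf)
  writeExpressionTsv(ex, paths$expression)
  writeFeaturesTsv(fa$features, paths$features)
  writePrecomputedEqtlTsv(fa$precomputed_eqtl, paths$precomputed_eqtl)
  writeAnnotationsTsv(fa$annotations, paths$gwas, layout = "gwas")
  writeAnnotationsTsv(fa$annotations, paths$pharmgkb, layout = "pharmgkb")
  c(paths, list(genotypes = gd, expression = ex, features = fa$features,
                precomputed_eqtl = fa$precomputed_eqtl,
                annotations = fa$annotations))
}
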