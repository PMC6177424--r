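## Orchestration of the full workflow: simulate -> map -> eQTL -> LD ->
## clinical join -> networks -> knockout, from one declarative config, with a
## manifest (hashes, parameters, row counts, timings, seed) sufficient to
## reproduce a run byte-for-byte.

#' Pipeline run configuration
#'
#' @param outdir output directory for all artifacts.
#' @param cohort a [cohortConfig()] describing the synthetic inputs; when
#'   `inputs` is supplied instead, existing files are used and the simulate
#'   stage is skipped.
#' @param inputs optional named list of existing input paths (`vcf`,
#'   `expression`, `features`, `precomputed_eqtl`, `gwas`, `pharmgkb`).
#' @param alpha adjusted-p significance threshold (inclusive).
#' @param ld_threshold minimum LD R-squared (inclusive).
#' @param linc_min_len,linc_max_len lincRNA length window in bases
#'   (exclusive bounds).
#' @param z_cut effect-size outlier threshold (strict absolute z).
#' @param knockout_mode `"nodes"` or `"edge"`.
#' @param seed integer seed for every stochastic stage.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(outdir, cohort = cohortConfig(), inputs = NULL,
                      alpha = 0.05, ld_threshold = 0.8, linc_min_len = 200,
                      linc_max_len = 100000, z_cut = 2,
                      knockout_mode = c("nodes", "edge"), seed = 1L) {
  knockout_mode <- match.arg(knockout_mode)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (ld_threshold <= 0 || ld_threshold > 1)
    stop("ld_threshold must be in (0, 1]")
  if (linc_min_len >= linc_max_len) stop("linc_min_len must be < linc_max_len")
  cfg <- list(outdir = outdir, cohort = cohort, inputs = inputs, alpha = alpha,
              ld_threshold = ld_threshold, linc_min_len = linc_min_len,
              linc_max_len = linc_max_len, z_cut = z_cut,
              knockout_mode = knockout_mode, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [runConfig()] arguments; the `cohort` key holds
#' [cohortConfig()] arguments (with `planted_effects` as a list of
#' `{variant, gene, beta}` records).
#'
#' @param path YAML file.
#' @param outdir optional override of the config's output directory.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohortConfig, c(
    y$cohort[setdiff(names(y$cohort), "planted_effects")],
    if (!is.null(y$cohort$planted_effects))
      list(planted_effects = data.table::rbindlist(y$cohort$planted_effects))
  ))
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- cohort
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(runConfig, args)
}

.stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  manifest$stages[[name]] <- list(
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
    rows = if (is.data.frame(value)) nrow(value)
           else if (methods::is(value, "AssociationNetwork"))
             nrow(netEdges(value))
           else NA_integer_
  )
  message("[", name, "] done")
  value
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes all intermediate artifacts under
#' `config$outdir`, and returns (and writes as JSON) a manifest with input
#' hashes, parameter values, per-stage row counts and wall times, and the
#' seed. Any stage failure aborts with the stage name; completed artifacts
#' are preserved.
#'
#' @param config a [runConfig()] (or path to a YAML accepted by
#'   [readRunConfig()]).
#' @return Invisibly, a list with the manifest and the main in-memory results
#'   (`catalog`, `eqtl`, `precomputed`, `ld`, `hits`, `mirna_net`,
#'   `lincrna_net`, `knockout_mirna`, `knockout_lincrna`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new.env()
  manifest$stages <- list()

  ## stage: simulate (or ingest existing inputs)
  if (is.null(config$inputs)) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    paths <- .stage(manifest, "simulate",
                    writeCohort(cohort, file.path(config$outdir, "inputs")))
  } else {
    paths <- config$inputs
  }

  ## stage: read inputs through the format layer
  genotypes <- .stage(manifest, "read_vcf", readGenotypesVcf(paths$vcf))
  expression <- .stage(manifest, "read_expression",
                       readExpressionTsv(paths$expression))
  features <- .stage(manifest, "read_features", readFeaturesTsv(paths$features))
  precomputed <- .stage(manifest, "read_precomputed_eqtl",
                        readPrecomputedEqtl(paths$precomputed_eqtl))
  annotations <- .stage(manifest, "read_annotations",
                        readAllAnnotations(paths$gwas, paths$pharmgkb))

  ## stage: feature catalog (lincRNA length filter, then overlap)
  features <- filterLincrnas(features, config$linc_min_len, config$linc_max_len)
  catalog <- .stage(manifest, "map", mapSnpsToFeatures(genotypes, features))
  data.table::fwrite(catalog, file.path(config$outdir, "snp_feature_map.tsv"),
                     sep = "\t")

  ## stage: cohort eQTL scan over binding-site SNP/target-gene pairs
  bs <- catalog[catalog$feature_class == "mirna_binding_site", ]
  pairs <- unique(data.table::data.table(snp_id = bs$snp_id,
                                         gene_id = bs$target_gene))
  pairs <- pairs[pairs$gene_id %in% rownames(exprMatrix(expression)), ]
  eqtl <- .stage(manifest, "eqtl",
                 runEqtlScan(genotypes, expression, pairs,
                             alpha = config$alpha, seed = config$seed))
  data.table::fwrite(eqtl, file.path(config$outdir, "eqtl_cohort.tsv"),
                     sep = "\t")

  ## stage: precomputed tissue-eQTL significance + effect-size outliers
  precomputed <- flagPrecomputedSignificant(precomputed, alpha = config$alpha)
  precomputed <- .stage(manifest, "outliers",
                        flagEffectOutliers(precomputed, "tissue",
                                           z_cut = config$z_cut))
  data.table::fwrite(precomputed,
                     file.path(config$outdir, "eqtl_tissues_flagged.tsv"),
                     sep = "\t")

  ## pooled significant eQTL (cohort arm + precomputed arm)
  sigPool <- data.table::rbindlist(list(
    eqtl[eqtl$significant,
         c("snp_id", "gene_id", "tissue", "p_adj", "significant")],
    precomputed[precomputed$significant,
                c("snp_id", "gene_id", "tissue", "p_adj", "significant")]
  ))
  sigPool <- unique(sigPool)

  ## stage: LD partners of every significant eQTL SNP
  ld <- .stage(manifest, "ld",
               if (nrow(sigPool))
                 ldPartners(unique(sigPool$snp_id), genotypes,
                            threshold = config$ld_threshold)
               else data.table::data.table(snp_a = character(),
                                           snp_b = character(),
                                           r2 = numeric(),
                                           n_used = integer()))
  data.table::fwrite(ld, file.path(config$outdir, "ld_pairs.tsv"), sep = "\t")

  ## stage: clinical joins (direct + LD-mediated)
  hits <- .stage(manifest, "annotate",
                 clinicalHits(sigPool, annotations, ld,
                              threshold = config$ld_threshold))
  data.table::fwrite(hits, file.path(config$outdir, "clinical_hits.tsv"),
                     sep = "\t")

  ## stage: networks; each model gets the hits whose SNP is in its catalog class
  snpClass <- function(cls)
    tolower(catalog$snp_id[catalog$feature_class == cls])
  mirnaHits <- hits[hits$snp_id %in% snpClass("mirna_binding_site"), ]
  lincHits <- hits[hits$snp_id %in% snpClass("lincrna"), ]
  mirnaNet <- .stage(manifest, "network_mirna",
                     buildMirnaNetwork(mirnaHits, catalog, sigPool,
                                       annotations, ld, config$ld_threshold))
  lincNet <- .stage(manifest, "network_lincrna",
                    buildLincrnaNetwork(lincHits, catalog, sigPool,
                                        annotations, ld, config$ld_threshold))
  for (nm in c("mirna", "lincrna")) {
    net <- if (nm == "mirna") mirnaNet else lincNet
    writeNetwork(net, file.path(config$outdir, paste0("network_", nm, ".sif")),
                 "sif")
    writeNetwork(net,
                 file.path(config$outdir, paste0("network_", nm, ".graphml")),
                 "graphml")
    data.table::fwrite(componentSummary(net),
                       file.path(config$outdir,
                                 paste0("network_", nm, "_components.tsv")),
                       sep = "\t")
  }

  ## stage: knockout scans
  emptyKo <- data.table::data.table(
    snp_id = character(), gene_id = character(), mode = character(),
    components_before = integer(), components_after = integer())
  koM <- .stage(manifest, "knockout_mirna", {
    if (any(netEdges(mirnaNet)$relation %in%
            c("sig_eQTL", "located_in_sig_eQTL")))
      knockoutScan(mirnaNet, config$knockout_mode)
    else emptyKo
  })
  koL <- .stage(manifest, "knockout_lincrna", {
    if (any(netEdges(lincNet)$relation %in%
            c("sig_eQTL", "located_in_sig_eQTL")))
      knockoutScan(lincNet, config$knockout_mode)
    else emptyKo
  })
  data.table::fwrite(koM, file.path(config$outdir, "knockout_mirna.tsv"),
                     sep = "\t")
  data.table::fwrite(koL, file.path(config$outdir, "knockout_lincrna.tsv"),
                     sep = "\t")

  ## manifest: parameters, per-stage counts/timings, artifact hashes, seed
  artifacts <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[!grepl("manifest\\.json$", artifacts)]
  hashes <- as.list(tools::md5sum(sort(artifacts)))
  names(hashes) <- substring(names(hashes), nchar(config$outdir) + 2L)
  man <- list(
    parameters = list(alpha = config$alpha, ld_threshold = config$ld_threshold,
                      linc_len = c(config$linc_min_len, config$linc_max_len),
                      z_cut = config$z_cut,
                      knockout_mode = config$knockout_mode,
                      seed = config$seed),
    stages = manifest$stages,
    artifact_md5 = hashes
  )
  jsonlite::write_json(man, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = man, catalog = catalog, eqtl = eqtl,
                 precomputed = precomputed, ld = ld, hits = hits,
                 mirna_net = mirnaNet, lincrna_net = lincNet,
                 knockout_mirna = koM, knockout_lincrna = koL))
}
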