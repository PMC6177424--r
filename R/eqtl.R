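## Step 2 of the workflow: cohort Spearman eQTL scan with Benjamini-Hochberg
## correction, OLS effect sizes, ingestion of precomputed tissue-eQTL and
## per-tissue effect-size outlier flagging.

#' Spearman rank correlation for one SNP-gene pair
#'
#' Pairs with a missing value in either vector are dropped (pairwise
#' complete-case). Rho is the Pearson correlation of mid-ranks (average ranks
#' for ties); the two-sided p-value uses the large-sample t approximation with
#' `n_used - 2` degrees of freedom. Pairs with fewer than 3 usable samples or
#' a constant vector are untestable (`testable = FALSE`, rho/p `NA`) and are
#' excluded from the multiple-testing family by [runEqtlScan()].
#'
#' @param dosage,expression paired numeric vectors over the same samples.
#' @return list with `rho`, `p`, `n_used`, `testable`.
#' @export
spearmanRho <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  x <- dosage[ok]
  y <- expression[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n_used = n, testable = FALSE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n_used = n, testable = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values satisfy `q >= p` elementwise and `q <= 1`; the family is
#' whatever vector is passed in (in a scan: all testable SNP-gene pairs).
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) && (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Ordinary-least-squares effect size
#'
#' Slope of expression regressed on alternative-allele dosage: the change in
#' expression per additional alternative-allele copy. Pairs with missing
#' values are dropped; zero dosage variance yields `NA`.
#'
#' @inheritParams spearmanRho
#' @return The slope (numeric scalar, `NA` if undefined).
#' @export
olsSlope <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  x <- dosage[ok]
  y <- expression[ok]
  if (length(x) < 2L || stats::var(x) == 0) return(NA_real_)
  unname(stats::lm.fit(cbind(1, x), y)$coefficients[2])
}

.permutationP <- function(x, y, rho_obs, permutations) {
  hits <- 0L
  rx <- rank(x)
  ry <- rank(y)
  for (i in seq_len(permutations)) {
    r <- stats::cor(rx, sample(ry))
    if (abs(r) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (permutations + 1)
}

#' Run the cohort eQTL scan
#'
#' For each candidate SNP-gene pair, computes the Spearman correlation between
#' dosage and expression over the shared samples, the OLS slope, and a raw
#' p-value; BH-adjusts over the family of all testable pairs and flags
#' significance at `p_adj <= alpha`. Untestable pairs (too few samples or a
#' constant vector) are reported with `testable = FALSE` and excluded from the
#' family. Output is deterministically ordered by (`snp_id`, `gene_id`).
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param expression an [ExpressionData-class] object; samples are intersected
#'   with the genotypes.
#' @param pairs data.frame with columns `snp_id`, `gene_id` (e.g. derived from
#'   [mapSnpsToFeatures()] binding-site rows and their target genes).
#' @param alpha adjusted-p significance threshold (inclusive; default 0.05).
#' @param permutations if > 0, p-values come from a seeded permutation test
#'   with this many permutations instead of the t approximation (intended for
#'   small cohorts).
#' @param seed RNG seed for the permutation test.
#' @return data.table of eQTL results: `snp_id`, `gene_id`, `tissue` (empty
#'   for the cohort arm), `n_used`, `rho`, `slope`, `p`, `p_adj`,
#'   `significant`, `testable`.
#' @export
runEqtlScan <- function(genotypes, expression, pairs, alpha = 0.05,
                        permutations = 0L, seed = 1L) {
  pairs <- unique(data.table::as.data.table(pairs)[, c("snp_id", "gene_id")])
  d <- dosageMatrix(genotypes)
  e <- exprMatrix(expression)
  shared <- intersect(colnames(d), colnames(e))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  d <- d[, shared, drop = FALSE]
  e <- e[, shared, drop = FALSE]
  bad <- setdiff(pairs$snp_id, rownames(d))
  if (length(bad)) stop("unknown SNP id(s) in pairs: ",
                        paste(utils::head(bad), collapse = ", "))
  bad <- setdiff(pairs$gene_id, rownames(e))
  if (length(bad)) stop("unknown gene id(s) in pairs: ",
                        paste(utils::head(bad), collapse = ", "))
  runScan <- function() {
    res <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      x <- d[pairs$snp_id[i], ]
      y <- e[pairs$gene_id[i], ]
      s <- spearmanRho(x, y)
      if (s$testable && permutations > 0L) {
        ok <- !is.na(x) & !is.na(y)
        s$p <- .permutationP(x[ok], y[ok], s$rho, permutations)
      }
      res[[i]] <- data.table::data.table(
        snp_id = pairs$snp_id[i], gene_id = pairs$gene_id[i], tissue = "",
        n_used = s$n_used, rho = s$rho, slope = olsSlope(x, y), p = s$p,
        testable = s$testable
      )
    }
    data.table::rbindlist(res)
  }
  out <- if (permutations > 0L) withSeed(seed, runScan()) else runScan()
  if (nrow(out) == 0L || !any(out$testable)) {
    warning("no testable SNP-gene pairs")
    out$p_adj <- numeric(nrow(out))
    out$significant <- logical(nrow(out))
  } else {
    out$p_adj <- NA_real_
    out$p_adj[out$testable] <- bhAdjust(out$p[out$testable])
    out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  }
  data.table::setorder(out, snp_id, gene_id)
  data.table::setcolorder(out, c("snp_id", "gene_id", "tissue", "n_used",
                                 "rho", "slope", "p", "p_adj", "significant",
                                 "testable"))
  out[]
}

#' Flag effect-size outliers in a precomputed eQTL table
#'
#' Within each group (tissue by default), computes `z = (slope - mean) / sd`
#' (sample standard deviation, denominator n-1) and flags rows with `z > 2` or
#' `z < -2` (strict). Groups with fewer than 2 rows or zero slope spread get
#' `NA` z-scores, are flagged non-outlier, and trigger a warning.
#'
#' @param eqtl data.frame with at least `slope` and the grouping column.
#' @param group_col grouping column name (default `"tissue"`).
#' @param z_cut absolute z threshold (strict; default 2).
#' @return The table with added `z` and `outlier` columns.
#' @export
flagEffectOutliers <- function(eqtl, group_col = "tissue", z_cut = 2) {
  dt <- data.table::as.data.table(eqtl)
  if (!group_col %in% colnames(dt)) stop("unknown grouping column: ", group_col)
  grp <- as.character(dt[[group_col]])
  dt$z <- NA_real_
  degenerate <- character()
  for (g in unique(grp)) {
    sel <- grp == g
    s <- dt$slope[sel]
    if (sum(sel) < 2L || stats::sd(s) == 0) {
      degenerate <- c(degenerate, g)
      next
    }
    dt$z[sel] <- (s - mean(s)) / stats::sd(s)
  }
  if (length(degenerate))
    warning("degenerate group(s) with undefined z-scores: ",
            paste(degenerate, collapse = ", "))
  dt$outlier <- !is.na(dt$z) & abs(dt$z) > z_cut
  dt[]
}

#' Flag significant rows of a precomputed eQTL table
#'
#' BH-adjusts the table's p-values as one family and flags
#' `p_adj <= alpha`.
#'
#' @param eqtl data.frame with columns `snp_id`, `gene_id`, `tissue`,
#'   `slope`, `p`.
#' @param alpha adjusted-p threshold (inclusive).
#' @return The table with added `p_adj` and `significant` columns.
#' @export
flagPrecomputedSignificant <- function(eqtl, alpha = 0.05) {
  dt <- data.table::as.data.table(eqtl)
  dt$p_adj <- if (nrow(dt)) bhAdjust(dt$p) else numeric()
  dt$significant <- nrow(dt) > 0 & dt$p_adj <= alpha
  dt[]
}
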