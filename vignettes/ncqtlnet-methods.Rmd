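---
title: "Methods: from ncRNA-linked variants to clinical association networks"
author: "ncqtlnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ncRNA-linked variants to clinical association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(ncqtlnet))
```

## The problem

Genetic variants that fall inside non-coding regulatory elements — microRNA
seed regions, the miRNA-binding sites they recognize in mRNAs, and long
intergenic non-coding RNA (lincRNA) genes — can perturb post-transcriptional
regulation without changing any protein sequence. `ncqtlnet` implements a
complete workflow for asking whether such variants measurably affect gene
expression and whether the resulting eQTL connect to traits of clinical or
pharmacological relevance:

1. **Catalog** SNPs overlapping miRNA seeds, miRNA-binding sites, and
   length-filtered lincRNA genes.
2. **Scan** cataloged SNP–gene pairs for expression associations (Spearman
   rank correlation, Benjamini–Hochberg control), and ingest precomputed
   tissue-eQTL tables with effect-size (regression slope) outlier flagging.
3. **Join** significant eQTL to GWAS-style and pharmacogenomic annotation
   catalogs, directly by rsid and indirectly through high-LD proxy SNPs.
4. **Model** the results as typed multi-graph association networks and probe
   their robustness by iterative eQTL knockout.

Because the real inputs for such a study (genome-scale SNP catalogs, cohort
genotypes and RNA-seq, tissue eQTL compendia, clinical catalogs) are huge and
heterogeneous, the package ships a seeded synthetic-cohort generator that
emulates their statistical structure at desk scale. Every pipeline stage is
exercised — and every statistical claim tested — against these synthetic
cohorts with planted, known effects.

## The statistical core

### Spearman eQTL scan

For a biallelic SNP with alternative-allele dosage $d_i \in \{0,1,2\}$ and a
gene with abundance $y_i$ over samples $i = 1,\dots,n$, the association
statistic is the Spearman rank correlation: the Pearson correlation of
mid-ranks (average ranks under ties). The two-sided p-value uses the
large-sample t approximation,

$$ t = \rho \sqrt{\frac{n-2}{1-\rho^2}}, \qquad t \sim t_{n-2}, $$

which is standard practice at cohort sizes of a few hundred. A seeded
permutation p-value is available (`permutations` argument of
`runEqtlScan()`) for small cohorts where the approximation is doubtful.
Samples with missing dosage are dropped pairwise; a pair is *untestable* when
fewer than 3 usable samples remain or either vector is constant, and
untestable pairs are reported but excluded from the multiple-testing family.

Multiple testing is controlled with the Benjamini–Hochberg step-up procedure
(`stats::p.adjust`, surfaced as `bhAdjust()`), with **one family per scan**:
all testable pairs of one analysis arm are adjusted together. Significance is
declared at $p_{adj} \le 0.05$ (inclusive). Effect sizes are
ordinary-least-squares slopes of expression on dosage: expression units per
additional alternative-allele copy, signed relative to the reference allele.

### Precomputed tissue-eQTL and outliers

Tissue-eQTL tables arrive with slopes and p-values already computed; the
package BH-adjusts them as one family, flags significance the same way, and
computes per-tissue effect-size z-scores
$z = (\beta - \bar\beta)/s_\beta$ (sample SD). A row is an outlier iff
$|z| > 2$, strictly: a z-score of exactly 2 is not an outlier.

### Linkage disequilibrium

LD between two SNPs is the squared Pearson correlation of their dosage
vectors over pairwise-complete samples — *composite* (genotypic) LD, which
needs no phasing and agrees with haplotypic $r^2$ under Hardy–Weinberg
equilibrium. Partners are enumerated at $r^2 \ge 0.8$ (inclusive), genome
wide by default; a basepair window is available. Pairs where either vector is
constant have undefined LD and are skipped rather than coerced to 0.

### Clinical joins and networks

Annotation matching is by rsid only (normalized to lowercase `rs…`); trait,
drug and gene strings are payload, never join keys. A *direct* hit pairs a
significant eQTL with an annotation on its own SNP; an *LD* hit pairs it with
an annotation on a high-LD partner, recording the proxy and its $r^2$. A SNP
annotated itself is never additionally reported as its own proxy.

Networks are typed multi-graphs with node roles partitioning the node set
(`snp`, `gene`, `mirna` or `lincrna`, `phenotype`) and seven labeled edge
relations with hard endpoint contracts, enforced by the S4 validity method:

| relation | endpoints | directed |
|---|---|---|
| `located_in` | snp → gene/mirna/lincrna | yes |
| `located_in_sig_eQTL` | snp → gene | yes |
| `sig_eQTL` | snp → gene | yes |
| `sig_associated_with` | snp → phenotype | yes |
| `associated_with` | gene/lincrna → phenotype | yes |
| `regulated_by` | gene → mirna | yes |
| `LD` | snp – snp | no (stored once, sorted endpoints) |

In the miRNA network, a SNP lying in a binding site of a gene with which it
also forms a significant eQTL gets the fused `located_in_sig_eQTL` label; the
plain labels are used otherwise. lincRNAs have no predicted gene targets, so
the lincRNA network never contains a lincRNA–gene edge: a SNP is
`located_in` its lincRNA and separately `sig_eQTL`-linked to genes.

Sub-networks are connected components of the underlying undirected simple
graph (direction and edge multiplicity ignored for connectivity; multi-edges
still counted per component), ordered by size with ties broken by smallest
node id.

### Knockout scan

The perturbation scan removes each distinct eQTL pair in turn from a fresh
copy of the network and recounts components. The default mode removes **both
endpoint nodes** (SNP and gene) with all incident edges. This is the
interpretation under which a single knockout can change the component count
by more than one — e.g. removing one hub eQTL from a k-gene star yields
$k-1$ components, and every eQTL sharing that hub SNP has identical impact —
which is the qualitative behaviour the scan is designed to expose. The
alternative `mode = "edge"` removes only the pair's eQTL edges and can
increase the count by at most one per removed edge; it is retained as an
option and recorded in the report. Nodes isolated by a knockout are kept and
counted as size-1 components, so the accounting is deterministic and
order-independent.

## The synthetic cohort generator

`cohortConfig()` + `simulateGenotypes()` / `simulateExpression()` /
`simulateFeaturesAndAnnotations()` generate every input the pipeline reads,
deterministically per seed.

* **Genotypes.** Variants are partitioned into LD blocks. Per block,
  `n_haplotypes_per_block` founder haplotypes are drawn with per-site
  alternative-allele frequency uniform in `maf_range`; each sample resamples
  two founders with replacement and dosage is their sum. Founder resampling
  guarantees valid dosages and tunable LD: 2 founders force $r^2 = 1$ between
  segregating sites of a block, a deep pool approaches linkage equilibrium.
  The default of 4 founders per 10-variant block mimics the handful of common
  haplotypes seen in real human LD blocks. Blocks are independent, so LD
  decays across block boundaries by construction. Missingness is masked in
  completely at random at `missing_rate`.
* **Expression.** Gaussian noise on an RPKM-like scale around a constant
  baseline, plus additive planted cis-effects `beta × dosage`; missing
  dosages contribute the variant's mean dosage. The matrix is shifted to be
  non-negative with the shift recorded; rank statistics are unaffected.
* **Features.** Each class covers a `feature_density` fraction of variants.
  Binding sites carry target gene and miRNA family, and every planted
  (variant, gene) pair is guaranteed a binding site targeting its gene so
  planted effects are cis by construction. Generated lincRNA lengths span
  below, at, inside and above the 200 bp–100 kb filter window so the length
  filter is genuinely exercised.
* **Catalogs.** The precomputed tissue-eQTL table contains the planted pairs
  (tiny p) plus decoys; annotation records hit an `annotation_hit_rate`
  fraction of planted SNPs directly (alternating GWAS-style and
  pharmacogenomics-style layouts) plus records that hit only the strongest
  same-block LD partner of a planted SNP, to exercise the indirect join.

**What the generator does not emulate:** realistic human haplotype maps,
population stratification, multi-allelic sites, expression covariates (batch,
ancestry), informative missingness. Passing tests therefore demonstrate
correctness of the statistics and the pipeline plumbing under a clean
additive model, not robustness to confounding in real cohorts; in particular
the scan fits no covariates, matching a plain Spearman design.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | adjusted-p significance threshold (inclusive) |
| `ld_threshold` | 0.8 | minimum $r^2$ for LD edges/proxies (inclusive) |
| `linc_min_len`, `linc_max_len` | 200, 100000 bases | lincRNA length window, strict bounds |
| `z_cut` | 2 | effect-size outlier threshold, strict |
| `knockout_mode` | `nodes` | what an eQTL removal deletes |
| `maf_range` | (0.05, 0.5) | per-site alternative-allele frequency range |
| `ld_block_size` / `n_haplotypes_per_block` | 10 / 4 | LD block geometry and strength |
| `noise_sd` | 1 | expression noise, RPKM-like units |
| `missing_rate` | 0.02 | genotype missingness |

## Numerical and design choices

* **lincRNA length bounds are strict**: lengths of exactly 200 or 100000
  bases are excluded. Both bounds are configurable.
* **Coordinates.** VCF positions are 1-based; BED-style feature files are
  0-based half-open. Internally intervals live in `GRanges`, converted at the
  boundary so that an interval's `width()` equals its 0-based length and a
  SNP at VCF position `pos` occupies exactly the base `[pos-1, pos)`.
* **Ties** take mid-ranks; **missingness** is handled by pairwise
  complete-case deletion throughout.
* **Degenerate inputs signal, never guess**: constant vectors yield
  untestable pairs (excluded from the BH family), undefined LD (pair
  skipped), or undefined z (flagged non-outlier with a warning).
* **Determinism.** Every stochastic routine is seeded; one run seed drives
  all stages, and the pipeline manifest records parameters, per-stage row
  counts and wall times, and MD5 hashes of every artifact, so identical
  configurations reproduce byte-identical outputs.
* **Problem sizes.** The bundled analyses run at desk scale: demo cohorts of
  200–373 samples and a few hundred variants, FDR calibration over tens of
  replicate cohorts of 500 pairs, effect-size recovery over tens to hundreds
  of single-variant replicates. These sizes give Monte-Carlo errors well
  inside the tolerances asserted by the test suite.

## Worked example

```{r example, eval = FALSE}
library(ncqtlnet)

cfg <- runConfig(
  outdir = "demo_run",
  cohort = cohortConfig(
    n_samples = 200, n_variants = 300, n_genes = 50,
    planted_effects = data.frame(variant = c(5, 65, 125, 185, 245),
                                 gene = c(1, 11, 21, 31, 41), beta = 0.8),
    annotation_hit_rate = 1, seed = 11),
  alpha = 0.05, ld_threshold = 0.8, seed = 11)

res <- runPipeline(cfg)
sum(res$eqtl$significant)          # significant cohort eQTL
res$hits                           # direct and LD-mediated clinical hits
res$mirna_net                      # typed multi-graph
networkComponents(res$mirna_net)$summary
res$knockout_mirna                 # perturbation impact per eQTL
```

## Known limitations

* Trans-effects, covariate regression (PEER/ancestry components) and
  FastQTL-style permutation schemes are out of scope; the scan is the plain
  Spearman design described above.
* LD is composite $r^2$ from the analysis cohort itself, not a reference
  panel; phased haplotypic $r^2$ and $D'$ are not computed.
* Phenotype node identity is the exact trait string; no ontology collapsing.
* The VCF layer supports the GT-only biallelic-SNP subset it documents, not
  the full VCF specification.
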