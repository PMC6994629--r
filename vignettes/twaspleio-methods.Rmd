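---
title: "Methods: individual-level TWAS and cross-trait pleiotropy in twaspleio"
author: "twaspleio authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level TWAS and cross-trait pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

A transcriptome-wide association study (TWAS) at the individual level asks,
for every gene and tissue, whether the *genetically regulated* component of
that gene's expression differs between cases and controls. The genetic
component (GReX) is not measured but imputed: a pre-trained per-tissue eQTL
model supplies a sparse set of variants with weights, and each sample's GReX
is the weighted sum of its effect-allele dosages. GReX is then regressed on
disease status with covariate adjustment, p-values from all gene-tissue
tests are adjusted jointly by Benjamini-Hochberg, and genes significant at
Q < 0.001 are classified against known GWAS loci. A second analysis asks
whether the disease-associated genes sit in genomic regions shared with
other complex traits: each trait's genome-wide significant lead variants
are expanded to *R² loci* (the span of all reference-panel variants with
r² > 0.5 to the lead), overlapping loci are merged into candidate
pleiotropic regions, genes are assigned to trait categories by positional
overlap, and enrichment of the disease-gene list in each category is tested
with Fisher's exact test against all predictable genes.

## Expression imputation

For gene $g$ with model entries $(k, w_k)$ in a tissue, sample $i$'s score is

$$\widehat{\mathrm{GReX}}_{ig} \;=\; \sum_k w_k \, d_{ik},$$

where $d_{ik} \in [0,2]$ is the dosage of the model's *effect allele*.
Three conventions matter:

* **Allele harmonization.** Weight tables reference variants by id and
  allele pair. If the effect allele equals the panel's alternate allele the
  dosage is used as-is; if the effect/non-effect pair matches the panel's
  ref/alt the effect-allele dosage is $2-d$; any other pair is incompatible
  and the entry is dropped with a warning. Joins are by `variant_id` —
  the weight-table format carries no positions, so id plus allele check is
  the whole identity (this mirrors how PrediXcan-style tools consume
  PredictDB content). Strand-ambiguous (A/T, C/G) entries are *kept*; with
  synthetic data there is no strand uncertainty, and real-data users should
  pre-filter if their panel and models may disagree on strand.
* **Missing genotypes.** Imputation requires a complete matrix. Missing
  cells are filled per variant with the modal genotype: non-missing dosages
  are rounded half-away-from-zero to {0,1,2}, the most frequent genotype
  wins, and ties resolve to the *lower* genotype. The fill is an explicit
  step (`fill_missing_dosages()`); missingness is never silently treated
  as dosage 0.
* **No normalization.** GReX is a plain weighted sum, with no intercept or
  variance scaling. The downstream regression is scale-equivariant, so
  p-values are unaffected; keeping the raw scale makes effect sizes
  interpretable against the weights.

Entries whose variant is absent from the panel are dropped rather than
imputed; a gene with no usable entry is omitted from that tissue's matrix.

## Association model

Per gene-tissue, ordinary least squares of status on
$[1, \mathrm{GReX}, \mathrm{sex}, \mathrm{age}, \mathrm{PC1}, \mathrm{PC2}]$;
the reported effect is the GReX coefficient with its t-test p-value.
Positive $\beta$ means predicted expression is higher in cases. Three
deliberate choices:

* **Status is the outcome, GReX the predictor.** With a simple (no
  covariate) model the two-sided p is identical under role exchange; with
  covariates it is not, and the outcome-on-predictor direction is the
  convention of individual-level TWAS tools.
* **Linear, not logistic.** The linear probability model on the 0/1
  outcome is the primary specification; a per-gene logistic GLM is
  available behind `method = "logistic"` for sensitivity analysis.
* **Joint FDR.** BH runs once across *all* gene-tissue tests — not per
  tissue — after MHC genes (chr6:28,477,797–33,448,354, hg19) are removed,
  and after zero-variance (degenerate) GReX columns are excluded, so
  neither inflates the test count $m$.

Computationally the package residualizes status and all GReX columns
against the covariate design once (Frisch–Waugh–Lovell), giving
coefficients, standard errors and p-values identical to per-gene `lm()`
fits (verified against a normal-equations oracle to 1e-8) at a small
fraction of the cost; 900 gene-tissue tests on 2,000 samples take well
under a second.

Per-gene summaries pick the *strongest-effect tissue* — the largest
absolute $\beta$ over all of the gene's records, ties broken by smaller p
then lexicographic tissue name — and classify each gene as **known**
(span intersects ±1 Mb of a focal-trait lead variant on the same
chromosome) or **novel**.

## R² loci and pleiotropy

For each lead variant the locus is
$[\min_j \mathrm{pos}_j,\ \max_j \mathrm{pos}_j]$ over reference-panel
variants $j$ on the lead's chromosome with $r^2_{j,\mathrm{lead}} > 0.5$
(strict; the lead itself always qualifies). $r^2$ is the squared Pearson
correlation of genotype-dosage vectors — phased haplotype correlation from
a reference panel would differ slightly, a documented approximation. The
LD search is bounded to ±2 Mb around the lead: long-range r² > 0.5 is not
expected under the block LD model and an unbounded scan is wasted work. A
lead absent from the panel degrades to a single-position locus and is
logged.

Merging is transitive and *cross-trait before category assignment*:
intervals sharing at least one bp (1-based inclusive, so [100,200] and
[200,300] merge but [201,300] does not) are unioned along with their trait
and category label sets. Both locus generations are first-class outputs:
the raw R² loci, and a 1-Mb-extended, re-merged set mirroring the cis
window of the prediction models. At desk scale the extended loci swallow
most of the simulated genome — the same behaviour the full-scale analysis
shows when 1-Mb extensions cover three quarters of all predictable genes —
which is exactly why the raw R² loci are the set used for inference.

Category enrichment uses the two-sided Fisher exact test on the 2×2 table
{disease-associated, other predictable} × {overlaps category locus, not},
with the two-sided p defined as the sum of all hypergeometric point
probabilities not exceeding the observed one (the `fisher.test`
convention; other two-sided conventions exist and would differ slightly).
The reported odds ratio is the sample cross-product ratio. Tissue-count
comparison between in-locus and out-of-locus genes uses the two-sided
Mann-Whitney U test: exact by enumeration when the combined n is ≤ 25 with
no ties, otherwise the normal approximation with tie and continuity
correction.

## Gene-set overrepresentation

Per term: one-sided hypergeometric upper-tail p (overrepresentation
semantics — the two-sided convention above applies only to the category
tables), BH adjustment across terms through the same `bh_fdr()`
implementation, and the combined score

$$\mathrm{score} = \ln(p) \cdot z_{\mathrm{rank}},$$

where $z_{\mathrm{rank}}$ is the z-score of the term's observed rank (by
Fisher p) against the ranks it attains for random queries of the same size
drawn without replacement from the background. The rank null uses 100
random lists by default and a fixed seed; a term whose random ranks are
constant (e.g. a single term) gets z = 0. Negative z means
better-than-expected rank, so strong terms get large positive scores. The
background defaults to all predictable genes, the natural comparison
universe for a TWAS hit list.

## What the synthetic cohorts emulate — and what they do not

`simulation_config()` defines the study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_samples` | 2,000 | cohort size (desk-scale stand-in for tens of thousands) |
| `n_variants`, `ld_block_size` | 3,000 / 20 | variants at 5 kb spacing, 20-variant LD blocks |
| `within_block_correlation` | 0.9 | latent haplotype correlation inside a block |
| `maf_range` | 0.05–0.5 | one MAF per block, shared by its variants |
| `n_genes`, `n_tissues` | 300 / 3 | prediction models per tissue |
| `weights_per_gene_range` | 1–10 | sparse cis model size |
| `cis_window` | 1 Mb | window for drawing model variants around a gene |
| `n_causal_genes`, `causal_effect_size` | 0 / 0.5 | liability drivers |
| `prevalence` | 0.5 | case fraction (balanced, as in a case/control design) |
| `missing_rate` | 0.01 | missing dosage cells, exercising the modal fill |
| `flip_fraction` | 0.1 | entries whose effect allele is the panel ref |

LD is block-constant: two latent Gaussian haplotypes per sample share a
one-factor correlation $\rho$ within a block and are thresholded at the
block MAF quantile. Thresholding attenuates correlation (the phi
coefficient is below the tetrachoric $\rho$), so dosage r² at $\rho = 0.9$
sits near 0.5 at MAF 0.5 and below it for rarer alleles; the generator's
r² is validated against an independent Monte-Carlo of the same thresholded
bivariate normal rather than against $\rho$ itself. All variants of a
block share one MAF so that within-block r² is a clean monotone function
of $\rho$.

Disease status follows a liability-threshold model: liability is the sum
of each causal gene's *standardized* tissue-1 GReX times its $\alpha$
(signs alternate across causal genes), linear covariate terms
(sex ~ Bernoulli(0.5), age ~ Uniform(50, 95), PCs ~ N(0,1)), and N(0,1)
noise. Standardizing the causal GReX makes $\alpha$ a liability-SD unit,
independent of model sparsity. Status is assigned by *empirical-quantile*
thresholding — exactly $\lceil K n \rceil$ top-liability samples become
cases — so realized prevalence is exact at any n, which makes calibration
tests sharp. Because each tissue's weight model is drawn independently, a
causal gene's GReX in another tissue may be anti-correlated with the
causal score; effect-direction checks are therefore made in the
liability-defining tissue.

GWAS catalogs: trait 1 is the focal disease; its leads and those of the
configured pleiotropic traits are planted inside causal-gene spans
(constructed cross-trait overlap), remaining traits get random leads.
Leads receive p < 5e-8; the lead's LD-block mates get graded sub-threshold
p-values; everything else is Uniform(0,1).

One deliberate desk-scaling choice: simulated genes are far denser than
real genes (tens of kb apart rather than hundreds), so test scenarios
that need a clean causal/background contrast scale the cis window down
with the gene spacing (e.g. 100 kb, covering a couple of neighbours — as a
1 Mb window does at real gene density). With the full 1 Mb window on a
dense desk-scale genome, nearly every model shares cis variants with
dozens of neighbours and a large fraction of all genes becomes
significant; that is faithful to how TWAS hits cluster in loci, but it
dilutes enrichment contrasts that the scaled window preserves.

Not emulated: realistic human LD maps (block-constant LD has no decay or
long-range structure), ascertainment bias, imputation-uncertainty dosages,
cross-tissue sharing of eQTL models, population stratification beyond the
synthetic PCs, and strand ambiguity. Passing tests therefore demonstrate
the correctness and calibration of the *procedures*, not performance on
real cohort data.

## Numerical and degenerate-input conventions

* Internal coordinates are 1-based inclusive everywhere; only BED I/O
  converts (0-based half-open), and the conversion is its own inverse.
* Printed percentages round half-up (`15.765 → 15.77`), matching how such
  bookkeeping is conventionally reported; a zero denominator yields null.
* `ld_r2` of a constant dosage vector is defined as 0.
* Dosages outside [0,2] are rejected at parse time (clamp-reject, never
  silently truncated).
* A variant whose dosages are all missing is an error naming the variant.
* Degenerate (zero residual variance) GReX columns are excluded before
  FDR; the exclusion is reported, not silent.
* Every generator is a pure function of (config, seed); stage seeds are
  derived offsets so stages can be re-run independently.

## Problem sizes used by the test-suite

Calibration and recovery checks run at sizes chosen to make their
statistical assertions sharp while keeping the suite quick: null FDR
calibration uses 20 replicates of 2,000 samples × 300 genes × 3 tissues
(5,400 null tests per replicate); power/effect-direction recovery uses
4,000 samples with 20 causal genes at $\alpha = 0.5$; oracle comparisons
(imputation, BH, Fisher, Mann-Whitney, interval algebra) use hundreds to a
thousand random small instances against exhaustive or closed-form
references. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The linear probability model can predict outside [0,1]; it is kept as
  the primary specification for comparability, with the logistic option
  for sensitivity.
* Fisher two-sided p-values depend on the chosen two-sided convention;
  alternative conventions (doubling the smaller tail) give slightly
  different values.
* The rank-deviation z depends on the random-list scheme (count, sampling
  without replacement); it is a defined estimator of a loosely specified
  quantity, deterministic given its seed.
* R² from genotype dosages, not phased haplotypes.
* With very small cohorts the empirical-quantile threshold makes status
  deterministic given liability ranks, which slightly understates
  binomial variation in prevalence across replicates.
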