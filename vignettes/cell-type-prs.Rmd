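---
title: "Cell-type-partitioned polygenic risk scores from summary statistics"
author: "ctprs"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

A polygenic risk score (PRS) summarizes one trait's genetic architecture
as a weighted sum of allele doses, with weights taken from an exposure
GWAS. Partitioning the score by the cell types in which the SNPs'
proximal genes are over-expressed asks a sharper question: *through
which cell populations does the genetic risk act on an outcome trait?*
The motivating application is Alzheimer's-disease genetic risk and white
matter hyperintensity volume, where the score restricted to smooth
muscle cell (SMC) marker genes carries a markedly stronger association
than the genome-wide score. `ctprs` implements that full analysis as a
reusable, tested pipeline, and ships a synthetic-study generator so that
every stage can be validated against planted ground truth.

## The estimator

All association fitting works from per-SNP summary statistics alone.
For a SNP set with exposure weights $w_j$ (beta per dose of the coded
allele), aligned outcome betas $b_j$ and outcome standard errors $s_j$,
the score regression (the "gtx" estimator, identical to the
inverse-variance-weighted estimator of two-sample Mendelian
randomization) is the no-intercept weighted least squares fit of $b$ on
$w$ with weights $1/s_j^2$:

$$\hat\alpha = \frac{\sum_j w_j b_j / s_j^2}{\sum_j w_j^2 / s_j^2},
\qquad
\mathrm{se}(\hat\alpha) = \Big(\sum_j w_j^2/s_j^2\Big)^{-1/2},$$

tested by $\chi^2_1 = (\hat\alpha/\mathrm{se})^2$. The pseudo variance
explained uses the likelihood-ratio form
$R^2_\text{pseudo} = 1 - \exp(-\chi^2/n)$ with $n$ the outcome GWAS
sample size (the first-order form $\chi^2/n$ is available via
`pseudo_r2_form = "first_order"`). The estimator is exact when the SNPs
are mutually uncorrelated, which is why the pipeline clumps first. No
intercept and no overdispersion scaling are applied — the plain
fixed-effect form; pleiotropy-robust variants (MR-Egger, weighted
median) are deliberately out of scope, since the score regression makes
no instrument-validity claim.

## Pipeline stages and their parameters

| stage | parameter | default | why |
|---|---|---|---|
| variant QC | `maf_min` | 0.01 | exclude rare, noisily imputed variants |
| | `info_min` | 0.9 | imputation quality floor |
| region exclusion | `excluded_regions` | APOE chr19:44.5–46 Mb, MHC chr6:26–34 Mb | single dominant locus / complex LD |
| clumping | `clump_window_kb` | 10000 (±10 Mb) | stringent: one index SNP per broad region |
| | `clump_r2_max` | 0.001 | keeps the IVW independence assumption honest |
| gene windows | `upstream_bp` / `downstream_bp` | 2000 / 500 | proximal promoter + short 3′ tail, strand-aware |
| threshold scan | `p_thresholds` | 0.01, 0.5, 1.0 | three progressive thresholds spanning 0.01–1.0 |
| permutation | `n_perm` | 1000 | resolution of the empirical p (~1/1000) |
| FWE | `fwe_alpha` | 0.05 | Bonferroni over cell sets × thresholds |

Boundary conventions are deliberate and tested: QC exclusion is strict
(`maf < maf_min` is removed, a variant exactly at the threshold is
kept); region exclusion is inclusive at both endpoints; the exposure
p-threshold comparison is strict (`p < threshold`, so a threshold of
1.0 excludes `p = 1` exactly); kilobase region bounds mean kb × 1000 bp.
Clumping breaks p-value ties by smaller (chromosome, position), so
results are independent of input row order. SNPs absent from the LD
reference are kept and treated as uncorrelated (the permissive
PLINK-like behaviour, configurable to `"drop"`). Palindromic (A/T, C/G)
pairs are kept and flagged by default because both synthetic GWAS share
one strand convention; real cross-consortium data may prefer
`palindromic = "drop"`.

Three progressive thresholds are scanned because the original analysis
names the range 0.01–1.0 without printing the intermediate values;
{0.01, 0.5, 1.0} spans it and is fully configurable. The whole-genome
score is not counted in the FWE family (the family is the 14 cell sets
× 3 thresholds, giving 42 tests when no instrument is empty); skipped
empty instruments never inflate the test count.

## SNP-to-gene annotation and marker sets

A clumped SNP maps to every protein-coding gene whose strand-aware
window `[start − upstream, end + downstream]` (reversed for "−" genes)
contains it; SNPs mapping to no gene leave the analysis. The gene map
is then collapsed to one SNP per gene — the smallest exposure-p SNP
wins, and a SNP still claiming several genes goes to the nearest gene
body. This reading of the deduplication step reproduces the direction
of the published reduction (tens of thousands of clumped SNPs down to
roughly one per gene) while keeping the strongest available instrument
per gene and staying deterministic.

Cell-type marker sets can be supplied directly (GMT) or derived from a
gene × cell-type mean-expression table with
`score_marker_enrichment()`. Over-expression is scored as
$\mathrm{lfc} = \log_2\frac{x_{gc}+\varepsilon}{\bar x_g+\varepsilon}$
(pseudocount $\varepsilon = 10^{-9}$ × the table mean keeps it finite),
and significance by a cumulative upper-tail hypergeometric on the
count-scale table: population = all expression units, successes = gene
$g$'s units, draws = cell type $c$'s units, observed = $x_{gc}$. BH
correction runs across genes within each cell type; a marker needs
lfc > 0, FDR < 0.05, and membership in the cell type's top-expression
bin (top decile by default, configurable or disabled). The bin-membership
idea alone admits no per-gene tail probability — a gene's membership is
a single binary outcome — so the expression-mass hypergeometric supplies
the per-(gene, cell type) test while the bin acts as the specificity
filter. A permutation caveat follows from this construction: the
per-cell test is invariant to shuffles that preserve single-cell
concentration, so label-shuffle calibration checks are run on
low-depth fixtures where the bin filter dominates.

## The synthetic study

`simulate_study()` generates everything with known truth, all
randomness flowing from one seed through named substreams (every stage
is independently reproducible):

* **Genome**: 300 protein-coding genes in well-separated per-chromosome
  stretches (10–60 kb bodies, 200 kb spacing) plus 10 non-coding genes;
  a handful of deliberately overlapping gene pairs host multi-gene
  decoy SNPs.
* **Variants**: 3000 SNPs placed in gene bodies, with planted decoys
  exercising every rule — 30 low-MAF (< 0.01), 30 low-INFO (< 0.9), 30
  APOE-region and 30 MHC-region SNPs, 10 intergenic, 10 multi-gene.
  Regular MAFs are uniform on [0.05, 0.5]; INFO on [0.9, 1.0].
* **LD**: 200 blocks of 3 consecutive same-chromosome SNPs at dosage
  correlation r = 0.9, realized by a shared-template haplotype-copying
  scheme whose expected dosage correlation is exactly r; everything
  else independent. Block-diagonal LD is all clumping correctness
  needs. The default reference panel has 2504 individuals — the 1000
  Genomes phase 3 panel size it emulates. This matters quantitatively:
  null $r^2$ sampling noise is $\sim 1/n_{\text{ref}}$, and a much
  smaller panel pushes that noise past the 0.001 clump threshold,
  spuriously pruning most of the genome.
* **Effects**: 20% of regular SNPs are causal for the exposure, with
  normal effects whose variance is 5× larger when the SNP's gene
  belongs to the target cell type (SMC); APOE decoys all carry large
  effects (5× scale), mimicking a single dominant locus. The exposure
  liability is the standardized genetic score plus environmental noise
  at heritability `h2_exposure = 0.5` (a middle-of-the-road value for a
  strongly heritable disease liability).
* **Outcome**: the outcome responds proportionally
  (`alpha_true = 0.3`) to the score
  $\sum_j \kappa_j \beta_j d_j$ where $\kappa_j$
  (`outcome_concentration`, default = the enrichment ratio) multiplies
  target-set SNPs. This concentrates the exposure→outcome coupling in
  the designated cell type — the structure the motivating study
  actually reports, where the SMC score's coefficient (~0.135) is about
  five times the whole-genome coefficient (~0.025). With
  `enrichment = 1` the model collapses to the homogeneous
  `y = alpha_true · G + noise` form, which is what all calibration and
  equivalence checks use. Under a *fully* homogeneous coupling, every
  SNP has the same expected `b/w` ratio, so a size-matched permutation
  null on $|\hat\alpha|$ has no power by construction — concentration
  is not a nuisance choice but the very thing the permutation test
  detects.
* **Cohorts**: independent exposure (n = 20000) and outcome (n = 20000)
  cohorts — the two-sample design with no overlap — plus the LD panel;
  the outcome cohort splits 2:1 into discovery and replication by
  simple random assignment (matching covariates are not simulated).

What the simulation does **not** emulate: case-control exposure
ascertainment (a liability-threshold AD phenotype; the proportional
target is invariant to this), population structure and relatedness,
imaging-derived outcome construction, realistic long-range LD, and
genome-scale SNP counts. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the stated generative
model, not robustness to confounding in real cohort data.

## Numerical and inference choices

* **Estimand of the calibration checks.** With weights estimated in a
  finite exposure GWAS, the score regression targets the
  errors-in-variables projection, attenuated by the weight-noise share
  $\sum \tilde w^2 / (\sum \tilde w^2 + \sum \mathrm{se}_w^2)$ relative
  to the infinite-data coefficient $\alpha_{\text{true}}/\sqrt{h^2}$.
  Bias and CI coverage are therefore assessed against the conditional
  estimand given the realized weights (projecting the true per-dose
  outcome slopes through the same inverse-variance fit), which is the
  quantity the reported standard error describes.
* **Permutation summary.** Both the normal-approximation two-tailed p
  from $z = (\text{obs} - \text{null mean})/\text{null sd}$ (the form
  the motivating study reports: Z = 2.47 → p = 0.013) and the add-one
  empirical p $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}}+1)$
  are reported; the empirical p is primary for calibration because it
  is exactly uniform under exchangeability. Draws are uniform without
  replacement from the gene-mapped universe at the matching threshold,
  and nothing is excluded — the observed set can recur by chance.
* **Leave-set-out attenuation.** For nested IVW fits the difference
  variance is $\mathrm{se}_c^2 - \mathrm{se}_f^2$ (precision-weighting
  identity), giving
  $z = (\hat\alpha_f - \hat\alpha_c)/\sqrt{\mathrm{se}_c^2 - \mathrm{se}_f^2}$.
  At desk scale this test and the permutation test are coupled: the
  permutation's separation scales like the attenuation z times the
  square root of the pool-to-full precision ratio. The published
  analysis threads the needle because its full score (23,869 SNPs)
  dwarfs its gene-mapped universe (754); a 3000-SNP synthetic genome
  cannot reproduce both "permutation detects the set" and "removal does
  not significantly attenuate" at once. The simulation keeps the
  substantive half — the complement (bulk) association remains clearly
  significant after removing the target set — while the attenuation
  z is expected to be large whenever the planted concentration is
  detectable at all.
* **Random numbers.** Every stage draws its seed from the single run
  seed through a named substream (`rng_substream`), so any stage can be
  re-run in isolation and reproduce itself. Genotype matrices are drawn
  in compiled code by a fast xorshift generator whose state is itself
  seeded from R's RNG stream — results remain a deterministic function
  of `set.seed()` while supporting the ~10^8 draws a 20000 × 3000
  cohort needs.
* **Degenerate inputs.** Zero-variance dosages define $r^2 = 0$ with a
  warning; monomorphic SNPs are dropped from the marginal GWAS with a
  log entry; a perfect single-SNP fit floors the SE at $10^{-12}$
  rather than zero; p-values are clamped to $[10^{-300}, 1]$; empty
  instruments are flagged and skipped (and excluded from the FWE test
  count); an empty complement or an empty harmonized intersection is an
  explicit error.
* **Rank concordance.** Spearman's rho across shared set names, exact
  permutation p (full enumeration) for n ≤ 8, t approximation above.

## Problem sizes used by the test battery

Routine unit tests run on 600-SNP/100-gene studies with cohorts of
500–4000. The validation battery runs the study conditions proper: 50
seeded end-to-end replicates at n = 20000 per cohort and 3000 SNPs
(ranking, FWE, permutation, replication), estimator calibration on
1000 + 1000 simulations at n = 2000 and 300 SNPs, permutation
uniformity over 200 replicates of 200 draws, and brute-force clumping
equivalence on 200 randomized instances. These sizes were chosen so the
Monte-Carlo error of each checked rate sits well inside its acceptance
band.

## Known limitations

* LD handling is composite-genotype correlation only — no phase, no
  cross-chromosome LD, no liftover, no binary PLINK formats.
* The expression input for marker derivation is a small mean-expression
  table; raw single-cell processing belongs upstream.
* `alpha_hat` is reported in outcome-SD per unit weighted dose; the
  absolute scale of published coefficients depends on their (partly
  unspecified) standardization, so cross-study comparison should use
  ranks, z statistics, or pseudo-R², which are standardization-robust.
* The estimator inherits the score regression's assumptions: summary
  statistics from non-overlapping samples, uncorrelated SNPs after
  clumping, and no attempt to separate horizontal pleiotropy from
  mediation.
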