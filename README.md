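# ctprs — cell-type-partitioned polygenic risk score association

`ctprs` asks *through which brain cell populations does one trait's
genetic risk act on another trait?* — working entirely from GWAS
summary statistics. The motivating analysis links Alzheimer's-disease
genetic risk to white matter hyperintensity volume and finds the signal
concentrated in SNPs proximal to smooth-muscle-cell (SMC) marker genes.
The package implements that design as a reusable pipeline for any
exposure/outcome GWAS pair, and ships a synthetic-study generator with
planted ground truth so every stage is testable.

The pipeline: variant QC (MAF ≥ 0.01, INFO ≥ 0.9) → APOE/MHC region
exclusion → greedy LD clumping (±10 Mb, r² ≤ 0.001) against a reference
panel → strand-aware SNP-to-gene annotation (2 kb upstream / 0.5 kb
downstream, protein-coding only) → one SNP per gene → per-cell-type SNP
sets (from GMT marker lists or hypergeometric expression enrichment) →
the IVW/gtx score regression over sets × p-thresholds → Bonferroni FWE
→ set-size-matched permutation nulls → leave-set-out attenuation →
split-sample replication with fixed-effect meta-analysis.

## The estimator

For a SNP set with exposure weights `w` (beta per coded-allele dose),
aligned outcome betas `b`, and outcome standard errors `s`, the score
association is the no-intercept weighted least squares of `b` on `w`
with weights `1/s²` — the gtx score regression, identical to the
inverse-variance-weighted (IVW) estimator of two-sample Mendelian
randomization:

    alpha_hat = sum(w*b/s²) / sum(w²/s²)
    se        = 1 / sqrt(sum(w²/s²))
    chi²      = (alpha_hat/se)²,   p = P(chi²₁ > chi²)
    pseudoR²  = 1 − exp(−chi²/n)

It is exact for uncorrelated SNPs, hence the stringent clumping first.

## Worked example

Simulate a 1000-SNP study with the exposure→outcome effect concentrated
in the SMC gene set, then run the full pipeline:

```r
library(ctprs)

arch <- sim_architecture(n_snps = 1000, n_genes = 150,
                         ld_blocks = data.frame(size = 3, r = 0.9, n_blocks = 60),
                         decoys = c(low_maf = 10, low_info = 10, apoe = 10,
                                    mhc = 10, intergenic = 5, multi_gene = 5))
study <- simulate_study(arch, n_exposure = 8000, n_outcome = 8000,
                        n_ld_ref = 1500, seed = 29)
res <- run_pipeline(study, prs_config(n_perm = 1000, rng_seed = 29))

res
#> <prs_pipeline_result>
#>   QC: 1000 -> 960 variants; clumped to 198 index SNPs; 111 gene-mapped
#>   scan: 44 fits, 2 FWE-significant cell scores

head(rank_cell_scores(res$scan), 3)
#>           set    best_z best_threshold rank
#> 1         SMC 21.349889           0.01    1
#> 2 Endothelial  6.861372           0.01    2
#> 3   Ependymal  2.864438           0.01    3

res$permutation$SMC
#> <permutation_result> obs=1.228 null=0.4053+/-0.308 Z=2.67 p=0.00754 p_emp=0.000999 (n_perm=1000)

subset(res$replication$meta, set == "SMC",
       select = c(threshold, p_discovery, p_replication, consistent))
#>   threshold  p_discovery p_replication consistent
#> 4      0.01 1.555983e-66  1.839398e-36       TRUE
#> 5      0.50 6.946725e-66  3.202575e-36       TRUE
#> 6      1.00 9.827099e-66  1.331061e-36       TRUE
```

Reading the output: after QC and clumping, 111 of the 198 index SNPs
map to genes. The SMC score tops the cell-type ranking (|z| = 21.3 at
the p < 0.01 threshold) and survives family-wise error control over the
14 sets × 3 thresholds. Its observed |alpha| (1.23) sits far above the
null of 1000 size-matched random SNP sets drawn at the same threshold
(0.41 ± 0.31, empirical p ≈ 0.001) — the association is not a set-size
artifact — and it replicates with consistent sign and nominal
significance in both the discovery (2/3) and replication (1/3) halves.

The numbered scripts under `analysis/` run the same stages as a
file-based workflow (`01_simulate.R` … `05_inference.R`), writing
intermediate data under `scratch/study/` and result tables under
`results/`.

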