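# transpopgen

Population divergence and diversity analysis for biallelic SNPs called on
assembled transcripts (unigenes), aimed at two-population RNA-seq designs —
for example an agricultural vs. a nonagricultural insect population
genotyped from gut transcriptomes. The package takes a VCF, a transcript
FASTA, an ORF annotation table and a sample→population sheet, and runs:

1. **Hard filtering** — GATK-style cascade with deterministic per-rule
   accounting: FS > 30, QD < 2, >3 SNPs per 35-bp window, depth < 25,
   GQ < 20 genotype masking, <16 called individuals per population, pooled
   MAF < 1%.
2. **Per-SNP differentiation** — Hs/Ht (Nei–Chesser small-sample corrected
   by default), `G_ST = (H_T − H_S)/H_T`, Hedrick's
   `G'_ST = G_ST (k−1+H_S)/((k−1)(1−H_S))`, Jost's
   `D = k/(k−1) · (H_T−H_S)/(1−H_S)`, AMOVA-based φ_ST, and a two-sided
   Fisher exact test with Bonferroni flags.
3. **Per-gene diversity** — nucleotide diversity
   `π = 1 − Σᵢ C(nᵢ,2)/C(n,2)` per site, averaged per gene (per-length and
   per-SNP conventions), Tajima's D with non-integer sample sizes via the
   digamma-generalized harmonic sums, and 2.5%-tail outlier flags per
   population.
4. **Effect classes** — synonymous / nonsynonymous / UTR / noncoding
   against the transcript ORF under the standard genetic code, with
   transition/transversion tallies.
5. **Structure** — complete-case genotype PCA (deterministic sign
   convention) and a k-means cluster summary with silhouettes.
6. **Synthetic data** — a Balding–Nichols generator
   (cluster frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F)) including a
   "standing variation" scenario where the derived population samples just
   one ancestral subcluster, plus planted filter artifacts with ground
   truth. Global G_ST under this model has the closed form `F/(2−F)`,
   which calibrates and validates the estimators.

## Worked example

```r
library(transpopgen)

cfg <- simulation_config(n_genes = 200, seed = 11)   # two_pop, F = 0.0354
sim <- simulate_dataset(cfg)
paths <- write_fixture(sim, "demo")

res <- run_pipeline(pipeline_config(
  vcf = paths["vcf"], fasta = paths["fasta"],
  annotations = paths["annotations"], samples = paths["samples"],
  out_dir = "demo/out"))

res$filtered$removed_by_rule
#>       fs       qd  cluster    depth presence      maf
#>        4        7       10       13        0        0

summarize_divergence(res$divergence)[c("mean_gst", "global_gst",
                                       "n_significant_snps")]
#> $mean_gst    [1] 0.01733
#> $global_gst  [1] 0.01867
#> $n_significant_snps [1] 36
```

The simulated world had F = 0.0354, so the expected global G_ST is
`F/(2−F) = 0.018`; the ratio-of-means estimate on 963 kept SNPs is 0.0187.
36 SNPs on 35 genes pass the Bonferroni-corrected exact test. The effect
summary shows 33.0% transitions (the generator substitutes uniformly, so
1/3 is expected), and the per-gene report flags 18 of 199 genes in the
2.5% Tajima's D tails. The top rows of the per-SNP report look like:

```
unigene_id pos    gst     gst_hedrick jost_d  phi_st  fisher_p   significant
g0045      942    0.230   0.519       0.376   0.375   2.3e-11    TRUE
g0170      408    0.188   0.296       0.133   0.321   3.9e-11    TRUE
```

`demo/out/` then contains `divergence.tsv`, `diversity.tsv`,
`effect_summary.tsv`, `filter_summary.tsv`, `pca_scores.tsv`,
`pca_variance.tsv`, `clusters.tsv` and a `manifest.json` with the config
hash and all row counts.

## Command line

```sh
inst/cli/transpopgen simulate --out demo --seed 1 --n-genes 200
inst/cli/transpopgen run-all --vcf demo/snps.vcf --fasta demo/transcripts.fa \
    --annot demo/annotations.tsv --samples demo/samples.tsv --out demo/out
```

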