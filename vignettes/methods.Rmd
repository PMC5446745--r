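---
title: "Methods: divergence and diversity from transcriptome SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence and diversity from transcriptome SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

`transpopgen` analyses biallelic SNPs called on assembled transcripts
(unigenes) for two populations of diploid individuals — the setting of a
comparison between an agricultural and a nonagricultural insect population
genotyped by RNA-seq. The pipeline answers three questions: which SNPs are
trustworthy (hard filtering), how differentiated the populations are at
each SNP and transcriptome-wide (G_ST and relatives, exact-test
significance), and what the within-population diversity looks like per
gene (nucleotide diversity, Tajima's D, outlier genes), plus SNP effect
classes and a PCA/k-means view of structure.

Coordinates are 1-based transcript positions; unigenes are treated as
single-exon, plus-strand sequences, so there is no strand or splice
handling anywhere.

## Hard-filter cascade

Defaults (all overridable): FS > 30 removed; QD < 2 removed; more than 3
SNPs in any 35-bp window removes *all* SNPs of the window (GATK
cluster-filter semantics — the narrative phrasing "more than 3 SNPs within
a 35 bp window" is ambiguous about whether the whole window or only the
excess is dropped; we follow GATK); site depth < 25 removed; genotypes
with GQ < 20 masked to "no call" *before* the site rules; sites called in
fewer than 16 individuals in either population removed; pooled minor
allele frequency < 1% removed (monomorphic sites fall under this rule).

Two policies are deliberate choices:

* **Rule attribution.** Each rule is evaluated on the full input and a
  removed record is attributed to the *first* rule it violates, in the
  fixed order above, so per-rule counts are deterministic and conservation
  (`kept + removed = input`) holds exactly. No ordering is prescribed by
  the filtering conventions we mirror; any order yields the same kept set
  because the rules are independent site predicates.
* **Missing INFO fields.** With `strict_info = TRUE` (default) a site
  lacking FS, QD or DP fails the corresponding rule — the conservative
  mirror of hard filtering. Setting it to `FALSE` lets minimal fixtures
  pass.
* **Depth is site-level.** The data model carries only the INFO `DP`
  field; a per-sample depth variant would need FORMAT `DP`, which the
  input contract does not include, so it is not offered.

## Differentiation statistics

For two populations with called allele copies at a biallelic site:

* Uncorrected: `Hs = mean_pop(1 - sum(p_a^2))`, `Ht = 1 - sum(p̄_a^2)`
  with `p̄` the unweighted across-population mean frequency.
* **Nei–Chesser corrected (default):** with `ñ` the harmonic mean number
  of individuals per population, `Ho` the mean observed heterozygote
  frequency and `k = 2`,
  `Ĥs = ñ/(ñ-1) (Hs - Ho/(2ñ))` and `Ĥt = Ht + Ĥs/(kñ) - Ho/(2kñ)`.
  These are the small-sample estimators used by the mmod family of
  implementations. The correction matters: the naive estimators carry an
  O(1/n) bias that, at 48 + 48 diploids and true global G_ST 0.018,
  inflates the estimate to ≈ 0.023. Corrected estimators may produce
  `hs > ht` and small negative statistics at individual sites; values are
  reported unclamped.

From `hs`/`ht`: `G_ST = (Ht-Hs)/Ht`; Hedrick's
`G'_ST = G_ST (k-1+Hs)/((k-1)(1-Hs))`; Jost's
`D = (k/(k-1))(Ht-Hs)/(1-Hs)`. φ_ST is a single-locus AMOVA over allele
copies with 0/1 mismatch distance; with per-population ref/alt counts the
SSDs collapse to closed forms (`SSD_within = Σ ref_i·alt_i/n_i`,
`SSD_total = R·A/N`), and `n₀ = (N - Σn_i²/N)/(k-1)`.

Significance is a two-sided Fisher exact test on the 2×2 allele-count
table: the p-value sums hypergeometric probabilities ≤ observed ×
(1 + 1e-7); the tolerance factor resolves floating-point ties the way the
conventional implementations do. The Bonferroni family `m` contains only
the tested (polymorphic, callable) SNPs — monomorphic-after-filtering
sites carry no test. The flag uses the strict inequality `p < α/m`.

The transcriptome-wide summary reports **both** aggregation conventions —
the arithmetic mean of per-SNP G_ST and the ratio of means
`(mean Ht - mean Hs)/mean Ht` — because "average across all loci" admits
both readings. The ratio of means is the headline default: it is the
estimator that converges to the Balding–Nichols closed form `F/(2-F)` and
is robust to low-diversity loci with noisy per-SNP ratios.

## Diversity and Tajima's D

Per-site nucleotide diversity follows the pair-counting identity
`π = 1 - Σ C(n_i,2)/C(n,2)` within each population separately. The
per-gene average is ambiguous between dividing by the transcript length
or by the number of SNPs, so both are emitted (`pi_per_length`, the
default headline; `pi_per_snp`).

Tajima's D uses the 1989 constants with the sample size taken as the
*average number of allele copies genotyped per SNP* in that gene and
population. That average is generically non-integer, so the harmonic sums
are generalized via `a1 = digamma(n) - digamma(1)` and
`a2 = trigamma(1) - trigamma(n)`, which reproduce the integer sums exactly
at integer n; an integer-rounding mode exists for comparison with
integer-only implementations. `S` is the number of sites segregating
*within that population* — a SNP fixed in the population is not a
segregating site of that sample, and counting it would bias D for genes
polymorphic only in the other population.

Outliers: a gene is flagged when its D falls at or beyond the 2.5th or
97.5th percentile (linear interpolation between order statistics,
inclusive boundaries) of its population's distribution, and a gene is an
overall outlier if flagged in at least one population. Fewer than 40
finite values give no flags (tails would be meaningless); a zero-spread
distribution flags nothing.

## Effect classification

No ORF → `noncoding`; outside the ORF → `utr` (5′/3′ side kept as
metadata, not a class); inside the ORF the containing codon is translated
with ref and alt under the standard genetic code — same amino acid is
`synonymous`, anything else including stop gain/loss is `nonsynonymous`.
The classes partition the kept SNPs exactly, and
synonymous + nonsynonymous equals the in-ORF count by construction. A
ref allele that contradicts the transcript base is a validation error,
not a silent skip.

## Structure

PCA uses only SNPs genotyped in all individuals (no imputation), dosages
mean-centered without frequency scaling by default (the 1/√(p(1-p))
scaling is selectable); scores come from the SVD, and each component is
sign-fixed so its largest-magnitude loading is positive — scores are then
exactly reproducible across runs and languages. k-means (fixed seed,
25 restarts, local RNG state) with a mean-silhouette summary stands in
for model-based admixture inference, which is out of scope.

## The synthetic world

The generator emulates the study-like design rather than real reads:

* 48 diploids per population; ~5 SNPs per gene on ~1 kb transcripts
  (≈ the observed 5.5 SNPs/kb).
* Balding–Nichols frequencies: ancestral p ~ Uniform(0.05, 0.95), cluster
  frequencies Beta(p(1-F)/F, (1-p)(1-F)/F). Default F = 0.0354 makes the
  closed-form global G_ST equal F/(2-F) = 0.018, the observed
  transcriptome-wide differentiation.
* `standing_variation` scenario: ancestral subclusters C1/C2; the
  "MN"-like population mixes them (an individual is C2 with probability
  `mix_weight` = 0.75, matching "about 25% of MN clusters with ND") while
  the derived "ND"-like population samples C1 only. Note the consequence:
  ND and the C1 part of MN are *one genetic group*; the recoverable
  planted partition has two clusters, and the derived population shows
  the Wahlund-direction heterozygosity deficit relative to the admixed
  population.
* Missingness: raw per-call missingness 1.7% plus a low-GQ tail (3.4% of
  calls uniform on [0, 40], about half of which fall under the GQ 20
  mask) gives ≈ 3.4% no-calls per genotype after masking — chosen so the
  fraction of SNPs genotyped in all 96 individuals reproduces the
  study-like ≈ 3.6% (2287 of 63,595).
* Depth ~ NegBin(mean 100, size 5) — overdispersed RNA-seq coverage; a
  small left tail fails the 25-read rule naturally.
* Artifacts planted at 1% each (FS > 30, QD < 2, dense 4-SNP clusters)
  with ground-truth labels, so filter tests can assert exact recovery.
* Substitutions: ref = transcript base, alt uniform over the other three
  bases, hence a 1/3 transition fraction ("expect 33% if transitions occur
  at random"); real transcriptomes show ~60% transitions, a feature the
  generator deliberately does not emulate.

What a green test does **not** establish: the generator draws ancestral
frequencies uniformly, which is *not* the neutral site-frequency
spectrum, so gene-level Tajima's D from these simulations is
systematically positive; neutrality-related properties of D are therefore
tested by sampling segregating-site counts from the neutral SFS
(P(i copies) ∝ 1/i) directly. Likewise there is no linkage, no sibling
structure, no expression-level variation, and no mapping bias.

## Numerical choices and degenerate inputs

* Fisher tie tolerance (1 + 1e-7), as above; empty margins give p = 1 by
  convention with a log message.
* φ_ST undefined (NA) for monomorphic sites or populations with < 2
  copies; negative values reported unclamped.
* Tajima's D is NA when the variance term is non-positive, with a
  warning.
* Percentile outliers: type-7 quantiles, inclusive tails.
* PCA rank deficiency: requested components beyond the rank are truncated
  with a warning; Gram reconstruction holds to 1e-8 at full rank.
* All generator randomness flows from the single config seed; k-means
  uses a locally scoped RNG so library calls never perturb the caller's
  stream.

## Known limitations

Two populations only for divergence (k = 2 is asserted); no multiallelic
sites or indels by scope; no haplotype statistics (transcript phasing is
unavailable); no model-based admixture or Bayesian outlier detection —
the PCA/k-means summary is a deliberate lightweight stand-in.
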