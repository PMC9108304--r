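---
title: "Methods: clonality, diversity and structure under fire management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, diversity and structure under fire management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

clonefire asks a management question with population-genomic tools: does a
disturbance regime — here, preventative roadside burning applied to an
invasive, partially clonal grass — change genetic structure, genetic
diversity, or the balance between sexual and asexual (clonal/apomictic)
reproduction? The package implements the full desk pipeline from a raw
DArTseq-style SNP dosage report to fire-by-cluster regression models, plus a
genotype simulator with known truth that every statistical claim in the test
suite is checked against.

```{r}
library(clonefire)
ds <- simulate_dataset(sim_config(seed = 1))
filtered <- filter_cascade(ds$genotypes)
```

## The data model

Genotypes live in a `geno` object: an individuals x loci matrix of
alternate-allele dosages (0/1/2, `NA` for missing calls) with per-sample
metadata (location, site, fire category, coordinates) and per-locus metadata
(sequence-tag id, platform call rate and reproducibility). Dosage orientation
is arbitrary; every statistic used downstream is allele-symmetric, so the
orientation never matters. On disk the package reads and writes a
one-row-per-SNP CSV dialect with `-` as the missing code, a converter from
two-row presence/absence exports, and a minimal VCF (GT-only) export.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the sampling design the analysis assumes:
paired burnt/unburnt sites at roadside locations spaced along a longitudinal
gradient (default 8 locations, 5 plants per site, plus a ranger-managed
location of three sites kept out of formal models), invaded by a small number
of highly divergent cultivars.

* **Cultivar divergence** uses the Balding–Nichols model: per-cultivar allele
  frequencies are beta draws with mean equal to the ancestral frequency `p`
  and variance `d·p(1-p)`. `d` acts as an F_ST dial; the default `d = 0.9`
  produces the near-fixed differentiation regime typical of crop accessions
  (between-cluster θ around 0.9 and above).
* **Clonality**: each individual is, with probability `clonal_fraction`
  (optionally fire-category-specific), an exact pre-error copy of a
  previously sampled member of its site — a ramet of an existing genet.
  Otherwise it is a sexual recruit drawn from the cultivar's mating pool
  under inbreeding `f` (default 0; cultivar-specific selfing rates are
  unknown, so `f` is a free parameter). Drawing recruits from the pool's
  allele frequencies is equivalent to mating two random site-local parents;
  explicit two-parent segregation is available separately as
  `mendelian_offspring()` and is used to build sib and parent-offspring
  pairs for the kinship calibration.
* **Measurement noise**: genotyping error resamples a call to one of the two
  wrong dosages (default 0.1%), missingness blanks calls (default 2%), and
  per-locus call rate / reproducibility metadata are attached (the latter
  drawn near 0.99, emulating platform replicate concordance rather than
  modelling it mechanistically).

Known departures from real data, and what they imply for the tests:

* Apomictic seed and vegetative spread are not distinguished — SNP data
  cannot tell them apart either.
* The species is polyploid; like the genotyping platform, the simulator
  works with diallelic dosages.
* Loci are independent: there is no physical linkage map, so linkage
  pruning removals reflect structure-induced correlation only.
* Clones are single-generation copies. Long-lived clonal lineages in nature
  accumulate *fixed heterozygosity* (no meiotic segregation), which is what
  drives the classic left-skewed F_IS signature of partial clonality. A
  one-generation copy of an HWE genotype cannot create that signature: it
  lowers mean F_IS and inflates its variance, but the skew of the per-locus
  F_IS distribution stays positive because low-frequency loci dominate the
  right tail. The F_IS-signature test therefore constructs clonal groups
  with lineage-wide fixed heterozygosity (heterozygous in every ramet at
  20% of loci) rather than relying on simulator clones. Passing that test
  shows the statistic detects the signature; it does not show the simulator
  reproduces multi-generation clonal evolution.

## SNP filtering

The two-stage cascade mirrors standard DArTseq practice, with every
threshold boundary strict exactly as usually printed:

* Stage 1: one SNP per 69-bp sequence tag (highest call rate wins, ties
  broken by smallest locus id), monomorphic loci out, call rate < 50% out.
* Stage 2: MAF < 5% out, reproducibility < 95% out, putative paralogs
  (observed heterozygosity > 80% over the pooled sample) out, then greedy
  linkage pruning at |r| > 0.75 on pairwise-complete dosage correlations.
  The later-scanned member of a correlated pair is removed unless call
  rates differ, in which case the lower-call-rate locus goes. Pairs sharing
  fewer than 3 complete samples have undefined correlation and are kept,
  with a warning.

Absolute correlation is used because the dosage coding sign is arbitrary.
Each sub-step appends a row to an attrition ledger (`FilterReport`); the
ledger is conserved (`n_before − Σ removed = n_after`) and both stages are
idempotent. One behaviour worth knowing: under near-fixed population
structure, strongly differentiated loci are mutually correlated across the
pooled sample, so LD pruning removes many of them and the pruned panel is
*depleted* of differentiation signal relative to the input panel.
Between-cluster θ is therefore best read on the stage-1 panel, which is also
the panel used for F_IS summaries so that extreme-F_IS loci survive.

## Structure: PCA, trees, and a k-means stand-in

PCA runs on the imputed (locus-mean), centered, binomially scaled
(`sqrt(p(1-p))`) matrix via SVD; results are deterministic up to axis sign
and everything downstream is sign-invariant. Hierarchical clustering uses
Euclidean distances with complete linkage by default (configurable;
dendrograms serialize to Newick). Hard cluster assignment uses seeded
k-means on the leading PCs. A variational admixture model is deliberately
not re-implemented: at the near-fixed differentiation this system shows,
hard assignments coincide, and hard labels are all the diversity and
clonality models consume. The "membership" proportions attached to
assignments are inverse-distance heuristics, not posterior probabilities.

`select_k()` scores candidate K by mean silhouette, but compares each K
against a permutation null (score columns permuted independently, which
keeps the marginals and destroys joint clustering — the gap-statistic idea).
Unclustered clouds reach silhouettes of ~0.25 in three dimensions, so a
fixed cutoff misreads noise; a K counts as structure only when it beats the
maximum of its permuted replicates.

## Outlier scans

Two scans flag loci putatively under selection, both re-implemented in
simplified, calibration-first form; reproducing any particular published
tool's outlier identities is explicitly out of scope.

* **PC scan**: each locus is regressed on the K = 3 leading PCs; the
  per-component z-scores are (optionally, default on) median-centered and
  MAD-standardized before an empirical covariance defines a Mahalanobis D².
  D² is divided by the genomic inflation factor
  λ = median(D²)/χ²-median(K), referred to χ²(K), and BH-adjusted; outliers
  have q < 0.05.
* **Latent-factor scan**: the environmental design (fire 0/1, standardized
  longitude, cluster dummies) plus intercept is projected out of the
  genotype matrix; the leading K = 5 left singular vectors of the residual
  become latent factors; each locus is then least-squares fit on
  environment + factors. Per-covariate z² statistics are λ-calibrated and
  BH-adjusted per covariate; the cluster dummy block is tested jointly
  (Wald, K−1 df). The union of both scans' outliers forms the non-neutral
  panel; the complement is the neutral panel used by all structure,
  diversity and kinship analyses, optionally re-filtered through stage 2
  (both counts logged).

The power condition tested is a selective-sweep scenario: target loci start
rare (frequency uniform on 0.05–0.2) and rise by Δp = 0.3 at burnt sites,
with 100 targets in a 5,000-locus panel and n = 90. A back-of-envelope
z ≈ 2Δp / √(4·avg 2pq / n) ≈ 4.3–5 against a BH cut near 3.4 puts power
clearly above 0.8 there; for targets drawn from the background frequency
range instead, the same arithmetic caps power near 0.78 for *any* per-locus
test, which is why the sweep framing — also the biologically natural one —
defines the planted-effect benchmark.

## Diversity and differentiation

Per group and locus: allele frequency, observed heterozygosity, unbiased
expected heterozygosity `He = (2n/(2n−1))·2p(1−p)` (Nei-style small-sample
correction; no formula is canonical here, this is the common choice), and
`F_IS = 1 − Ho/He` where `He > 0`. F_IS distributions are summarized per
cluster by mean, interlocus SD and skewness (third standardized moment,
computed in-package). Rarefied allelic richness uses the hypergeometric
closed form `AR = Σ_a [1 − C(N−N_a, g)/C(N, g)]`, with `g` defaulting to the
largest copy count every group supports; loci untyped in any group are
excluded from all groups so groups are compared on one panel. The exhaustive
subsample enumeration oracle (N ≤ 8) in the test suite pins the closed form
exactly.

Differentiation is Weir & Cockerham's θ with per-locus typed counts
(standard unequal-n variance components a, b, c), combined across loci as a
ratio of sums; negative estimates are legitimate and never truncated. On
two-deme Balding–Nichols simulations (n = 50 each, 5,000 loci) the
multi-locus θ tracks the divergence parameter within ±0.03 across
d ∈ {0.2, 0.5, 0.9}, hits 1 at fixed differences and 0 under the null.
The Mantel test correlates lower triangles with significance from
simultaneous row/column permutations, one-tailed for positive association,
`p = (1 + #{r* ≥ r})/(n_perm + 1)` with 9,999 permutations by default;
geographic distances are haversine on a 6,371 km sphere from site mean
coordinates.

## Kinship and asexuality rates

The kinship coefficient φ (probability that two alleles sampled one from
each individual are identical by descent) is estimated by maximum
likelihood under the non-inbred identity-by-descent model: at each locus
the genotype-pair probability is a mixture over sharing 0, 1 or 2 alleles
IBD with weights (k0, k1, k2), and an EM iteration alternates per-locus
posterior mode weights with their average. φ = k2/2 + k1/4; clones sit at
0.5, full sibs and parent-offspring at 0.25, half sibs at 0.125, unrelated
pairs at 0. Numerical choices: mode likelihoods are floored at 1e−6 so a
genotyping error in a clone pair (a discordant call that is impossible
under 2-IBD sharing) cannot collapse the likelihood; convergence is
max |Δk| < 1e−6 or 500 iterations (slow convergence for unrelated pairs is
expected and harmless — φ is already stable); pairs typed at fewer than 100
common informative loci are refused rather than estimated. Allele
frequencies are estimated once from all typed individuals; clonal
replicates bias them slightly toward their genet, which is inherent to
pooled estimation and left uncorrected. The constrained EM keeps φ ≥ 0 by
construction; no clamping is applied afterwards. A method-of-moments
product estimator is kept alongside purely as an independent cross-check.

A pair with φ strictly above 0.45 is counted as clonal/apomictic, and the
asexuality rate is the proportion of such pairs — in the whole dataset,
within locations (paired sites pooled), and within sites. When clones
arise only within sites, these rates must order site ≥ location ≥ dataset,
and on simulations the site-level estimate recovers the realised clone-pair
proportion (known from the simulator's genet labels) within ±0.05.

## Fire-by-cluster models

Site-level allelic richness is modelled by OLS on
`fire_category * K` (treatment coding, unburnt/K1 reference). Individual
heterozygosity uses the same mean model on individual rows with standard
errors clustered on site (CR sandwich, t with G−1 df) — the fixed-effect
point estimates equal those of a site-random-intercept model under the same
mean structure, and the inference is conservative; this replaces REML
machinery by design. The within-site asexuality rate is modelled by a
logit-link beta regression with constant precision, fit by BFGS on the
log-likelihood after the standard boundary compression
`y' = (y(N−1) + 0.5)/N`; with only factor covariates there are no smooth
terms to estimate, so the model is a plain beta GLM.

Structurally empty design cells (a cluster observed only burnt, as happens
in this sampling design) produce aliased coefficients: these are reported
as aliased and never estimated or imputed. Term p-values are Type II
(nested-model F for OLS, nested Wald blocks under the clustered or beta
covariance), chosen for order-invariance since no test is canonical here.
Parameter recovery is verified by simulation: coefficients land within 2
standard errors of truth in ≥ 90% of replicates for both the OLS and the
beta model at 40 sites.

## Problem sizes and limitations

The test suite runs at deliberately desk-scale sizes — 2,000–5,000 loci,
40–100 individuals, tens of model-fit replicates, hundreds of Mantel
permutation replicates — chosen so the full suite completes in a few
minutes while leaving the statistical margins comfortable (the kinship
calibration, for instance, is tested at 10,000 loci where the ±0.01
tolerance is several Monte-Carlo standard errors wide).

Limitations to keep in mind: kinship assumes non-inbred pairs (under
strong inbreeding φ is biased; the 9-mode inbred model is out of scope);
admixture proportions are not estimated; the simulator's clones are
single-generation (see above); and the beta regression's constant
precision is an approximation when site pair counts differ greatly.
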