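---
title: "Evaluating low-pass sequencing imputation for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating low-pass sequencing imputation for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpeval)
```

## The problem

Low-pass sequencing (LPS) genotypes an animal by sequencing its whole genome
at well under 1X mean depth and recovering genotypes by imputation against a
phased haplotype reference panel. In cattle, this is an attractive
alternative to SNP arrays: it reaches every variant segregating in the
panel — tens of millions of sites, including putatively functional ones an
array cannot probe — at a comparable cost. Whether it is *good enough* for
genomic prediction hinges on two empirical questions:

1. How accurate are the imputed genotype posteriors, and how does accuracy
   depend on coverage, on the animal's relationship to the panel, and on
   minor allele frequency (MAF)?
2. Do breeding values computed from imputed genotypes agree with those
   computed from array genotypes, once marker effects have been trained
   without the animals being predicted?

`lpeval` answers both questions on synthetic data with known truth. Every
stage of a realistic LPS evaluation is implemented as a testable function:
simulation of a structured haplotype panel and pedigreed target animals,
read-count downsampling, genotype likelihoods, haplotype-copying
imputation, quality metrics, pedigree/genomic BLUP with REML variance
components, marker-effect backsolving, and a leave-out validation of
molecular breeding values (MBV).

## The models

### Genotype likelihoods

At a biallelic site with `r` reference and `a` alternate reads and per-read
error $\varepsilon$, the three genotype likelihoods are
$L(RR) = (1-\varepsilon)^r \varepsilon^a$, $L(RA) = 0.5^{\,r+a}$,
$L(AA) = \varepsilon^r (1-\varepsilon)^a$, computed in log space (floored
at $-745$ natural-log units so `exp()` cannot underflow) and normalised so
the largest equals 1. Downsampling acts directly on counts by binomial
thinning, which is equivalent in distribution to sampling raw reads when
only counts are retained.

### Haplotype-copying imputation

Imputation is a diploid Li–Stephens hidden Markov model. The hidden state
at each site is an ordered pair of panel haplotypes; each of the two
copying processes independently stays on its haplotype with probability
$1-s$ between adjacent sites and otherwise jumps uniformly, with
$s = 1 - e^{-\rho d}$ for inter-site distance $d$ bp. Emission combines a
per-haplotype copying error $\mu$ (the copied allele flips with probability
$\mu$) with the site's genotype likelihoods. Forward–backward posteriors
are collapsed to the genotype probability triple GP = (RR, RA, AA) per
site, from which come GP$_{\max}$, the dosage GP(RA) + 2·GP(AA), the argmax
hard call (ties broken toward the lower genotype index), and a pass flag
(GP$_{\max} > 0.9$ by default). Because alleles are binary the emission
matrix is constant on the four allele-class blocks, which keeps the exact
$O(K^2)$ per-site cost fast in compiled code; the panel is capped at
`max_panel` haplotypes per target (default 100), chosen as those sharing
the most rare alleles with the target's reads. The implementation is pinned
to an exhaustive path-enumeration oracle on all instances with up to 4
haplotypes and 4 sites at $10^{-10}$.

Defaults $\rho = 10^{-6}$/bp and $\mu = 10^{-3}$ are stated, configurable
choices: commercial low-pass imputers do not publish their parameters, and
this module is a standard, documented stand-in with the same input/output
contract (read counts in, GP/DS/GT out), not a reproduction of any
proprietary algorithm.

### Quality metrics

Per library, the call confidence is the phred-scaled mean error probability
of the uncertain calls,
$\mathrm{CC} = \operatorname{mean}\{-10\log_{10}(1-\mathrm{GP}_{\max})\}$
over sites with $\mathrm{GP}_{\max} < 1$. Two conventions are deliberate:
the sign follows the phred convention so that better libraries score
higher, and "certain" is judged after rounding GP to the 4 decimals a VCF
carries, so 0.99996 counts as certain. A library with no uncertain calls is
capped at 100. Agreement metrics are Pearson correlations of 0/1/2 codes
and hard-call concordance over shared non-missing passing sites, reported
per library, per variant, and averaged within half-open 0.01-wide MAF bins
(MAF always taken from the comparator, a property of the variant); empty
bins are retained and flagged rather than dropped. Pass rates are
summarised per variant and per 1-Mb window (window $k$ covers
$[k\cdot10^6+1, (k+1)\cdot10^6]$), and library identity is verified by
best-concordance matching against comparator genotypes, which also exposes
sample swaps and chimeric mixtures (a 50/50 read mixture of two animals
measurably depresses both CC and concordance). Panel structure is checked
by centred PCA of the haplotypes on a random subset of variants with
panel-wide MAF above 5% (150,000 by default). PCA rows are haplotypes, not
re-paired diploids: the panel type is a haplotype set, and duplicated
haplotypes must receive identical scores.

### Genetic prediction

The animal model is $y = X\beta + Zu + e$ with
$\operatorname{var}(u) = K\sigma_g^2$ and
$\operatorname{var}(e) = I\sigma_e^2$, where $K$ is either the pedigree
numerator relationship matrix $A$ (tabular method with inbreeding; unknown
parents are unrelated founders) or the genomic relationship matrix
$G = ZZ'/2\sum p_i(1-p_i)$ with $Z$ the 0/1/2 genotypes centred by $2p_i$.
$G$ is stabilised as $G^* = 0.99\,G + 0.01\,I$ before inversion. Genotypes
are centred even though the plain cross-product $MM'$ is sometimes written
without centring: uncentred $MM'$ does not scale to a relationship matrix
(a `center = FALSE` flag reproduces the literal form for comparison).
Allele frequencies default to the analysed sample, since no base population
is defined for simulated data.

Variance components come from EM-REML through the mixed-model equations
with average-information (AI) acceleration: an AI/Newton step is taken only
when it keeps both variances positive and does not decrease the restricted
log-likelihood, otherwise the guaranteed-monotone EM update is used —
so the log-likelihood is non-decreasing at every iteration by
construction. Convergence is a relative parameter change below $10^{-8}$
(500-iteration cap, variances floored at $10^{-10}$); the reported standard
error of $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ is the standard
information-based (inverse-AI, delta-method) approximation and is labelled
as such.

Marker effects are backsolved from genomic breeding values. The textbook
form $\hat\alpha = M'[MM']^{-1}\hat u$ is singular for centred $M$, so the
default route is the equivalent well-conditioned expression
$\hat\alpha = Z'(G^*)^{-1}\hat u / k$ with $k = 2\sum p_i(1-p_i)$; a
literal pseudoinverse mode exists for oracle tests. MBV are
$Z_s\hat\alpha$ with target genotypes centred by the *training*
frequencies; effect variants absent from a target matrix are dropped with a
logged count. Trait-specific variant subsets are selected by permutation:
the observed $|\hat\alpha|$ of each variant is compared with its own null
distribution from refits on permuted phenotypes, and the variants with the
largest exceedance over their null 99th percentile are kept (percentile
configurable; ties break by observed $|\hat\alpha|$, then variant order).
The leave-out validation excludes holdout animals from effect training and
correlates their MBV — from array-truth genotypes and from imputed
dosages — with full-data pedigree EBV and genomic EBV, with
$\mathrm{SE} = \sqrt{(1-r^2)/(n-2)}$.

The postweaning-gain phenotype is constructed the way weight records are
processed in practice: a per-animal least-squares quadratic of weight on
age, projected to the average daily gain over the 160 days after weaning
(default weaning age 205 days).

## The synthetic world

`sim_config()` states the world once; all randomness flows from one master
seed through per-stage child seeds, so every output is reproducible
byte-for-byte.

* **Panel.** Ancestral allele frequencies are uniform on (0.05, 0.95); each
  population drifts by a Balding–Nichols Beta draw with an $F_{st}$-like
  `divergence` knob (default 0.15, two populations — roughly a
  taurine/indicine split, which the panel PCA separates cleanly on PC1 from
  divergence ≈ 0.1 upward). Haplotypes are binomial within population.
* **Targets.** Founder chromosomes are recombinant mosaics of panel
  haplotypes; later generations inherit Poisson-recombined gametes
  (`recomb_rate` default $10^{-8}$/bp, i.e. 1 cM/Mb). Founders carry
  `founder_generations` (default 30) generations' worth of effective
  recombination against the panel. This knob sets panel–target relatedness:
  with a single meiosis' worth of crossovers a 10-Mb founder chromosome is
  a near-verbatim panel haplotype and 1X imputation saturates near
  $r = 0.9999$, which is not the regime low-pass evaluation operates in;
  at 30 effective generations 1X accuracy lands in the high 0.99s with CC
  around 29, the range reported for real multi-breed cattle pipelines, and
  coverage still matters. An optional `reference_sires` argument copies
  panel haplotypes verbatim into chosen founders for the
  "sire-in-the-reference" contrast.
* **Phenotypes.** QTL are drawn from panel variants with MAF > 0.01;
  effects are standard normal, rescaled so realized additive values have
  unit variance, and true breeding values equal the centred QTL genotypes
  times the effects exactly. Residuals are scaled so
  $\sigma_g^2/(\sigma_g^2+\sigma_e^2)$ hits `h2_true` (default 0.5, a
  moderately heritable growth trait) on the realized genetic variance;
  contemporary-group-like fixed factors get standard-normal level effects
  with the first level constrained to zero.
* **Reads.** Depth is Poisson(`coverage`) per animal × site; each read
  reports the true allele with probability $1-\varepsilon$
  (`base_error` default 0.01). No read strings are generated — counts are
  sufficient for the likelihood model.

What the generator does **not** emulate: coalescent linkage-disequilibrium
structure (drift is per-variant, so background LD between panel variants is
weaker than in real chromosomes), mutation private to the targets,
alignment and variant-calling artefacts, indels and multi-allelic sites,
and depth heterogeneity along the genome (GC, mappability). A green test
therefore establishes that the *machinery* behaves as specified in a world
with known truth — not that any particular real population would show the
same numbers.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (VCF convention); GP are
  serialised to 4 decimals with round-half-to-even, and the CC "certain"
  rule keys off that precision.
* The forward–backward works in scaled linear space with per-site
  renormalisation; posteriors sum to 1 within $10^{-8}$ per site.
* Pedigrees are topologically sorted internally; cycles are an error
  naming the animals involved.
* Missing genotypes entering $G$ are imputed to $2p_i$ with a logged
  count; animals missing more than 5% of sites are rejected.
* Configuration files are JSON (round-tripped losslessly, unknown keys
  rejected). JSON was chosen over YAML so the package has no dependency
  outside the guaranteed-available set.
* The null control for permutation selection needs records to dominate the
  kept subset: selecting $k$ variants on the same phenotypes used to
  re-estimate $h^2$ leaves an irreducible selection-bias floor of roughly
  $k\,z^2/n$ (with $z$ the null exceedance quantile), so the no-QTL
  collapse ($\hat h^2 < 0.1$) is only visible when $n \gg k$, matching the
  full-scale design of a few hundred selected variants against tens of
  thousands of records. The package tests use $n = 500$, $k = 6$.

## Known limitations

* The HMM stores $K^2$ doubles per site (predicted forward state), about
  400 MB at $K = 100$, $T = 5000$; cap `max_panel` or chunk chromosomes
  for larger problems.
* REML is dense ($O(n^3)$ per iteration) and intended for desk-scale
  $n \lesssim 2000$.
* Single chromosome per simulation; multi-chromosome worlds are
  independent replicates with concatenated coordinates.
* The permutation null refits breeding values with fixed variance
  components (standard practice); it does not re-estimate REML per
  permutation.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- default_config(
  seed = 11L,
  sim = list(n_panel_haplotypes = 60L, n_variants = 500L,
             chromosome_length = 2e6, n_target_animals = 16L,
             n_qtl = 20L, coverage = 1.0),
  impute = list(max_panel = 60L),
  agreement = list(min_compared = 10L),
  effects = list(holdout_fraction = 0.25, n_perm = 30L,
                 subset_fraction = 0.2))
res <- run_pipeline(cfg, out_dir = tempfile("lpeval_demo_"))
res$lib_report[1:3, ]     # per-library CC, correlation, pass rate
res$validation            # the MBV validation grid
```

Every number in the outputs is recomputed from scratch on each run and is
identical on rerun with the same config; the tests assert this byte-wise.
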