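---
title: "Severity-weighted aggregative variant association: model and design"
author: "aggvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-weighted aggregative variant association: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggvar)
```

## The problem

Single-variant association tests are powerless for rare alleles: a variant
seen a handful of times cannot reach genome-wide significance on its own.
Aggregative variant association tests pool the evidence across all the
variants of a gene, and gain further power by weighting each variant by how
likely it is to damage the protein. This package implements such a test: a
composite binomial likelihood-ratio test over case/control allele counts in
which each variant's contribution is updated by a *severity ratio* learned
from disease and neutral training variants, with phylogenetic conservation
controlled explicitly. Around the test it provides the full study
apparatus: coding-consequence annotation, severity-matrix training,
baseline tests, simulators, and a benchmarking harness.

## The severity matrix

Every coding change is an ordered amino-acid substitution (AAS) type over a
21-symbol alphabet (20 amino acids plus stop, so nonsense and stop-loss
changes are scoreable types). For type $i$, two endpoint likelihoods are
estimated from a disease training set of size $C_D$, using each variant's
conservation score $P_{ij} \in [0,1]$ (a PhastCons-style probability of
negative selection) as a soft assignment between the fully conserved and
fully unconserved endpoints:

$$a_{i1} = \frac{1}{C_D}\sum_j P_{ij}, \qquad
  a_{i0} = \frac{1}{C_D}\sum_j (1 - P_{ij}),$$

and analogously $h_{i1}, h_{i0}$ from a neutral set of size $C_N$. The
severity of a variant of type $i$ at conservation $x$ is the linear
interpolation **of the endpoint ratios**

$$\frac{a_{ix}}{h_{ix}} = x\,\frac{a_{i1}}{h_{i1}} +
  (1-x)\,\frac{a_{i0}}{h_{i0}},$$

not an interpolation of numerator and denominator separately; the two
parameterizations differ whenever $h_{i1} \neq h_{i0}$, and the ratio form
is the one that makes the severity a convex combination of the two
endpoint likelihood ratios.

Zero cells are floored with a Laplace-style pseudocount
$\varepsilon = 1/(C + m)$ ($C$ = training-set size, $m$ = number of types:
420 for AAS, 20 for indel categories) added to every endpoint when ratios
are formed. The stored matrix keeps the raw proportions, so the
normalization $\sum_i (a_{i0} + a_{i1}) = 1$ holds exactly and the
pseudocount scheme can be changed without retraining. A type absent from
both sets scores $\varepsilon/\varepsilon = 1$: no evidence, no weight.

Indels are binned by kind (insertion/deletion), affected coding length
(1, 2, 3, 4--9, $\ge$10) and reading-frame status; the bin's severity is
the pseudocounted ratio of its disease and neutral proportions, with no
conservation interpolation. The length bins are this package's choice --
small fixed bins keep every category estimable from a few thousand
training indels.

## The gene test

For one variant with $x_c$ alternate alleles out of $n_c$ case chromosomes
and $x_b$ out of $n_b$ background chromosomes, the frequency term is the
binomial log likelihood ratio

$$\ell = \log \frac{\max_{p_c, p_b} L(x_c; p_c) L(x_b; p_b)}
                    {\max_{p} L(x_c; p) L(x_b; p)} \ge 0,$$

with binomial coefficients cancelling and $0\log 0 = 0$. The variant's
contribution is $\max(0, \ell + \log(a_{ix}/h_{ix}))$ if the case
frequency exceeds the background frequency and $0$ otherwise; the gene
score is twice the sum of contributions. The one-sided clamp is
deliberate: the test targets risk-increasing alleles, and letting
background-enriched or neutral sites subtract signal would allow a few
common benign variants to erase a genuine rare-variant burden.

**Collapsing.** Before scoring, variants with background MAF below 0.01
(or background allele count at most 1; both configurable) are merged into
one pseudo-variant per category -- one group for SNVs, one for indels, so
imprecisely called overlapping indels always share a group. Group counts
are member sums (capped at the chromosome count); group severity is the
case-allele-count-weighted mean of member severities, falling back to the
plain mean when no case alleles are observed. Weighting by case counts
reflects that the group's severity should describe the alleles actually
driving its case excess.

**Inheritance options.** The recessive option zeroes a gene's score unless
some case individual carries at least two scoring allele copies in the
gene; the dominant option requires one (which any scoring gene satisfies).
These are power boosters for known inheritance modes, not assumptions of
the default test.

**Significance.** Permutation of case/control labels is the reference
mode, with the $(k+1)/(N+1)$ estimator and the full scoring path --
group membership, group severities, clamping -- recomputed under every
relabeling (an exhaustive-enumeration mode is available for small
cohorts). For deep-tail thresholds such as the genome-wide level
$2.4\times10^{-6}$, permutation is infeasible and an asymptotic mode is
provided: the frequency-only clamped statistic is referred to its
large-sample null, the chi-bar-square mixture
$\sum_{j=0}^{k} \binom{k}{j} 2^{-k} \chi^2_j$ over the $k$ evaluated
pseudo-variants. A plain $\chi^2_k$ would be wrong here: each clamped
one-sided component is a half-half mixture of a point mass at zero and
$\chi^2_1$, and ignoring that is badly conservative for $k > 1$ (for
$k = 1$ the mixture is half the $\chi^2_1$ tail). The asymptotic mode
holds the severity term out of the statistic because the severity update
has no chi-square calibration; the test suite checks that the two modes
agree within Monte-Carlo error at moderate levels. Ranking sorts by
ascending p, breaking ties by descending score (so the severity evidence
orders genes the frequency term cannot separate) and then by gene id; rank
bins 1--10 / 11--100 / 101--1000 / >1000 follow the genome-wide search
convention.

## Annotation

Gene models are minimal: chromosome, strand, CDS intervals (1-based
inclusive at the interface, converted internally), and the coding-strand
CDS. Multi-transcript genes use the longest-CDS transcript, so each
variant gets one deterministic annotation. SNVs are translated through the
standard genetic code with reverse-complementation on the minus strand; a
VCF reference allele that contradicts the gene model is a hard error,
while positions outside every CDS are simply `noncoding`. Indels use the
VCF left-anchored convention; only the CDS-overlapping portion counts
toward the affected length and frame status, and boundary-spanning events
are flagged. The conservation score of an SNV is taken at the variant
position; for a deletion it is the mean over the deleted positions --
the summary over a span is this package's choice, as is the missing-score
policy (default: score 0, i.e. unconserved, so every variant remains
scoreable; `na` and `error` policies are available). Splice, UTR and
regulatory consequences are out of scope; such variants still enter the
frequency term with severity 1.

## The simulators

`simulate_case_control()` implements the population-attributable-risk
framework: the total PAR is split equally over `nd` causal sites
($PAR_i = PAR/nd$); each site draws a MAF $p_i$, forms its risk-genotype
frequency ($g_i = 1-(1-p_i)^2$ dominant, $p_i^2$ recessive), and solves
$RR_i = 1 + PAR_i / (g_i(1-PAR_i))$. Case genotypes come from the
Bayes-inverted per-site distribution $P(G\mid\text{case}) \propto
P(\text{case}\mid G) P(G)$ (sites independent under the multiplicative
risk model; the closed form
$P(\text{risk genotype}\mid\text{case}) = PAR_i + g_i(1-PAR_i)$ is exposed
as `risk_genotype_case_freq()` and verified against the generator);
controls use Hardy-Weinberg population frequencies, the rare-disease
approximation (default prevalence 0.01, at which the approximation error
is negligible next to Monte-Carlo noise). Causal sites are annotated as
high-conservation damaging changes and noncausal sites as low-conservation
benign ones, so the severity pathway is exercised end to end.

**The MAF spectrum.** The default causal-site MAF law is log-uniform on
$[10^{-5}, 2\times10^{-4}]$ (mean MAF $\approx 6\times10^{-5}$),
a 1/p-shaped spectrum for alleles held rare by purifying selection --
under mutation--selection balance a deleterious allele with selection
coefficient $s$ equilibrates near $\mu/s$, orders of magnitude below
common-variant frequencies. This regime is the one rare-variant
aggregative tests are built for: with causal MAFs in the percent range a
collapsed rare-variant statistic has essentially no power at the
published sample sizes, because each site's case-control allele excess is
fixed by its PAR share while the collapsed background frequency (the
noise) grows with the MAFs. Power results are sensitive to this choice,
which is therefore configurable (`maf_distribution`), and the spectrum
applies to causal and noncausal sites alike.

`simulate_stratified()` draws two subpopulations from the Balding-Nichols
beta model around shared ancestral MAFs (default $F_{st} = 0.01$, the
order of within-Europe differentiation) and mixes them into cases and
controls at configurable ratios; there are no causal sites, so any excess
of significant genes is stratification-induced false positives.
`spike_in_mendelian()` builds a multi-gene background panel from a
site-frequency model spanning rare through common variation and inserts
one (dominant) or two (recessive) distinct high-severity alleles per case
genome into a target gene, absent from all background genomes -- the
spike-in ranking protocol. The default panel size of 2,000 genes is a
desk-scale stand-in for a full exome; the test suite uses 100--150-gene
panels, which leaves rank bins comparable because null genes are
exchangeable. `generate_training_sets()` emulates a curated
disease-mutation database (conservation $\sim$ Beta(8,2), nonsense and
cross-property-group missense changes enriched, frameshift-enriched
indels) and a common-variant neutral set (Beta(2,8), benign profile).

**What the simulations do not emulate:** linkage disequilibrium (sites
are independent), sequencing and genotyping error, covariates and
relatedness, locus heterogeneity across genes, and real mutation-spectrum
composition. Passing tests therefore certify the statistical machinery
under the stated generative model, not performance on any particular real
cohort; the real-data behavior of the method depends on training-set
quality and cohort structure in ways synthetic data cannot capture.

## Numerical and degenerate-input choices

* $0 \log 0 = 0$ throughout; the log-LR is clamped at 0 against
  floating-point rounding (it is analytically non-negative).
* Genes with no variants score 0 with p = 1; zero scoring variants give
  asymptotic p = 1.
* Missing genotypes are excluded from both the allele and chromosome
  counts of their cohort when observed counts are formed; within
  collapsed groups and under permutation they are treated as reference
  (the permutation conditions on the observed missingness pattern).
* Pseudo-variant counts are capped at the cohort chromosome count so the
  collapsed frequency stays a probability even for extremely burdened
  groups.
* Sample-size searches walk the grid ascending and stop at the first
  size meeting the power target; Monte-Carlo error on each grid point is
  reported so near-threshold crossings can be recognized as such.

## Problem sizes used by the test suite

The suite runs at desk scale by design: 100 replicates for power points
(300 per grid point in the sample-size checks, bringing the per-point
Monte-Carlo error near 2%), 1,000 null genes for type-I error control,
10,000 cases for parameter-recovery checks, and 100--150-gene panels for
the spike-in ranking protocol. These sizes make every stochastic
acceptance check reproducible in minutes on one CPU while keeping
Monte-Carlo bands tight enough to be informative.

## Known limitations

Dichotomous phenotypes only; no covariate adjustment, so stratified
cohorts inflate the false-positive rate exactly as the stratified
simulator demonstrates -- the package measures this but does not correct
it. No linkage-disequilibrium modeling. Annotation covers CDS
consequences against a single transcript per gene; GVF output is not
emitted (VCF plus a tab-separated annotation table carry the same
information). The bundled training-set generator is a synthetic stand-in
for licensed disease-mutation databases: severities trained from it are
internally consistent but not transferable to real variant
prioritization, for which users should supply their own training tables.
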