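---
title: "CNV calling, signal review and case-control association with cnvflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV calling, signal review and case-control association with cnvflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cnvflow` implements a complete SNP-array copy-number-variant (CNV)
case-control association workflow of the kind used in large
neurodevelopmental-disorder (NDD) cohort screens: signal simulation, HMM
calling from Log R Ratio (LRR) and B-allele frequency (BAF) tracks,
sample-level quality control, automated "review first" validation of every
call against expected signal structure, probe-level Fisher association
collapsed into CNV regions (CNVRs), multiple-testing correction, and
restriction to a gene network of interest. Because cohort-scale patient
genotype data are not publicly distributable, the package ships a
first-class synthetic-data module that generates cohorts with planted CNVs,
and every downstream claim about the pipeline's behaviour is demonstrated
on those cohorts.

# The generative signal model

A SNP array reports, per probe, a log-scaled total intensity (LRR, zero for
two copies) and the fraction of signal from the B allele (BAF). For a probe
with population B-allele frequency $p$ inside a segment of copy number
$c$, the number of B alleles is $k \sim \mathrm{Binomial}(c, p)$ and BAF
clusters at $k/c$:

* $c=1$: clusters at $\{0, 1\}$ — no heterozygotes;
* $c=2$: $\{0, 1/2, 1\}$;
* $c=3$: $\{0, 1/3, 2/3, 1\}$;
* $c=4$: $\{0, 1/4, 1/2, 3/4, 1\}$;
* $c=0$: no genotype exists; BAF is diffuse (uniform noise).

`signal_model()` parameterises the emission Gaussians. The defaults —
LRR means $-3.5, -0.66, 0, +0.40, +0.68$ for copy numbers 0–4, SD 0.18
(1.3 at copy 0, where only background hybridisation remains), BAF cluster
SD 0.03, 0.5% genotype no-calls — are conventional values for Illumina-style
arrays; the qualitative pattern (deletion = LRR drop and loss of
heterozygous BAF; duplication = LRR rise and interior clusters at thirds or
quarters) is what the downstream review stage asserts, and every number is
configurable. No public noise calibration exists for the specific arrays
such screens use, so these defaults are a modelling choice, made once, not
a fit.

BAF is clipped to $[0,1]$: boundary clusters become half-Gaussians with an
atom of mass exactly at 0 or 1, matching the hard floor and ceiling of
array BAF. Genotype calls are derived from the BAF cluster (below 0.25
$\to$ AA, above 0.75 $\to$ BB, otherwise AB), so deletions carry no
heterozygous calls; copy-0 probes and a small random fraction of all probes
are no-calls that keep their intensity signal. The default no-call rate
(0.5%) leaves unmodified samples above the call-rate filter; a
degraded-sample flag raises it so the filter can be exercised both ways.

What the generator deliberately does **not** model: GC-content intensity
waves, array-version batch shifts, mosaic (fractional) copy states, and
nested or overlapping events in one sample (rejected at generation).
Passing tests therefore certify the pipeline's logic under clean
Illumina-like noise, not its robustness to wave artefacts or mosaicism on
real arrays.

# The copy-number HMM

`viterbi_call()` decodes a five-state (copy number 0–4) HMM per chromosome.
PennCNV-style callers additionally model copy-neutral LOH; that state is
omitted here because nothing downstream consumes it. Emissions multiply a
Gaussian LRR term by a binomial-weighted BAF cluster mixture (half-Gaussian
boundary clusters, uniform for copy 0); both factors are floored at
$10^{-9}$ so a single outlier probe cannot dominate a segment. Probes with
failed genotype calls contribute the LRR factor only — the signal is
present even when genotyping fails — and fully missing probes contribute
nothing.

Transitions depend on inter-probe distance $d$: the probability of leaving
the current state is $\beta\,(1 - e^{-d/L})$ with $\beta = 10^{-3}$ and
$L = 100$ kb, so adjacent probes are sticky and distant probes approach
independence; at $d=0$ the matrix is the identity. From the diploid state
the exit mass splits equally over the four CNV states; from a CNV state 80%
of the exit mass returns to diploid (a CNV segment is far more likely to
end in diploid than to jump to another aberrant state). These forms and
constants are design choices made for stability — the field's callers do
not publish a single canonical transition model — and are configurable
through `hmm_params()`. With them, entering a CNV costs roughly 9–10 log
units, i.e. two to three probes of consistent evidence, which is what makes
the 3-probe detection floor meaningful rather than vacuous.

Maximal non-diploid runs of at least `min_probes` (default 3) probes become
calls. Each call's confidence is the log-likelihood ratio of the decoded
path against the all-diploid path over the call span (emissions plus
within-span transitions). This definition is local to this package:
PennCNV prints a `conf` field but does not document its formula, so the
round-trippable `rawcnv` dialect here carries this LLR instead.

The decoder is validated against exhaustive enumeration of all $5^n$ state
paths on random instances up to 10 probes — the dynamic program and the
enumeration share emissions and transitions but nothing else.

# Sample QC

Following standard array-QC practice for these screens, a sample is
excluded if its genotype call rate is not above 0.985, if the standard
deviation of its LRR track is not below 0.30, or if it carries any call
longer than 10 Mb (large syndromic events are a clinical finding, not
cohort-association material; the generator can plant a whole-chromosome
event to exercise this path). The first matching rule, in that order, is
recorded as the exclusion reason.

# Automated signal review

Cohort screens of this kind manually inspect every candidate call before
association ("review first"). `score_call()` operationalises that
inspection with explicit thresholds, every one of which is reported in the
verdict table so a reviewer can audit the decision:

* **Deletions (copy 1)**: region median LRR below $-0.25$, and at most 2%
  of informative probes (population B-allele frequency in $[0.05, 0.95]$)
  with BAF in the heterozygous band $(0.25, 0.75)$. Heterozygosity is
  measured from BAF, not genotype calls, because genotyping fails inside
  real CNVs while BAF remains informative.
* **Homozygous deletions (copy 0)**: region median LRR below $-1.0$; BAF is
  diffuse noise at zero copies, so no heterozygosity test applies.
* **Duplications (copy 3/4)**: region median LRR above $+0.15$, and more
  BAF mass within 0.07 of the state's interior clusters ($\{1/3, 2/3\}$ or
  $\{1/4, 1/2, 3/4\}$) than in the rest of the heterozygous band — a
  diploid region's 0.5-cluster fails this for copy 3 directly, and fails
  copy 4 on the LRR rule.
* **Flanks**: the flanking region (call width per side, capped at 50
  probes; one-sided at chromosome ends) must look diploid — median LRR
  within $\pm 0.10$ and at least 10% heterozygous BAF among informative
  probes. A call without a diploid-looking flank is indistinguishable from
  a baseline shift.
* Fewer than 3 informative probes in the region is an automatic fail: the
  BAF evidence the review relies on does not exist.

The numeric cut-offs quantify rules that are stated qualitatively in the
visual-review tradition (deviation below/above zero, absence of
heterozygotes, normal flanks); they were chosen once from the geometry of
the signal model — e.g. $-0.25$ is about one-third of the copy-1 LRR shift
and more than one noise SD from zero — and are deliberately asymmetric
(duplications shift LRR less than deletions do). On balanced synthetic sets
of true planted calls versus fabricated diploid-span calls the review
achieves $\ge 95\%$ sensitivity and specificity, which is the package's
operating claim for it.

# Association and multiple testing

Deletions (copy $<2$) and duplications (copy $>2$) are tested separately
throughout; a region is never labelled both. At every probe,
`probe_burden()` counts distinct carrier samples per cohort (a sample
counts once per probe and class regardless of how many calls overlap), and
`fisher_exact_2x2()` tests the carrier table with the two-sided Fisher
exact test — the sum of hypergeometric probabilities of tables no more
probable than the observed one. The reported odds ratio is the sample odds
ratio $\frac{a/(N_\mathrm{case}-a)}{b/(N_\mathrm{ctrl}-b)}$ — the quantity
such studies print — not the conditional MLE `stats::fisher.test()`
reports; it is $\infty$ when $b=0<a$, with no continuity correction by
default.

`collapse_cnvr()` merges significant probes ($p < 0.05$) of the same class
and chromosome into a CNVR whenever consecutive *significant* probes are at
most 1 Mb apart; intervening non-significant probes do not break a region
(the literal reading of "within 1 Mb of each other", and configurable).
The region reports its peak probe — the regional minimum $p$, smallest
position on ties — with counts and odds ratio taken there.

Corrections run within the family of discovered CNVRs per contrast and
class: Bonferroni ($p \times m$, capped at 1), Benjamini–Hochberg FDR, and
simpleM, where the effective test count $M_\mathrm{eff}$ is the smallest
number of principal components of the member-probe carriage-indicator
correlation matrix explaining $\ge 99.5\%$ of variance (constant columns
dropped, floor of 1). A CNVR is significant when any corrected value is at
most 0.05. On the simulated cohorts all three corrections agree, as they
do in practice when regions are few and highly correlated.

Phenotype contrasts (ADHD, ASD, ADHD+ASD, pooled NDD — each against all
controls) run independently on their own QC-passed sample sets;
`render_summary()` aligns the resulting CNVRs across contrasts by class and
interval overlap into one wide table and flags each locus's most
significant contrast.

# Gene-network restriction

`load_gene_bed()` accepts any BED gene list (converted from 0-based
half-open to the 1-based inclusive convention used everywhere else;
duplicate symbols collapse to union intervals). Overlap of at least 1 bp
assigns a gene — published screens state "overlapping" without a fractional
threshold. Restriction can be applied to the call set before burden
counting (default, treating the network as the search space, as a targeted
screen does) or to discovered CNVRs before correction; in both modes the
correction family is recomputed after restriction, so restricting never
inherits a larger family's penalty. The 273-gene mGluR-network list used in
the motivating screens is supplementary material, not redistributable data,
so analyses here use a synthetic gene set (labelled as such); any real list
drops in through the same BED interface.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the PennCNV convention);
  BED is converted at the reader boundary.
* Probability floors of $10^{-9}$ keep every emission finite; transition
  zeros at distance 0 are handled in log space by the decoder.
* Viterbi ties (measure-zero under continuous noise) resolve to the
  lowest-numbered state; CNVR peak ties resolve to the smallest position.
* An all-missing chromosome is skipped with a warning; an empty call set
  flows through review, association and summary as empty tables, not
  errors.
* Simulation, calling, review and association are pure functions of their
  arguments and seeds; the pipeline manifest records the seed and a
  configuration hash, and reruns are byte-identical.

# Problem sizes used in the shipped analyses

The bundled analysis scripts and the verification suite run, by design, at
desk scale: cohorts of 200–240 samples on maps of 2,000–4,000 probes for
signal-level claims (caller recall/precision $\ge 0.95$ with $\ge$10-probe
events; review sensitivity/specificity $\ge 0.95$ on 200 true versus 200
fabricated calls), and carriage-level cohorts of 2,000 cases and 2,000
controls — skipping per-probe signal, which the caller's own checks already
cover — for the statistical claims (family-wise false-positive rate of the
corrected association at most $0.05 + 2\,\mathrm{SE}$ over 1,000 null
replicates; $\ge 90\%$ recovery of a locus planted at 2% case versus 0.2%
control frequency). Published cohort-scale results (tens of thousands of
samples, hundreds of thousands of probes) are not reproducible without the
patient data; the package instead reproduces exactly the published
worked-example statistics that are fully determined by printed counts —
carrier tables like 40/7,920 vs 12/19,993 give odds ratio 8.45 and
$p = 5.26\times 10^{-13}$ from `fisher_exact_2x2()` alone.

# Known limitations

* The HMM is single-sample: no trio calling, no multi-array consensus
  training (a single parameter set is configured per run), no GC-wave
  adjustment, no mosaic fractions.
* The review thresholds are tuned to the generative model's geometry; on
  real arrays with waves or batch shifts the flank rules in particular
  would need recalibration.
* Batch matching is represented as an optional metadata column; the
  default analysis pools batches into one Fisher table, with
  `cmh_peak_test()` available to re-test CNVR peaks stratified by batch
  (Cochran–Mantel–Haenszel) when batch confounding is a concern.
* Printed odds ratios in the motivating literature that are inconsistent
  with their stated cohort totals (implying undisclosed per-analysis
  denominators) are not targets of the verification suite.
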