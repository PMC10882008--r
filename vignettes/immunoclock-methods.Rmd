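---
title: "Methods: tracking immune escape across sequential tumor samples"
author: "immunoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking immune escape across sequential tumor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoclock)
```

# Scope and model overview

`immunoclock` implements the quantitative backbone of a longitudinal
immuno-genomic study design: a patient is sampled repeatedly over the course
of metastatic disease (sequential on-treatment biopsies) and again across
many anatomical sites at one terminal time point (parallel multiregion
samples).  Four complementary views are computed per sample and then
integrated:

1. **TCR repertoire structure** — diversity, overlap, and a sequence
   similarity network over CDR3 amino-acid clonotypes;
2. **immune microenvironment state** — gene-signature scores and an
   inflamed / desert / excluded immunophenotype;
3. **clonal architecture** — clonality calls, subclonal Shannon diversity,
   mutational burden and neoantigen filtering;
4. **a molecular clock** — a relative 0–1 timeline for mutations and
   neoantigens built from multiplicities around copy-number gains.

Because the data such studies use are protected patient genomes, every
module is exercised against seeded synthetic generators whose ground truth
is emitted alongside the data.  The generators are first-class, tested code:
the package's claims about recovery accuracy are claims about these
generating processes, not about any patient cohort.

# TCR repertoire and similarity networks

A clonotype is a unique CDR3 amino-acid string with a template count.  Only
productive rearrangements enter statistics; non-productive rows are retained
on ingest for auditability.  Diversity is the inverse Simpson index
$1/\sum_i p_i^2$ (the effective number of equally abundant clonotypes;
values near 1 indicate expansion).  Pairwise repertoire overlap is the
abundance-weighted Morisita–Horn index

$$C = \frac{2\sum_i x_i y_i}{(d_x + d_y)\,X\,Y}, \qquad
  d_x = \sum_i x_i^2 / X^2 ,$$

which is 0 for disjoint and 1 for compositionally identical repertoires and
is invariant to uniform count rescaling.  Because sharing statistics depend
strongly on repertoire size, samples are downsampled to a common number of
unique clonotypes (default 1000, drawn uniformly without replacement with
counts preserved) before overlap comparisons; template-level rarefaction is
available as a non-default option.  Overlap is computed after downsampling
by default; both orders are possible and the choice is configurable.

The similarity network has one node per unique productive CDR3 across all
samples and an edge wherever the Levenshtein distance between two sequences
is exactly 1 (one substitution, insertion, or deletion).  Building this by
all-pairs comparison is quadratic, so the implementation uses symmetric
deletion indexing: each sequence is keyed by itself and every
single-deletion variant; only key-sharing candidate pairs are verified with
an exact distance-1 check.  The test suite proves the indexed edge set equal
to brute-force all-pairs Levenshtein on every tested input.  Three
connectivity metrics summarize a network: density $2E/(N(N-1))$, the mean
local clustering coefficient (nodes of degree $<2$ contribute 0 — a stated
convention, since it changes the average), and the S metric
$\sum_{(u,v)\in E}\deg(u)\deg(v)$.  Stability under unequal sample sizes is
assessed by a bootstrap (default 10 replicates) that downsamples every
sample to the smallest sample's size and recomputes all metrics.

# Immune signatures and immunophenotypes

Raw counts are normalized per sample by subtracting the mean
$\log_2(\text{count}+1)$ of ten housekeeping genes (geometric-mean scaling
on the log scale), after which the housekeeping mean is exactly zero in
every sample.  Signature scores are arithmetic means of member-gene values;
weighted scores use $\sum_g w_g z_g / \sum_g |w_g|$ on cohort-wide per-gene
z-scores.  The $\sum|w|$ normalizer (rather than $\sum w$) is a deliberate
interpretation of a "weighted arithmetic mean": it stays bounded and
sign-interpretable when weights have mixed signs.  Whether to z-score is
configurable (`zscore = FALSE` combines raw normalized values).

The cytolytic score is the geometric mean of GZMA and PRF1 on the linear
scale; when either value is 0 in a sample, a pseudocount of +1 enters both
terms for that sample so the score stays finite and monotone.

The exhaustion metagene uses eleven checkpoint genes (PDCD1, LAG3, HAVCR2,
KLRG1, TIGIT, CD244, CD160, BTLA, CTLA4, ENTPD1, ID2) with weights equal to
each gene's log2 fold-change in a metastasis-versus-primary comparison, so
the more exhausted group scores positive by construction.

Immunophenotypes are assigned from the IFN-γ signaling and
antigen-presentation machinery (APM) scores with the cohort medians as
cutoffs: IFN ≥ median and APM ≥ median is *inflamed*; IFN < median is
*desert* regardless of APM; IFN ≥ median with APM < median is *excluded*.
Ties at the median count as "high" — stated explicitly because it changes
the class exactly at the boundary.  Only median comparisons are used, so
the classification is invariant under strictly monotone transforms of both
score vectors.  The bundled IFN-γ/APM/proliferation gene sets are editable
GMT defaults assembled from conventional literature members, not an
authoritative platform definition.

# Clonal architecture

A mutation is **clonal** when its probability of being clonal exceeds 50%
or the lower bound of the 95% CI of its cancer cell fraction (CCF) exceeds
0.9; otherwise subclonal.  When a callset carries no external clonality
annotations, the package computes both pieces of evidence itself from read
counts:

* the CCF point estimate and Clopper–Pearson 95% interval on the VAF,
  propagated through the multiplicity algebra below; and
* a clonality probability from a two-hypothesis binomial model — clonal
  (CCF = 1, binomial likelihood maximized over integer multiplicities up to
  the major copy number) versus subclonal (multiplicity 1, CCF uniform on
  (0, 1), integrated numerically).  The mixture weight between the
  hypotheses is estimated from the callset by EM rather than fixed at 1/2,
  mirroring how cluster-based callers borrow strength across mutations: in
  a mostly clonal sample, a borderline mutation should not be over-called
  subclonal.  A fixed prior is available via `prior_clonal`.

Subclonal diversity is the Shannon–Wiener index
$H = -\sum_i p_i \log_2 p_i$ over clonal-cluster proportions.  The default
$p_i$ is each cluster's share of mutations; normalized cellular prevalence
is offered as an alternative, since "proportion of the community" admits
both readings.  Tumor mutational burden is the nonsynonymous count per
megabase of capture footprint (65 Mb for the Agilent exome design, 37 Mb
for Nextera).  A nonsynonymous mutation passes the neoantigen filter when
predicted binding affinity ≤ 500 nM **and** rank percentile ≤ 2% **and**
expression ≥ 5 TPM, all thresholds inclusive; an affinity-OR-rank variant is
available behind a flag because the conjunction is a design choice.

# The molecular clock

For a clonal mutation observed at variant allele fraction $v$ in a tumor of
purity $\rho$ with total copy number $C_T$ at the locus (normal $C_N = 2$),
the multiplicity is

$$m = v\,\frac{\rho C_T + (1-\rho) C_N}{\rho}.$$

On a segment that gained one allele, mutations acquired *before* the gain
were duplicated with it ($m = 2$); mutations after the gain have $m = 1$.
Four timing states follow: `clonal_early` ($m=2$ on a gained segment),
`clonal_late` ($m=1$ on a gained segment), `clonal_not_specified` (clonal
on a non-gained segment), `subclonal`.  Per-mutation states use hard
maximum-binomial-likelihood assignment over $m \in \{1, 2\}$ — a
deliberately desk-scale, oracle-testable substitute for the full Bayesian
multiplicity assignment of the timing literature.

With per-copy mutation accumulation at unit rate, a segment gained at
molecular time $t \in [0,1]$ accumulates $m{=}2$ mutations in proportion
$t$ on the pre-gain gained copy and $m{=}1$ mutations on every other
copy-time interval.  Counting copies gives, for $n_2$ multiplicity-2 and
$n_1$ multiplicity-1 clonal mutations:

* (2,1): $n_2 \propto t$, $n_1 \propto t + 3(1-t)$, hence
  $t = 3n_2/(2n_2+n_1)$;
* (2,2): $n_2 \propto 2t$, $n_1 \propto 4(1-t)$, hence
  $t = 2n_2/(2n_2+n_1)$;
* (2,0): the lost allele's pre-gain mutations vanish, giving the same
  $2n_2/(2n_2+n_1)$ form.

Estimates are clipped to $[0,1]$.  By default the multiplicity-2 *fraction*
entering these formulas is not the hard count ratio but the
maximum-likelihood weight of a two-component binomial mixture fitted by EM
per segment: hard assignment contaminates the minority class in proportion
to the majority class's size, which biases $t$ upward near 0 and downward
near 1, while the mixture MLE is asymptotically unbiased.  The hard counts
are always reported alongside (`n1`, `n2`), and `method = "counts"`
restores the plain count estimator.

A sample's molecular time **T1** is the mode of its first-gain times:
a 100-bin histogram over $[0,1]$ of per-segment gain times, weighted by
informative-mutation count, with ties broken toward the earlier bin (bin
count configurable).  The histogram-mode construction is a declared
stand-in: the upstream literature names the quantity without specifying the
density or weighting.  "First gains" are interpreted as the single gain
event per segment; whole-genome-doubling chronology is out of scope.
Samples are stratified at the cohort T1 quartiles (type-7 linear
interpolation): T1 ≤ Q25 → *early*, T1 ≥ Q75 → *late*, else *inter*, with
boundaries inclusive and early taking precedence, so an all-equal cohort is
all early.  Quartile cutoffs are computed over all samples including the
primary tumor.  **Neoantigen Time** applies the same timeline to mutations
passing the neoantigen filter and reports the early/inter/late proportions
per sample (clonal_early → neo-early; clonal_late and clonal_not_specified
→ neo-inter; subclonal → neo-late); a sample without neoantigens yields an
explicit flagged result, not silent zeros.  Samples are ordered by
agglomerative hierarchical clustering (Euclidean distance, average linkage)
of the samples-by-segments gain-time matrix, with untimed segments
mean-imputed per segment.

Segment coordinates are 1-based inclusive on ingest and converted to
0-based half-open internally; mutations map to segments by point
containment, and a mutation outside (or inside more than one) segment is an
error rather than a silent drop.

# Integration statistics

Correlations between per-sample features follow a fixed decision rule:
Pearson only when both variables pass Shapiro–Wilk at α = 0.05, neither
contains an outlier (|robust z| > 3.5 on median/MAD — a concrete stand-in
for a visual "absence of outliers" check), and a quadratic-term t-test
finds no curvature at α = 0.05 (the stand-in for "presence of a linear
relationship"); otherwise Spearman.  The decision trail is returned so the
choice is reproducible.  Correlation matrices are computed on
pairwise-complete observations, masked at p > 0.05, and deliberately carry
no multiplicity adjustment by default (Benjamini–Hochberg is behind a
flag), matching the exploratory single-cohort setting they serve.
Ordinal features such as the number of imbalanced HLA class-I alleles
(0–3) enter as numeric columns.

The Mann–Kendall trend test reports $S=\sum_{i<j}\mathrm{sign}(x_j-x_i)$,
$\tau = S/\binom{n}{2}$ and a two-sided p-value: exact for tie-free series
with $n \le 10$ (inversion-number recursion over the permutation null),
exact by full multiset enumeration for tied series with $n \le 8$, and a
tie-corrected normal approximation with continuity correction otherwise.

# Synthetic generators: what they emulate, and what they do not

**Repertoires.** Clonotypes are drawn from a global pool containing planted
single-edit families (ancestor plus distance-1 variants — the substrate of
network edges).  A day-indexed active pool evolves by retaining members
across a lag of $\Delta t$ days with probability
$2^{-\Delta t/\text{halflife}}$, so expected sharing decays with temporal
lag at a controlled half-life; an infinite half-life removes the decay.
Later samples draw a growing fraction of clonotypes from a fixed convergent
subpool, emulating convergent evolution.  Abundances are Zipf over ranks
(heavy-tailed expansion with controllable inverse Simpson).  CDR3s use the
20 standard amino acids at lengths 8–20.  Defaults mirror a closely
monitored index case: nine samples — four sequential (days 373, 799, 1687,
1687) and five parallel at day 2033 — with 2000 unique clonotypes each
(within the reported per-sample range of unique productive rearrangements),
100 families of 5, Zipf exponent 1, sharing half-life 500 days and a
convergence rate of $2\times10^{-4}$ per day; the cohorts behind the design
publish no distributional detail, so these are documented stand-ins chosen
once as plausible, not fitted values.  There is no V(D)J recombination,
thymic selection, or sequencing-error model on CDR3 strings.

**Expression.** $\log_2$ values are gene baseline + class effect +
Gaussian noise; housekeeping genes have constant baseline and zero planted
effect, so housekeeping normalization is exact up to noise.  Effects can be
a per-gene vector (two classes) or a gene-by-class matrix.  No
count-distribution (e.g. negative binomial) realism is attempted: the
consumers are location-scale scores, and planting effects on the log scale
keeps truth exact.

**Genomes.** Segments carry allele-specific states (1,1), (2,1), (2,2),
(2,0); gained segments have a true gain time.  Clonal mutations get
multiplicity 2 with the accumulation-model probability ($t/(3-t)$ for
(2,1), $t/(2-t)$ for (2,2) and (2,0) — the same algebra the estimator
inverts), subclonal mutations draw CCF from a configurable interval
(default (0.1, 0.6), i.e. clearly subclonal populations).  Reads are
Poisson depth (mean 100 by default; 80 in the timing-recovery studies,
matching realistic exome coverage) with binomial alternate counts at the
expected VAF.  Neoantigen prediction columns are generated so the standard
filter reproduces the planted flag exactly.  Default purity 0.6 is a
typical exome-cohort value.  No subclone phylogeny, no subclonal
copy-number, no mutational signatures.

Passing recovery tests therefore demonstrates correctness of the inference
*given this generative model* — binomial read noise, correct segment
assignments, honest purity — not robustness to purity error, segmentation
error, or non-binomial overdispersion in real sequencing.

# Numerical choices and degenerate inputs

* Empty repertoires, empty housekeeping lists, zero-variance correlation
  inputs, samples with no timed gains ("untimeable"), and samples with no
  neoantigens all raise explicit, named errors rather than propagating NA.
* The EM loops (clonality weight; per-segment multiplicity fraction) run to
  a $10^{-8}$–$10^{-9}$ tolerance with bounded weights and a smoothed start
  so a zero hard count cannot pin the estimate at 0.
* Cohort z-scores map zero-variance genes to 0 instead of dividing by 0.
* `which.max` tie-breaking toward the first (earlier) histogram bin is
  relied upon and tested.
* All randomness flows from one root seed through derived child streams, so
  adding a consumer does not perturb existing ones; identical configuration
  and seed reproduce every output byte for byte.

# Problem sizes used by the test-suite studies

The packaged studies run at deliberately compact sizes chosen to keep
Monte-Carlo error well inside the asserted margins: gain-time recovery uses
2 copy-number states × 9 true times × 20 seeds at 500 mutations per
segment and depth 80; immunophenotype recovery uses 50 cohorts of 60
samples; exhaustion separation uses 100 replicate cohorts of 20;
correlation calibration uses 1000 independent feature pairs at n = 24; the
Mann–Kendall power study uses 500 replicate series of 9 time points.

# Known limitations

* The package consumes upstream products (cluster assignments, CCF
  annotations where present, binding predictions, purity and segments); it
  does not call variants, infer copy number, cluster clones, or predict
  binding.
* The clonality probability is a two-hypothesis approximation, not a full
  subclonal-structure model; heavily overlapping subclonal and clonal CCFs
  (low depth, low purity) will degrade both it and the timing states.
* T1's histogram-mode definition is one defensible reading of an
  underspecified construction; cohort-level conclusions should be checked
  for robustness to the bin count.
* Signature gene memberships ship as editable defaults; results on real
  data depend on the platform's actual panels.
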