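---
title: "Methods: somatic-evolution analysis of tumor WGS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic-evolution analysis of tumor WGS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somevo)
library(dplyr)
```

somevo reconstructs how a breast-cancer (or any tumor) genome evolved from
bulk whole-genome sequencing of a cohort: which mutations are clonal, how
unstable each genome is, which copy-number changes recur beyond chance,
how heterogeneous each tumor is, and in what order the recurrent events
happened. This vignette explains each model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Clonality from read counts

For a variant with VAF $f$ in a region of tumor copy number $n_t$, tumor
purity $\rho$, carried by $m$ chromosome copies (the multiplicity, or
NCBM), the cancer cell fraction is

$$\mathrm{CCF} = \frac{f\,(\rho n_t + 2(1-\rho))}{\rho\, m},$$

the fraction of tumor cells carrying the mutation. On subclonal
copy-number segments $n_t$ is the cell-fraction-weighted total copy
number of the two states, and the multiplicity estimate
$m = \mathrm{round}(f(\rho n_t + 2(1-\rho))/\rho)$ is clamped to
$[1, \max(\text{major allele count})]$. Variants inside homozygous
deletions, or not covered by any segment, have no defined CCF and are
excluded (they are returned in a `dropped` attribute with a reason).

Clonal status is decided without a CCF cut-off: the observed VAF is
modeled as binomial, its 95% interval is pushed through the CCF map, and
a variant whose upper CCF bound reaches 1 is indistinguishable from
clonal — it is reported clonal with CCF 1; anything else keeps its point
CCF as subclonal. The interval is Clopper–Pearson by default
(`ci_method = "clopper-pearson"`): exact at low depth and free of
normality assumptions; a Wald interval is available behind the same flag
for comparison. At 90× depth and purity 0.5 this rule assigns over 95% of
true-clonal and true-CCF-0.4 variants correctly (the acceptance suite
measures both rates).

In a whole-genome-duplicated tumor, a clonal mutation on two or more
copies must predate the duplication (it was copied along), while a clonal
single-copy mutation postdates it; subclonal mutations postdate the
clonal WGD by definition. This gives every coding mutation a
pre-WGD/post-WGD label used by the timing model.

## Purity QC and power

Heterozygous clonal SNVs in diploid 1+1 regions sit at VAF $\rho/2$, so
twice the clonal VAF peak is an independent purity estimate.
`estimate_purity_from_vaf()` takes a kernel density (Silverman bandwidth)
of VAFs restricted to clonal 1+1 segments — the strictest reading of
"diploid" — finds local maxima with topographic prominence at least 5% of
the density maximum, and calls the largest-VAF maximum the clonal peak;
equal heights resolve to the larger VAF. At least 50 diploid SNVs are
required (configurable); below that the sample is flagged instead of
guessed. On simulated 90× cohorts the estimate lands within 0.05 of truth
in over 95% of samples.

Samples with copy-number purity below 10% (strict) are flagged for
exclusion. Subclone detectability is governed not by mutation count but
by reads per chromosome copy,

$$\mathrm{NRPCC} = \frac{d\,\rho}{\rho P + 2(1-\rho)},$$

with mean depth $d$ and tumor ploidy $P$; heterogeneity analyses retain
samples with NRPCC ≥ 10, the regime where subclones of CCF > 0.3 are
reliably visible.

## Genomic instability

Two WGD definitions serve two purposes. The descriptive call asks whether
more of the genome sits in a balanced tetraploid 2:2 state than in
diploid 1:1 (length-weighted, clonal segments only). For the timing
model, WGD is an *event* in samples with mean ploidy above 3 — a stricter
criterion that only fires when the duplication is genome-wide enough to
dominate ploidy.

PGA is the length-weighted fraction of the covered genome whose state
departs from the baseline — 1:1, or 2:2 in WGD samples, so a cleanly
duplicated genome is not scored as fully altered. PGA ignores
fragmentation, so PGAn supplements it:
$\mathrm{PGAn} = \sqrt{\mathrm{PGA} \times \#\text{breakpoints}}$, the
geometric mean of extent and segment count, which separates focal
shattering from single broad events.

### Kataegis

Kataegis foci are runs of at least 6 consecutive SNVs with mean
inter-mutation distance (IMD) ≤ 1 kb. Detection is systematic: per
chromosome, the log10 IMD sequence (each distance assigned to the latter
SNV) is segmented by *exact* piecewise constant fitting — an $O(n^2)$
dynamic program minimizing squared error plus a per-breakpoint penalty
$\gamma$, not a greedy heuristic — and segments are post-processed
against the two thresholds. The log scale is used because rainfall-style
IMD data span four orders of magnitude; on the raw scale no single
$\gamma$ works at both ends.

Two numerical choices matter here:

* **$\gamma$ = 8 by default.** The penalty was calibrated once on
  simulated chromosomes (Poisson background at 1/100 kb with injected
  minimum-size foci): isolating a 6-SNV run buys roughly
  $5\,\delta^2 \approx 27$ in squared error (with $\delta \approx 2.3$
  the log10 contrast) and costs $2\gamma$, so $\gamma$ must stay below
  ~13; values in $[4, 10]$ gave 100% detection of minimum-size foci with
  zero false foci over 50 seeds, and 8 was frozen. Larger penalties
  (e.g. 25) cannot isolate minimum-size foci at all.
* **Sub-run rescue.** The optimal segmentation occasionally absorbs one
  oversized flanking or interior gap into a focus segment, lifting its
  mean IMD just over 1 kb. Segments failing the mean test are therefore
  searched exhaustively for qualifying sub-runs (≥ 5 distances, mean
  ≤ 1 kb; an exact sliding-window prefilter keeps this cheap), and
  adjacent qualifying segments are merged before the 6-SNV count is
  applied. Without this, detection of minimum-size foci drops to ~95%.

The mean distance is the arithmetic mean of consecutive IMDs within the
run, and focus bounds are the first and last SNV of the qualifying run.
Indels are excluded throughout.

## Recurrent copy-number regions

Segments are reduced to typed events — HD (total copy 0), LOH (minor
allele 0, total ≥ 1), Gain (total above baseline ploidy: 2, or 4 under
WGD; a 3+0 state is both LOH and Gain). The Gain baseline of 4 under WGD
mirrors the 2:2 PGA baseline and is configurable. The cohort landscape
partitions each chromosome at the union of observed event boundaries and
assigns each interval the fraction of samples carrying the event type
there.

Significance comes from a permutation null: each permutation re-places
every event uniformly at random along its own chromosome, preserving
event length and chromosome assignment — the simplest background
consistent with a "random copy-change rate" that respects per-chromosome
event density. Because neighboring intervals are massively dependent,
the null statistic is the genome-wide *maximum* interval frequency per
permutation; each observed interval gets
$p = (1 + \#\{\text{null max} \ge \text{observed}\})/(n_{perm}+1)$,
followed by BH correction across intervals (FDR < 0.05). This
max-statistic construction makes the p-values conservative
(super-uniform) by design, which the acceptance suite verifies with a
one-sided Kolmogorov–Smirnov test on null cohorts. Note the p-value floor
$1/(n_{perm}+1)$: with BH across many intervals, detecting even a fully
penetrant region needs $n_{perm}$ comfortably above
$m/0.05$ for $m$ intervals — the pipeline default is 1,000.

Enriched regions overlapping the HLA locus (6p21; bundled with the GRCh37
genome model), regions confined to the terminal 1 Mb of a chromosome
(the buffer is a documented choice — no numeric definition of "telomeric"
exists upstream), and regions supported by a single sample are flagged
excluded rather than dropped.

## Non-coding hotspot scan

Each chromosome is tiled into 100-kb bins from position 1 (final partial
bin kept). Recurrence is sample-level — a sample counts once per bin no
matter how many SNVs it has there — so hypermutators cannot fabricate a
hotspot. Each bin with at least one mutated sample is tested between two
groups with the two-sided Fisher exact test; empty bins stay out of the
BH family (they carry no evidence and would only dilute the correction);
significance is FDR < 0.1. Restriction to non-coding territory is the
caller's choice via an optional mask of coding intervals, off by default
since annotation pipelines live outside this package.

## Intra-tumor heterogeneity: wCCF

Mutation clusters are local peaks of the per-mutation CCF density over
(0, 1.5] (Silverman bandwidth, 5% prominence floor), each mutation
assigned to the nearest peak; the peak within 0.1 of CCF 1 is the clonal
cluster, and if none exists one is forced at 1 with a warning and given
the highest-CCF mutation. This density-peak procedure is a deliberately
simple stand-in for full Dirichlet-process clustering; externally
produced cluster tables are accepted everywhere a cluster table is, so
the stand-in is never load-bearing.

The heterogeneity statistic is the burden-weighted mean of cluster peaks,

$$\mathrm{wCCF} = \frac{\sum_k \min(\mathrm{peak}_k, 1)\; n_k}{\sum_k n_k},$$

which is 1 exactly when every mutation is clonal and decreases as
subclonal burden grows — lower wCCF, more heterogeneity. This
weighted-mean reading is the only formula consistent with the statistic's
reported behavior; peaks above 1 (clonal by the binomial rule) are capped
at 1 for weighting while the raw peaks stay in the output. Downstream
group comparisons should adjust for NRPCC, which is emitted as a
covariate column; the GLM itself is routine and left to the caller.

## Chronological ordering of events

Per tumor and per iteration, one strict ranking of its events is drawn:

1. Clonal events precede subclonal ones.
2. In WGD tumors the clonal block is pre-WGD events (random order), then
   WGD, then post-WGD events (random order). Clonal events with no
   usable NCBM information are inserted at uniformly random positions
   across the whole clonal block — they carry no information about their
   side of the WGD, so no side is imposed. When a tumor has only pre- or
   only post-WGD events, WGD still sits after/before the respective
   block.
3. Subclonal events follow their cluster phylogeny: every rooted tree
   over the clonal root and subclonal clusters satisfying the sum rule
   (children's CCFs sum to at most the parent's at every node) is
   enumerated by exhaustive parent assignment (up to 6 subclones; beyond
   that valid trees are sampled), one tree is drawn uniformly per
   iteration, and events follow a uniform random linear extension of it;
   events in the same cluster are shuffled within it.

A Plackett–Luce model is then fitted to the cohort's partial rankings by
minorization–maximization (relative log-likelihood tolerance 1e-8, cap
10,000 iterations), estimating a positive "worth" per event; unobserved
events in a tumor simply do not appear in its ranking — no imputation.
When an event never wins a comparison or the comparison graph is
disconnected the MLE does not exist; a pseudo-observation scheme (every
event beats and loses to a shadow reference item 0.5 times, shadow
dropped afterwards) is engaged automatically and recorded on the fit —
clean data always get the exact MLE, which is what the likelihood-oracle
tests check.

The per-iteration relative time of an event is its normalized rank by
descending worth, $(r-1)/(K-1)$: worth magnitudes are scale-free, so the
rank is the comparable statistic across iterations (raw worths are also
emitted; ties break stably by event id). Repeating for `n_iter`
iterations (default 1,000) yields each event's mean relative time and
2.5/97.5-percentile CI. Frequency does not move an event's mean —
clonality does — but rarer events fluctuate more between iterations and
get wider CIs, which the test-suite checks by construction.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the statistical structure the
analyses assume: per sample, purity uniform on 0.1–0.9, WGD with
probability 0.2, up to two subclones on a chain phylogeny (always
sum-rule-valid) with peaks in 0.15–0.7 separated by ≥ 0.15; catalog
events instantiated by per-group prevalence, clonal with probability
$1 - 0.6\,t$ for latent time $t$ (the simplest monotone link), pre-WGD
when clonal and earlier than the WGD time (0.3); segment tables laid over
a 1+1 (2+2 under WGD) baseline; background SNVs at 5/Mb; kataegis runs
of 6–20 SNVs at ~300 bp spacing; reads drawn
$\mathrm{alt} \sim \mathrm{Binomial}(d, \rho m c/(\rho n_t + 2(1-\rho)))$
with Poisson depth around 90×. Variants drawing zero alt reads are
dropped, as they would never be called. The defaults describe a plausible
~90× breast-cancer cohort; truth tables for every latent quantity
accompany each cohort, and identical seeds give identical cohorts.

What the generator does **not** emulate — trinucleotide signature
spectra, mapping artifacts, germline contamination, segmentation error in
the copy-number input, multi-region sampling — bounds what green tests
mean: they certify the estimators against their own generative
assumptions, not against every failure mode of real pipelines.

One generator parameter deserves a note. The `"recovery"` fixture
(60 samples, 8 events at staggered latent times, observation
probabilities 0.3–0.9) exists to exercise order recovery, and it uses the
full-range clonality link $P(\mathrm{clonal}) = 1 - t$ rather than the
global $1 - 0.6t$ default. With the damped default, the clonal-fraction
separation between adjacent events (≈ 0.075) is smaller than the binomial
noise at these prevalences, and *no* estimator — including sorting events
by their true clonal fractions — recovers the order reliably at this
cohort size; with the full-range link the Plackett–Luce pipeline reaches
Spearman ≥ 0.9 against truth in essentially every replicate. The damped
link remains the default everywhere else.

## Problem sizes and numerical choices

The test and acceptance runs use the 3×10-Mb toy genome, cohorts of 6–60
samples, 200 permutations for null calibration (999 where a planted
region must clear the p-value floor), 200 timing iterations, and 10–100
seeded replicates per operating characteristic — sizes chosen so the full
suite completes in minutes while every rate is estimated from at least
50 Bernoulli draws. Other conventions: 1-based fully closed coordinates
everywhere internally; `chr` prefixes stripped on input; overlapping
segments resolved deterministically (first by position wins, with a
warning); multi-allelic VCF records rejected rather than guessed;
Fisher odds ratios are sample ORs with Haldane–Anscombe 0.5 correction
only when a zero cell is present, while p-values always come from the
uncorrected exact test.

## Known limitations

* CCF treats the purity and segment inputs as known; their uncertainty is
  not propagated.
* The density-peak clustering stand-in underfits tumors with close-set
  subclones (peaks within ~0.1 CCF merge); use an external DP-clustering
  tool and pass its cluster table for such cohorts.
* The permutation null preserves event length and chromosome but not
  inter-event spacing; clustered event processes (e.g. chromothripsis)
  are only approximately modeled.
* Timing relies on clonality and tree constraints only; it does not use
  mutation-copy-number dosage to time individual gains.
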