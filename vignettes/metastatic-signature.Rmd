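---
title: "Methods: the median-vote metastatic signature pipeline"
author: "metsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the median-vote metastatic signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsig)
```

# Scope and data model

`metsig` analyses matched primary / omental-metastasis ovarian tumor
cohorts. The central container is the `PairedExpressionCohort`, a
`SummarizedExperiment` whose column data carry the matched design (one
primary and one metastasis sample per case); validity enforces complete
pairing, unique gene ids and finite log2 values. Copy-number data live in
`GRanges` objects (probes with log10 tumor/reference ratios; segments with
probe counts and means), survival data in plain data frames with `time`,
`event` and covariate columns.

# Paired differential expression

Samples are quantile normalized (every column is mapped onto the
across-sample mean of sorted vectors; ties receive the mean of the
reference values over the tied rank span, so the operation is idempotent).
Genes whose values fall below the global lower quartile of the whole
matrix are removed when this happens in *every* sample — the strictest
reading of "consistent" low signal; `filterLowSignal(fraction =)` exposes a
laxer fraction for sensitivity analyses. Percentiles use linear
interpolation between order statistics (R type 7), stated here because the
removal count depends on the convention.

Per gene, the paired differences $d_i = \mathrm{met}_i - \mathrm{pri}_i$
give $t = \bar d / (s_d/\sqrt n)$ with the $n-1$ sample SD and a two-sided
p from $t_{n-1}$ (sidedness is a choice; two-sided is the conservative
default). Zero-variance genes get $p = 1$ and *remain* in the
Benjamini–Hochberg family, so the multiple-testing family size is never
silently shrunk. A candidate gene must pass all three of $q < 0.25$,
$p < 0.05$ and $|\overline{\log_2 \mathrm{FC}}| > 0.9$; the three
thresholds are independently configurable because they bind in different
regimes (the FC filter dominates at small $n$, the FDR filter at large
gene counts).

# The median-vote signature

A signature is an ordered gene set with per-gene metastasis directions and
an integer threshold. Scoring is deliberately rank-based: the cutpoint for
each gene is the median expression *within the evaluation cohort* —
cutpoints are never transferred between cohorts, which is what makes the
score portable across array platforms with different intensity scales. A
patient gains a point per up-gene strictly above its median and per
down-gene strictly below; ties at the median score nothing ("higher than
the median" is strict). With $k = 6$ genes, score $> 3$ defines high risk;
the generalized default threshold is $\lfloor k/2 \rfloor$. Because only
order statistics enter, the score is invariant to any strictly monotone
per-gene transform — the property the test suite checks directly.

The canonical six genes ship as `canonicalSignature()`. Their directions
default to up-in-metastasis (the candidate pool from which they came was
77 up versus 10 down, and IL7R is explicitly higher in metastases, likely
from infiltrating T cells); directions are user-settable, and an
alternative orientation mode derives them from the signs of training Cox
coefficients, mirroring the two readings of the published scoring text.

## Derivation from candidates

`selectSignature()` reconstructs the two-stage selection: candidates are
screened by univariate Cox regression (continuous expression, Efron ties)
in a training dataset at $\alpha = 0.05$; the retained genes are searched
for the size-$k$ subset minimizing the *worst-case* (maximum) high/low
log-rank p across all supplied datasets. The search is exhaustive while
$\binom{n}{k}$ is below a cap (default 5000; $\binom{12}{6} = 924$),
otherwise greedy-forward; both iterate genes in lexicographic order, the
documented tie-break. The published procedure does not state how twelve
screened genes became six, so this minimax-p search is an explicit
reconstruction — a design choice, flagged as such.

# Survival analysis

Kaplan–Meier estimation uses the product-limit estimator with Greenwood
variance via the `survival` package. The reported median is the smallest
$t$ with $S(t) \le 0.5$ (`survfit` averages the two flanking times when
$S$ hits 0.5 exactly; the definitional rule is used instead so the median
of four uncensored deaths at 1, 2, 3, 4 is 2, not 2.5). The median CI
inverts log-log transformed pointwise bands (Brookmeyer–Crowley style) —
the CI method is not dictated by the problem and is documented as a
choice. Tied censored observations count as at risk at their time
(censored-after-events).

The two-group log-rank statistic is computed natively — observed minus
hypergeometric-expected events summed over distinct event times, squared
over the summed variance, $\chi^2_1$ — because the empirical null
evaluates it tens of thousands of times; it matches `survival::survdiff`
to 1e-10 and a hand 2×2-table oracle to 1e-12 in the tests, and the Cox
score test on a binary covariate to 1e-6, the classical equivalence.

`evaluateSignature()` fixes the evaluation order: treatment filter first,
then scoring (medians from the treated cohort), then residual-disease
stratification. Scoring before stratifying reflects how a clinical cohort
is scored once and then examined in subsets; computing medians within each
stratum would change the score's meaning across strata.

# Random gene-set specificity null

The empirical p of a signature is the fraction of `nRandom` random
same-size gene sets whose log-rank p is *strictly lower* than the
observed one, all scored with the identical median-vote procedure on the
same cohort. Random sets that place every patient on one side of the
threshold are degenerate; they are recorded with $p = 1$ rather than
discarded so the denominator stays the number of sets tested. The plain
$n_{lower}/n_{random}$ estimator is the default (it can be exactly 0); the
positively-biased $(n_{lower}+1)/(n_{random}+1)$ variant is available.
Random directions are assigned uniformly per gene by default, with a
Cox-sign mode as the alternative reading of "using the same parameters";
the mode is recorded in the result object.

# Copy number

**Smoothing.** A probe deviating more than 3 track-SDs from the median of
its ±10-probe window is pulled back to that window median ±3 SDs. The
track SD is a MAD estimate so that the spikes being removed do not inflate
their own detection threshold — the exact trimming constants of the
original array pipeline are not published, so this SD-window rule is the
package's documented implementation of SD-based outlier smoothing.

**Segmentation.** Circular binary segmentation: within a segment, the
two-sample t-like statistic is maximized over all contiguous arcs (the
complement being the joined ends of the circularized segment); a split is
accepted when its permutation p (label permutations of the probe values)
is below $\alpha = 0.05$, and accepted arcs recurse. Segments shorter than
twice the minimum arc width (2 probes) are never split; permutation count
defaults to 1000 (tests use 100–200 — the permutation p is exact at any
count, only its resolution changes). The permutation loop terminates early
once significance is unreachable. Because the split test is a permutation
test, the first-split false-positive rate is controlled at $\alpha$ by
construction, and the suite verifies this empirically.

**Gene scores.** Every probe inherits its segment mean; a gene's log10
copy number is the average over probes overlapping the gene region (any
overlap counts, 0-based half-open coordinates in files, `GRanges`
semantics in memory), and genes with fewer than three probes are dropped.
Metastasis-specific calls use a log10 threshold of ±0.1 — the
amplification threshold is not dictated by the data model, so it is a
configurable default reported in output metadata — with tissue specificity
evaluated within each case, recurrence across ≥ 2 cases, and an
expression–copy-number Pearson correlation above 0.7 required to report a
gene as correlated.

**Clustering.** Samples cluster by average linkage on 1 − Pearson
distance; a matched pair "clusters together" when its two samples form a
cherry (merge with each other before any other sample) — a conservative,
unambiguous reading of mutual nearest cluster neighbors.

# Staining statistics

Percent-positive Ki-67 and TUNEL indices are treated as log-normal; the
metastasis-vs-primary comparison is a paired t-test on log percentages
(natural log; the statistic is base-invariant), with Shapiro–Wilk p-values
on raw- and log-scale paired differences reported as the normality
diagnostic. Zeros are replaced by half the smallest positive observed
value and flagged; identical pairs yield the degenerate no-difference
result ($t = 0$, $p = 1$) rather than an error. The Ki-67 correlation
ranking uses signed Pearson r between paired expression deltas (log2) and
staining deltas on the raw percent scale — the correlation is invariant to
affine transforms of the staining delta, so percent versus fraction does
not matter; a log-delta mode exists for sensitivity analysis.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analysis assumes,
at the study's design points:

* **Matched pairs** (default 9 cases, 1000 genes): gene-level abundance
  $\mu_g \sim N(7, 1.5^2)$, a shared per-(gene, case) baseline
  ($\sigma = 0.5$) inducing the within-pair correlation the paired t-test
  exploits, planted shifts of ±1.2 log2 units for 77 up / 10 down genes,
  and residual noise $\sigma = 0.4$. Inter-case variance components are
  not published for this design; 0.5 was chosen once as a realistic
  inter-patient spread for array data and is documented rather than tuned.
* **Survival cohorts** (default 400 patients): signature-gene expression
  iid $N(0,1)$, the true score computed by the package's own vote rule,
  exponential event times with hazard
  $h_0 \exp(\beta \cdot \mathrm{score})$ ($h_0 = 0.02$/month — median
  around three years at score 0 — and $\beta = 0.4$), independent
  exponential censoring with its rate solved so the expected censored
  fraction matches the target (0.3).
* **Probe tracks** (default 3 chromosomes × 200 probes): piecewise-
  constant means alternating between 0 and ±0.3 log10, Gaussian probe
  noise ($\sigma = 0.05$), and 2% single-probe spikes of 5–8 noise-SDs
  with random sign — exactly the artifact the SD-window smoother targets.
* **Staining tables**: log-normal primary percentages with a
  multiplicative metastasis effect (default 1.5×) and within-case
  log-scale scatter (CV 0.4), sized to the 19-case staining design.

One master seed drives everything; each generator draws from its own
sub-stream (`(seed·1009 + offset) mod (2^31 − 1)` with a fixed offset per
generator), so changing the probe count never perturbs the expression
cohort, and identical seeds give byte-identical outputs.

What the generators do *not* model: probe-level hybridization noise, batch
effects, tumor purity below the >70%-cancer-cell selection, platform
differences between validation cohorts, non-proportional hazards, or
informative censoring. Passing tests therefore demonstrate that the
*procedures* are correct and powered under the assumed model — not that
real cohorts satisfy those assumptions.

# Experiment sizes and numerical choices

The recovery experiments are sized for stable verdicts at interactive
runtimes: breakpoint localization uses 100 replicates of 200-probe
chromosomes at 150 permutations per split; Cox coverage uses 100
replicates at the planted $\beta = 0.4$, $n = 400$; the signature
derivation recovery uses a deliberately powered design
($\beta = 0.8$/point, $n = 800$) because the two-stage procedure requires
all six planted genes to survive the per-gene Cox screen, whose per-gene
power at the survival default ($\beta = 0.4$, $n = 400$) is only ~60% —
a property of the screen, worth knowing, and the reason the published
procedure screened before searching. The Kaplan–Meier closed-form check
averages five $n = 1000$ medians because a single exponential-sample
median has ~4.6% relative SE, right at the 5% comparison band.

Degenerate inputs are handled by rule, not by error, wherever the
degenerate case has a defensible answer: zero-variance genes ($p = 1$ in
DE; excluded from correlation rankings), degenerate random-set groupings
($p = 1$, kept in the denominator), all-censored cohorts (flat KM curve,
median "not reached"), identical staining pairs ($t = 0$, $p = 1$).
Errors are reserved for contract violations: missing signature genes,
single-patient cohorts, unpaired cases, non-finite values.

# Known limitations

* The six-gene directions and the twelve-to-six reduction are
  reconstructions where the published description is silent; both are
  exposed as options rather than hidden defaults.
* CBS here implements the published recursive arc-split outline; it is not
  a line-for-line port of the reference implementation (different
  tie-breaks and trimming details can shift a breakpoint by a probe or
  two on noisy data).
* The empirical null treats random sets as exchangeable with the
  signature; gene–gene correlation structure in real cohorts (absent in
  the generator) can make real random sets less exchangeable than
  synthetic ones.
* External-cohort evaluation (TCGA, GEO series) requires user-supplied
  matrices; the package deliberately ships no download clients.
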