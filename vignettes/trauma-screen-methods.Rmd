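---
title: "Scoring trauma-induced dopaminergic neurodegeneration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring trauma-induced dopaminergic neurodegeneration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumaScreen)
```

# The screen and its statistic

`traumaScreen` quantifies a reverse-genetic screen for modifiers of
trauma-induced neurodegeneration in *C. elegans*. Worms expressing GFP
exclusively in dopaminergic neurons are injured by high-frequency agitation,
raised on RNAi bacteria targeting one candidate gene per condition, and run
through a large-particle flow cytometer (a COPAS-style sorter) that records,
for every object passing the beam, a time-of-flight (TOF, a length proxy),
an extinction value (optical density), and green/red fluorescence.
Neurodegeneration appears as loss of GFP signal in injured relative to
uninjured animals.

For each condition and biological replicate the pipeline forms the
retained-fluorescence ratio

$$R_x = \frac{\bar g_{\text{injured}}}{\bar g_{\text{uninjured}}},$$

the mean green signal of gated injured worms over that of age- and
RNAi-matched uninjured controls. The screen statistic, the **Dopaminergic GFP
Index**, normalizes each knockdown's ratio against the empty-vector (EV)
control of the same experiment:

$$\mathrm{Index} = \frac{EV - RNAi}{EV - 1}.$$

The anchors follow directly from the algebra: a knockdown whose injured
worms retain as much GFP as uninjured controls ($RNAi = 1$) scores exactly
1 (full protection); one that loses exactly as much as the control
($RNAi = EV$) scores 0; values below 0 mean increased loss (sensitization).
The index is invariant to any common rescaling of the fluorescence axis,
and — for a control with genuine loss ($EV < 1$) — strictly increasing in the
knockdown's retained-fluorescence ratio.

## Error propagation

All uncertainties follow the general quadrature rule
$\delta R = \sqrt{\sum_X (\partial R/\partial X \cdot \delta X)^2}$.
Concretely:

* each arm's mean carries its standard error $s/\sqrt{n}$ (sd with the
  $n-1$ denominator);
* the ratio's error is the quotient rule,
  $\delta R = R\sqrt{(\mathrm{sem}_i/\bar g_i)^2 + (\mathrm{sem}_u/\bar g_u)^2}$;
* the single-replicate index error propagates both ratio errors through the
  index's partial derivatives,
  $\delta = \sqrt{\left(\frac{\delta_{RNAi}}{EV-1}\right)^2 +
  \left(\frac{(RNAi-1)\,\delta_{EV}}{(EV-1)^2}\right)^2}$.

The last line is a deliberate design choice. A popular shortcut treats the
control ratio as an error-free constant and scales every operand error by
$1/(1-EV)$; the two forms agree exactly when $RNAi = EV$ (index 0) but the
shortcut overstates the error by ~15–20% at indices near $\pm 0.5$–$0.8$.
Only the full-gradient form tracks a Monte-Carlo propagation oracle within
10% across the index range the screen actually produces, so the package
uses it; the test suite pins this agreement.

Replicates are combined as the mean of per-replicate indices. The
within-replicate errors are added in quadrature and scaled as an error of a
mean ($\sqrt{\sum_r \delta_r^2}/n$); the between-replicate error is the SEM
of the replicate indices; the two combine in quadrature into
$\delta_{\text{total}}$, and hits are called from normal 95% intervals
$\mathrm{Index} \pm z_{0.975}\,\delta_{\text{total}}$: *protective* when the
interval lies entirely above 0, *sensitizing* entirely below, otherwise
*no effect*.

Two caveats are worth stating plainly. First, the within and between
components partially overlap (replicate scatter includes measurement
noise), so $\delta_{\text{total}}$ is mildly conservative by construction.
Its validation is therefore *calibration*: across simulated screens the 95%
intervals must cover the planted index 93–97% of the time — a Monte-Carlo
oracle can only target the propagated within-replicate component, because
the between term is an empirical SD, not a propagated one. Second, hit
calling by CI-excludes-zero is a normal approximation, not an exact test.

## Degenerate controls

If the EV control shows essentially no GFP loss the index denominator
vanishes and the statistic is meaningless. `gfpIndex()` refuses to score a
replicate whose control ratio lies within `epsilonGuard` of 1 (default
0.02, configurable) and raises a degenerate-control error instead of
returning an arbitrarily inflated index.

# Gating

Raw event tables are contaminated by larvae, *E. coli* clumps, worm
doublets, and curled worms. Gates are fully configuration-driven
(`GateConfig`); `defaultGates()` derives thresholds from the adult medians
of an uninjured reference run:

| gate | rule | default |
|---|---|---|
| bacteria | extinction below `extMin` | 0.1× median extinction |
| larva | TOF below `tofMin`, extinction not above the curl threshold | 0.5× median TOF |
| doublet | extinction above `doubletIntercept + doubletSlope * tof` | 1.7× median extinction |
| curl | TOF < `curlTofMax` and extinction > `curlExtMin` | 0.6× / 1.2× medians |

Flags are assigned in the fixed order bacteria → larva → doublet → curl,
first match only. Two details matter. The extinction cut targets bacteria
and the TOF cut targets larvae: larvae are small on *both* axes, so a
single 0.5× cut on both channels could not distinguish them from debris.
And the larva gate excludes short-but-dense objects, which are coiled
adults: without that exclusion the curl gate would be unreachable, since a
curled worm always fails the TOF bound first. Intervals are closed-left,
open-right — an event exactly at a lower bound is retained — and gating is
idempotent because flags are recomputed from channels alone.

Dead worms (propidium-iodide-positive, red channel above
`redDeadThreshold`) are flagged but not removed; `deadFraction()` reports
their proportion with a Wilson 95% interval (via `prop.test` without
continuity correction). Percentile selection (`selectPercentile()`, e.g.
the bottom decile of GFP intensity) uses the linear-interpolation
percentile definition (`quantile` type 7), keeps `[lo, hi)` and closes the
top at 100 so complementary bands partition the table.

# The synthetic-data generator

No deposited arrays or animals are available at desk scale, so every input
is simulated with planted ground truth; parameter recovery is the package's
acceptance surface.

**Optics.** All channels are lognormal — cytometry intensities are
right-skewed and strictly positive. Defaults describe an age-synchronized
day-1 adult population: tight TOF/extinction laws (sdlog 0.1; synchronized
adults are morphologically uniform) and a broader GFP reporter law (sdlog
0.5; transgene expression varies more between animals than body size
does). Contaminants are parameterized *relative to adult medians* so gates
can be derived from configuration: larvae at 0.3×, bacteria at 0.02×,
doublets as channel-wise sums of two adult draws, curls at 0.4× TOF and
1.43× extinction.

**Injury.** A Bernoulli fraction of worms (default 0.8) multiplies its GFP
by a retention factor (default 0.5 for EV). This two-component mixture
reflects the observed per-worm heterogeneity — some injured worms retain
healthy neurons. The mixture cancels from the index, so a planted index
$t$ is realized exactly in expectation by inverting the index formula:
$\text{factor}_g = 1 - (1-t)(1-\text{factor}_{EV})$.

**Replicate structure.** Each condition × replicate is a separately
agitated tube, so the *delivered* injury varies between tubes: the GFP
loss is jittered by an independent lognormal factor with sdlog
`replicateInjurySd = 0.05`. This 5% day-to-day severity variation was
chosen once, at design time, to reflect the two-tier error model the
estimator assumes — genuine between-replicate variability of the same
order as the within-replicate sampling error at 500 worms/arm. With it,
the 95% intervals are calibrated (93–97% coverage); without it they would
be systematically conservative.

**Seeding.** A single integer seed governs a hierarchical stream: each
condition/replicate/arm draws from a child stream keyed by a rolling hash
of its labels, so adding conditions never perturbs existing ones, and
identical configurations reproduce byte-identical tables.

**Expression data.** Cross-dataset fold-change vectors come from a latent
stress-program model: dataset $d$ expresses gene $g$ as
$\sum_p L_{dp} E_{pg} + \varepsilon$, Gaussian noise on top of a small
number of shared programs. The implied dataset-by-dataset correlation
matrix, $\mathrm{cov2cor}(L S L^\top + \sigma^2 I)$ with $S$ the empirical
effect covariance, is returned as ground truth; at $\sigma = 0$ it equals
the empirical correlation of the generated data to machine precision. A
configurable fraction of entries is masked `NaN` to exercise complete-case
handling.

**What the generator does not emulate.** No optical physics of the sorter
(laser geometry, PMT saturation), no spatial structure, no
count-distribution realism for sequencing data (fold changes are drawn
directly), no correlated missingness. Passing recovery tests therefore
demonstrates the correctness of the *computations*, not robustness to
every failure mode of real instruments.

# Transcriptomic comparisons

**Differential expression.** Per-gene Welch two-sided t-tests on log2
values, fold change as the ratio of group means on the linear scale,
thresholds inclusive (fold-change magnitude ≥ 2, p ≤ 0.05, matching a
"≥ / ≤" convention). The RNAseq-style variant thresholds the
Benjamini–Hochberg q-value instead (`fdr = TRUE`). A beta-binomial
count-model test that commercial software implements is deliberately not
reproduced; the filtering and overlap logic is what this package
exercises, and the documentation says so. Genes with zero variance in both
groups get p = 1 by convention; significance is monotone in both
thresholds.

**Cross-correlation.** Each dataset restricted to a reference gene set, z-score
normalized (mean/sd of non-missing entries, $n-1$ denominator), then every
gene missing in *any* dataset is dropped — complete-case across all
datasets jointly, matching a concatenate-then-filter workflow — and Pearson
correlations are computed on the aligned remainder. Pairwise-complete
handling is offered as an option. Whether the inputs are log2 or linear
fold changes is ambiguous in common usage; the default assumes log2 with a
switch for linear (z-scoring makes the choice mostly immaterial for
monotone relationships). Fewer than 3 complete-case genes is an error, not
a silent correlation.

**Age comparison.** The day-1 vs day-4 attenuation summary is a paired
t-test on per-gene log2 responses with the count of genes above the 2-fold
threshold at both ages. A constant difference has no sampling
variability; its p-value is defined as 1 when the difference is zero and 0
otherwise.

# Assay metrics

* **Chemotaxis**: $(\#\text{butanol} - \#\text{ethanol})/\#\text{total}$.
  Worms still in the neutral center circle count in the denominator but in
  neither tally — the formula's denominator is the total, and this is the
  documented convention for the silent case.
* **Paralysis / death fractions**: binomial proportions with Wilson 95%
  intervals.
* **Nose touch**: five trials per worm; the worm, not the trial, is the
  experimental unit (per-worm percent positive, population mean ± SEM over
  worms).
* **qPCR**: technical replicates with more than one melt-curve peak are
  excluded; ΔCt subtracts the arithmetic mean of the two housekeeping Cts
  (*tba-1*, Y45F10D.4 by default), which is algebraically identical to
  dividing the $2^{-Ct}$ level by the geometric mean of the housekeeping
  levels — the suite verifies the identity numerically to $10^{-12}$.
  Amplification efficiency is assumed to be 100% (plain $2^{-\Delta Ct}$,
  no efficiency correction).

# Numerical and interface choices

* $z_{0.975}$ is `qnorm(0.975)` (1.959964…), not the rounded 1.96.
* TSV is the canonical on-disk format (gene and condition labels may
  contain commas); CSV is accepted on read. Numbers are serialized with 17
  significant digits so write→read round-trips reproduce doubles exactly.
* Configuration errors and data errors are distinct condition classes;
  the command-line layer maps them to exit codes 2 and 3 and logs a JSON
  line (seed, config hash, package version) to stderr, keeping stdout and
  output files deterministic — `full-run` under a fixed config and seed is
  byte-identical across invocations.
* Benjamini–Hochberg adjustment is `stats::p.adjust`; the suite validates
  it against an independent step-up implementation exhaustively for all
  grid vectors of length ≤ 2 and all sorted length-3 combinations on a
  0.01 grid, plus thousands of random length-4/5 vectors (the full
  length-5 grid, $10^{10}$ cases, is not enumerable).

# Validation problem sizes

The simulation studies the test suite runs were sized as a deliberate
compromise between statistical resolution and a test suite that stays
pleasant to run: calibration uses 200 simulated screens of 4 planted
indices (+0.8, +0.3, 0, −0.5) at 3 replicates × 500 worms/arm (800
gene-conditions; a 93–97% coverage band is resolvable at ±0.9% binomial
SE), recovery uses 100 screens of {+0.8, −0.5, 0}, Monte-Carlo oracles use
$10^5$ draws, and correlation recovery uses 2000 genes at noise sd 0.2.

# Known limitations

* Hit calling is a normal-interval approximation; no multiplicity
  correction is applied across genes (matching the screen's design, where
  hits are candidates for follow-up, not final claims).
* $\delta_{\text{total}}$ double-counts measurement noise by construction
  (see above); its coverage is calibrated under the generator's error
  model, not proven for arbitrary real-data error structures.
* The DE path is a generic two-group test on (log) values; it is not a
  count model and should not be used as a substitute for one on raw
  sequencing counts.
* The generator's contaminant geometry is idealized; gate performance
  claims (99% purity/recall) hold for well-separated classes and degrade
  gracefully, not provably, on messier data.
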