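---
title: "Methods: loop-design expression, candidate filtering, kdr association and qPCR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-design expression, candidate filtering, kdr association and qPCR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `anoresist`, the
choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate. The package analyses
escalating pyrethroid resistance in *Anopheles coluzzii* from south-west
Burkina Faso on three fronts: transcription (two-colour microarrays),
target-site genetics (the kdr mutations L1014F and N1575Y), and qPCR
validation of candidate genes.

## Two-colour loop-design differential expression

### Model

Each array co-hybridizes two populations labelled cy3 and cy5. For probe
$g$ on array $h$ the normalized log ratio is modelled as

$$M_{gh} = \beta_{g,\,c5(h)} - \beta_{g,\,c3(h)} + \delta_g\,o_h + \varepsilon_{gh},$$

where $\beta_{g,p}$ is the log2 expression of population $p$ relative to a
reference population (one column is absorbed), $\delta_g$ a common dye
coefficient with orientation entry $o_h = \pm 1$, and
$\varepsilon_{gh}$ i.i.d. Gaussian. Interwoven loops (each pair of
populations connected by dye-swapped replicate arrays) make all pairwise
contrasts estimable whenever the design graph is connected;
`build_design_matrix()` refuses disconnected or rank-deficient designs by
name. Fitting is per-probe ordinary least squares; a contrast
$c^\top\beta$ gets a two-sided t-test on the residual degrees of freedom
(arrays minus rank). We deliberately use plain fixed-effects least squares
rather than a mixed model or empirical-Bayes variance moderation: the
downstream filtering consumes only (log2FC, q), the design has equal
replication on every edge, and the plain model is exactly invertible on
noise-free data, which the test suite exploits heavily.

Normalization defaults to within-array median-centring of $M$
(`method = "median"`), with an intensity-dependent lowess alternative
(`method = "loess"`, span 0.4) for data with an M–A trend. Intensities in
$(0, \varepsilon)$ are floored at $\varepsilon = 1$ intensity unit
(configurable); non-positive values cannot be logged and are flagged and
excluded from fitting rather than silently patched.

Numerical corner cases: probes whose residual sum of squares is zero to
relative tolerance 1e-10 (which happens systematically on zero-noise
synthetic data) keep their — exact — estimates but get `p = q = NA` and a
`zero_residual` flag instead of a spurious `p = 0`; saturated models
(zero residual degrees of freedom) are flagged `no_df`. FDR control is
Benjamini–Hochberg within each contrast, with `NA` p-values excluded from
the number of tests.

The 2011 (VKR/VKC/MAL triangle) and 2012 (VKR/TEN/MAL/NG loop)
hybridizations are fitted as **separate models** and their contrast tables
merged afterwards; the two experiments share no arrays, so a joint fit
could only couple them through shared variance assumptions we have no
basis for.

### The dye-orientation column

Relabelling an array's channels in the data file (swapping cy3/cy5 and
negating $M$) is a pure bookkeeping change, so estimates must not move.
This holds if and only if the whole design-matrix row — including the dye
entry — changes sign with the relabelling, which is why the design may
carry a `dye_orientation` column ($+1$ by default, $-1$ for arrays
recorded in swapped orientation). The invariance is verified in the test
suite.

## The candidate-gene filtering cascade

Candidates are required to satisfy three biological hypotheses, applied as
intersective filters on the merged contrast table:

1. **Consistent over-expression in resistant vs susceptible** (steps A–C):
   positive log2FC in *every* configured resistant-vs-susceptible contrast
   (VK7/MAL 2011, VK7/MAL 2012, VK7/NG 2012) with q < 0.05. The source
   methodology says probes must be "significant" across comparisons without
   specifying whether that means in each contrast or in at least one; we
   default to the strict reading (every contrast) and expose
   `significance_mode = "any"` as the lenient alternative.
2. **Escalation between years** (step E): strictly greater VK7/MAL log2FC
   in 2012 than 2011, on point estimates only — no test is applied to the
   difference, matching the plain fold-change comparison the study
   describes. Ties are excluded.
3. **Stronger in VK7 than Tengrela** (step D): positive log2FC with
   q < 0.05 on the VK7/TEN contrast.

Because all filters are intersective the final set is order-independent;
intermediate counts are reported in the order A–C, E, D, the order in
which the analysis narrative proceeds. The down-regulated mirror list
applies steps A–C and D with all inequalities reversed and skips step E.
Note one structural property: a probe violating the sign condition of the
VK7/MAL-2012 filter while passing the 2011 one necessarily also fails the
year-increase filter, since both compare the same pair of fold changes —
no probe can violate the 2012-significance step in isolation.

Probes with **undefined q** (possible only for zero-residual fits, i.e.
noise-free data where the estimate is exact) pass the significance
component on sign alone under the default `na_q = "keep"`; `"drop"`
excludes them. Without this policy the cascade would be vacuous on
noise-free input.

Probe-to-gene collapse averages fold change on the natural scale
($2^{\mathrm{log2FC}}$, arithmetic mean over a gene's probes) on one
reporting contrast (VK7/MAL 2012 by default), mirroring how per-gene
"average FC" values are conventionally quoted. The probe→gene map is a
user-supplied two-column table, decoupling the pipeline from any genome
annotation release; unmapped probes are retained under their own id and
reported.

Candidate profiles (log2FC over the three VK7 comparisons) are clustered
agglomeratively with Euclidean distance. Linkage is not specified by the
source methodology; we use average linkage, the common default for
expression heatmaps, and sort rows by probe id before clustering so tied
merges resolve identically regardless of input order.

## kdr population genetics

Allele frequencies are mutant-allele counts over total alleles with a
binomial confidence interval. The interval method behind the published
VK7/Tengrela table is unstated; we compared Clopper–Pearson, Wilson
(with and without continuity correction), Wald and Agresti–Coull against
all 28 published intervals and none reproduces every bound at three
decimals, but the Clopper–Pearson exact interval reproduces the designated
reference bound (0.744 for 102 mutant alleles of 124) and tracks the
published intervals more closely than Wilson. Clopper–Pearson (beta
quantiles) is therefore the default, Wilson available by flag; stage 4 of
the analysis recomputes and prints the comparison rather than asserting an
exact match.

Dead-vs-survivor association uses the exact conditional (Fisher) test:
with margins fixed, the two-sided p is the sum of hypergeometric
probabilities of all tables no more probable than the observed one, with
the customary 1e-7 relative tolerance for ties. The reported odds ratio is
the sample cross-product ratio (not the conditional MLE), with a Haldane
0.5 correction applied only when a cell is zero, and is oriented so OR > 1
means the mutant allele increases the odds of *survival*. The
implementation is verified against exhaustive enumeration for every table
with margins up to 30.

### Haplotype phasing and association

With two biallelic loci the only phase-ambiguous genotype is the double
heterozygote LF/NY, which is either {L-N, F-Y} (cis) or {L-Y, F-N}
(trans). Under Hardy–Weinberg random pairing the EM update has a single
free quantity, the cis fraction
$t = p_{LN}p_{FY} / (p_{LN}p_{FY} + p_{LY}p_{FN})$; all other genotype
classes contribute fixed haplotype counts. EM starts from an equal split
($t = 1/2$), iterates to a 1e-8 max-frequency-change tolerance, tracks the
genotype log-likelihood (non-decreasing by construction, asserted in
tests), and flags — not discards — non-convergence. Because every
stationary point of the likelihood lies on the one-parameter ridge traced
by $t$, a fine 1-D grid over $t$ is an exhaustive independent oracle for
the maximum-likelihood frequencies; the tests and the acceptance script
use it.

Association mirrors the standard expected-count approach of haplotype
software: one EM over the pooled sample (default; per-group EM by flag),
per-group expected haplotype copy counts obtained by partitioning each
group's fixed counts plus its share of double heterozygotes at the pooled
$t$, then per-haplotype 2×2 tables (haplotype vs all others × survivor vs
dead) scored with a cross-product odds ratio (Haldane on zero cells) and a
1-df Pearson chi-square. Haplotypes with essentially zero expected copies
in both groups are omitted and listed. We do not claim bit-for-bit
agreement with any particular phasing program — the procedure is the
standard one, and its parameter recovery is demonstrated by simulation.

L1014S is accepted as a data code but the association machinery is
biallelic: observed S alleles are an error unless explicitly collapsed
into L (`allow_triallelic = TRUE`), so records are never discarded
silently. Specimens missing either genotype are dropped from two-locus
operations only.

## qPCR relative quantification

For target $T$ in sample replicate $s$ against calibrator mean Ct values,
the efficiency-corrected estimator is

$$\mathrm{ratio}_s = \frac{E_T^{\,\overline{Ct}_{cal,T} - Ct_{s,T}}}
{\mathrm{geomean}_{r \in \mathrm{refs}}\; E_r^{\,\overline{Ct}_{cal,r} - Ct_{s,r}}},$$

which reduces to the classical $2^{-\Delta\Delta Ct}$ when all
efficiencies are 2. "Average of three housekeeping genes" is read as the
geometric mean of per-gene relative quantities — the standard
multi-reference normalization — with an arithmetic-mean-of-Ct alternative
by flag. Efficiencies are inputs in fold-amplification-per-cycle units,
constrained to (1, 2]; estimating them from dilution series is routine
curve fitting and out of scope. Technical triplicates are averaged to one
Ct per biological replicate beforehand; wells more than 0.5 cycles from
the within-group median are flagged, not removed. Between-year comparisons
are two-tailed t-tests on log ratios (Welch default, pooled by flag; the
two coincide in balanced equal-variance designs), unadjusted for multiple
testing since no correction is described for this step. The calibrator
(VK7 2011 by default) is a presentation choice and configurable; no
numeric readouts of the published validation figure are available, so all
qPCR verification is property-based (closed-form inversion, power by
simulation).

## What the synthetic generator emulates — and what it does not

`expression_truth()` plants, among null probes, a candidate class
satisfying every cascade filter, one violator class per filter, and a
down-regulated mirror class, over the seven populations of the two array
experiments; genes carry 1–4 probes so the gene collapse is exercised.
Intensities are generated on the log2 scale as true level + per-array
offset + cy5 dye offset + Gaussian noise, the exact generating model of
the estimator, so zero-noise data are exactly invertible. Defaults: 1000
probes (a desk-scale stand-in for the 8×15K platform), 3 biological
replicates per loop edge as in the study, per-channel noise SD 0.25,
dye bias 0.1, array-effect SD 0.1 — replicate-level variances are not
reported for the original arrays, so these are stand-ins exposed as
parameters. Planted class separations (log2 offsets 2–3, natural-scale FC
4–8, within the range reported for field detoxification genes) are
calibrated so that classes are reliably recovered and violators reliably
excluded at that noise level with 3 replicates per edge: separations are
roughly three standard deviations of the contrast estimator under those
conditions.

`simulate_genotypes()` draws two haplotypes per specimen i.i.d. from the
configured frequencies (default L-N 0.15, F-N 0.55, F-Y 0.30, with L-Y
structurally absent — 1575Y arises only on a 1014F background) and assigns
survival from a logistic model in which each haplotype copy multiplies the
odds by its odds ratio (default 2.7 for F-Y); dead and survivor arms are
then sampled case-control style. Note a deliberate property of this
design: the per-copy conditional odds ratio of 2.7 corresponds to a
marginal copy-level odds ratio of about 2.6 in the association table
(odds ratios are non-collapsible), so recovery checks use an interval
around the planted value, not equality. `simulate_qpcr()` generates Ct
from the inverse of the estimator's efficiency model, with reference genes
flat across populations.

Passing tests on these data therefore demonstrate correctness of the
estimators under their own assumptions — they do not demonstrate
robustness to spatial artefacts, intensity-dependent variance,
print-tip effects, Hardy–Weinberg violations, genotyping error, or
inter-plate qPCR effects, none of which are simulated. Image-level array
simulation and bioassay time–mortality modelling are out of scope.

## Problem sizes and determinism

All generators are pure functions of (parameters, seed); the pipeline
orchestrator derives stage seeds from one master seed and records every
parameter, seed and output hash in a JSON manifest, and reuses a stage
only when its parameter fingerprint and outputs are unchanged. The
default analysis runs at 1000 probes × 27 arrays; the verification suite
uses 150–500 probes, 200-run Monte-Carlo batches for calibration checks,
2000 specimens per outcome arm for odds-ratio recovery, and margins up to
30 for the exhaustive Fisher enumeration — sizes chosen to give stable
Monte-Carlo estimates at interactive runtimes.

## Known limitations

- No empirical-Bayes moderation or spot-quality weighting; per-probe
  variance at 3 replicates per edge is noisy, which the cascade partially
  offsets by requiring consistency across contrasts.
- The published interval bounds for allele frequencies are reproduced
  only approximately (see above); the point frequencies are reproduced
  exactly at the printed precision.
- Haplotype association uses expected counts, ignoring phasing
  uncertainty in the test statistic itself (as standard tools do); with
  only one ambiguous genotype class the effect is small at these allele
  frequencies.
- The original candidate counts from the deposited array experiments
  (hundreds of probes surviving each filter) require the real intensity
  data and are not reproduced here; the pipeline reproduces the *shape*
  of that analysis — nested, order-reported filter counts — on planted
  synthetic data.
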