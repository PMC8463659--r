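---
title: "Censored qPCR arrays: normalization, censored comparison, and multivariable dependence"
author: "qpcrcens maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored qPCR arrays: normalization, censored comparison, and multivariable dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrcens)
```

## Scope and model

`qpcrcens` analyzes miRNA qPCR array data in which a substantial share of
wells never amplify above threshold. The measurement model is: each
reaction yields a quantification cycle Cq (log2-scale inverse abundance),
an amplification score (signal quality in the linear phase), and a Cq
confidence. A reaction is a technical failure when its amplification
score falls below 1.0 (flag `excluded`); otherwise, if no Cq was called
or Cq ≥ 34, the transcript is below the detection limit and the
observation is *censored at Cq = 34* (flag `censored`); otherwise it is
`good`. The ceiling comparison is `≥ 34` and configurable; we adopt the
inclusive form because the flagging rule is stated that way in the
assay's processing convention, while the equivalent "> 34" phrasing
appears elsewhere — with continuous Cq values the choice is immaterial
beyond the exact boundary.

The study design the defaults encode is a three-group comparison —
community controls (ComC, n = 52), deployed controls (DepC, n = 18), and
deployed veterans with repetitive blast mTBI (DepTBI, n = 45) — on a
377-probe human miRNA card with U6-class control probes, with CSF AD
biomarkers (Abeta42, tTau, pTau181 and their ratios), age, BMI, MMSE,
APOE genotype, smoking and race as phenotypes.

## Endogenous-control normalization

EC candidates must be annotated miRNAs (control probes are ineligible)
detected in 100% of samples with AmpScore ≥ 1, Cq < 30 (strict) and
CqConf > 0.8 (strict). Candidates are ranked by the geNorm stability
measure computed directly on Cq: M(j) is the mean over partners k of the
SD across samples of (Cq_j − Cq_k). Cq is already a log-scale quantity,
so this equals the classical SD-of-log-ratios construction up to the
constant log base, and the ranking is identical; we therefore do not
linearize to 2^−Cq first. The worst candidate is removed iteratively
(ties broken lexicographically, so the smaller id counts as more stable —
an arbitrary but deterministic rule).

The pairwise variation V_k is the SD across samples of the difference
between the log-scale normalization factors of the top-k and top-(k+1)
sets. On the log scale the classical normalization factor (geometric mean
of linear quantities) is the *arithmetic* mean of Cq, and that is what we
use; the selection threshold 0.1527 is the conventional one and
configurable. The selected set is the smallest k ≥ 2 with V_k below the
threshold (all candidates if none qualifies).

ΔCq is Cq minus the per-sample *geometric mean of the EC Cq values* —
deliberately the geometric mean of the Cq numbers themselves, matching
the processing convention of the instrument workflow this pipeline
mirrors, not of linearized quantities. Each censored cell carries the
sample-specific censoring threshold 34 − g_s as its value, with the
censoring mask set; excluded cells carry nothing. Samples missing a good
EC reaction are dropped with a warning and leave every downstream
denominator.

Probe-level filters: failure fraction strictly greater than 20% drops a
probe; of the rest, detection (good-cell) fraction of at least 10% keeps
it. Censored cells count toward neither.

## Censored two-group comparison

ΔCq is a right-censored variable: an undetected transcript is known only
to lie *above* the sample's ΔCq threshold (lower abundance). Treating
ΔCq as the time axis, differential expression uses the standard
two-group log-rank statistic with hypergeometric variance and pooled
ties, with p from χ²(1). The test is rank-based, hence invariant to
monotone transforms of the ΔCq axis, and is exactly the statistic of the
survival literature — the test suite cross-checks it against
`survival::survdiff` at 1e−10 and verifies its type-I calibration under
30% censoring by simulation.

Fold changes follow 2^−ΔΔCq. Group means substitute censored cells at
their thresholds — a conservative choice consistent with "censored at
Cq 34"; a Kaplan–Meier-median alternative is available
(`fc_policy = "km_median"`) but not default, since with heavy censoring
group medians can be undefined. The interval is 2^−(ΔΔCq ± s) with
s = √(sd₁² + sd₂²), the combined-SD convention of the relative
quantitation guides; note it is an SD-scale (spread) interval, not an
SE-scale one, so the point estimate need not be centered and, for
noiseless data, the interval degenerates to the point. Significance is
raw p < 0.025; BH FDR is reported alongside but does not drive the flag.

Differential detection compares detected-vs-censored counts per contrast
by Fisher's exact test with the conditional-MLE odds ratio and exact CI
(the convention that yields `Inf` estimates with one finite bound on
zero-cell tables). Excluded cells leave both margins.

## Dependency search

Information measures require discrete data. MiRNAs are binned into three
near-equal-mass bins with thresholds μ ± f·s, f grid-searched over
(0, 2] in 0.01 steps to minimize the maximum deviation of bin counts
from n/3 (ties to the smallest f; boundary values to the lower bin). The
μ and s are estimated from *uncensored* cells only; censored cells are
then forced into the highest-ΔCq (lowest-expression) bin, because a
detection failure is informative about low abundance — dropping them
instead is available via `censored_policy = "drop"`. Probes too censored
to bin (< 6 uncensored values) fall back to a binary detected/censored
coding so every assayable probe is scored in every list.

Primary phenotypes: `deployment` (ComC vs rest), `tbi` (DepTBI vs rest),
`exp_grp` (three levels). Secondaries: `age` and `bmi` tertile-binned as
above; `mmse`, the three biomarkers and their three ratios mean-split
(boundary to the upper bin); `apoe` category-mapped; `apoe4` = genotype
contains e4; `smoke` and `race` category-mapped with merging beyond
three levels (most frequent keep their codes, the rest pool into
"other").

Entropies are plug-in, base 2 — bits make the XOR benchmark land on
integers — with no small-sample bias correction (a deliberate parallel to
the plug-in practice this analysis style uses; all scores are compared
*within* a list, where the bias is shared). Pairwise dependence is
I(M,P); three-way dependence is the symmetric delta
Δ̄ = Δ_M·Δ_P·Δ_S built from the interaction information
I(M,P,S) = I(M,P) − I(M,P|S). All terms of one triple are computed on
the same complete-case sample set, so the decomposition is internally
consistent; each list assembles its own complete cases, maximizing the
usable samples per computation. Δ̄ vanishes whenever one variable is
independent of the rest; for purely synergistic (XOR-like) triples the
deltas are negative and Δ̄ = −1 bit exactly on the fair XOR
distribution.

The search produces 43 lists: MI of each miRNA with each of the 3
primaries; Δ̄ with each (primary, secondary) pair (39); and Δ̄ of each
miRNA with deployment and tbi jointly — the list that isolates purely
collective structure. Each list z-scores all probes on |raw| (delta
lists are negative; magnitudes make "top-scoring" uniform across MI and
delta lists — the alternative of signed-delta z-scoring mainly reorders
mid-list entries, not the extreme tail) and ranks the ≤ 20 probes with
z > 1, ties broken by z then id. Lists with fewer than 10 usable samples
are emitted empty with a warning.

Composite scores aggregate per primary:
cs(p,m) = z_MI + ½(max of the three biomarker-ratio Δ̄ z's + z_apoe4) +
⅓(z_age + z_bmi + z_smoke). The ratio term takes the maximum because the
three ratios are mutually correlated; delta terms carry weight ½ because
delta scores fluctuate more than MI on small samples, and the age/BMI/
smoking terms carry ⅓ because their anticipated effect is smaller.
Missing list entries contribute zero. The stringent filter keeps probes
whose composite exceeds mean + 2 SD of the all-probe composite
distribution for any primary (the source analysis defers its exact
cutoffs to supplementary material; mean + 2 SD is our distribution-based
stand-in, exposed as `stringent_k_sd`), intersected with the QC-passing
set.

## The synthetic world

`simulate_qpcr()` draws latent Cq = probe baseline (uniform 24–33; EC
probes 24–27 with SD 0.1) + planted group effects + a shared per-sample
card offset (SD 0.3 — exactly the artifact EC normalization must remove,
which keeps the normalization tests non-trivial) + probe noise (SD
0.4–1.5). A reaction whose latent Cq reaches 34 is emitted censored, so
detection and level effects are mechanistically coupled as in a real
assay — a planted expression shift near the ceiling changes detection
rates too, by construction rather than by independent coin flips.

Technical failures (1% overall) are realized as a probe-level mixture: 5%
of probes are "flaky" and fail in 20% of their reactions. Failures on
real cards cluster by primer/probe lot — this is what the > 20%-failure
filter exists to catch — and i.i.d. per-reaction failures at 1% would
leave no probe present in 100% of 115 samples, making the EC candidacy
rule unsatisfiable in principle. Cq confidence degrades gently with Cq
and collapses for censored wells.

Planted effects: level shifts (ΔCq added to one group), detection
effects (latent mean positioned to hit target detection probabilities),
and synergy (a Cq shift wherever deployment XOR tbi = 1, i.e. the DepC
samples — a parity-style function of the two binary primaries, which
pairwise measures see only weakly but the ⟨m, deployment, tbi⟩ delta
list ranks first). Phenotypes are drawn per group with the location/
scale structure of the study population (e.g. BMI 25.1 ± 3.4 / 26.9 ±
4.3 / 28.5 ± 4.4; e4-carrier and smoking frequencies per group;
genotyping dropout included). The truth manifest records every planted
quantity, so each pipeline stage can be scored.

What a green test does *not* establish: the generator draws phenotypes
independently of miRNA levels unless planted, uses normal/lognormal
shapes, and has no plate-to-plate chemistry drift, probe cross-talk, or
correlated miRNA co-regulation. Passing recovery tests shows the
machinery detects what it claims under the stated noise model, not that
the study's biological effect sizes are re-derivable — the participant
data are not publicly deposited, so the headline counts of the source
study are checked only conditionally (and currently not at all).

## Numerical choices and edge cases

- Flag precedence: exclusion beats censoring (a failed reaction tells
  nothing about abundance).
- Strict vs inclusive boundaries follow their sources: Cq < 30 and
  CqConf > 0.8 strict for EC candidacy; failure fraction > 20% strict;
  detection fraction ≥ 10% inclusive; mean-split boundary to the upper
  bin; tertile boundary values to the lower bin.
- The log-rank variance term skips risk sets of size 1; an all-censored
  or empty group yields an absent result, never a fabricated p.
- `fisher.test` is the Fisher engine (probability-mass two-sided rule,
  conditional MLE, exact CI); the test suite proves p equal to exhaustive
  enumeration for every table with total ≤ 40.
- Stability ranking computes all pairwise SDs once from the column
  covariance (var(x_j − x_k) = C_jj + C_kk − 2C_jk), making the
  iterative removal O(p²); a constant candidate column is legal and
  contributes SD 0.
- z-scoring a list whose scores are all equal yields z = 0 everywhere
  (no ranked set) rather than 0/0.
- All randomness flows from a single integer seed; identical seeds give
  bit-identical bundles.

## Known limitations

- Multi-group (> 2) log-rank and covariate-adjusted survival regression
  are out of scope; the three contrasts are pairwise.
- Dependencies among more than three variables are not searched (sample
  sizes in this design cannot support them).
- No inter-plate calibration or alternative normalization schemes
  (global mean, quantile).
- Exact reproduction of the source study's list memberships would
  require its per-miRNA binning factors and stringent cutoffs, which
  live in its supplementary material; the grid-search rule and the
  mean + 2 SD cutoff are documented stand-ins.
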