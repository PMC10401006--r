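---
title: "Methods: simulating and analysing networked clinical risk estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing networked clinical risk estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netwisdom)
```

## The experiment being modelled

A *trial* presents one clinical vignette — a case with an evidence-based
correct risk value on a 0–100 scale and a correct categorical treatment
recommendation — to a group of 40 clinicians over three response rounds.
In the **network** condition the 40 clinicians occupy the nodes of a fixed
degree-4 regular random graph; before each revision round every clinician
sees the arithmetic mean of their four neighbours' previous-round
estimates (never the neighbours' treatment recommendations). In the
**control** condition clinicians answer the same questions in the same
rounds, but in isolation. Participants are allocated to conditions at a
2:1 ratio. The default study design replicates each of 7 vignettes in 8
network and 4 control trials: 84 trials, i.e. 56 and 28 trial-level
observations.

The degree-regular ("egalitarian") topology matters: every participant has
the same connectivity, so any differential influence must come from
behaviour, not position. The package's topology generator draws the graph
by configuration-model stub pairing with rejection of self-loops and
duplicate edges. One realized topology, fixed by an internal master seed
(`canonical_topology()`), is reused across all network trials; only the
clinician-to-node assignment is re-randomized per trial.

**Connectivity.** Nothing in the design forces the realized graph to be
connected, but a disconnected component would give its members a peer
signal decoupled from the rest of the trial and, in the extreme, isolated
nodes no signal at all. We therefore reject disconnected draws by default
(`connected = TRUE`, configurable). A practical limit of rejection
sampling is near-complete graphs (a 5-regular graph on 6 nodes is K6,
which random pairing essentially never realizes); the study-relevant
regime — 40 nodes, degree 4 — accepts within a few hundred attempts.

## Outcome measures

Error is the absolute distance between estimate and truth, in percentage
points. Accuracy arranges the *negated* errors on a 0–1 scale by min–max
normalization. Two bound conventions are implemented:

* **fixed** (default): bounds are the theoretical extremes of the negated
  error, (−100, 0), so accuracy = 1 − error/100 and the accuracy/error
  pair always sums to 100 on the percent scale. This convention is what
  makes reported pairs like 76.8 %/23.2 points self-consistent. (A pair
  whose two members were rounded independently to one decimal can sum
  slightly off 100 — e.g. 79.3/20.9 — which the package treats as rounding,
  not as a different normalization.)
* **observed**: bounds are the dataset's own min/max negated error, so the
  worst observation scores 0 and the best 1.

All confirmatory inference is **trial-level**: each trial contributes one
summary (mean accuracy per round, correct-recommendation rate per round,
and their round-1-to-final changes), because clinicians who influence each
other within a network are not independent. Differential analyses group
clinicians by round-1 accuracy into equal-frequency quartiles or deciles
(bin 1 = least accurate). Binning pools clinicians across all trials of a
condition by default; a per-trial scope is available
(`binning = "trial"`). Ties at bin boundaries are broken by the stable
order (accuracy, trial id, clinician id), making the partition
deterministic with bin sizes differing by at most one. Clinicians missing
any round are excluded from the panel and recorded in an exclusion log.

Whether the quartile-level condition contrasts should be computed on
trial-level or clinician-level change scores is genuinely ambiguous in
designs of this kind; `run_analyze()` computes **both**, side by side, in
`quartile_contrasts$level`, with the trial level regarded as the primary
inference scale.

## The synthetic cohort

The generator is a first-class, tested component, not a fixture. Each
clinician has a persistent systematic bias drawn from N(0, `bias_spread`)
plus round-level noise N(0, `noise_sd`); the round-1 estimate is
truth + bias + noise clipped to [0, 100]. Defaults (`bias_spread = 29`,
`noise_sd = 5` points) were chosen once so that initial accuracy spans a
wide range — quartile means run from roughly the high 40s to the high 90s
on the percent scale, the heterogeneity the differential analyses need —
with an overall mean absolute error in the low 20s.

Revision in the network arm is a convex self/peer combination
(DeGroot-style), the simplest rule that generates the empirically expected
accuracy–revision link. The self-weight is

w = clip(`stubbornness_base` + `alpha_link` · (1 − error₁/100), 0, 1),

computed once from the round-1 error: with `alpha_link > 0` accurate
clinicians revise less, which is precisely the positive *revision
coefficient* that lends them greater de facto influence and drives
network-wide improvement. Defaults `stubbornness_base = 0.3`,
`alpha_link = 0.6` put self-weights in [0.3, 0.9]. Estimates are clipped
to [0, 100] before they feed the next round's peer signals.
Recommendations are recomputed each round by ordered thresholds on the
estimate; an estimate exactly at a threshold maps to the higher-index
option (fixed convention).

Control clinicians move a fraction `control_gain` of the way toward the
truth each revision round, plus noise — the minimal mechanism producing a
modest improvement from independent reflection. `control_gain = 0.055`
was sized so the simulated control arm improves by about 2–3 accuracy
points over the two revision rounds; `control_noise_sd = 2` points keeps
round-to-round wobble small.

Every trial draws from its own RNG stream derived from the master seed by
a multiplicative hash (`split_seed()`), with vignette-blocked stream
indices, so datasets are bit-for-bit reproducible and adding trials or
vignettes never perturbs earlier trials.

**What the generator does and does not emulate.** It reproduces the
structural conditions (panel dimensions, topology, allocation ratio), the
heterogeneity of initial skill, the accuracy-dependent revision mechanism,
and threshold-driven recommendations. It does not model clinician
demographics, attrition (panels are complete by construction; the analysis
side nevertheless handles incompleteness), learning across vignettes by
repeat participants, or the empirical per-vignette estimate distributions
of any real dataset — so passing mechanism-recovery tests shows the
pipeline detects the modelled mechanism, not that real clinicians behave
exactly this way.

## Inference procedures

All tests are implemented from first principles with three modes:

* **exact**: full enumeration — rank assignments for the rank-sum test
  (all C(N, n_a) subsets, midranks, so ties are handled as a permutation
  test), sign patterns for the signed-rank test (2^n, via convolution on a
  doubled-rank integer support), and distinct group-label arrangements for
  Jonckheere–Terpstra. Exact p-values are rational multiples of
  1/(number of arrangements). Auto thresholds: N ≤ 12 (rank sum), n ≤ 15
  (signed rank), N ≤ 10 (JT).
* **permutation**: seeded Monte-Carlo for JT (default 10,000 permutations)
  and Spearman, with the add-one rule (1 + extreme)/(1 + n_perm), which is
  valid (super-uniform) under the null. The JT null permutes the *sorted*
  pooled values, so the p-value is invariant to relabeling within groups.
* **normal approximation**: tie-corrected variances with continuity
  corrections for the two Wilcoxon tests; the standard tie-corrected JT
  variance. Used automatically at large N.

Two-sided p-values double the smaller tail and cap at 1. Zero differences
in the signed-rank test are dropped (Wilcoxon's convention); the Pratt
variant (rank first, then discard zero ranks) is available by flag.
Degenerate inputs are explicit: all-zero differences and constant inputs
to Spearman raise classed errors; a two-sample t on two equal constant
samples returns t = 0, p = 1, while unequal constant samples raise a
degenerate-input error rather than fabricating an infinite statistic.
Welch's unequal-variance form is the t default (pooled by flag); the
least-accurate-quartile switching contrast uses the pooled Student form,
matching how such contrasts are conventionally reported.

The Hodges–Lehmann shift estimate is the median of all pairwise
differences, with its confidence interval obtained by inverting the
rank-sum test — order statistics of the pairwise differences at the exact
Mann–Whitney critical value (lattice-recursion null distribution) for
m·n ≤ 5000, and at the normal-approximation critical value beyond.

Power for the between-arm comparison is estimated by simulation
(`power_rank_sum()`): normal shift of Cohen's d, two-sided rank-sum at the
trial-level sizes 56 vs 28. We report simulated power rather than a
closed-form claim; at d = 0.207 with these sizes the simulated power is
small (on the order of 13–14 %, `power_rank_sum(0.207, seed = 7)`), which
is why the package makes no assertion that such a design is well powered
for that effect size at the trial level.

## Numerical and testing choices

Exact-mode tail comparisons use an epsilon of 1e-9 on rank-scale
statistics to make ≥/≤ robust to floating-point midranks; oracle
comparisons in the test suite require agreement to 1e-12. The test suite
verifies every exact mode against independent brute-force oracles
(pairwise-count subset enumeration, explicit sign-vector enumeration,
label-multiset permutation) on hundreds of random small inputs, checks
null calibration of all five tests at α = 0.05 over 5,000 replicates at
the study's own trial-level dimensions, and checks mechanism recovery —
negative revision trend across deciles, network > control improvement,
and bottom-quartile > top-quartile improvement in the network arm — on 20
independently seeded full-scale studies (84 trials each). Pipeline
determinism is asserted byte-for-byte across reruns of one master seed.
These problem sizes make the whole suite run in a few minutes on a single
core while still exercising the full default study scale.

## Known limitations

* The generator's revision rule is the simplest form consistent with the
  mechanism; real revision behaviour is surely richer (asymmetries,
  anchoring, occasional contrarian moves).
* The configuration-model generator is impractical for near-complete
  regular graphs (inherent to rejection sampling; irrelevant at the 40/4
  study density).
* Spearman p-values use the t approximation (or permutation), not the
  exact small-n distribution; at the sample sizes involved (hundreds to
  thousands of clinicians) the approximation error is negligible.
* No multiplicity adjustment is applied across quartiles or outcomes, by
  design — results are reported unadjusted, as is conventional for this
  family of analyses.
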