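---
title: "Score-weighted gene-set enrichment: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-weighted gene-set enrichment: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Classical over-representation analysis (ORA) tests, for each pathway,
whether the pathway's intersection with a pre-selected list of significant
genes is larger than chance. With $N$ genes on the array, $m$ of them
significant, $n$ measured pathway members and $k$ of those significant,
the hypergeometric version computes

$$P(X > k) \;=\; 1 - \sum_{r=0}^{k}
  \frac{\binom{m}{r}\binom{N-m}{n-r}}{\binom{N}{n}},$$

and the chi-squared version tests the 2×2 table (in / not in pathway
against genes on array / significant genes) with the uncorrected statistic
$N(n_{11}n_{22}-n_{12}n_{21})^2/(N_{1r}N_{2r}N_{1c}N_{2c})$ on
$(r-1)(c-1)=1$ degree of freedom. Both discard effect sizes: a gene at
$p = 0.011$ with an 8-fold change counts exactly as much as one at
$p = 0.9$ with no change — namely nothing.

The weighted variants let every gene contribute in proportion to a power
of its absolute log fold change:

$$g_i = \left|\log_2 \mathrm{FC}_i\right|^{a},$$

with pathway score $k = \sum_{i=1}^{n} g_i$ and $Q = \max_i g_i$ over the
measured members. The absolute value makes the score direction-blind, so
pathways mixing up- and down-regulated genes accumulate weight from both
sides — a deliberate contrast to rank-based methods that follow one
direction.

**Weighted hypergeometric.** The hypergeometric distribution is discrete
while $g_i$ is continuous, so per-gene scores are rounded to the nearest
whole number and a *pseudo pathway* is constructed: each of the $N$ array
genes is replicated $Q$ times ($Q$ rounded, per pathway), a gene's rounded
score is the number of its copies counted significant, the rounded score
sum $S$ over the whole array plays the role of the significant-gene total,
and $nQ$ pseudo genes are drawn. The p-value is the hypergeometric tail
beyond the rounded pathway score:
population $NQ$, successes $S$, draws $nQ$, tail $P(X > k)$.

This construction is the one design point that required a genuine
decision: the combinatorial layout of the weighted tail does not pin
itself down, and we fixed it by requiring two properties simultaneously —
(i) a gene's rounded score must equal the number of its pseudo-pathway
copies counted significant, and (ii) substituting the 0/1 significance
indicator for $g_i$ must collapse the weighted test *exactly* onto the
classical one (then $Q = 1$, $S = m$, and the pseudo population is the
array itself). Property (ii) is enforced by the test suite at $10^{-12}$
on randomized inputs, so the construction cannot drift.

**Weighted chi-squared.** The 2×2 table keeps its first column (measured
members $n$, rest of array $N-n$) but the significant-genes column is
replaced by score mass: the pathway's unrounded $k$, and below it the rest
of the array's score mass $S - k$. The chi-squared distribution is
continuous, so no rounding is involved, and the reported pathway score is
the unrounded $k$. An alternative convention puts the whole array score sum
$S$, rather than the remainder $S - k$, in the second row; we default to
$S - k$, which preserves the row-exclusive semantics of the unweighted
table, and expose the alternative as `score_margin = "total"` for
sensitivity analysis.

## Parameters

* `a` (default 1): the score power, dimensionless. `a = 1` weighs genes by
  their absolute log2 fold change; larger values concentrate weight on
  extreme genes; `a = 0` is an edge configuration in which every changed
  gene weighs 1 and — by the convention $0^0 := 0$ adopted here —
  unchanged genes (FC exactly 1) weigh 0, so null genes never contribute.
* `alpha` (default 0.01): the per-gene two-tailed t-test threshold used by
  the *unweighted* methods and reported in summaries. The weighted methods
  do not threshold.
* `top_k` (default 10): length of the ranked head used in reports and in
  the cross-dataset consistency analysis. Multiple-testing correction of
  enrichment p-values is reported (Benjamini–Hochberg) but never used for
  filtering: FDR on the handful of p-values enrichment produces is highly
  variable, so the intended reading is the ranked top-`top_k` list, with
  FDR included for completeness.
* `score_margin` (weighted chi-squared only): `"exclusive"` ($S-k$,
  default) or `"total"` ($S$).

## Preprocessing conventions

* Intensities are quantile-normalized (limma's implementation: every
  column receives the vector of row means of the column-sorted matrix;
  ties within a column get the mean of the reference values they span).
  Normalization is idempotent, which the suite checks.
* Fold change is `mean(case) / mean(control)` on the *normalized linear*
  scale. Orientation is a convention, not a result: the weighted methods
  use $|\log_2 \mathrm{FC}|$, so inverting every fold change provably
  leaves their p-values unchanged (tested), and the `case` argument lets
  file-based runs swap labels.
* Significance comes from a pooled-variance (Student) two-sample t-test,
  not Welch. With the equal group sizes typical of the designs this
  package targets the distinction is minor; degenerate rows (zero pooled
  variance) get $p = 1$ when the group means agree and $p = 0$ otherwise.
* Probe-level statistics collapse to genes by the arithmetic mean of
  linear-scale fold changes and the minimum p-value. Probes mapping to no
  gene are dropped with a logged count; probes mapping to more than one
  gene are rejected outright — with only a flat mapping table there is no
  principled way to split a probe's signal, so the restriction is made
  explicit rather than silently resolved.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero (`floor(x + 0.5)` for the non-negative
  scores), matching the plain reading of "nearest whole number"; base R's
  round-half-to-even would differ at exact halves. Scores are rounded
  per gene and then summed.
* The hypergeometric tail is evaluated by `stats::phyper`, which works in
  log space and is stable for pseudo populations of millions; an
  exhaustive enumeration oracle pins it on every instance with
  $N \le 12$.
* A pathway none of whose members is measured on the array is
  *untestable*; a pathway whose every member score rounds to zero
  (weighted hypergeometric, $Q = 0$), or any chi-squared table with a zero
  margin, or a weighted chi-squared run with zero total score mass, is
  *degenerate*. Both get $p = 1$ and a status flag rather than being
  dropped, so ranks always form a permutation of the full collection.
* In the pseudo population the success count $S$ can in principle exceed
  the population size $NQ$ (the pathway's $Q$ is a per-pathway maximum,
  not an array-wide one); it is capped at $NQ$ and the pathway flagged.
* Ranking sorts by p-value ascending with ties broken by larger pathway
  score, then lexicographic set ID — output files are byte-identical
  across runs.

## What the synthetic generator emulates

`simulate_dataset()` produces log-normal intensities (log2 scale: gene
baselines $\mathcal{N}(8, 1)$, within-group noise sd 1 by default) for a
binary design, with disjoint random pathways and planted class effects:

* `significant_shift` — all members shifted by the effect magnitude
  (default 2 log2 units) with a tight within-group sd (0.5), so most
  members pass $\alpha = 0.01$: the regime classical ORA detects. At
  5 samples per class and magnitude 2 the pooled t has power
  $\approx 0.98$ at sd 0.5, versus $\approx 0.4$ at sd 1 — the tight sd
  is what makes the mode live up to its name.
* `high_fc_nonsig` — members shifted by the magnitude with a large
  within-group sd (2.5), so observed fold changes are high but the t-test
  misses at $\alpha = 0.01$ (power $\approx 0.07$ at 5 + 5 samples): the
  regime only score-weighted enrichment can see, mirroring the bundled
  globo-series example.
* `bidirectional` — members alternate up/down shifts, exercising the
  direction-blindness of the score.

The generator is seeded and bit-reproducible, and it deliberately does
*not* emulate probe-level artifacts, GC effects, inter-gene correlation or
heavy-tailed noise; passing tests demonstrate the statistics' behaviour
under a clean log-normal world, not robustness to real microarray noise.
One consequence surfaces in the suite: the Student t applied to
*linear-scale* log-normal intensities is mildly liberal at 5 samples per
class (skewness), so the null type-I check on the full pipeline asserts
the right order of magnitude rather than exact binomial coverage, while
the t-test itself is verified to exact binomial coverage on normal data.

## Calibration of the enrichment p-values

The ORA p-values — weighted or not — are functions of a discrete count,
so under a null their distribution is a finite mixture of atoms, not
uniform. Moreover the tail is *strict* ($P(X > k)$, excluding the
observed outcome), which makes the p-value stochastically *smaller* than
uniform: $E[p] = \tfrac{1}{2}\bigl(1 - \sum_k P(X=k)^2\bigr) < \tfrac12$.
Both effects are inherent to the method as defined, not implementation
artifacts; a distribution-level uniformity test (Kolmogorov–Smirnov)
rejects on null data for structural reasons even when the rejection
*rate* at conventional thresholds is close to nominal, which is what the
suite verifies for the chi-squared baseline (null rejection rate within
2.5 points of 5% over 1000 pathway tests). Users comparing pathways
should rely on ranks, as the top-k reading intends, rather than on the
absolute calibration of small ORA p-values.

Problem sizes used by the suite, chosen as realistic desk-scale
configurations: null calibration runs 100 datasets of 2000 genes ×
10 samples per class with 10 pathways of 20–200 genes each (1000 pathway
tests per method); the planted-pathway recovery study runs 50 seeds of
500-gene arrays with a 14-member-scale planted pathway; oracle equivalence
enumerates every hypergeometric instance with $N \le 12$.

## Known limitations

* Pathway topology is ignored: opposing changes in an upstream activator
  and its downstream target both add weight, where a topology-aware
  method would let them cancel.
* The score uses fold change only; a gene with a huge but wildly variable
  change contributes as much as a tightly estimated one. That is the
  method's point (it is how the high-FC/non-significant regime becomes
  visible) and its risk.
* FDR values on enrichment p-values are reported for completeness but are
  fragile at typical collection sizes; the supported workflow is the
  ranked top-k list and, across related datasets, the recurrence
  tabulation of `cross_tabulate()`.
* Probe-to-many-gene mappings are rejected, not resolved.
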