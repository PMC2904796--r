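---
title: "Methods: pooled barcode screen analysis for chronological lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled barcode screen analysis for chronological lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment this package models

In a pooled chronological-lifespan (CLS) screen, thousands of barcoded yeast
deletion strains age together in one non-dividing culture. At sampling days
(default 3, 9, 11, 15, 20; day 3 is defined as 100% survival) an aliquot is
regrown briefly, its DNA extracted, and each strain's two barcodes (uptag
and downtag) are quantified on a barcode array. A strain's array intensity
tracks its *relative* abundance among viable cells; pool-level colony
forming unit (CFU) counts anchor absolute survival. Strains that die early
fade from the pool; long-lived strains take it over.

`chronoscreen` implements the full analysis: aging profiles, quality
filters, K-means classification, a time-course significance test,
survival-curve reconstruction with Boltzmann lifespan fits, and term
enrichment — plus a generator of synthetic screens with planted truth so
every stage is testable end to end.

# From intensities to aging profiles

Each (replicate, day) array is **mean normalized**: rescaled so every array
mean equals the grand mean over all arrays. Any common target gives the same
downstream log2 ratios; the grand mean keeps output in input units.

Uptag and downtag are combined by **geometric mean** — the arithmetic mean
on the log scale, consistent with the multiplicative error model of array
intensities. If exactly one tag of a pair sits at background level (below
`k_factor x background_level` at every day, default `k_factor = 2`), the
other tag is used alone; if both do, the strain is left to the background
strain filter. Normalization happens before combination, so tag-specific
affinity differences never leak across arrays.

The **aging profile** of strain *s* is `r[s, t] = log2(I[s, t] / I[s, ref])`
per replicate, with the reference-day column identically zero, plus an
averaged layer. Zero or missing reference intensities mask the strain with a
reason code; masks propagate, nothing is silently dropped.

# Quality control

Two exclusion rules run in order:

1. **Background strains** — combined intensity below `k_factor x
   background_level` at *every* day in at least one replicate. One bright
   day rescues a strain. What "similar to background" means numerically is
   not standardized; `k_factor` is exposed, 2 is the default.
2. **Replicate concordance (RSME)** — the root squared mean error between
   the two replicate profiles over non-reference days (the reference column
   is identically zero in both replicates and would only dilute the
   statistic). The threshold is the **nearest-rank** 90th percentile (the
   value at position `ceiling(0.9 n)` of the sorted RSMEs); strains strictly
   above it are excluded, so ties at the threshold survive. Nearest rank
   rather than an interpolated percentile gives a reproducible integer
   cutoff.

Background exclusion runs first, RSME on the survivors — the order the
analysis narrative implies, and the one that keeps the RSME distribution
free of background noise.

# Cluster classification

Averaged profiles (non-reference days only; the reference column carries no
information) are clustered with K-means, K = 10 by default. The
implementation is Lloyd's algorithm with Euclidean distance, the best of
`n_init = 20` seeded restarts by within-cluster sum of squares (ties to the
lowest restart index), and empty clusters re-seeded from the point farthest
from its centroid. Strains are processed in sorted-id order, so results are
independent of input row order. The algorithm is implemented in the package
rather than delegated because this exact contract (restart and
empty-cluster policy) is what makes runs reproducible across environments.

Historically, clusters were labeled short- or long-lived by eye. Here the
rule is explicit: a cluster is **short** when its centroid's mean over
non-reference days is at or below `-theta_short`, **long** at or above
`+theta_long`, else neutral; `theta_short = theta_long = 0.5` log2 units by
default — half of a full halving/doubling of relative abundance. Strains
inherit their cluster's label. The thresholds are configurable because the
boundary is a judgment call in log2-ratio space, not a derived quantity.

# Time-course significance

The test asks whether a strain's representation changes over the time
course *consistently in both replicates*. Both replicates' log2 ratios are
stacked and two nested least-squares fits compared: intercept-only versus
an intercept plus natural cubic spline in day (df = `min(3, T - 2)`,
interior knots at day quantiles). The statistic is the raw residual ratio

```
F = (rss0 - rss1) / (rss1 + 1e-8),  capped at 1e12
```

without degrees-of-freedom scaling: the permutation calibration makes any
monotone rescaling irrelevant, and the guard only matters for exact fits.

The null is built by permuting day labels once per replicate per round —
independently across replicates, *shared across strains within a
replicate* — and recomputing every strain's statistic. Sharing permutations
preserves the cross-strain dependence structure; pooling the `B x n` values
gives resolution that five time points (120 day orderings) cannot give per
strain. P-values use the add-one formula `(1 + #{null >= F}) / (1 + |null|)`.

False discovery rates use Storey's machinery: `pi0 = min(1, #{p > 0.5} /
(0.5 m))` (fixed lambda = 0.5, robust at the few-thousand-test scale), and
the step-up q-value `q_(i) = min_{j>=i} pi0 m p_(j) / j`. Strains with
`q <= 0.1` are called significant by default.

# Survival reconstruction and lifespan

Per-strain survival is approximated by multiplying the fold change
(`2^r[s,t]`, averaged layer) by the pool CFU at each day (averaged across
replicates), then normalizing to the reference day = 100%. In the noiseless
limit this returns the planted survival sigmoid exactly (the package's
generator/estimator consistency test holds it to 1e-9).

Each curve is fitted with the Boltzmann sigmoid
`V(t) = bottom + (top - bottom)/(1 + exp((t - t50)/tau))` by bounded
least squares (Levenberg-Marquardt, with a box-constrained quasi-Newton
fallback), parameterized as (bottom, span, t50, tau) so `bottom <= top` is
structural. Initialization: top = max, bottom = min, t50 = day nearest the
half-range, tau = (last - first)/8; t50 is bounded within 10 days of the
sampled range and flagged `extrapolated` outside it. Flat curves (range
< 5%) or monotone rising curves are flagged degenerate and not fitted —
rising "survival" means regrowth or takeover, not death.

**Mean lifespan** is reported as the day the *fitted* curve crosses 50%
absolute survival, `t50 + tau log((top - 50)/(50 - bottom))` — equal to the
midpoint parameter when top = 100 and bottom = 0, and undefined (flagged)
when the curve never crosses 50%. The 50%-of-initial crossing, not the
curve midpoint, is the quantity comparable across strains when curves are
normalized to 100% at the reference day; both are available. The area under
the survival curve (trapezoid, %·days) is the model-free alternative.

# Term enrichment

For a gene list against a universe (default: strains retained after the
background filter), each term's tail probability is
`P(X >= k)` for X ~ Hypergeometric(N, K, n), computed in log space.
Bonferroni adjustment over the terms tested, significance at adjusted
p < 0.01. Only direct annotations are used — ontology-graph ancestor
propagation depends on an ontology release and is out of scope; users can
pre-propagate their annotation map if desired.

# The synthetic screen generator

`screen_config()` / `simulate_screen()` emulate the experimental design:
two replicate pools of 4,800 strains, sampling at days 3/9/11/15/20,
survival following the same Boltzmann sigmoid the survival module fits
(normalized to 1 at the reference day — this shared definition is what
makes noiseless parameter recovery exact), per-tag lognormal hybridization
affinities, lognormal measurement noise, ~10% of tags at background level,
and adaptive regrowth: a step gain (default x5) applied to a small fraction
of strains (default 2%) from day 12, which reproduces the late bump in pool
CFU curves. The step gain is a deliberate simplification of renewed
exponential growth; it injects the right artifact (late abundance inflation
mimicking longevity) without modeling growth kinetics.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `pool_t50_mean` | 11 d | pool survival falls through 50% between days 9 and 15 |
| `pool_t50_sd` | 0.5 d | "neutral" means no lifespan phenotype: residual strain-to-strain scatter is a fraction of a day, while planted class effects move t50 by multiples of days |
| `slope_tau` | 1.5 d | survival falls from >90% to <10% across roughly a week |
| `frac_short`, `frac_long` | 0.12, 0.01 | order of magnitude of short/long calls in genome-wide CLS screens |
| `short_t50_multiplier`, `long_t50_multiplier` | 0.5, 1.8 | halved vs near-doubled lifespan — clear phenotypes |
| `noise_sigma` | 0.3 | lognormal array measurement noise (log scale); multinomial sampling noise is folded in here rather than modeled separately, since cells sampled per time point are not quantified in this design |
| `tag_affinity_sigma` | 0.5 | per-tag hybridization efficiency spread; cancels in log2 ratios, stresses normalization and tag combination |
| `frac_background_tags` | 0.10 | tags that hybridize poorly |
| `p_regrow`, `regrow_day`, `regrow_gain` | 0.02, 12, 5 | sporadic adaptive regrowth fed by dead-cell nutrients, visible as a day-12/15 CFU bump |

What the generator does **not** emulate: PCR amplification bias, spatial
array artifacts, cross-hybridization between tags, death–regrowth feedback
between strains (one strain's death feeding another's regrowth), and
growth-rate differences during the pre-tagging outgrowth (assumed
proportion-preserving; a per-strain growth multiplier is a config extension
left off by default). Passing tests on synthetic screens therefore
demonstrate the pipeline's correctness and calibration under this noise
model, not robustness to every artifact of real arrays.

A property worth knowing when reading results: abundance is
*compositional*. When a few percent of strains live much longer than the
rest, they dominate the late pool and push every other strain's relative
share down; with low measurement noise the time-course test correctly
flags these systematic share changes, so the fraction of significant
strains can far exceed the fraction of strains with a lifespan phenotype.
The classifier thresholds (`theta_*`) and the planted-truth recovery
metrics, not the raw significant count, are the quantities to interpret.

# Numerical choices and degenerate inputs

- Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; the pipeline fans one master seed out by fixed
  offsets.
- `F` guard `delta = 1e-8`, cap 1e12; `rss1` clamped to `rss0` (nested
  models) against rounding.
- Truncated-normal t50 draws floor at the first sampling day (rejection
  sampling).
- Intensities of zero are floored at the smallest positive double inside
  the geometric mean; zero reference intensities mask the strain instead.
- Strains with any missing averaged value are dropped from clustering (with
  a message); strains with too few unmasked observations are flagged
  untestable rather than scored.
- Pool CFU jitter is lognormal with sd 0.02 (plating counts are positive
  with a few-percent error).

# Problem sizes used by the test suite

The suite exercises the pipeline at 120–2,000 strains, B = 100–200
permutations and 10 seeds for the null-calibration study; the acceptance
script runs the full default screen (4,800 strains, B = 1,000) plus a
10-seed null study at 2,000 strains, a 1,000-strain planted-recovery run,
and 100-curve fit-recovery studies. These sizes give stable estimates of
the reported rates while keeping a complete run in tens of seconds.

# Known limitations

- Replicate count is fixed at two for the RSME filter (more replicates
  error out rather than silently averaging).
- The q <= 0.1 significant-strain count on synthetic defaults is dominated
  by the compositional effect described above and is not comparable to
  published counts from noisier array data.
- Cluster labels depend on K and the theta boundaries; K is not selected
  automatically.
- Enrichment frequencies depend entirely on the user-supplied annotation
  map and universe choice.
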