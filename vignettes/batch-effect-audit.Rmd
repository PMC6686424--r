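---
title: "Auditing sequencing-center batch effects in germline variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing sequencing-center batch effects in germline variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbatch)
```

## The audit model

`varbatch` quantifies technical variation tied to the sequencing center in
a pooled germline SNV call set where sample groups (cancer types) are
confounded with centers. The audit treats the call set as fixed data — it
starts from VCFs, not reads — and asks four nested questions:

1. Do per-sample variant totals differ by center? (one-way ANOVA on
   per-sample counts)
2. Does the substitution spectrum differ by center? (ANOVA on per-sample
   TiTv ratios)
3. Does the allocation of variants *among* genes differ? (per-gene
   densities, sample–sample Pearson correlations)
4. Does the distribution of variant positions *within* genes differ?
   (all-pairs two-sample KS per gene, summarised by the ratio
   `r_g = p_min / p_max`)

The within-gene stage is the core. Its unit of data is the location
collection `L[g, t]`: the multiset of gene-exomic coordinates of all calls
in gene `g` from all samples of group `t`. Working on multisets is
deliberate — recurrent sites contribute once per carrier, so the ECDF
weights positions by how often they are called, which is exactly the
quantity a center-specific artifact distorts.

The declaration rule is conservative by construction. With within-center
pairs `W` and between-center pairs `B`,

    r_g = min(p[w], w in W) / max(p[b], b in B)

exceeds 1 only when *every* between-center p-value is smaller than *every*
within-center p-value. `r_g` is a ranking score, not a calibrated test
statistic: the pair p-values share samples, so the null distribution of
`r_g` has no closed form, and no multiple-testing correction is applied.
The package estimates the null flag rate by simulation instead (see the
property tests), and the test suite asserts the rule's logical equivalence
to the all-pairs ordering on every run.

### Pair designs

Which pairs count as "within" and "between" is a design choice. The
`"reference"` design compares the reference center's group pairs (three
pairs when it hosts three groups) against the pairs crossing the reference
and one designated contrast center (six pairs for three-vs-two groups),
leaving the third center's pairs out. This asymmetric design maximises the
number of groups on each side of the contrast while keeping a pure
within-center null set. The `"generalized"` design — all same-center pairs
versus all cross-center pairs — is provided for symmetric cohorts; both are
first-class and the choice is echoed in every output.

## Statistical components

**KS test with ties.** Gene-exomic coordinates are integers, so ties are
guaranteed. The statistic is computed on multiset ECDFs (tied values raise
the step height); the p-value uses the asymptotic two-sided Smirnov
distribution at `sqrt(n) D` with `n = k1 k2 / (k1 + k2)`, switching to the
theta-function series below the Marsaglia crossover so both tails are
accurate. The asymptotic p-value ignores the tie structure and is therefore
anti-conservative under heavy ties — acceptable here because `r_g` is a
ratio of p-values computed under the same policy, but worth remembering if
the p-values are read in isolation. An exact conditional p-value
(permutation distribution given the pooled tie pattern) is available with
`ks_two_sample(..., exact = TRUE)` as a validation aid for small
collections.

**Evaluability.** A pair is evaluable when both collections hold at least
`min_k` locations (default 3). `min_k = 1` reproduces the
any-variant-in-every-group convention; the default avoids one- and
two-point ECDFs whose KS p-values are nearly uninformative. Genes missing
any design pair are flagged not-evaluable rather than silently dropped.

**Numerical guards.** `p_max` is floored at 1e-300 and `r_g` capped at
1e300 to keep the ratio finite; ANOVA and log-rank p-values are computed on
the log scale (`log10_p`) because center effects at cohort scale can push
p-values below double-precision underflow; equal design p-values give
`r_g = 1`, which the strict `> 1` rule leaves unflagged; ranking ties in
`r_g` break lexicographically by gene id so outputs are stable across runs.

**Survival.** The Kaplan–Meier estimator and the two-group log-rank test
are implemented from first principles (product-limit over distinct event
times; hypergeometric expectation and variance per event time, chi-square
with 1 df, two-sided). Ties between an event and a censoring at the same
time process the event first — the standard convention. The test suite
cross-checks both against the `survival` package and against brute-force
oracles.

**ANOVA.** Classical one-way fixed-effects ANOVA via the equal-variance
F statistic; the package recomputes the p-value from the F distribution on
the log scale. Groups need at least two finite values each, and an overall
zero within-group variance is an explicit error, not a silent `NaN`.

## The synthetic cohort generator

No public generative model exists for center-specific calling artifacts,
so the generator's distributional choices are explicit stand-ins shaped to
reproduce the *structure* of the observed effects, not their mechanism:

* **Counts**: per-sample totals are negative-binomial with center-specific
  means (default 100 vs 130, i.e. 30% inflation) and dispersion 50 — a
  realistic overdispersion for exome call totals.
* **Spectrum**: each substitution is a transition with probability
  `r / (1 + r)` from the center's target TiTv `r` (defaults 2.73 for the
  reference center, 2.57 elsewhere), then a concrete REF/ALT pair is drawn
  uniformly among the valid pairs. TiTv is the only spectrum property the
  audit measures, so nothing finer is modelled.
* **Density skew**: per-gene weights are Gamma-distributed (scaled by
  transcript length) and optionally perturbed per center by a log-normal
  factor (`density_skew`), giving samples from one center a shared density
  profile.
* **Within-gene positions**: positions are drawn over `[0, L)` from a Beta
  law scaled to the transcript — `Beta(1, 3)` by default. For "affected"
  genes, non-reference centers interpolate the Beta parameters toward
  `Beta(3, 1)` by the shift magnitude in `[0, 1]`. One knob moves the
  distribution continuously from identical (`shift = 0`) to strongly
  displaced (`shift = 1`), which is what the power properties sweep.
* **Callers**: each caller replicate independently drops true calls
  (`fn_rate`) and injects spurious calls (`fp_rate`, uniform positions,
  TiTv 0.5 as expected of random errors), exercising union/consensus
  merging.
* **Survival**: exponential event times with a carrier hazard ratio and an
  independent exponential censoring process whose hazard is `censor_rate`.

Determinism is structural: every unit (gene set, sample, sample-by-caller
replicate, survival table) draws from its own stream keyed by
`(seed, unit indices)`, so identical configs reproduce files byte for byte
and enlarging the cohort never reshuffles existing samples. Within a
sample, duplicate `(position, ref, alt)` draws collapse to one call (a
diploid sample has one genotype per site); at the default gene space this
removes well under 1% of draws.

What the generator does *not* emulate: linkage disequilibrium, realistic
allele-frequency spectra, indels, genotype content (all calls are written
as heterozygous with a fixed QUAL), per-gene mutation-rate covariates, or
read-level error processes. Passing tests therefore demonstrate that the
audit statistics recover *injected* structure of the modelled kinds — they
do not certify behaviour on artifacts with a different geometry (e.g.
center-specific effects confined to a few exons, which the one-knob Beta
shift only crudely approximates).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_qual` | 30 | Phred-like | conventional call-confidence floor; applied per caller **before** merging, since per-caller quality scores are not comparable after unification |
| `min_callers` | 2 | callers | consensus rule: a variant must appear in at least two callers |
| `min_k` | 3 | variants | smallest collection size for an evaluable KS pair |
| `decile` | 0.10 | fraction | extreme gene-set size for the survival contrast, `floor(decile * n)` genes |
| `kde_window` | 100 | nt | Gaussian bandwidth for presentation-only location density curves |
| `shift` | 0.5 | — | generator mixture-shift magnitude for affected genes |
| `density_skew` | 0 | — | sd of the per-center log-normal gene-weight perturbation |

## Problem sizes in the shipped tests

The test suite exercises the pipeline at deliberately modest scale: module
tests use cohorts of 18–90 samples over 10–60 genes; the calibration
recovery tests use 900 samples at ~1000 SNVs each; the KS implementation is
checked against a brute-force ECDF oracle on exhaustively enumerated small
multisets plus random tied multisets; ANOVA and log-rank type-I error are
estimated from 1000 null replicates each; and the `r_g` power sweep runs
four 72-sample cohorts across shift magnitudes `{0, 0.25, 0.5, 1}`,
evaluating sensitivity on genes with at least 30 variants in every group.
These sizes were chosen so the full suite documents the estimators'
behaviour while remaining quick to run on a laptop.

## Known limitations

* The KS p-values are asymptotic and anti-conservative under heavy ties;
  `r_g` inherits this on both sides of the ratio.
* `r_g > 1` has no finite-sample error guarantee; its null rate depends on
  the dependence structure among pair p-values and is estimated by
  simulation only.
* The audit detects batch structure; it does not correct it. Location/scale
  adjustment of the density matrix, or any recalibration of calls, is out
  of scope.
* The survival contrast takes mutation and survival tables at face value;
  no covariate adjustment or competing risks are modelled, and with
  real cohorts the carrier fractions of the two gene sets should be
  compared before reading anything into a p-value difference.
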