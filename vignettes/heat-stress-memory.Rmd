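---
title: "Heat-stress transcriptional memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-stress transcriptional memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmem)
```

## The experimental design and the questions it asks

A priming/triggering experiment samples plants in up to four treatment
states: untreated (**N**), immediately after a triggering heat treatment
(**T**), two days after a priming treatment (**P**), and primed then
triggered (**PT**), across a wild type and mutant genotypes, with three
biological replicates per genotype × treatment cell. Two questions drive
the analysis:

1. **Which genes carry transcriptional memory?** *Type I* genes keep
   responding after the stress is over (significant in both T/N and P/N,
   same direction). *Type II* genes respond more strongly to the second
   stimulus than the first (significant in both PT/N and PT/T, same
   direction), subdivided into `+/++` (also responsive after a single
   treatment) and `0/+` (responsive only after two), with negative mirrors
   `-/--` and `0/-`.
2. **Do the candidate regulators act gene-by-gene or globally?** If a
   transcription factor works as an *amplifier*, its mutants should show a
   coherent shift of the whole response distribution rather than the loss
   of a specific gene set. This is tested by comparing per-genotype ECDFs
   of a log2 ratio over a fixed gene set with two-sample
   Kolmogorov–Smirnov tests, summarised as a compact letter display.

## The NB differential-expression core

The engine is a deliberately transparent simplified negative-binomial
pipeline; numerical identity with full production DE engines is not a
goal, and none of their extras (independent filtering, outlier
replacement, fold-change shrinkage, multi-factor GLMs) is implemented.

**Normalization.** Median-of-ratios size factors: for sample *j*,
`sf_j = median_g counts_gj / geomean_g`, over reference genes with no zero
count. Factors are not re-centred, so they are meaningful up to a common
scale; all downstream statistics depend only on factor ratios (a common
rescaling shifts the fitted intercept and nothing else). Scaling one
sample's counts by *c* multiplies its factor *relative to every other
sample* by exactly *c*; the raw factors themselves change by
*c*^((n−1)/n) because the scaled sample also moves every gene's geometric
mean — a property worth knowing when comparing factors across runs.

**Dispersion.** Per gene, a pooled within-cell method-of-moments estimate
on normalized counts, `alpha_hat = max((s2 − mu)/mu^2, alpha_floor)` with
`alpha_floor = 1e-8`, pooling means and variances over design cells with
at least two replicates. A trend `alpha(mu) = a1/mu + a0` is fit by least
squares on genes whose estimate exceeds the floor, and the final value is
the log-space compromise `exp(0.5 log alpha_hat + 0.5 log alpha_trend)`.
One numerical choice matters at three replicates: roughly half of all
truly NB genes will, by chance, show a sample variance at or below their
mean, clamping the method-of-moments estimate at the floor. Averaging the
floor (an arbitrary tiny constant) with the trend in log space would
assign those genes near-Poisson confidence and make the Wald test sharply
anti-conservative. Clamped genes therefore take the trend value directly:
when the gene-wise estimate carries no signal, shrinkage goes all the way
to the trend. With this rule the all-null rejection rate of the Wald test
at p < 0.05 sits inside [0.03, 0.08] at three replicates (the residual
anti-conservativeness of small-sample Wald tests is expected and
tolerated). Dispersions are estimated once per genotype across its design
cells, so all contrasts within a genotype share one fit.

**Testing.** Each contrast (T/N, P/N, PT/N, PT/T) is a two-group NB GLM
with log link and log size-factor offsets, fit by iteratively reweighted
least squares at fixed gene-wise dispersion; the fit is vectorised across
genes (closed-form 2×2 weighted solves), capped at 50 iterations with
convergence declared when the relative deviance change drops below 1e-8
(an absolute 1e-8 on deviances of order 10–100 is below the float
resolution of the update path, hence the relative form). Linear
predictors are capped at ±30 and coefficients at ±60 to keep
one-group-all-zero genes finite; genes with zero counts in both groups,
or non-converged fits, are reported with missing statistics and excluded
from BH. Wald p values are two-sided normal; BH is applied within each
(genotype, contrast) table separately — the conventional reading when the
correction family is not stated — with missing values ignored and
propagated.

## Memory typing and dependence calls

Typing applies the global DE thresholds (|log2FC| > 1, p_adj < 0.05 by
default) to the relevant contrasts; a gene with any required statistic
missing is *unclassifiable*, a state deliberately distinct from *none* so
upstream filtering can never silently create negatives. Type I and type
II flags are assigned independently (no precedence is defined between
them; a gene may carry both).

Raising the fold-change threshold or lowering alpha is monotone at the
level of the union classes (positive type II, negative type II, type I
positive/negative): no gene ever *enters* a union class under tighter
thresholds. At sub-class level this is lawfully non-monotone — a `+/++`
gene whose T/N fold change falls below a raised threshold moves to
`0/+` — which is why the package's monotonicity guarantees are stated for
the unions.

A wild-type memory call is *lost* in a mutant when at least one positive
criterion defining the call's class fails in the mutant at identical
thresholds: PT/N and PT/T (plus T/N for `+/++`) for type II, T/N and P/N
for type I. The "not responsive after one treatment" clause of `0/+` is
treated as classificatory rather than as a memory criterion, so a mutant
that *acquires* a single-treatment response is not scored as having lost
memory — loss means losing the enhanced re-induction, not changing
sub-class.

## Distribution-shift statistics

Two-sample KS tests use the exact distribution whenever n·m ≤ 10 000
(this cutoff balances runtime against accuracy; the exact branch handles
ties) and the asymptotic Kolmogorov formula otherwise; tests are
two-sided. No multiplicity correction is applied across the pairwise
tests by default, since the convention in this setting is to report raw
pairwise KS p values; a Holm option exists for users who want it.

The compact letter display uses the standard insert-and-absorb algorithm
over the non-significance relation, which guarantees its defining
invariant exactly: two groups share a letter if and only if their
pairwise test is non-significant. Letters are assigned in order of
descending group median, with ties broken lexicographically by group
label, so output is stable across runs. The invariant is re-checked
programmatically (`cld_check()`) in the test suite on randomised
significance patterns.

EASE scores are one-sided hypergeometric upper tails computed after
removing one gene from the overlap cell (k ≤ 1 gives p = 1); they are
never smaller than the classical one-sided Fisher p for the same table.
Enrichment uses the full supplied background as the universe, with terms
tested only when they have at least one hit in the gene set, and BH
across tested terms. Ortholog overlaps project the second set through a
strictly one-to-one map and test the observed overlap against the
hypergeometric tail with the mapped pairs as universe — a statistic added
on top of the raw overlap count, clearly labelled as such in the output.

## Reference genes and comparative Ct

Four stability measures run on a shared Cq matrix restricted to samples
with complete measurements:

- **geNorm M**: mean SD of pairwise Cq differences (equivalently log2
  expression ratios) with all partners. Invariant to per-sample constants
  (global efficiency drift cancels in ratios).
- **NormFinder-style**: SD (or, with condition groups, the square root of
  the between-group variance component plus pooled within-group variance)
  of two-way centred log2 expression. The original tool's bias-correction
  covariance terms are omitted; ordering behaviour, not published values,
  is the contract. The sample-centring step is what makes the measure
  invariant to per-sample constants.
- **BestKeeper SD**: raw Cq spread per gene (the tool's correlation step
  is omitted). Invariant to per-gene constants only — by design it *does*
  react to sample-wide drift.
- **Comparative ΔCt**: mean SD of pairwise Cq differences — numerically
  identical to geNorm M on a complete table, retained as a separate entry
  because aggregate rankings conventionally include it.

The RefFinder-style aggregate is the geometric mean of per-method ranks
(ties by average rank). Comparative-Ct quantification normalizes the
target against the arithmetic mean of the reference genes' Cq values
(equivalent to the geometric mean of reference expressions, the standard
convention when the averaging rule is unstated) and assumes amplification
efficiency 2.0 exactly; the control condition's fold change is 1 on means
by construction.

## What the synthetic-data generator does and does not emulate

`sim_config()` encodes the study conditions: three replicates per cell,
treatments N/T/P/PT (or the reduced N/T/PT design), a wild type plus
mutants whose heat-responsive log2 effects are all multiplied by an
attenuation factor γ ∈ (0, 1] — the amplifier model in generative form.
Defaults: type II effects e_T = 2 and δ = 2, plain heat-response effects
of 3 log2 units, lognormal baselines (meanlog 5, sdlog 1.5 on the natural
scale, i.e. median ≈ 150 counts), dispersion trend α(μ) = 2/μ + 0.01, and
median-centred lognormal library depths with log-scale SD 0.1 — values a
desk-scale RNA-seq simulation would conventionally use. Counts are
gamma–Poisson (NB) with dispersion evaluated from the same trend family
the DE core fits, so parameter recovery is well-posed. Archetypes are
apportioned by deterministic largest-remainder rounding; one root seed
feeds fixed, labelled substreams per generator, so adding a generator
never perturbs another's stream.

The generator does **not** emulate: read-level structure (no FASTQ, no
mapping ambiguity), sample-level batch or outlier effects, correlated
genes or co-regulated modules, isoforms or UMIs, or dispersion outliers
off the trend. Passing recovery tests therefore demonstrates that the
pipeline's inference is correct *under its own model assumptions*; it
does not certify behaviour on real data with batch structure or heavy
dispersion outliers, where a production engine's robustness machinery
matters.

The Cq generator plants unstable genes in magnitude-matched +/− pairs so
sample means stay balanced — otherwise the sample-centring step of the
NormFinder measure would bleed the planted condition shifts into the
stable genes. This mirrors a realistic mix of up- and down-regulated
unstable candidates. The growth generator uses linear elongation within
each measurement window with lognormal rate noise; it does not model
growth curvature or measurement error in the imaging itself.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
type II recovery on five 2000-gene wild-type simulations (60 planted
genes per type II class), null calibration on all-constitutive 2000-gene
genomes, amplifier detection on a 500-gene planted up-set inside a
2500-gene genome (γ = 0.6 against a γ = 1 null) — a set large enough for
the KS test to resolve the planted shift while keeping the
median-of-ratios assumption (majority non-DE genes) valid — and
reference-gene recovery on 4 + 4 planted candidates over 12 samples at
0.1 cycles of technical noise. These sizes were chosen as the smallest at
which the planted effects are comfortably resolvable; all are adjustable
through the generator configuration.

## Known limitations

- The Wald test is mildly anti-conservative at three replicates, as
  expected without t-type corrections; adjusted-p thresholds inherit
  this.
- Per-contrast two-group fits discard information a factorial GLM would
  share across cells; interaction questions (genotype × treatment) must
  be asked through the dependence calls, not through a single model.
- The hypergeometric overlap and enrichment tests condition on set sizes
  and ignore any correlation structure among genes.
- GO annotations are taken as given; no ontology-graph propagation is
  performed.
- qPCR efficiency is fixed at 2.0; standard-curve efficiency correction
  is out of scope.
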