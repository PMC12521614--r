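---
title: "Methods: scoring substitution sensitivity in site-saturation scans"
author: "rheoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring substitution sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoscan)
```

## Overview

rheoscan analyzes site-saturation substitution scans: datasets in which
one protein position is substituted with all (up to) 19 alternative
amino acids and every variant is measured in one or more cellular
assays. The motivating system is a membrane transporter assayed for
substrate uptake (multiple substrates) and for the amount of protein at
the cell surface; the methods apply to any scan with a wild-type
reference, a background control, and replicate measurements.

The pipeline has four stages, each usable on its own:

1. **normalize** raw wells to percent of wild type with per-batch
   background subtraction;
2. **correct** transport for surface expression with propagated
   uncertainty, excluding substitutions whose expression is
   undetectable;
3. **score** each (position, assay) with histogram-based RheoScale
   scores and classify it as neutral, toggle, rheostat or moderate
   rheostat;
4. **correlate** substitution outcomes with residue property scales,
   across substrates, with evolutionary conservation, and against
   variant-effect predictor bands.

## Normalization model

A *batch* is a set of wells measured together (a plate, or a blot for
surface expression) containing empty-vector (EV) wells, wild-type (WT)
wells, and variant wells. Assumptions: raw signals are already
normalized per well to total protein; the EV mean estimates a common
additive background for the batch; the WT mean defines the batch's
scale.

For each batch, `netUptake()` subtracts the EV mean from every well and
`percentOfWT()` scales nets so the batch WT net mean is exactly 100.
Per-well percentages are pooled *across* batches only after this
scaling (`normalizeUptakeWells()`), which makes results invariant to
any positive rescaling of a batch's raw signals — a property the test
suite checks exactly. Surface-expression lanes are referenced to the
mean of the same blot's WT lanes (conventionally two).

Below-background wells (net < 0) occur at the dead floor whenever the
background is jittered. Negative values are *retained and flagged*
through percent-of-WT — they are evidence about the noise floor — and
clamped to the dead value only at the moment of histogram binning. A
variant with no detectable band on any blot is encoded as surface mean
0 with SD 0 and `n` = number of blots.

## Expression-corrected transport

Cellular uptake conflates expression and per-molecule transport.
Corrected transport is `t = 100·u/s` with `u` (uptake) and `s` (surface
expression) in percent of WT. The SD is propagated to first order
(delta method) treating the assays as independent, which they are —
uptake and blot quantification come from separate experiments:

$$\mathrm{sd}(t) = \frac{100}{s}\sqrt{\mathrm{sd}_u^2 +
  (u/s)^2\,\mathrm{sd}_s^2}$$

This equals $t\sqrt{(\mathrm{sd}_u/u)^2 + (\mathrm{sd}_s/s)^2}$ for
nonzero uptake but remains defined at $u = 0$. Wild type corrects to
exactly 100, and correcting any zero-error measurement by itself gives
exactly 100 (a tested identity).

**Exclusion filter.** A substitution whose surface expression is below
1% of wild type (strict `<`, configurable via
`exclusion_threshold`) has no interpretable transport phenotype: the
numerator measures background. Such substitutions are excluded from
uptake and corrected-transport scoring but *count as dead* in the
surface-expression histogram, where the absence of protein is itself
the phenotype. Division by a vanishing `s` is unreachable once the
filter has run; `correctForExpression()` therefore applies it first.

## RheoScale scoring

For one (position, assay), the substitution means are binned into a
histogram whose domain runs from the dead value (0) to
`max(observed values, 100)`:

- anchoring at the dead value gives the dead bin a fixed, interpretable
  meaning;
- extending to the observed maximum lets enhanced (>WT) substitutions
  populate bins beyond wild type, which real scans show at many
  positions.

Bins are half-open `[a, b)` with the last bin closed (so the maximum
and a WT value at the domain edge bin deterministically). The
**rheostat score** is the number of distinct populated bins divided by
the total bin count; the WT and dead bins count in both numerator and
denominator, so a position whose substitutions sample every outcome
scores exactly 1. The default bin count is 10; scores are also swept
over 5–11 bins, and a classification is reported as *stable* when the
label is identical at every count in the sweep.

### The neutral test

A substitution is counted as neutral when it is statistically
indistinguishable from wild type. Two criteria are combined:

1. its mean falls in the histogram bin containing the WT value, or
2. when replicate SDs are available, its mean lies within a two-sample
   z window of the WT mean:
   $|\bar{x} - 100| \le z\sqrt{\mathrm{sd}^2/n +
   \mathrm{sd}_{wt}^2/n_{wt}}$ with $z = 1.96$ (95% two-sided).

The purely positional rule (criterion 1 alone) is not robust for
percent-of-WT data: the WT reference is itself estimated from a few
wells per batch, so reference noise shifts the entire variant cloud
*jointly* while the WT value stays pinned at 100. With a realistic
3-batch × 3-replicate design at 10% replicate CV, that joint drift
regularly moves a genuinely neutral cloud out of the WT bin (and, when
an enhanced value stretches the domain, the bin containing 100 can
stop containing the cloud entirely). The z window is the standard
two-sample equivalence criterion for comparing two means — the same
logic as the ANOVA/Dunnett comparisons used when such scans are tested
variant-by-variant against wild type — and it degrades gracefully: with
no SD information the test reduces to the bin rule. Simulated neutral
scans under the design above are recovered >95% of the time with the
window and only ~75% without it; no other archetype is affected. A
value counted as neutral is not simultaneously counted as toggle, which
keeps `neutral_fraction + toggle_fraction ≤ 1`.

### Classification

Labels are assigned with a fixed precedence so that pathological
overlaps resolve deterministically:

1. **neutral** if `neutral_fraction ≥ 0.70`;
2. else **toggle** if `toggle_fraction ≥ 2/3`;
3. else **rheostat** if `rheostat_score ≥ 0.5`;
4. else **moderate rheostat**.

The thresholds (70%, two-thirds, 0.5) are the conventions of the
RheoScale literature and are configurable. Neutral is tested first
because a position where most substitutions look like wild type should
never be labelled by the spread of its few outliers; toggle precedes
rheostat because a dead majority is a stronger statement than range
coverage.

Rules for special cases: the WT self-record is displayed but never
counted among the substitutions; means (not replicate draws) are
binned and replicate SDs enter only the neutral test; a channel whose
substitutions are all excluded is reported as not scorable rather than
given a label; a degenerate domain (all values dead and WT at the dead
value) is an error.

## Correlation analyses

All coefficients come from `stats::cor.test`. Spearman is used for
property scales, substrate concordance and the expression/transport
trade-off (rank-based claims); Pearson for summed sensitivity versus
conservation (a linear trend claim on 4+ points). p-values are
two-sided; for Spearman the asymptotic approximation is the default,
which is adequate at the n ≈ 14–19 of a scan (an exact option exists
for tiny n). Pairs are dropped listwise when a variant is excluded or a
scale omits a residue, and the number dropped is reported. Results with
fewer than 3 pairs or zero variance are flagged not computable rather
than returned as numbers.

Per-position *summed* sensitivities add each parameter's rheostat score
(or each parameter's average substitution outcome). Average outcomes
follow the same exclusion rules as scoring: undetectable-expression
variants count 0 for surface expression and are omitted from transport
parameters. This treatment of non-expressed variants is a package
decision — counting absent protein as zero expression is measurement,
while inventing a transport value for it would not be.

The predictor banding comparison takes a table of predictor scores in
[0, 1] with published category cutoffs (defaults 0.34 / 0.564, the
AlphaMissense class boundaries). The measured "benign" band defaults to
the WT mean ± SD; a likely-benign prediction is concordant only when
the measurement falls inside that range, a likely-pathogenic prediction
only when it falls below it, and ambiguous predictions are excluded
from the discordance denominator.

Property scales ship as editable two-column files (a synthetic example
is in `inst/extdata/`); the package deliberately hard-codes no
literature values, so analyses name their scale and its provenance.

## Synthetic-data generator

`generatePositionScan()` emulates the statistical structure of a real
scan — not transporter biophysics. Per archetype the *true* means are:
neutral, all exactly 100; toggle, 13 of 19 at the dead floor and the
rest spread over 20–120; rheostat, evenly spread over 0–120 (including
>WT); moderate rheostat, confined to 30–49 (under half the range at
every bin count from 5 to 11). Replicate noise is multiplicative
log-normal parameterized by a CV — uptake signals are positive and
heteroscedastic — applied per well on the raw-signal scale, with EV
background wells (background 50, WT net signal 1000, arbitrary units)
so that the background-subtraction and percent-of-WT paths run end to
end and below-background wells occur at the dead floor. Surface blots
carry two WT lanes each. Defaults are 3 replicates × 3 batches at CV
0.10, the design and noise level of a typical radioligand-uptake study.
Dropout substitutions get intensity 0 on every blot; expression can be
independent of transport, correlated with it, or anti-correlated
(trade-off). Everything is seeded: a fixed spec reproduces byte-identical
tables.

What the generator does *not* emulate: batch-specific systematic
shifts beyond the shared WT/EV reference, plate-position effects,
heavy-tailed blot quantification error, and any mechanistic coupling
between substrate identity and substitution (substrates share the
transport profile unless profiles are supplied explicitly). Passing
recovery tests therefore shows that the pipeline's inference is correct
under its stated noise model, not that any particular laboratory's
error structure is benign.

Ground truth is kept beside each emitted scan, with the *intended*
label per assay computed by scoring the noise-free truth itself — so
recovery tests compare like with like even when dropouts change the
scorable set.

## Numerical and reproducibility choices

- Bin assignment is `floor((v - lo)/width) + 1`, capped at the last
  bin; values below the dead value are clamped to it at binning time
  only.
- CSV writers emit numerics with `%.17g`, so write-then-read round
  trips reproduce doubles bit for bit (a tested contract).
- The pipeline writes no timestamps; rerunning an identical
  configuration reproduces every output byte-identically.
- Substrate labels are free-form and compared case-insensitively;
  duplicate (position, substitution, assay) rows are parse errors with
  line numbers.
- Test problem sizes: archetype recovery uses 200 seeded scans per
  archetype at CV 0.10 (the generator's default design); oracle
  equivalence for the correlation machinery uses 1,000 random
  instances; the remaining properties use 25–200 seeded cases each.
  These sizes give the recovery fraction a standard error of about
  1% while keeping the default suite runnable in a couple of minutes.

## Known limitations

- The neutral equivalence window assumes approximately normal,
  independent replicate means; with n = 3 replicates the z criterion
  is anti-conservative relative to a t criterion (a deliberate choice:
  the window exists to absorb shared reference drift, not to be a
  hypothesis test).
- The rheostat score depends on the observed maximum through the
  histogram domain; a single extreme enhanced outcome widens every bin.
  The bin-count sweep flags, but does not remove, this sensitivity.
- Summed sensitivities weight all parameters equally; nothing
  calibrates transport against expression.
- With four positions, the conservation correlation has n = 4; its
  p-value is reported but carries little power, and the analyses
  scale to more positions without modification.
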