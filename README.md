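# rheoscan

Rheostat, toggle and neutral classification for site-saturation
mutagenesis scans.

## The problem

In a site-saturation scan, one protein position is replaced by all 19
alternative amino acids and every variant is assayed for one or more
cellular phenotypes — here, substrate uptake by a membrane transporter
(e.g., the bile-acid transporter NTCP with taurocholate,
estrone-3-sulfate and rosuvastatin as substrates) and the amount of
transporter at the cell surface. The scientific question is what *kind*
of position was scanned:

- **neutral** — most substitutions are statistically equivalent to wild
  type;
- **toggle** — most substitutions abolish function or expression
  (all-or-none);
- **rheostat** — substitutions produce a continuum of outcomes spanning
  at least half of the accessible range, including enhanced (>WT)
  outcomes;
- **moderate rheostat** — mostly non-neutral outcomes confined to less
  than half of the range.

Rheostat positions are where variant-effect predictors perform worst, so
identifying them — and correlating their substitution sensitivity with
residue properties, substrate identity and evolutionary conservation —
matters for interpreting variants of unknown significance.

## What the package computes

**Normalization.** Raw wells are normalized per batch: the empty-vector
background mean is subtracted, and each well is scaled so the same-batch
wild-type mean is exactly 100%. Surface-expression blots are scaled to
the mean of the wild-type lanes on the same blot. Pooling across batches
happens only after percent-of-WT scaling.

**Expression-corrected transport.** For uptake *u* and surface
expression *s* (both % of WT), corrected transport is
`t = 100 u / s`, with first-order (delta-method) error propagation for
independent assays:

```
sd(t) = (100 / s) * sqrt(sd_u^2 + (u/s)^2 * sd_s^2)
```

Substitutions with surface expression below 1% of wild type (strict
`<`, configurable) are excluded from transport scoring — their transport
cannot be determined — but count as "dead" in the surface-expression
histogram.

**RheoScale scoring.** Substitution means are binned into a histogram
over `[0, max(values, 100)]` (default 10 bins; one bin holds the
wild-type value, one the dead value). The **rheostat score** is the
fraction of bins populated: a position sampling every possible outcome
scores 1.0. A position is **neutral** if ≥70% of substitutions are
indistinguishable from wild type (in the WT bin, or within a two-sample
z window `1.96·sqrt(sd²/n + sd_wt²/n_wt)` of the WT mean), **toggle** if
≥2/3 fall in the dead bin, **rheostat** if the score is ≥0.5, otherwise
a **moderate rheostat**. A bin-count sweep (5–11 bins) verifies that
labels do not depend on the discretization.

**Correlations.** Spearman correlations of outcomes with residue
property scales and between substrates (rank concordance = unchanged
substrate specificity); Pearson correlation of summed per-position
rheostat scores (and summed average outcomes) with ConSurf-style
conservation grades; expression-vs-transport trade-off checks; and a
banding comparison of measured phenotypes against AlphaMissense-style
predictor categories.

**Synthetic data.** `archetypeSpec()` / `generatePositionScan()` /
`generateStudy()` simulate complete scans — batch empty-vector and
wild-type wells, log-normal replicate noise, expression dropouts,
expression/transport coupling — with known ground truth, so the whole
pipeline is testable without experimental data.

## Worked example

`syntheticStudy()` returns a deterministic, fully synthetic four-position
bundle (documented in `?syntheticStudy`) whose structure mirrors a real
transporter scan study. Scoring the channel-buried position G102:

```r
library(rheoscan)
study <- syntheticStudy()
scan <- correctForExpression(study$scans$G102)
scan
#> PositionScan: position 102 (wild type G)
#>   19 substitution(s) [5 excluded], 7 assay channel(s):
#>    - cellular_uptake:TCA
#>    ...
scoreScan(scan)[, c("kind", "substrate", "rheostat_score", "label")]
#>                  kind    substrate rheostat_score    label
#> 1     cellular_uptake          TCA            1.0 rheostat
#> 2     cellular_uptake          E3S            0.9 rheostat
#> 3     cellular_uptake rosuvastatin            0.8 rheostat
#> 4  surface_expression         <NA>            1.0 rheostat
#> 5 corrected_transport          TCA            0.7 rheostat
#> 6 corrected_transport          E3S            0.7 rheostat
#> 7 corrected_transport rosuvastatin            0.7 rheostat
```

The five substitutions with undetectable surface expression
(`excludedSubstitutions(scan)` → I, K, L, R, V) are omitted from the
transport channels (`n_used = 14`) but scored as dead for surface
expression. A TCA-uptake rheostat score of 1.0 means the 19
substitutions sample every bin of the accessible range — a textbook
rheostat position despite its high conservation.

The full pipeline (filter → correct → score → sweep → correlate, plus
tidy CSV outputs and a run manifest) is one call:

```r
res <- runPipeline(runConfig(scan_table = "scan.csv",
                             conservation_table = "conservation.csv",
                             output_dir = "results"))
```

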