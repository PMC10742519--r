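---
title: "Genomic fabric analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic fabric analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfabric)
```

## The three descriptors

Most differential-expression analyses reduce each gene to a single number
per condition: its average expression level. This package treats a
replicated expression profile (typically a microarray experiment with
`n = 4` biological replicas per tissue condition and 1-3 redundant spots
per gene) as carrying three independent kinds of information per gene and
condition:

* **AVE** — the mean of the median-normalized expression over the
  biological replicas. Values above 1 mean the gene is expressed above the
  sample's median gene.
* **REV** — the *relative expression variability*, in percent: an interval
  estimate of the coefficient of variation across replicas and redundant
  spots. A small REV indicates a transcript whose abundance the cell keeps
  under tight homeostatic control; its inverse, `100/REV`, is used as an
  expression-control scale, and **REC** centers that scale at the
  condition's median gene.
* **COR** — the Pearson correlation of the log2 normalized expressions of
  two genes across the replicas of one condition. Significantly positive
  pairs are *synergistic*, significantly negative pairs *antagonistic*, and
  near-zero pairs (`|COR| <= 0.05`) *independent*.

The premise for REV and COR is that biological replicas — quarters of the
same point biopsy — are exchangeable instances of the same system under
slightly different local conditions, so the co-fluctuations of transcript
abundances across them reflect real regulatory coupling rather than batch
structure. That assumption, not any property of the arithmetic, is what
makes the coordination analysis biologically interpretable.

## Preprocessing

A spot whose foreground fluorescence is below twice its background in *any*
sample is removed from *all* samples, so every sample quantifies the same
probe set. Net values (`fg - bg`, floored at `1e-6` times the sample median
net so logs stay defined) are summed over a gene's redundant spots and the
sample is scaled so the median gene-level value is exactly 1. The median of
an even number of genes is the mean of the two central values. The scale is
computed once from the gene-level aggregates (no iteration); dividing by
the median *after* spot summation is the natural reading of normalizing
"to the median gene", since the median gene is defined among gene-level,
not spot-level, quantities.

## The REV estimator

With four replicas, the plain sample CV is badly downward-biased and very
noisy. REV therefore uses the mid-point of the central chi-square
confidence interval of the CV:

    REV = 1/2 * ( sqrt(r / chisq[(1-ci)/2; r]) + sqrt(r / chisq[(1+ci)/2; r]) )
          * (s / mu) * 100

pooled over all `upsilon * n` spot-level normalized values of the gene in
the condition, with `r = upsilon * n - 1` degrees of freedom and
`ci = 0.95` (consistent with the p < 0.05 conventions used everywhere
else). The correction factor is 2.15 at `r = 3` and decreases monotonically
to 1, so REV converges to the plain CV for well-replicated genes. Pooling
spot-level values (rather than aggregating spots first) is deliberate: the
estimator is parameterized by both the replica count and the spot
redundancy, and redundant spots carry real technical information. Note the
flip side: when redundant spots are near-copies of the replicate value, the
nominal degrees of freedom overstate the information content; the estimator
is honest only to the extent that spot noise is real.

## Coordination and its thresholds

Significance of a pairwise correlation uses the exact t-transform:
`t = |COR| * sqrt((m-2)/(1-COR^2))` on `m - 2` degrees of freedom, giving
the critical magnitudes 0.95 for `m = 4` paired values, 0.71 for `m = 8`,
and 0.58 for `m = 12`. By default genes are paired by replica on the
aggregated values (`m = n`), because nothing defines how to pair spots of
genes with *unequal* redundancy; the spot-paired mode (`m = upsilon * n`)
is available when all genes share one spot count, which is exactly the
regime of the lower thresholds. Ties at the threshold are significant
(the inequalities are `>=`/`<=`), the independence cut `|COR| <= 0.05` is a
fixed convention, and undefined correlations (a zero-variance profile) are
never counted as independent — independence is a positive claim about
near-zero correlation, not missingness. No multiple-testing correction is
applied across pairs; the pathway COORD score

    COORD = %SYN + %ANT - %IND

is a descriptive summary over all `choose(k, 2)` pathway pairs, not a
family-wise inference.

## Regulation calling

For a cancer-versus-reference contrast the signed fold change is
`x = AVE_c/AVE_r` (reciprocal and negated when below 1), and the gene's own
significance cut-off combines the variability of both conditions in
quadrature:

    CUT = 1 + sqrt((REV_c/100)^2 + (REV_r/100)^2)

A gene is significantly regulated when `|x| > CUT` *and* the two-tailed
Welch (unequal-variance) t-test of the replica expressions gives
`p < 0.05`. The Welch test runs on linear normalized values because the
fold change compares linear means; a log-scale test would answer a
different question. Relative to the traditional uniform `|x| > 1.5` rule
this produces both *false positives* (noisy genes whose large ratio is
within their own noise) and *false negatives* (tightly controlled genes
whose small but real change clears their low CUT); `false_hit_audit()`
tabulates both. The weighted regulation

    |WIR| = AVE_ref * (|x| - 1) * (1 - p)

keeps the graded contribution of every gene (significant or not), signed by
direction, and `WPR` averages `|WIR|` over a pathway's quantified genes.
The `(1 - p)` weight uses the two-tailed Welch p-value as-is, a choice
confirmed by reproducing published worked values to 2 decimals.

## Fabric remodeling and the gene hierarchy

Three orthogonal per-gene regulations are combined without rescaling:
expression level (WIR), expression control
(`delta_control = 100/REV_c - 100/REV_r`), and expression coordination
(`delta_cor`, the net change in absolute correlation with a gene set,
pathway-restricted when a pathway context is given and all-gene
otherwise). Their Euclidean norm is the transcriptomic distance TDI. The
axes are left unnormalized deliberately: published worked values where WIR
dominates (TDI barely above |WIR|) are only consistent with raw axes, and
rescaling would make TDI depend on the gene set analyzed.

The gene commanding height combines protection with influence:

    GCH_i = (median(REV) / REV_i) * exp(4 * mean_{j != i} COR_ij^2)

averaged over *all* quantified genes, since commanding height is a
region-wide notion. A median-variability gene with no coordination scores
exactly 1, and halving a gene's REV doubles its score at fixed
coordination. The exponential weighting makes strong coordination count
multiplicatively rather than additively, keeping the score positive and
sharply separating hub genes; its scale constant (4) reproduces the
published order of magnitude of top scores. The top-ranked gene is the
region's gene master regulator (GMR); ties (possible only on degenerate
data) break lexicographically with a warning.

## The synthetic-data generator

`gfp_simulate()` is a first-class module, not a test fixture: it generates
probe-level data with exactly the statistical structure the analysis
assumes, plus the ground truth needed for parameter-recovery tests.

* Gene means are lognormal around `baseline_mean` (default 500
  fluorescence units, log-sd 1), giving the strictly positive,
  right-skewed dynamic range typical of microarrays.
* Replicate values are `mu * exp(sigma*z - sigma^2/2)` with `sigma` set so
  the lognormal CV equals the gene's drawn CV (uniform on `cv_range`,
  default 5-50%, overridable per gene for planting).
* Correlation blocks share one latent factor per (condition, replica):
  `z = l*f + sqrt(1-l^2)*e`, planting pairwise log-scale correlation
  `l_i * l_j` — signed loadings plant antagonism.
* Redundant spots add independent lognormal technical noise at CV 5%;
  background is constant (default 20) with 10% Gaussian jitter truncated
  at zero; planted fold changes multiply (or divide) the condition mean;
  a configurable fraction of probes is forced to fail the quality filter
  in one random sample.
* Everything is reproducible from the single `seed`.

What the generator does *not* emulate: dye and spatial array artifacts,
probe-specific affinity differences, heavy-tailed outlier replicas,
condition-dependent variance, and the correlation structure of a real
13,000-gene transcriptome. Passing recovery tests on this generator
therefore demonstrates that the estimators recover the parameters of the
model they assume — it does not certify performance on real arrays, where
the filtering and normalization steps carry most of the burden.

## Validation problem sizes and expected rates

The test suite validates parameter recovery with Monte-Carlo runs at sizes
chosen to keep the whole suite fast while leaving the conclusions stable:
40-200 seeds per property, 4-150 genes per dataset, 20 genes per group for
the planted-CV ordering, and 8-9 block partners for hub recovery. Two
subtleties are worth recording:

* With `n = 4` replicas at CV 10%, the ratio of condition means around a
  planted fold of 2 has relative sd `sqrt(2) * 0.1 / 2 ~ 7%`, so a
  `[1.8, 2.2]` window captures only ~84% of runs — no estimator can do
  better, because that is the generator's own sampling noise. Recovery
  tests therefore compare the pipeline's empirical rates against rates
  derived from an independent simulation of the model itself, rather than
  against wished-for constants.
* Per-sample median normalization with *few* genes injects a common noisy
  scale into every profile, which biases correlations upward and can wash
  out planted antagonism; the effect vanishes as the gene count grows
  (real arrays have thousands). Correlation-sign recovery is therefore
  validated at 60+ genes, and antagonism additionally in the spot-paired
  mode where the threshold is lower.

## Degenerate inputs and numerical conventions

Zero-variance profiles: REV = 0 yields an infinite control, flagged and
excluded from condition medians and GCH; a zero-variance profile makes COR
undefined (flagged, counted in pair denominators as non-significant); a
Welch test between two constant equal groups returns p = 1. All output
tables are sorted and printed at 6 significant digits so reruns diff
cleanly; fixture files print 17 significant digits so they round-trip
doubles losslessly.

## A worked example

```{r example, eval = FALSE}
cfg <- gfp_sim_config(
  n_genes = 150, conditions = c("NOR", "PTA", "PTB", "CWM"),
  planted_folds = data.frame(gene = c("G0001", "G0002"),
                             condition = c("PTA", "PTB"), fold = c(3, -3)),
  correlation_blocks = list(list(genes = sprintf("G%04d", 20:24),
                                 loading = 0.98)),
  seed = 11)
sim <- gfp_simulate(cfg)
pw <- read_gmt(system.file("extdata", "excretory_pathways.gmt",
                           package = "gfabric"))
fit <- gfp(sim$probes, reference = "NOR",
           pathways = list(BLOCK = sprintf("G%04d", 20:24)))
summary(fit)
write_gfp_tables(fit, "gfp-out")
```

## Known limitations

* The correlation analysis is strictly pairwise; higher-order
  co-expression clusters are represented only through their pairwise
  shadows.
* With `n = 4` the per-pair significance threshold (0.95) is severe, so
  individual SYN/ANT calls are low-powered; pathway-level COORD summaries
  are the more stable quantity.
* REV assumes exchangeable replicas; any replicate-level batch effect
  inflates it for every gene.
* The GEO loader for the original deposited series is intentionally not
  included; any probe-level TSV in the documented schema can be analyzed.
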