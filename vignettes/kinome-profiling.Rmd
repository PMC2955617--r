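---
title: "Kinome-array profiling and inhibitor viability analysis with kinoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome-array profiling and inhibitor viability analysis with kinoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinoscope)
```

## The measurement and its model

A peptide kinome array carries short peptide substrates; kinases in a cell
lysate phosphorylate them, and the incorporated label is read out as a
per-spot intensity. The default chip design in this package has 1024
distinct substrates printed in triplicate plus 16 negative and 16 positive
control spots. Control spots are printed once each: the replicate
structure of controls is not part of the chip description we model, so we
deliberately do not invent one.

The analysis assumes:

* spot intensities are non-negative and right-skewed, with a multiplicative
  (log-scale) error structure;
* replicate spots of one substrate measure the same quantity up to
  multiplicative jitter, so a median over replicates is a robust summary;
* arrays of one experiment share an intensity distribution after
  normalization — differences in distribution are technical, differences
  in rank are biological;
* the substrate-to-kinase annotation is many-to-many and incomplete.
  A substrate annotated to several kinases is evidence for each of them;
  unannotated substrates are retained through preprocessing and top-N
  selection (dropping them early would bias the top-N composition) but
  contribute to no kinase.

## Preprocessing

Stages run in this order by default: acquisition QC, replicate QC,
background correction, median summarization, quantile normalization of the
summarized profiles. Normalizing after summarization makes the
normalization robust to spot dropouts (each array contributes one value
per surviving substrate rather than a variable number of replicates);
`preprocess_scans(..., normalize = "before_summarize")` supports the other
order for users who prefer to normalize at spot level.

* **Acquisition QC** (`min_total_hits`, default 1e6): an array whose total
  collected signal is below the minimum is excluded with a logged reason.
  The boundary is inclusive — an array at exactly the threshold passes.
* **Replicate QC** (`cv_threshold`, default 0.5; `min_replicates`,
  default 2): per substrate, the coefficient of variation of surviving
  replicates; above the threshold the replicate farthest from the median
  is ejected and the CV recomputed once. At most one replicate is ever
  ejected per substrate — repeated ejection could hollow out a triplicate
  on the basis of a statistic (the CV of two points) with almost no
  information. Substrates with fewer than `min_replicates` survivors are
  dropouts, reported as `NA`, never an error.
* **Background correction**: the mean negative-control intensity is
  subtracted from every substrate spot and results are clipped at zero.
  Clipping is why downstream log transforms use an offset (below).
* **Summarization**: the median of surviving replicates; with exactly two
  survivors the median is their mean.
* **Quantile normalization**: every array's values are replaced by the
  across-array mean of order statistics at the value's rank. Ties all
  receive the mean of the reference values at the ranks the tie group
  occupies (computed exactly, not by interpolating at the average rank —
  the two differ for ties of three or more). Missing values are imputed on
  the reference distribution at the substrate's mean empirical quantile
  across the arrays where it was observed, and flagged in the `"imputed"`
  attribute so downstream code can discount them. Normalization needs at
  least two arrays; with one it is undefined and an error.

## Kinase activity

The default flow averages the (tumour-group) profiles, selects the top
`n = 100` substrates by intensity (ties at the cut broken by lexicographic
substrate id, so selection is deterministic), and scores every annotated
kinase: `n_hits` = number of its substrates in the top list,
`mean_intensity` = their mean intensity. A substrate annotated to several
kinases contributes fully to each, which is why the report can contain
adjacent rows with identical intensities.

Two orderings are exposed, on purpose:

* `score_kinases()` sorts by `mean_intensity` (ties by `n_hits`, then
  kinase id) — the conventional report shape for this assay.
* `call_active_kinases()` ranks by total attributable top-substrate
  signal, `n_hits × mean_intensity`. This is the ordering used to *call*
  active kinases (and to feed pathway enrichment) because mean intensity
  alone is not identifiable under a many-to-many annotation: a kinase that
  shares a single strongly phosphorylated substrate with a truly active
  kinase inherits that substrate's full intensity as a one-hit entry, and
  such aliased one-hit kinases outrank genuinely active multi-substrate
  kinases about half the time regardless of noise level (the shared spot
  is one draw from the same distribution whose mean the true kinase's rank
  rests on). Summing over hits restores identifiability: sustained
  activity across several substrates dominates any single shared spot.
  This mirrors how practitioners actually read such tables — frequency
  and intensity together.

`filter_kinases()` reruns the ranking excluding whole categories (e.g.
`cell_cycle`, whose members can be artificially upregulated by culturing),
and `kinase_hit_frequency()` provides the per-sample mode: top-N within
each sample, then cross-sample hit frequency.

## Differential specificity

Tumour-versus-control specificity per substrate uses a moderated t on
log2(x + 1) intensities (the offset 1 tolerates background-corrected
zeros). The per-substrate pooled variance is shrunk toward a prior,
`(d0*s0_sq + df*s2)/(d0 + df)`, with the prior estimated by matching the
mean and variance of log sample variances to their scaled-F
digamma/trigamma moments. When the observed dispersion of log variances
does not exceed the pure sampling dispersion `trigamma(df/2)`, the moment
equation has no positive solution and `d0 = Inf` (complete shrinkage); in
the exactly degenerate case of zero dispersion the prior variance is the
common observed value itself, with no moment-bias correction, since there
is no sampling scatter to correct for. `d0 = 0` reproduces the ordinary
pooled t exactly, a limit the tests pin to 1e-10. P-values use
`df + d0` degrees of freedom and are BH-adjusted; `tumor_specific()`
applies a configurable (default q < 0.05, not a fixed constant of the
method) up-regulation filter.

The groups must each have at least two samples — with one sample a
within-group variance does not exist, and the method refuses rather than
guesses.

## Pathway over-representation

Pathways are ranked by the upper-tail hypergeometric probability of their
overlap with the active set, BH-adjusted, ties broken by larger overlap
then pathway id. This is a deliberately transparent substitute for
proprietary literature-based pathway scores: every number it produces can
be re-derived by enumeration, which the test suite does exactly for all
universes up to 15 kinases. An empty active set returns p = 1 for every
pathway (with a warning) rather than an error, so pipelines degrade
gracefully.

## Viability analysis

Plate normalization maps absorbances to fraction-of-vehicle viability,
`(A - mean blank)/(mean vehicle - mean blank)`, preserving replicates.
Wells darker than the blank give negative viabilities that are retained
(with a warning): clipping them would bias the lower asymptote of the fit
upward.

The dose-response model is the four-parameter logistic
`v(c) = lower + (upper - lower)/(1 + (c/ec50)^hill)`, fitted by bounded
least squares (`lower` in [0, 1], `upper` in [0.5, 1.5], `ec50` within
[min dose/10, max dose×10], `hill` in (0, 10]) with L-BFGS-B from three
deterministic starts (EC50 at the geometric-mean dose, at the dose nearest
the half-response level, and at the median dose with a steeper slope).
A 24-start comparison over simulated plates never improved the residual
sum of squares, so three starts suffice for these 6-dose designs; on
optimizer failure the best-effort parameters are returned with
`converged = FALSE`.

The IC50 is *absolute*: the concentration where fitted viability equals
0.5, solved in closed form, and censored as **not reached** when the curve
never attains 0.5 within the tested dose range — in particular whenever
the viability floor is at or above 50%. The absolute definition is the
only one under which "a drug decreased viability by at most 40%, so no
IC50 could be computed" is coherent; a relative EC50 always exists and
would mislead here.

Combination experiments are summarized by the Bliss excess,
`v_A × v_B − v_combo`, per dose of drug A at a fixed dose of drug B, with
an enhancement flag when the excess exceeds `excess_threshold`
(default 0.1) at `min_doses` (default 2) or more doses. The output is
labelled *enhancement (Bliss excess)* and never "synergy": a synergy
claim (e.g. a combination index) requires monotherapy IC50s for both
drugs, which a floor above 50% makes unobtainable for one of them.
Schedule metadata (such as one drug preceding the other by 30 minutes) is
recorded in the result but does not alter the computation.

## The synthetic-data generator

The generator exists so that every stage has an input with known ground
truth. It emulates:

* a chip of `n_substrates = 1024` substrates in triplicate with 16 + 16
  controls;
* a many-to-many annotation: each of `n_kinases = 120` kinases gets
  `substrates_per_kinase = 8` substrates, a fraction
  `multi_map_rate = 0.2` of assignments reusing substrates already claimed
  by another kinase; about `cell_cycle_fraction = 0.27` of kinases are
  tagged `cell_cycle`; a pathway catalog of random kinase subsets plus an
  optional planted pathway covering chosen kinases;
* log-normal background spot intensities, `meanlog = log(500)` (arbitrary
  intensity units) and `sdlog = 0.5` (geometric CV ≈ 53%, moderate
  spot-to-spot heterogeneity), redrawn per sample; substrates of active
  kinases have expected intensity multiplied by `boost = 3`. The effect is
  multiplicative because array intensities are positive and right-skewed,
  and a multiplicative boost survives quantile normalization as a rank
  shift;
* triplicate jitter at `replicate_cv = 0.1`, spot dropout at
  `dropout_rate = 0.01`; positive and negative controls at the 99th and
  1st percentile of the background, extremes chosen to make QC tests
  unambiguous;
* a cohort of 6 tumour-like samples sharing one planted active set and 2
  control-like samples under a different planted set;
* viability plates with blank and vehicle wells, additive viability noise
  (`noise_sd = 0.02`), and quadruplicate wells per condition on the two
  packaged 6-dose grids (50–5000 nM and 10–500 µM). Two curve presets
  mirror the study drugs: a TBB-like curve (floor 0.25 reached inside the
  grid, `ec50 = 100` µM, `hill = 2` — a full response attained by the
  second-highest dose) and a dasatinib-like curve (floor 0.60,
  `ec50 = 200` nM, `hill = 1.5`), whose absolute IC50 is never reached.

None of the noise magnitudes are estimates of a particular chip
technology; they are fixtures chosen once as plausible. The generator has
no spatial artifacts (scratches, gradients, print-tip effects), no image
model, and its background is exchangeable across substrates — so passing
recovery tests demonstrates the statistical machinery, not robustness to
structured artifacts in real scans. The simulation sizes used by the test
suite and the acceptance script (100 cohorts of 6 arrays; 200 simulated
plates) were chosen to keep Monte-Carlo error comfortably below the
margins being tested.

## Numerical choices and degenerate inputs

* Quantile-normalization tie blocks are averaged by direct indexing, not
  via cumulative sums, so agreement with a naive oracle is exact to
  floating-point.
* `trigamma_inverse()` uses Newton iteration on `1/trigamma` with
  asymptotic branches for extreme arguments.
* Rankings break ties deterministically (by id) everywhere, so identical
  inputs give byte-identical outputs under a fixed seed.
* All-zero variances, empty active sets, plates with vehicle ≤ blank,
  fits with fewer than four doses, and single-array normalization each
  fail (or warn) with a named reason rather than propagating nonsense.

## Known limitations

* The substrate→kinase and kinase→pathway tables are user-supplied or
  simulated; the package ships no reconstruction of any vendor's
  annotation, and pathway results inherit whatever biases the supplied
  catalog has.
* Hit counts are computed within the top-N list only; chip-wide hit
  counting would need a background model for annotation density that the
  assay does not provide.
* The differential module compares groups of arrays; it does not
  meta-analyse across panels from different experiments, though the same
  contrast serves when users supply such panels as groups.
* Enhancement is reported per dose against the Bliss reference; no
  combination-index or isobologram analysis is attempted.
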