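---
title: "Screening CpG-island hypermethylation-silenced tumor-suppressor candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CpG-island hypermethylation-silenced tumor-suppressor candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgiscreen)
```

## The problem and the model

Aberrant promoter CpG-island (CGI) hypermethylation is a common route to
tumor-suppressor gene (TSG) inactivation in epithelial cancers, including
lung adenocarcinoma. Given Infinium-style methylation arrays on a cohort of
patient-matched tumor/normal tissue pairs, the question is: which CGIs are
consistently hypermethylated in tumors, and which of the genes they control
show the expression behavior of a methylation-silenced TSG?

`cgiscreen` implements that analysis in two coupled stages plus validation
helpers.

**Stage 1 — region-level differential methylation.** Each array probe
reports a beta-value

$$\beta = \frac{I_\mathrm{meth}}{I_\mathrm{meth} + I_\mathrm{unmeth}} \in [0, 1],$$

the fraction-methylated readout of the interrogated CpG. Probes are assigned
to CGIs by coordinate containment, and for each region $r$ and sample $s$ the
summary value is the **median** of the member-probe beta-values (robust to a
single aberrant probe; a mean and a per-probe-difference-first variant are
available as configuration switches, since the exact aggregation order is a
genuinely open choice). For each matched pair $i$ the region's
beta-difference is

$$\Delta\beta_{r,i} = \beta^{tumor}_{r,i} - \beta^{normal}_{r,i},$$

and the region effect is the mean of $\Delta\beta_{r,i}$ over pairs. The
design is paired, so the per-region test is the one-sample (paired) *t* of
the differences against zero; Welch's *t* and the rank tests are provided for
the unpaired comparisons (e.g. smoking strata). P-values are
Benjamini–Hochberg adjusted across **all tested regions as one family**
(hyper- and hypomethylated tails together — both tails share one adjusted
scale in the conventional volcano display). Regions are selected with
**strict** thresholds, adjusted $p < 0.05$ and $\Delta\beta > 0.25$
(hypermethylation direction), and ranked by adjusted $p$, ties broken by
$|\Delta\beta|$ descending, then region id, so output order is
deterministic. Two-sided p-values are used everywhere; directionality is the
job of the $\Delta\beta$ sign filter, not of one-sided testing.

**Stage 2 — the expression evidence funnel.** Genes annotated to the
top-ranked regions face four criteria, all with strict comparisons:

1. *Expressed in normal lung*: at least one normal-lung or paired-normal
   value above the detection floor (default $10^{-3}$, i.e. qRT-PCR-style
   non-detect). Genes failing this short-circuit — the other criteria are
   reported as missing, mirroring the dashes of printed evidence tables.
2. *Tumor downregulation*: tumor/paired-normal ratio $< 0.5$ (a >50%
   reduction) in at least 6 of 11 pairs. Pairs whose normal-side value is a
   non-detect leave the denominator: a ratio against zero is meaningless.
3. *Cell-line silencing*: expression $< 0.2$ of the normal-lung reference
   (a >80% reduction) in at least 8 of 14 lines.
4. *Pharmacologic restoration*: $\log_2$ fold change $> 2$ (i.e. >4-fold)
   after 5-aza-2′-deoxycytidine treatment versus vehicle in at least 2 of 3
   treated lines. The fold change is floored at the detection limit so
   non-detects cannot produce infinities.

When an observed panel is not the reference size $n_0$, the minimum count
$k_0$ rescales as $\lceil k_0 / n_0 \times n \rceil$, which reproduces
6/11, 8/14 and 2/3 exactly at the reference sizes. A candidate passes the
funnel only if it passes all four criteria; the report ranks genes by
(passes-all, number of criteria passed, tumor fraction, name).

**Validation.** Site-level percent-methylation tables (pyrosequencing-style,
0–100%) are compared pairwise per site with the paired *t* or the Wilcoxon
signed-rank test — the caller chooses by flag; normality is never
auto-tested, because no automatic criterion is universally defensible and
the choice should be visible in the analysis code. Methylation–expression
coupling is quantified by Pearson correlation, pooled across tumor and
normal samples by default (silencing separates the compartments into the
high-methylation/low-expression and low-methylation/high-expression corners,
which is what the pooled correlation measures); per-compartment correlation
is available by flag. Smoking-status stratification compares S vs NS within
one tissue compartment by Welch's *t* (or Mann–Whitney by flag).

## The synthetic cohort generator

Real discovery cohorts of this design are small (a dozen pairs) and live in
public repositories; the package instead ships a seeded generator so every
stage is testable offline, with ground-truth labels. `sim_config()` defaults
describe the emulated study conditions and are not tuning knobs:

* **12 tumor/normal pairs, split 6 smokers / 6 never-smokers** — the
  discovery design the screen targets.
* **1000 CGI regions, 3–15 probes each** — enough regions for the BH family
  to behave realistically at desk scale.
* **Baseline beta ~ Beta(3, 17)** (mean 0.15), matching the 0.1–0.2 band
  typical of unmethylated CGIs in non-tumor tissue; values are clipped to
  [0.001, 0.999] to avoid degenerate variance at the boundaries.
* **5% planted regions with true shift ~ N(0.30, 0.05²)** — the effect
  regime of top screen hits ($\Delta\beta$ 0.25–0.37); per-probe,
  per-sample Gaussian noise with sd 0.03.
* **Expression coupling**: genes of planted regions are silenced — the
  tumor/normal ratio falls below 0.5 with probability 0.9 per pair; each of
  14 cell lines falls below 0.2 of normal lung with probability 0.75 (mean
  10.5/14 silenced lines, chosen so that a planted gene clears the 8-of-14
  criterion in ≥95% of cohorts — the only calibration near "about 10 of 14"
  that does); 3 treated lines re-express with fold changes drawn uniformly
  from 5–50×, all clearing the 4× bar. Non-planted genes follow a null model
  with ratios centered at 1. With `coupling = FALSE` every gene follows the
  null model, decoupling expression from the methylation truth.
* **Validation panel**: 46 pairs split 25 S / 21 NS, one hypermethylated
  site tied to the first planted gene and one stable null site; smoking
  status has **no** effect by construction, which is the null the
  stratified comparison should (and does) report.

All random streams derive from one master seed (stream $k$ uses
$((\mathrm{seed} + 1000003k) \bmod (2^{31}-2)) + 1$), so the methylation
cohort, expression panels and site panel can be regenerated independently
and reproducibly.

What the generator deliberately does **not** emulate: Infinium I/II probe
chemistry and normalization artifacts, batch effects, cell-type composition,
copy-number confounding, or correlated probe noise within a region. Passing
tests therefore demonstrate that the statistics and the funnel logic are
correct and calibrated under the stated model — not that any particular
real cohort is free of those upstream effects. Raw IDAT processing and
array normalization are out of scope; inputs are assumed-normalized
beta-values.

## What recovery means here

With the generator's true effects drawn from N(0.30, 0.05²) and the strict
$\Delta\beta > 0.25$ filter, about $\Phi(1) \approx 16\%$ of planted regions
have a *true* effect below the screening threshold; the estimator noise on a
12-pair mean is only ≈0.005, so those regions are essentially undiscoverable
by a screen defined with that filter, by design. Recovery statistics are
therefore reported **conditional on discoverable plantings** (true
$\Delta\beta > 0.25$); the unconditional value (≈0.84 in expectation) is
reported alongside for transparency. The false-discovery proportion counts
selected regions that were never planted, regardless of effect size.

## Numerical choices and degenerate inputs

* Strict inequalities at every threshold, matching the screening rule's
  wording; boundary cases (ratio exactly 0.5 or 0.2, fold change exactly 4,
  $\Delta\beta$ exactly 0.25, adjusted $p$ exactly 0.05) fail and are
  pinned by tests.
* A region whose differences are all zero has no variance and no effect and
  is excluded from testing (with a warning, never silently); zero variance
  with a nonzero mean is reported with $p = 0$ and flagged degenerate.
* Regions with fewer than `min_pairs` (default 3) complete pairs are
  excluded — a paired *t* below that is meaningless.
* Missing beta-values propagate: a (region, sample) summary uses the
  non-missing member probes and is itself missing below `min_probes`.
* Rank tests use exact small-sample null distributions (n ≤ 25, no ties)
  and the normal approximation beyond.
* Exact zeros in expression are legal; every ratio or fold change is floored
  at `detect_floor` before logs.
* Coordinates are stored 0-based half-open (BED interoperability); every
  user-facing region string is rendered 1-based inclusive
  (`chr1:248020330–248021252`). The genome build of input coordinates is
  treated as opaque.

## Problem sizes

The test suite and the acceptance script run the full screen at the target
scale — 1000 regions × 12 pairs — across 20 replicate seeds per property
(null calibration, screen recovery, end-to-end recovery), which keeps each
property estimate's Monte-Carlo error small while a complete run stays in
the low minutes on one core. Smaller cohorts (30–300 regions) are used for
structural unit tests where scale adds nothing.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- simulate_methylation_cohort(cfg)
scr <- screen_regions(cohort$beta, cohort$manifest, cohort$regions,
                      cohort$design)
head(scr$top[, c("region_id", "gene", "delta_beta", "adjusted_p")])

expr <- simulate_expression_panels(cohort$truth, cfg)
report <- run_funnel(unique(scr$selected$gene), expr)
report[report$passes_all, c("gene", "tumor_k", "tumor_n", "cell_k", "restore_k")]
```

## Known limitations

* The screen takes regions as given; it does not discover differentially
  methylated regions de novo.
* No probe-type bias correction or cell-type deconvolution — those belong
  upstream of the beta matrix this package consumes.
* The evidence funnel consumes relative expression values; it performs no
  RNA-seq normalization or differential-expression modelling of its own.
* Survival analysis, gene-ontology enrichment and downstream functional
  readouts are out of scope.
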