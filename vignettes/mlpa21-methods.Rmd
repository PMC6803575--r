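---
title: "Methods: dosage-quotient CNV calling on chromosome 21"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-quotient CNV calling on chromosome 21}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpa21)
```

## The measurement and the model

MLPA (Multiplex Ligation-dependent Probe Amplification) measures relative
copy number at ~50 loci simultaneously: each probe produces a fluorescent
amplicon whose peak height is roughly proportional to the number of template
copies, times a probe-specific amplification efficiency, times the overall
PCR yield of the run. `mlpa21` works on the P327 iAMP21-ERG panel layout: 46
target probes tiling chromosome 21 from 21q11.2 to 21q22.3 (six of them on
*RUNX1*) plus reference probes on other chromosomes.

Two nuisance factors are removed in two stages:

1. **Intra-sample normalization** divides every peak by the *median*
   reference-probe peak of the same sample. This cancels the per-run yield
   exactly (the output is invariant under global rescaling of a sample's
   peaks). The median, rather than the mean, is used so a single aberrant
   reference probe cannot shift the whole profile; this choice is standard
   MLPA practice, and the exact summary the upstream software uses is not
   observable from peak tables alone.
2. **Reference comparison** divides the resulting relative ratio by the
   arithmetic mean of the same quantity across healthy reference samples
   (at least three are required; with fewer, "average" degenerates to a
   value a single outlier can dominate). This cancels the probe-specific
   efficiency, because sample and reference runs share the same physical
   probemix.

The result is the Dosage Quotient (DQ): 1.0 for a diploid locus, c/2 for
copy number c in a pure aberrant sample.

### Blast-fraction dilution

Bone-marrow samples are mixtures. If a fraction $f$ of cells are leukemic
blasts and a fraction $s$ of blasts carry the aberration, a locus at copy
number $c$ in the aberrant cells has expected DQ

$$\mathrm{DQ} = (1 - fs) + fs\,\frac{c}{2}.$$

This mixture is implemented in `expected_dq()` and is the entire mechanism
of false negatives in this assay: a trisomy ($c = 3$) at blast fraction
0.4 sits at DQ 1.2, inside the unclassified gap, and below $f \approx 0.3$
it is indistinguishable from normal. Nothing in the caller tries to undo
the dilution — MLPA is semi-quantitative and the package deliberately keeps
the published rule set rather than inventing a purity correction.

## Probe classification windows

`classify_probe()` is a pure lookup against fixed DQ windows:
normal $[0.85, 1.15]$, heterozygous deletion $[0.35, 0.65]$, homozygous
deletion $< 0.35$, heterozygous duplication $[1.35, 1.55]$, homozygous
duplication $[1.70, 2.20]$, amplification $> 2.20$. The windows are
conventionally quoted without open/closed qualifiers; here all named
windows are closed on both ends, the unnamed gaps (0.65–0.85, 1.15–1.35,
1.55–1.70) report `borderline` rather than being silently absorbed, and
ties at the two shared bounds (0.35, 2.20) resolve to the lower-severity
named category. This makes the partition of the DQ axis total and the
category severity monotone in DQ — both properties are tested by sweeping
the axis.

## Sample-level calling

The diagnostic call uses two summaries: the median DQ over all 46 probes
and the median over the six *RUNX1* probes (the median of six is the mean
of the central two). The decision ladder:

1. median *RUNX1* DQ strictly above 2.20 and the profile **not**
   uniformly elevated → `iamp21`;
2. median *RUNX1* DQ above 2.20 but uniformly elevated →
   `chr21_multiplication` with a hyperdiploidy note;
3. median DQ (all probes) ≥ 1.35 → `chr21_multiplication`;
4. median DQ within $[0.85, 1.15]$ → `no_chr21_aberration`;
5. otherwise `indeterminate` (typically the dilution gap).

iAMP21 outranks plain gain because it is the clinically overriding
diagnosis. The *median*-of-RUNX1 statistic is used (rather than any single
probe or all six) because it is the summary the corresponding clinical
reports quote and it tolerates one discordant probe on either side.

### Separating iAMP21 from hyperdiploidy

Gaining two or more whole copies of chromosome 21 at high blast fraction
pushes the *RUNX1* median past 2.20 without any focal amplification — the
known false-positive mode of the RUNX1 rule. `is_uniform_elevation()`
captures the distinguishing phenotype: a whole-chromosome gain raises
*every* probe by the same factor, whereas iAMP21 shows a megabase block
(characteristically NCAM2..RIPK4, always containing *RUNX1* and *ERG*)
between non-amplified flanks. A profile counts as uniformly elevated when
at least 90% of target probes classify as gains *and* the 90th/10th DQ
percentile ratio is below 1.5. Both numbers are package choices — the
phenomenon is described qualitatively in the clinical literature, not
parameterized — and both are exposed in `dq_thresholds()`; the defaults
comfortably separate the two regimes at the noise levels the generator
produces (a flat profile at lognormal sd 0.05 has a percentile ratio of
about 1.14).

`detect_amplified_block()` reports the longest maximal run of consecutive
probes at DQ ≥ 1.35, ties broken by higher mean DQ, with gene endpoints,
probe count, approximate span in Mbp, and whether the immediately flanking
probes classify as normal. It is validated against a brute-force
enumeration of all contiguous windows.

## Cohort statistics

Percentages are reported half-up to two decimals, matching clinical-table
style (`round_half_up()`; base R rounds half-to-even). Group summaries use
median and type-7 (linearly interpolated) quartiles. Group comparisons use
the tie-corrected Kruskal–Wallis test with pairwise two-sided Mann–Whitney
U post hocs under Holm correction. Two implementation notes:

* The nonparametric post hoc replaces the parametric Tukey HSD sometimes
  paired with rank tests in clinical reports; a rank-based omnibus test
  with a rank-based post hoc is internally consistent.
* `stats::wilcox.test()` refuses exact p-values under ties, but clinical DQ
  summaries are heavily tied. For small groups (up to 100,000 label
  assignments) the package therefore enumerates the permutation
  distribution of U directly, which is exact under ties; larger groups fall
  back to the tie-corrected normal approximation. On untied data the
  enumeration reproduces `wilcox.test(exact = TRUE)` to machine precision
  (tested).

`concordance()` reports the two error modes against FISH/karyotype truth:
false negatives among gain samples (median DQ inside the normal window) and
false positives among no-aberration samples (a duplication-range call), plus
iAMP21 sensitivity and overall expected-call accuracy. Copy-neutral
ETV6-RUNX1 fusions are *expected* to call `no_chr21_aberration`: a balanced
translocation changes no copy number and is structurally invisible to
dosage analysis, so calling it normal is counted as correct.

## The synthetic-data generator

`simulate_cohort()` generates raw peak tables with known truth. Per sample:
a truth group, a blast fraction, a per-probe copy-number vector, and

$$\text{peak}_p = I_0 \cdot e_p \cdot a \cdot
  \mathrm{DQ}_{\mathrm{exp}}(c_p, f, s) \cdot \varepsilon_p,$$

where $I_0$ is the base intensity, $e_p$ a fixed per-probe efficiency
(lognormal, log-sd 0.15, deterministic for a given panel so that sample and
reference runs share it — as they share the physical probemix — and it
cancels exactly in the DQ), $a$ a per-sample lognormal scale (sd 0.2,
cancelled by intra-sample normalization) and $\varepsilon_p$ independent
lognormal probe noise (log-sd 0.05 by default). Reference probes are always
diploid.

Default parameters mirror the cohort the rule set was characterized on:

* group proportions from the 142/56/34/3 split of 235 samples (stored as
  exact count ratios so they sum to one);
* blast percentage from a beta(7.89, 0.96) distribution rescaled to
  \[0, 100\], quantile-matched to median 92.4 with IQR 84.2–96.0 (fitted
  quantiles 84.5/92.0/96.7); the family is a package choice — blast counts
  are bounded and left-skewed;
* 1–5 extra chromosomes 21 with probabilities (0.53, 0.27, 0.11, 0.05,
  0.04), mean 1.80, maximum 5;
* iAMP21 blocks spanning NCAM2..RIPK4 with 5–12 *RUNX1* copies, uniform —
  5 is the FISH diagnostic minimum and reported cases run from 6–9 copies
  to beyond 12;
* ETV6-RUNX1 simulated copy-neutral ($c \equiv 2$ everywhere).

What the generator does **not** emulate: saturation of PCR at high copy
number (real amplified-probe ratios compress below $c/2$; simulated iAMP21
DQs are therefore higher than the 2.3–3.4 range seen in patients),
inter-probe noise correlation (independence is assumed), batch effects
between runs, degraded-DNA artefacts, and non-chromosome-21 CNVs. Passing
the recovery tests therefore shows the *rule set and plumbing* are correct
under the stated statistical model, not that the assay performs at any
particular level on real specimens.

## Numerical and design notes

* **Determinism**: every stochastic function takes a seed and restores the
  caller's RNG state; equal configuration gives bit-identical cohorts.
  Table writers emit fixed-format TSV (6 significant digits, Unix
  newlines), so outputs are stable for golden-file comparison.
* **Degenerate inputs**: a zero target peak yields DQ 0 (homozygous-deletion
  semantics) rather than an error; an all-zero reference-probe set is a
  hard normalization error; empty tables distinguish "no samples" from "no
  probes"; configuration files reject unknown keys.
* **Block ties**: equal-length candidate blocks are resolved toward the
  higher mean DQ; with all-equal profiles the whole chromosome is one
  block and the normal-flank property holds vacuously at the chromosome
  ends.
* **Panel fixture**: the packaged P327 catalogue is a synthetic
  reconstruction — the gene set and ordering follow the published panel
  description, per-gene multiplicities place six probes on *RUNX1* and five
  each on *ERG*, *DYRK1A* and *ETS2* to reach 46, and coordinates are
  approximate hg19-era megabase positions used only for ordering and span
  reporting (NCAM2..RIPK4 spans 20.87 Mbp in the fixture). Eight synthetic
  reference probes are included; commercial mixes carry on the order of
  8–13, and only a stable median is needed.
* **Problem sizes**: validation suites use 400-sample cohorts for recovery,
  200 samples per point for the nine-point dilution sweep, and 1,000 random
  profiles for the block-detection oracle — large enough that the binomial
  noise on every reported fraction is well below the margins being
  asserted, and small enough to run in seconds.

## A worked pipeline

```{r pipeline}
panel <- load_panel("P327")
cfg <- sim_config(n_samples = 100, seed = 42)
cohort <- simulate_cohort(cfg, panel)
refs <- simulate_reference_runs(10, panel, seed = 43)
dq <- peaks_to_dq(cohort$peaks, refs, panel)
calls <- classify_cohort(dq, panel)
concordance(calls, cohort$truth)
```
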