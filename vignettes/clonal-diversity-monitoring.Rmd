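---
title: "Measuring clonal diversity for insertion-site safety monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clonal diversity for insertion-site safety monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The problem

In gene therapy with integrating retro- or lentiviral vectors, every
transduced cell carries the vector at a genomic insertion site (IS), and all
descendants of that cell share it. Treating clones (cells sharing one IS) as
species turns safety monitoring into an ecology question: *richness* (how
many clones) tracks efficacy of transduction and engraftment, while
*evenness* (how uniformly abundance is spread across clones) tracks safety —
a clone expanding disproportionately is the signature of insertional
mutagenesis.

The practical difficulty is that the popular summary, the Shannon index,
confounds these two things. It grows with the number of clones a sample
happens to capture, which in turn depends on sampling effort, sequencing
technology and DNA input, so its absolute value is not comparable across
patients, time points or studies. `clonediv` implements the full index
suite used in clonal tracking, quantifies by simulation how each index
responds to sampling effort and dominance, and provides a pipeline that
converts the summaries trials actually publish — richness and Shannon —
into Pielou evenness with a fixed alert threshold.

## The index suite

For one sample with counts $y_i$, relative abundances
$p_i = y_i / \sum_j y_j$ and observed richness $S$:

* **Shannon** $H = -\sum_i p_i \log p_i$, in a stated log base
  (`shannon_index`). Confounds richness and evenness.
* **Pielou** $J = H / H_{max} = H / \log S$ (`pielou_index`). Pure evenness
  in $[0, 1]$, independent of the log base. Undefined at $S = 1$
  ($H_{max} = 0$): the package returns an `NA` sentinel that is carried
  through panels and reports, never a silent zero.
* **Simpson** $D = 1 - \sum_i p_i^2$ (`simpson_index`): one minus the
  probability that two random cells share a clone.
* **Gini** via Brown's formula on abundances ranked in increasing order,
  $G = 2\sum_i i\,y_i / (n \sum_i y_i) - (n+1)/n$ (`gini_brown`); 0 for
  equal contributions.
* **Chao1** $\hat S = S + f_1(f_1 - 1) / (2 f_2)$ (`chao1_richness`), with
  $f_1, f_2$ the singleton and doubleton counts. When $f_2 = 0$ the
  denominator uses $f_2 + 1$ — the standard bias-corrected convention,
  chosen because it avoids a division by zero while reducing to the plain
  formula whenever $f_2 > 0$.
* **UC50** (`uc50`): the smallest number of top clones jointly holding at
  least 50% of abundance. The comparison is $\ge 0.5$, so a clone at
  exactly half the sample already gives UC50 = 1.
* **Coverage-corrected Shannon** (`shannon_corrected`):
  $\hat H = -\sum_i c\,p_i \log(c\,p_i) / (1 - (1 - c\,p_i)^k)$, a
  Horvitz–Thompson-style correction. The default `"printed"` dialect uses
  coverage $c = 1 - f_1/S$ and exponent $k = S$; the `"chao-shen"` dialect
  uses the standard Chao–Shen form $c = 1 - f_1/n$, $k = n$ with $n$ the
  total count. The two differ substantially on small samples; both are
  provided because the printed form is what the simulation study evaluates,
  while the Chao–Shen form is what the wider literature uses. With all
  clones singletons the coverage is $\le 0$ and the estimator is undefined
  (`NA`).

All indices accept fractional abundances (fragment-count estimates) except
Chao1 and the corrected Shannon, whose frequency-of-frequencies inputs only
exist for integer counts; those error rather than silently rounding.
`diversity_panel()` computes everything at once and converts such errors
into `NA` sentinels so one awkward index never aborts a report.

```{r}
diversity_panel(c(6, 2, 2))
```

## The clonal-dominance simulation

`run_dominance_experiment()` studies how each index behaves when one clone
expands. The design: $N$ clones (default 1,000) start equi-abundant. Each
clone has a per-step proliferation rate; non-dominant rates start
$\mathcal N(r, (r/10)^2)$ ("a similar rate") while one designated clone
gets $4r$. At each of 20 pseudotime steps, abundances are updated
multiplicatively, $x_i \leftarrow x_i e^{r_i}$, and renormalised; each
non-dominant rate then receives an additive Gaussian perturbation. At every
step the population is sampled multinomially (with replacement) at sizes
10–10,000, 50 replicates each, and the full panel is computed per sample;
the summary holds mean and SD per (step, size, index) plus the true
population value.

Choices the design left open, and how they were resolved:

* **Update rule.** "Updated according to the proliferation rate" fixes no
  functional form. Multiplicative exponential growth with renormalisation is
  the standard branching-process limit and gives a closed form for two
  clones — dominant fraction $e^{3rt}/(e^{3rt}+1)$ — which the unit tests
  check directly.
* **Rate perturbation scale.** "A random value from N(0,1)" fixes neither
  whether the rate is replaced or perturbed nor on what scale. The package
  perturbs additively with SD `rate_volatility`. A unit-SD walk would
  swamp the $3r$ selective advantage within 20 steps (the cumulative
  perturbation SD grows like $\sigma \sqrt{t^3/3}$, about 52 at $t = 20$),
  making the designated clone's dominance impossible — so the default is
  $\sigma = r/10$, which keeps drift an order of magnitude below the
  advantage while still randomising every background trajectory. The
  dominant clone's rate is held fixed so "four times larger" stays
  meaningful throughout.
* **Calibration.** `DEFAULT_BASELINE_RATE = 0.18` is chosen so the dominant
  clone exceeds 95% abundance by step 20 at $N = 1000$. The closed-form
  guide $e^{3rt}/(e^{3rt}+N-1)$ alone suggests $r \approx 0.17$, but rate
  drift boosts aggregate background growth by roughly
  $e^{\sigma^2 t^3/6}$ (a Jensen effect), which that form ignores; 0.18
  absorbs it and lands the trajectory at ~0.97.
* **Replicates.** 50 per condition, following the reported experiment.
* **Extinction.** True abundances are floored at the smallest positive
  double; clones never go extinct in the population, only in samples.
* **Reproducibility.** One seed in the config drives the whole experiment;
  identical seeds give bitwise-identical summaries.

Two estimator properties the simulation exposes are worth knowing. The
sampled dominant fraction is an unbiased estimate of the true one at every
size. Pielou evenness is nearly independent of sampling effort while the
population is polyclonal (means across sizes 100–10,000 agree within ~0.015),
but once diversity has collapsed, small samples overestimate evenness: at
true dominance ~0.9 a 100-cell sample sees only a handful of clones and
reports $J \approx 0.13$ versus $\approx 0.06$ at 10,000 cells, so the
spread across sizes transiently reaches ~0.10 before the trajectories
reconverge near zero. Small-sample Pielou values from low-diversity samples
should therefore be read as upper bounds.

## The richness-by-dominance surfaces

`diversity_surface()` maps Shannon, Pielou and Simpson over a grid of
richness $S$ and imposed dominance $d$: one clone fixed at $d$, the other
$S - 1$ clones uniform-random rescaled to $1 - d$. Defaults
($S \in \{2, 10, 50, 100, 250, 500, 1000\}$, $d = 0, 0.05, \ldots, 0.95$,
20 replicates per cell) were chosen because only the ranges were given;
richness starts at 2 since every index is degenerate below it, and cells
whose Pielou is undefined are marked `NA` with `n_defined` recording how
many replicates contributed. Under this construction the expected Simpson
has a directly computable expectation ($1 - d^2 - E[\sum \text{bg}^2]$),
which the tests verify by independent Monte Carlo; Shannon grows
like $\log S$ at fixed $d$ while Pielou and Simpson stay within a narrow
band — the quantitative version of "use a normalised index".

## The trial re-analysis pipeline

Published trials report richness (unique ISs) and Shannon, in whichever log
base the authors preferred. The pipeline normalises bases
(`convert_log_base`), derives evenness directly from the two summaries
(`pielou_from_summary`: $J = H / \log_b S$, which needs no abundance
table), and labels records (`classify_evenness`) against a fixed alert
threshold of 0.5 — below it, the probability of clinically relevant clonal
dominance rises steeply. The comparison is strict: exactly 0.5 is "high",
since it is values *below* the threshold that signal concern. Published
values are rounded, so $J$ can land marginally above 1 or $H$ marginally
above $\log S$; the former is clamped to 1 with a warning, the latter
flagged in a `shannon_consistent` column rather than dropped. The threshold
is applied as a fixed rule, not re-estimated: fitting an event-probability
model would need clinical outcome labels that are not distributable.

`spiked_condition_report()` covers the experimental validation design in
which known clones are spiked into a polyclonal background at increasing
expected shares: per condition it reports each major clone (above a 1%
cutoff), the aggregate minor share, and the evenness indices — Pielou
drops faster than Simpson once the spiked share passes ~20%, which is why
the pipeline leans on Pielou.

## Synthetic data

No per-point data from the five published trials are distributable, so the
generators produce tables with the same statistical structure; everything
shipped or tested is synthetic and labelled as such.

`generate_trial_table()` emulates a monitored cohort: per-patient true
richness log-uniform over 100–10,000 (pyrosequencing-era studies recover
hundreds of ISs, Illumina-era ones up to 10,000 — the main driver of
between-study Shannon differences); background abundances symmetric
Dirichlet, with the concentration solved (via
$E[H] = \psi(S\alpha + 1) - \psi(\alpha + 1)$, `evenness_alpha`) to hit a
baseline evenness drawn from a configurable band, default 0.85–0.98 so
event-free patients are realistically uneven but safely polyclonal; each
record is a multinomial subsample (10 cells per true clone by default)
from which richness and Shannon are *computed*, so every record satisfies
$H \le \log S$ exactly. Event patients get a dominant clone at 75% at the
diagnosis time, rising along a logistic-shaped trajectory (matching the
simulator's dominance curve) to a configurable peak of up to 98%; 75% at
onset puts post-onset evenness decisively below 0.5 at any richness in
range. An optional recovery schedule collapses the clone after the
midpoint, emulating diversity restored by chemotherapy.

`generate_spiked_tables()` emulates the spiking design: 900 background
clones at near-even weights (Dirichlet, concentration 50) fixed across
conditions because they represent the same source DNA, 2,500 sampled cells
per condition, and per condition a set of spiked clones jointly holding
the expected share (split by their vector copy numbers). Default
conditions — 0/1/2/3 spiked ISs at expected shares 0/25/50/75% — span the
design's range; the exact published per-condition values are not tabulated,
so these are the package's own emulation.

What the generators deliberately do **not** model: sequencing reads, PCR
and sonication bias, fragment-length abundance estimation, cell lineages,
or real between-study protocol differences. Passing tests on synthetic
tables therefore shows the pipeline's arithmetic and contracts are right,
not that any specific published dataset is reproduced.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the study's native sizes
where they are cheap (the full 1,000-clone, 20-step, 50-replicate
experiment runs in seconds) and modest Monte-Carlo sizes elsewhere
(20–50 replicates per surface cell or sampling condition; 50-sample
resampling studies), with fixed seeds throughout. Undefined index values
are excluded from means and SDs with the number of defined replicates
reported alongside. Ties in UC50 are harmless by construction (any
ordering of equal counts gives the same count); the cumulative comparison
carries a $10^{-12}$ slack against floating-point shortfall. Delimited
outputs serialise sentinels as the literal `NA` token and floats at 6
significant digits.

## Known limitations

* The 0.5 evenness threshold is adopted, not re-derived; its clinical
  calibration rests on the original cross-trial comparison.
* Chao1 assumes random sampling of individuals; PCR duplicates and
  capture bias violate this in real IS data, so its absolute estimates
  should be read cautiously.
* The printed coverage-correction dialect divides by inclusion
  probabilities computed with the observed richness $S$ in the exponent;
  on very small samples this behaves differently from the Chao–Shen
  estimator, and no position is taken here on which is preferable — both
  are exposed.
* Small-sample Pielou overestimates evenness once diversity is low (see
  the simulation section); longitudinal comparisons should keep sampling
  effort comparable.
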