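---
title: "Models and methods behind pol2wave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pol2wave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pol2wave analyses timed ChIP-seq of elongating (Ser2-phosphorylated) RNA
polymerase II around a CDK9-inhibitor block-and-release experiment, and
ships a stochastic kinetic simulator that generates synthetic timed read
sets with known ground truth so that every analysis stage can be
validated without external data.  This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and
what validation on simulated data does and does not establish.

## The experimental design being modelled

CDK9 inhibitors such as flavopiridol prevent new pause-release (and
hence new Ser2 phosphorylation) events without stopping polymerases that
are already elongating.  Two complementary time courses result:

* **Block ("retreating wave"):** during inhibition, the elongating
  cohort keeps moving 3'-wards and drains off gene ends, leaving a
  signal front that retreats from the TSS; meanwhile polymerases that
  terminate may be handed back to the promoter (recycling), where they
  sit — still carrying the Ser2 mark — because release is blocked.
  Promoter-region signal therefore *accumulates* in proportion to
  recycling efficiency.
* **Washout ("emerging wave"):** after inhibitor removal, the queued
  promoter cohort is released as a coherent wave whose leading edge
  advances at the elongation velocity.

## Coverage tracks

Reads (BED6, 0-based half-open) are replaced by fragments of fixed
length anchored at the read 5' end and oriented 5'→3'
(`extend_reads()`, default 300 bp, standing in for the sequenced
library fragment).  Fragments are clamped at chromosome bounds rather
than discarded; clamping removes the clamped bases from the mass
balance, which the track-mass conservation test accounts for.  Per-base
overlap counts are scaled by `target_depth / n_reads` (default target
5e7 reads) so that libraries are compared at a common depth; the factor
uses the raw aligned-read count taken before extension.  Tracks store
per-nucleotide densities; with `bin_width > 1` (default 10 bp) the
density is the bin mean repeated across the bin, so every downstream
statistic is defined on per-nucleotide values regardless of binning.
Note that depth normalisation makes every track compositional: a
time point where most polymerase has left the templates redistributes
its fixed read mass over the remaining occupancy.

## Pausing and release ratios

Each gene longer than 700 bp is split into a 5'-end bin
`[TSS−50, TSS+200)`, a gene-body bin `[TSS+200, TTS−500)` and a 3'-end
bin `[TTS−500, TTS+500)` in transcription coordinates, reflected onto
the genome for minus-strand genes.  The 5' pausing ratio is the mean
per-nucleotide 5'-bin density over the mean body density; the 3'
release ratio is the 3'-bin density over the body density.  Both are
scale-free, hence independent of the normalisation factor.  A gene with
zero body density gets an *invalid* flag rather than a pseudocount or
an infinite ratio: pseudocounts would distort the sorted-ratio curves
that the package plots, and downstream summaries simply report the
exclusion count.  Overlapping genes are scored independently (no
overlap resolution is attempted), and "promoter region" always means
the 5'-end bin, everywhere in the package.

## Metagenes and promoter decay

`scaled_metagene()` rescales each gene body to `body_bins` equal
sub-intervals (default 100) and keeps ±`flank` bp of context at fixed
50-bp resolution (default 2 kb); genes whose flanked window runs off
the chromosome are dropped with a message.  `promoter_series()` tracks
per-gene 5'-bin densities over the time points of one condition; the
gene set is constant across time because validity depends only on
geometry.  `percent_decrease()` is `100 × (1 − central(t1)/central(t0))`
with the median as the default central statistic (box-plot figures in
this literature display medians; the mean is available via `stat =
"mean"`).  Conditions are compared at a time point with the
Kruskal–Wallis rank test (`compare_distributions()`), the two-group
case of one-way ANOVA on ranks.

## Wave fronts and the elongation rate

`wave_front()` locates the position where the 5'→3' cumulative
gene-body density first reaches a mass quantile (default 0.9).  A
cumulative-mass quantile was chosen over a threshold crossing because
it is invariant to sequencing depth and normalisation and needs no
absolute cutoff; the computation runs on the run-length encoding, so it
is exact at base resolution.  The leading edge (high quantile) tracks
the emerging wave after washout; the trailing edge (low quantile,
e.g. 0.1) tracks the retreating wave during the block.
`elongation_rate()` is an ordinary least-squares fit of the per-time
median front position against time; its slope is the apparent velocity
in bp/min.  Front positions saturate once the wave reaches the TTS, so
rate fits should use genes longer than `v × t_max` — the bundled
recovery study uses ~200-kb genes so that even 4000 bp/min × 40 min
stays inside the body.

The **recycling index** summarises promoter re-accumulation during the
block: the least-squares slope of the median promoter density over
block time, divided by a baseline median gene-body density.  It is a
package-defined summary (and is labelled as such in report output),
not a literature statistic.

## The kinetic simulator

Each gene carries four compartments: `U` (promoter-engaged, not yet
released, Ser2-invisible), `E` (elongating at position *x*, visible),
`T` (terminating dwell at the TTS, visible) and `R` (recycled back to
the promoter after termination, visible — the Ser2 mark is retained
through recycling).  Transitions per step of `dt` minutes
(fixed-step tau-leaping, default `dt = 0.05` min):

* initiation: a new `U` with probability `k_init·dt` (default
  0.5/min/gene);
* release: each `U` and `R` enters `E` at `x = 0` with probability
  `k_release·dt` (default 2/min) — **zero while the block is engaged**;
* advance: `x += max(Normal(v·dt, v_sd·√dt), 0)` (defaults
  `v = 2000` bp/min, `v_sd = 200`);
* termination: on reaching the gene end, a `term_dwell`-minute dwell
  (default 1 min), after which the molecule becomes `R` with
  probability `rho` (default 0.9) or leaves the template.

The block affects only release, matching the mechanism of CDK9
inhibition: elongating and terminating molecules are untouched, and
newly initiated `U` molecules remain invisible until their first
release.  Visibility acquired at release and retained through recycling
is a modelling choice consistent with promoter accumulation of the
elongation mark during a block.

Per-step event probabilities are bounded at 0.2 (violations raise an
error that asks for a smaller `dt`), which keeps tau-leap error small.
One caveat of the truncated-normal advance: when `v·dt` is comparable
to `v_sd·√dt`, truncation at zero inflates the mean step — about +6%
at `v = 1000` bp/min with the default jitter, and under +1% from
2000 bp/min up.  Recovered rates inherit this structural bias, which is
well inside the 10% recovery tolerance of the validation suite.

Reads are drawn multinomially over the occupancy histogram
(`occupancy_bin = 50` bp), with a 5% uniform background over each gene
±2 kb emulating nonspecific ChIP signal, placed on the gene's strand
with a 36-bp read length, exactly `depth` reads per time point
(default 2e5).  The synthetic gene panel places genes on one
chromosome with 5-kb gaps and alternating strands, with lengths drawn
uniformly from 10–200 kb: a human-like spread in which long genes
retain body signal through a 40-min block.  That retention matters —
if every gene drained completely, depth normalisation would
concentrate all remaining mass at promoters in *both* conditions and
recycling differences would vanish from the compositional signal.

Schedules follow the 0/10/20/40-min design in both phases with a
60-min block and a 60-min burn-in before the first sample.  With high
recycling the recycled flux amplifies initiation (total flux tends to
`k_init/(1−rho)` at stationarity), and 60 min does not fully reach
that limit for long genes; all analyses are comparative across
matched conditions, so the shared partial burn-in is immaterial.

## Validation studies and their interpretation

* **Rate recovery** (`rate_recovery_experiment()`): 200 genes of
  180–220 kb, no burn-in, a 60-min block that builds a paused queue on
  otherwise empty templates, washout samples at 10/20/40 min, 1e6
  reads per sample.  The released queue forms a dominant pulse whose
  centre moves at `v`, so the 0.9-quantile front regresses to the true
  velocity within a few percent.
* **Recycling response** (`recycling_experiment()`): block-phase
  sampling at the default panel; the index median over seeds increases
  strictly over `rho ∈ {0, 0.3, 0.6, 0.9}`, and is identically zero at
  `rho = 0` when the background fraction is disabled (with background
  on, it is a mean-zero noise variable — the background floor puts a
  constant pedestal under the promoter bins).
* **Discrimination** (`discrimination_experiment()`): full pipeline on
  paired conditions (control `rho = 0.9, v = 2000` vs depleted
  `rho = 0.2, v = 1200`, the depletion acting on both recycling and
  velocity).  The defect flag requires the depleted recycling index to
  fall below the control index by a 25% relative margin *and* a lower
  washout percent decrease.  The margin was set from matched-null
  replicate pairs, where index ratios stay within ~±12% of 1 while
  true-effect ratios are below 0.12; the percent-decrease comparison
  is directional because its absolute level is background-dominated
  once promoters have emptied (both conditions sit near 100% with the
  fast default release rate).

What passing these studies shows is that the pipeline's statistics
respond to the generative parameters they target, at realistic depths
and panel sizes, under this kinetic model.  What they do not show:
robustness to chromatin structure, sequence-specific pausing, antibody
efficiency, ChIP enrichment nonlinearity, replicate batch effects, or
gene-overlap artefacts — none of which the generator emulates.  Results
on real data should lean on the comparative design (matched conditions,
identical processing), which is exactly the structure the statistics
are built around.

## Problem sizes and determinism

The bundled studies use 5 seeds per configuration (10 replicate pairs
for discrimination), 50-gene default panels at 2e5 reads per sample and
200-gene panels at 1e6 reads for rate recovery; these sizes give
stable medians while keeping a full validation run in the minutes
range.  Every stochastic stage is driven by a single master seed per
run (`sim_config(seed = )`), and identical configuration plus seed
reproduces outputs byte-for-byte, including written BED files and
manifests.
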