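---
title: "Quantifying the pyloric rhythm over days: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pyloric rhythm over days: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyloric)
```

## The scientific problem

The pyloric circuit of the crustacean stomatogastric ganglion (STG) produces a
triphasic motor pattern — bursts of the pyloric dilator (PD), lateral pyloric
(LP) and pyloric constrictor neurons — whose cycle frequency and phase
relationships are remarkably conserved across animals while the rhythm is
driven by descending neuromodulatory input. Removing that input
(*decentralization*, by transecting or blocking the stomatogastric nerve)
slows the rhythm within minutes and alters its phases, and a long-standing
question is whether the circuit compensates over subsequent days. Answering it
requires quantification machinery for continuous multi-day recordings: burst
timing, per-cycle frequency and phase, transient frequency *bouts*,
long-duration summaries, and the comparison statistics. This package
implements that machinery, together with a synthetic-data generator that
provides ground truth for every stage.

## The per-cycle model

All quantities derive from burst onset and offset times of the two monitored
units:

* **Cycle period**: the interval between consecutive PD burst onsets
  (onset-referenced); **frequency** is its reciprocal. Onset referencing is
  the standard convention when phases are measured relative to PD burst start.
* **Phase**: latency of an event from the cycle's PD burst onset, divided by
  the period. `pd_off_phase` (the pacemaker duty cycle), `lp_on_phase` and
  `lp_off_phase` are dimensionless in (0, 1). Phases are invariant under any
  rescaling of time, which the tests exploit.
* **LP assignment**: the first LP burst starting in the half-open interval
  `[pd_start, next_pd_start)` belongs to the cycle. Cycles with no LP burst
  are retained and flagged `lp_silent` (LP-silent preparations occur in real
  data and are excluded from LP-phase aggregates, not deleted); a second LP
  burst in one cycle is counted in `lp_extra` and the first is used.

### Burst segmentation

Bursts are maximal runs of spikes whose inter-spike intervals do not exceed
`max_isi`, with at least `min_spikes = 2` spikes (a one-spike burst has zero
duration and breaks every phase definition). The segmentation rule is an
explicit convention of this package: published long-term STG studies used
semi-automated proprietary detection whose criteria are not described, so the
rule is kept simple, exposed as a knob, and verified against a brute-force
run-enumeration oracle. The default `max_isi = 0.3` s suits pyloric-range
rhythms; `adaptive_max_isi()` offers 0.25 x the trailing median period when a
provisional cycle estimate exists.

### Chain breaks at gaps

Whether a silent pause should produce one absurdly long "cycle" or break the
cycle chain is genuinely open; this package breaks the chain. A putative
period exceeding `gap_factor = 5` times the trailing median of (up to) the
previous ten accepted periods is flagged invalid with reason `"gap"`, and the
trailing median then **restarts** from the following cycles. The restart
matters: without it, a rhythm that resumes much slower than before the break
— exactly what decentralization to a slow rhythm looks like — would be
rejected forever against the old tempo. With the restart, at most one cycle
is lost at a genuine regime change.

## The bout statistic

A bout is a transient frequency elevation: with background defined as the
trailing mean of the previous ten cycle frequencies (the candidate cycle
excluded), the rule fires at cycle *i* when the next three cycles are all at
least 40% above background. Both the lookback (10), the lookahead (3) and the
relative increase (0.40) are exposed in `bout_params()`. Two readings of
"a >40% increase ... at least a 40% increase" are possible; the inclusive
`>=` reading is the default, with `strict = TRUE` available. Consecutive
firing indices merge into a single bout event (a new event requires at least
one non-firing index between firings); the unmerged firing count is also
reported, since the original analyses do not define bout extent. Note that
once a bout is underway the trailing mean starts absorbing elevated cycles,
so the rule typically stops firing before the elevation ends — the merged
extent is a detection extent, not the physiological bout duration.

`detect_bouts()` is verified against a quadratic-time oracle that re-evaluates
the definition at every index with no incremental updates, over 10,000 random
series.

## Long-duration summaries

* **Binned series**: per-cycle frequencies summarized in 0.1 h (6 min) bins
  by the median (robust to single aberrant cycles); empty bins are absent
  (`NA`), never zero.
* **Box statistics**: median, type-7 (linear-interpolation) quartiles,
  whiskers to the most extreme datum within 1.5 x IQR of the nearest
  quartile, points beyond listed as outliers. The original software's
  quartile convention is unknown; type 7 is R's default and is documented
  here as the package's choice.
* **Daily means**: 24 h bins counted from decentralization, or — for intact
  preparations — from a matched reference one hour after recording start
  (matching a one-hour baseline protocol). Days without valid cycles are
  flagged for exclusion from repeated-measures analyses rather than imputed.
* **Snapshot**: the "30 minutes after decentralization" value is the mean
  frequency in a window of half-width 5 min around that time point; the
  exact window used historically is unstated, so it is a documented,
  configurable default.
* **Fastest window**: the 5 h stretch (within a 120 h post-decentralization
  horizon) maximizing mean frequency, slid in 0.1 h steps, ties broken by
  earliest start. Windows with under 50% of their 0.1 h sub-bins populated
  are ineligible, preventing degenerate maxima over sparse or silent data.
  Verified against exhaustive evaluation of every candidate window.
* **Variability**: within-preparation cycle-to-cycle variability is the
  sample CV (SD/mean, n-1 denominator) of per-cycle frequency within a day;
  across-preparation variability is the sample CV of per-preparation daily
  means. No formula is given in the source literature; the sample-SD
  convention is this package's documented definition.
* **Silence**: 60 s tiles with fewer than 3 PD bursts, merged into maximal
  intervals. Again a documented convention — published criteria for "no
  rhythmic activity" are unstated.
* **Saline exchanges**: mean frequency in the hour before vs the hour after
  each exchange; exchanges closer than two hours apart get truncated,
  non-overlapping half-gap windows with a logged message.

## The statistics battery

Implemented from the standard formulas, with base R's distribution functions
supplying p values, and cross-checked in the tests against `cor.test`,
`t.test`, `chisq.test` and `aov` with error strata:

* **Pearson correlation** with `t = R sqrt((n-2)/(1-R^2))` against t(n-2).
* **Paired t** on the pairwise differences, df n-1.
* **Unpaired t**, pooled variance by default (the historical choice for
  groups with similar n and variances), Welch optional.
* **Mood's median test** for groups of very different sizes and variances:
  counts above vs at-or-below the grand median per group, Pearson chi-square
  on the 2x2 table, 1 df, no continuity correction. Ties at the grand median
  count as "at or below" (the source literature is silent; this is the
  documented choice).
* **Split-plot mixed ANOVA**: the classical univariate decomposition with one
  between-subjects factor (condition) and one within-subjects factor (day).
  Group effects are tested against subjects-within-groups; the within factor
  and the interaction against the within x subjects residual. Unequal group
  sizes use the cell-mean formulas weighted by per-group n; with every
  subject complete, cell frequencies are proportional and the decomposition
  is orthogonal (the tests confirm exact agreement with `aov`'s sequential
  strata on unbalanced data). No sphericity correction is applied by
  default, matching how such ANOVAs were historically reported;
  Greenhouse-Geisser is available via `gg_correct = TRUE`. Subjects missing
  any level are dropped with a message, and no multiple-testing correction
  is applied anywhere.

The "mixed-model ANOVA" here is deliberately the classical split-plot, not a
likelihood-based (REML) mixed-effects model.

## The synthetic-data generator

`sample_population()` draws per-preparation baseline (and, for decentralized
populations, post-step) frequencies from truncated normal distributions,
rejecting draws at or below 0.05 Hz (active preparations never show sustained
frequencies that low). The population defaults are the study conditions this
package targets: intact 1.2 +/- 0.29 Hz across preparations, decentralized
0.52 +/- 0.30 Hz, with decentralization after one hour of baseline. Note that
the truncation raises the realized decentralized population mean to about
0.56 Hz; this is a property of the declared sampling model, not an estimation
bias.

`generate_cycle_series()` composes, per cycle:

* the regime baseline (pre- or post-decentralization);
* a slow **Ornstein-Uhlenbeck drift** (default mean-reversion rate 1/300 s^-1,
  stationary SD 0.05 Hz) — the two-time-scale structure (slow drift plus
  fast jitter) mirrors what long-term recordings of decentralized
  preparations look like, with variability on both hour and cycle time
  scales. The OU process is discretized on a fixed clock at the nominal
  baseline period, making it a precomputable stationary AR(1) sequence; the
  variability model itself is this package's construction, since the source
  literature describes but does not model it;
* a decaying **saline boost**: each exchange lifts frequency to `factor`
  (default 1.5) times the regime baseline, decaying exponentially with a 2 h
  time constant — consistent with observed activations lasting several
  hours; the exact kinetics are unreported, so this is a modeling choice;
* a multiplicative **bout amplitude** over scheduled cycle indices (factor
  >= 1.4, at least 3 cycles, so injected bouts satisfy the detection rule in
  expectation; no ramping — the simplest construction satisfying the rule);
* i.i.d. multiplicative **period jitter** with CV 0.03 by default. No
  empirical short-term jitter magnitude is available for intact
  preparations; 0.03 was chosen once as a realistic value and is a free
  parameter, not an empirical one.

Silence episodes suppress cycle emission entirely; a bout scheduled across a
silence episode raises an error naming the conflict. Phases are applied per
cycle from `phase_targets` (defaults 0.30 / 0.45 / 0.75, within the range
reported for intact preparations); alternatively `duration_mode = "fixed"`
places burst events at fixed latencies in seconds, which makes phase grow
linearly with frequency — the construction used to probe phase-vs-duration
constancy.

`render_spike_times()` spreads a configurable number of spikes evenly over
each burst, endpoints included, so segmentation recovers burst boundaries to
machine precision (a pipeline round-trip oracle). `render_trace()` produces an
extracellular-style trace: a fixed biphasic template (positive peak exactly at
the spike time, then a shallower undershoot at 40% amplitude) scaled per unit,
plus white noise. Spike detection uses amplitude-ordered non-maximum
suppression within the refractory window rather than first-come suppression:
with noise, local maxima on a template's rising flank would otherwise displace
the true peak.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis relies on: across- and
within-preparation frequency distributions, the step at decentralization,
two-time-scale variability, triphasic phase structure, bouts, silences, and
saline transients. It does **not** simulate biophysics (no conductance-based
neurons), the PY unit or the gastric mill rhythm, waveform shape changes,
bout ramping, or slow non-stationary trends beyond the OU drift. Passing
tests therefore demonstrate that the quantification rules are implemented
correctly and recover known ground truth under realistic noise — not that
any biological claim about real recordings is reproduced. Published summary
tables from wild-caught-animal datasets cannot be regenerated without the
original recordings, and no attempt is made to do so.

## Numerical choices and degenerate inputs

* Quartiles: type 7. Ties in `fastest_window`: earliest start. Mood ties: "at
  or below". Bout rule boundary: inclusive.
* Truncated sampling: rejection, not clipping (no probability mass piles up
  at 0.05 Hz).
* Zero-variance inputs error in `pearson_corr`, `unpaired_t` (both groups),
  `moods_median` (degenerate table) and `mixed_anova` (zero error mean
  square); a constant phase regressed on varying frequency returns slope 0
  and R 0 rather than an error.
* Fewer than 2 PD bursts yield an empty cycle table; fewer cycles than
  `lookback + lookahead` yield an empty bout table with a message; an empty
  snapshot window yields `NA` with a message, never 0.
* All simulation entry points take an explicit seed and restore the caller's
  RNG state; identical seeds give bit-identical outputs.

## Problem sizes used in the checks

The test suite exercises the oracle equivalences at 10,000 random instances
for the bout and burst rules, 1,000 fixtures for the fastest-window search,
200 simulated populations of 30 preparations for the decentralization-step
recovery, and 2,000 null replicates (19 vs 9 subjects, 6 within levels) for
the ANOVA type-I error. `scripts/acceptance.R` recomputes the headline
quantities at somewhat smaller sizes (2,000 random instances per oracle,
1,000 null replicates) chosen to summarize the same properties in a few
seconds.

## Known limitations

* The burst segmentation and silence rules are conventions; real noisy
  extracellular data may need tuned `max_isi` or spike sorting beyond the
  two-window amplitude discriminator provided.
* The split-plot ANOVA assumes sphericity when uncorrected, and its
  unbalanced-group behavior follows the proportional-frequency decomposition;
  other software may use other sum-of-squares conventions.
* `detect_spikes` is a front end for synthetic traces; it is not a
  replacement for full spike sorting on real lvn recordings carrying more
  than two units.
* The generator's bout amplitudes switch on and off instantaneously; detected
  bout extents on real, ramped bouts will differ from the merged detection
  extents reported here.
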