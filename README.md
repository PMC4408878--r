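# pyloric

Quantification of the crustacean pyloric rhythm in long-term
electrophysiological recordings.

The pyloric circuit of the stomatogastric ganglion (STG) produces a triphasic
motor pattern — pyloric dilator (PD), lateral pyloric (LP) and pyloric
constrictor bursts — whose frequency and phases depend on descending
neuromodulatory input. Removing that input (*decentralization*) slows the
rhythm and disrupts its phase constancy, and whether the circuit compensates
over days is a question that can only be answered with quantification
machinery for continuous multi-day recordings. This package provides that
machinery for anyone analyzing rhythmic burst data of this kind:

* **Burst segmentation** (`segment_bursts`): maximal spike runs with every
  inter-spike interval below a threshold; brute-force-verified.
* **Cycle/phase tables** (`build_cycles`, `filter_cycles`): onset-referenced
  periods (PD start to PD start), frequency, and phases
  `phase = (event - pd_start) / period` for PD off, LP on, LP off; LP-silent
  cycles flagged, long gaps break the cycle chain.
* **Bout detection** (`detect_bouts`): a bout is three or more consecutive
  cycles each at least 40% above the background frequency, with background
  the trailing mean of the previous ten cycles.
* **Long-term summaries** (`bin_series`, `hourly_boxstats`, `daily_mean`,
  `snapshot_mean`, `fastest_window`, `within_prep_cv`, `across_prep_cv`,
  `detect_silence`, `saline_effect`): 6 min binned medians, box statistics
  with 1.5 IQR whiskers, 24 h daily means from decentralization, the fastest
  5 h stretch within 120 h, silence intervals, and pre/post saline-exchange
  contrasts.
* **Comparison statistics** (`pearson_corr`, `paired_t`, `unpaired_t`,
  `moods_median`, `mixed_anova`): implemented from the standard formulas,
  including the classical split-plot (two-way mixed) ANOVA with
  decentralization state as the between-subjects factor and day as the
  within-subjects factor:
  `F_between = MS_group / MS_subjects-within-groups`,
  `F_within = MS_day / MS_day-x-subjects`,
  `F_interaction = MS_group-x-day / MS_day-x-subjects`.
* **A synthetic-data generator** (`population_config`, `sample_population`,
  `generate_cycle_series`, `render_spike_times`, `render_trace`): multi-day
  two-unit ground truth with across-preparation frequency distributions
  (intact 1.2 ± 0.29 Hz, decentralized 0.52 ± 0.30 Hz), slow
  Ornstein–Uhlenbeck drift, per-cycle jitter, scheduled bouts, silence
  episodes and saline transients — so every stage of the analysis is
  testable against known truth without any recordings.

## Worked example

Simulate one decentralized preparation (1 h baseline at 1.25 Hz, step to
0.55 Hz, one scheduled bout), then run the full analysis chain on its spike
trains:

```r
library(pyloric)

p <- prep_params(prep_id = "prep007", baseline_freq = 1.25,
                 decentralization_time = 3600, post_dec_freq = 0.55,
                 bout_schedule = data.frame(start_cycle = 6000,
                                            n_cycles = 4, factor = 1.6))
sim <- simulate_preparation(p, duration = 4 * 3600, rng_seed = 42)
a <- analyze_preparation(sim$spikes, sim$timeline)
a
#> Pyloric analysis of prep007 (decentralized)
#>   102230 spikes -> 10223 PD / 10223 LP bursts -> 10222 cycles (10222 valid)
#>   mean frequency 0.835 Hz; phases PD off 0.300, LP on 0.450, LP off 0.750
#>   1 bout(s) (2 unmerged firings); 0.0% of record silent
```

The 102,230 spikes collapse to 10,223 bursts per unit and 10,222 cycles; the
mean frequency of 0.835 Hz mixes the baseline hour (~1.25 Hz) with three
decentralized hours (~0.55 Hz); the configured phase targets (0.30, 0.45,
0.75) are recovered exactly; and the single injected bout is found, merged
from two firings of the trailing-mean rule. `plot(a)` draws the binned
frequency trace with the decentralization time and the detected bout marked.

The statistics battery prints in the shape such results are usually tabled:

```r
paired_t(c(1.31, 1.12, 0.95, 1.40, 1.18),   # baseline Hz per preparation
         c(0.61, 0.35, 0.47, 0.82, 0.50))   # 30 min decentralized Hz
#> paired t: t = 12.6787, df = 4, p = 0.0002229 (n = 5)

moods_median(c(1, 2, 3, 4), c(5, 6, 7, 8))
#> Mood's median test: chi-square = 8.0000, df = 1, p = 0.004678 (n = 4, 4)
```

A config-driven layer ties the stages together (`run_simulate`,
`run_analyze`, `run_stats`, YAML config with per-stage sections, effective
config echoed next to outputs), and `inst/cli/pyloric.R` is a thin Rscript
wrapper with `simulate` / `analyze` / `stats` subcommands.

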