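# wavekin

Kinematic analysis of the body *wave* — the hip-hop dance move in which a
vertical displacement pulse travels hand → wrist → elbow → shoulder →
shoulder → elbow → wrist → hand across the horizontally extended arms.
`wavekin` turns raw per-trial 3D marker trajectories into per-trial
wave-quality metrics and cohort-level statistics, and ships a synthetic
trial generator with known ground truth so every stage of the pipeline is
testable without access to laboratory recordings.

It is aimed at movement scientists and dance-education researchers who want
reproducible, automated scoring of sequential multi-joint coordination
tasks recorded with optical motion capture.

## The measurement model

A wave is segmented from the successive peaks of the eight chain markers'
vertical displacements. For marker *i*, the **sub-movement** is its primary
peak — the local maximum with the largest *topographic prominence* within
the analysis window — and its amplitude is that prominence: the height of
the peak above the higher of the two minima separating it from higher
terrain. From the eight primary peaks the package computes, per trial:

| metric | definition |
|---|---|
| wave amplitude (mm) | mean of the 8 primary prominences |
| wrist − shoulder amplitude (mm) | mean wrist minus mean shoulder prominence |
| residual amplitude (mm) | mean largest secondary-peak prominence (motion in segments that should be still) |
| wave/residual ratio | amplitude ÷ residual — the trial's signal-to-noise ratio |
| wave duration (s) | sum of the 7 inter-peak intervals |
| COV of propagation speed (%) | 100 · SD/mean of the 7 intervals (0 = perfectly constant speed) |
| shoulder-to-shoulder interval (s, %) | time between the two shoulder peaks; long values mark a one-arm-pause-other-arm "chunking" strategy |

Upstream, marker-dropout gaps are repaired by cubic-spline interpolation
(interior gaps ≤ 0.3 s; trials with ≥ 3% unresolved missing data are
excluded), and the analysis window is selected automatically from each
marker's supra-threshold activity. Downstream, `cohort_stats` provides
participant ranking, Pearson/Spearman correlation matrices over
per-participant means, a repeated-measures one-way ANOVA for the
attentional-focus factor with eta squared, and quadrant reports.

## Worked example

Simulate a small practice cohort (6 participants, 4 counterbalanced
ABBA/BAAB blocks of 5 trials), run the full pipeline, and summarize:

```r
library(wavekin)

design  <- cohort_design(n_participants = 6, trials_per_block = 5, seed = 42)
metrics <- analyze_cohort(design)
summ    <- summarize_participants(metrics, by_focus = FALSE)
summ[, c("participant_id", "n_valid_trials", "wave_amplitude",
         "cov_propagation", "amplitude_rank")]
#>   participant_id n_valid_trials wave_amplitude cov_propagation amplitude_rank
#> 1            P01             20          146.4          10.946              1
#> 2            P02             20          109.5          12.781              6
#> 3            P03             20          130.9          15.237              3
#> 4            P04             20          139.4           8.315              2
#> 5            P05             20          127.7          12.175              4
#> 6            P06             20          121.7          15.905              5
```

Participant P01 produced the largest waves (mean primary-peak prominence
146 mm, rank 1); P04 combined large amplitude with the most constant
propagation speed (COV 8.3%). Cohort-level structure:

```r
pearson_matrix(summ, c("wave_amplitude", "cov_propagation", "wave_duration"))
#> <wave_cormat> pearson, n = 6-6
#>                 wave_amplitude cov_propagation wave_duration
#> wave_amplitude           1.000          -0.524         0.423
#> cov_propagation         -0.524           1.000        -0.629
#> wave_duration            0.423          -0.629         1.000

focus_anova(metrics)
#> <wave_anova> wave_amplitude (within): F(1, 5) = 8.91, p = 0.0307, eta^2 = 0.64
#>   condition means: external 133.5, internal 125.1
```

The negative amplitude–COV correlation is the induced coupling of the
default generator: participants who produce larger waves propagate them
less constantly. The ANOVA tests the attentional-focus effect
(external vs internal) on per-participant condition means with
repeated-measures degrees of freedom (1, n − 1).

Every generated cohort carries its ground truth
(`attr(metrics, "truth")`), so recovered quantities can always be checked
against the parameters that produced them.

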