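# roomtrack

Room-level indoor localization from Bluetooth-beacon proximity and
wrist-worn accelerometry.

Behavioural scientists increasingly need to know not just *what* and
*how much* people move, but *where*: which room of a home, office or
clinic a behaviour happens in. GPS is useless indoors, and most people
spend most of their day indoors. A practical compromise instruments the
building with fixed Bluetooth low-energy (BLE) beacons and has the
participant wear an accelerometer that also logs the received signal
strength (RSSI) of nearby beacons at 10-second epochs. `roomtrack`
implements the full analysis chain for such data: a graph-constrained
Bayesian filter that turns the noisy RSSI stream into a room-level
position trace, a jerk-based activity classifier, an evaluation suite
against criterion (e.g. video-coded) traces, and a synthetic-trial
generator for testing the whole pipeline without hardware.

## The algorithm

The building is modelled as a graph of *N* grouped areas (rooms, social
areas, corridors, a stairway) whose edges are walking pathways, encoded
in a sparse adjacency matrix *A* with *a*<sub>ij</sub> = 1 when areas
*i* and *j* are connected (and on the diagonal). The walker's position
is a probability vector *X<sub>k</sub>* over areas, updated each epoch
in two stages:

- **Predict.** *X̃*<sub>k+1</sub> = norm(*X<sub>k</sub> M*), where the
  transition-weight matrix *M* comes from one of three a priori motion
  models: model 1 uses *M = A* (constant weights); model 2 modulates the
  diagonal with the epoch's step count (*m*<sub>ii</sub> = 0.5 if more
  than 2 steps were taken in the 10 s, else 2.0); model 3 does the same
  but pins corridor diagonals at a constant weight *w* (corridor
  traversal is governed by corridor length, not step count).
- **Update.** Each beacon's RSSI maps to a proximity probability (1 at
  or above −45 dBm, 0 below −90 dBm, linear between); per-area maxima,
  normalized, give the measurement vector *Y*<sub>k+1</sub>, and
  *X*<sub>k+1</sub> = norm(*X̃*<sub>k+1</sub> ⊙ *Y*<sub>k+1</sub>).

Three exception rules make the recursion robust: a measurement that is
inconsistent with the motion model (all-zero posterior) resamples the
state to uniform and holds the reported area; a silent epoch (no RSSI
at all) performs no update; and an anti-hopping rule only lets the
reported area switch once the new area has been stable for 2 samples
(20 s), suppressing single-epoch flicker between adjacent rooms.

Activity is summarized per epoch by a jerk-proportional metric (moving
SD of the acceleration magnitude, window 5 samples at 100 Hz, averaged
over 1000-sample blocks) classified into low/middle/high by k-means,
and localization quality is scored by a transition/nontransition error
decomposition (*e*<sub>t</sub> = 100 *ê*<sub>t</sub>/*T*<sub>t</sub>,
*e*<sub>nt</sub> = 100 *ê*<sub>nt</sub>/*T*<sub>nt</sub>, overall
*e* = 100 (*ê*<sub>t</sub>+*ê*<sub>nt</sub>)/*T*), dwelling-time
agreement (ICC(A,1), linear regression with SSE/R²/RMSE) and
time-weighted confusion matrices.

## Worked example

```r
library(roomtrack)

g <- read_beacon_map(example_map())   # packaged two-floor office map
g
#> Area graph: 14 areas, 14 pathways, 17 beacons
#>   kinds: corridor=6, room=5, social=2, stairs=1

trial <- simulate_trial(g, trial = 1, seed = 42, accel = FALSE)
trial
#> Synthetic trial 1: 156 epochs (1560 s) at 1.4 m/s, seed 42
#>   RSSI rows: 435; noise 4.0 dB, glitch 2%, dropout 5%

fit <- localize(g, trial$rssi, trial$steps,
                model = motion_model("model3", w = 1.0))
summary(fit)
#> Localization of 156 epochs ( 1560 s ) under model3
#> Exceptions fired: 13 ; epochs corrected by anti-hopping: 12
#> Dwelling time by area (s):
#> 1R1 1S1 2S1 2R2 2R1 1R2 1R3 1C1
#> 360 210 210 200 190 180 180  30

error_report(fit, trial$truth)
#> Trial of 1560 s: transition 300 s, nontransition 1260 s
#>   e_t  (transition error)          : 43.33 %
#>   e_nt (nontransition error)       : 0.00 %
#>   e_bar (transition share of trial): 8.33 %
#>   e    (overall relative error)    : 8.33 %

dwelling_agreement(fit, trial$truth)
#> Dwelling-time agreement over 17 visits
#>   regression  p1 = 1.0135 (0.9797-1.0473), p2 = -8.886 (-13.153--4.619) s
#>   ICC(A,1) = 0.9946, mean difference = -7.65 s
#>   all visits      (n= 17): SSE=483 s^2  R2=0.9963  RMSE=5.67 s
#>   dwell > 100 s  (n=  8): SSE=147 s^2  R2=0.0222  RMSE=4.94 s
```

Reading the output: the filter dwelt in the right rooms for the whole
walk — all misclassified time sits inside the ±1-epoch transition
windows (`e_nt` = 0%, `e_t` = 43%), the known weak spot of a 0.1 Hz
proximity stream, where a room change can fall between samples. The
dwelling-time regression slope is ~1 with a small negative intercept
(transitions shave seconds off each visit), and the absolute-agreement
ICC is high. `plot(fit, trial$truth)` draws the step-plot comparison,
`confusion(fit, trial$truth)` the time-fraction confusion matrix, and
`plot_lasagna(fit, activity_profile(trial$accel))` the area-by-activity
time heatmap.

A command-line front end wrapping the same functions ships in
`inst/cli/roomtrack` (subcommands `simulate`, `localize`,
`classify-activity`, `evaluate`, `plot`).

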