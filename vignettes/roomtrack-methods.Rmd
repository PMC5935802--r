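---
title: "Graph-constrained Bayesian room tracking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-constrained Bayesian room tracking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roomtrack)
```

This vignette is the package's own account of the method: the model and
its assumptions, the parameters that matter, what the synthetic-trial
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The state-space model

The tracked quantity is discrete: which *grouped area* of a building a
person is in. Beacons serving the same social area or corridor are
grouped, so the state space is the set of `N` areas, not the set of
radios. A probability vector `X_k` over areas is carried through a
predict/update recursion at the proximity stream's epoch interval
(10 s, the receiver hardware's fastest proximity rate):

* predict: `X~_{k+1} = norm(X_k M_k)`;
* update: `X_{k+1} = norm(X~_{k+1} ⊙ Y_{k+1})`, with `⊙` the pointwise
  product;

`X_0` is uniform, `norm()` divides by the vector sum, and the reported
area is the posterior argmax (ties broken towards the lowest area
index — a stable, documented rule that in practice only fires on
degenerate inputs). This is a hidden-Markov-model filter whose
transition structure is *constrained by the floorplan*: `M_k` is zero
wherever the adjacency matrix `A` is zero off the diagonal, so
probability mass can only flow along walking pathways. The diagonal of
`A` is set to 1: staying put must always be representable, otherwise
the self-transition weights of the motion models would have nothing to
act on.

Assumptions worth stating plainly:

* movement between epochs is at most one pathway hop (10 s is short
  relative to room-to-room travel, marginal for fast corridor walking);
* RSSI is informative about *which* area is closest, not about exact
  distance — no fingerprinting or propagation model is fitted, because
  static RSSI models transfer poorly across real, cluttered buildings;
* floors do not leak: a beacon on another floor is either inaudible or
  so attenuated that grouping by floor is safe.

## The three motion models

| model | off-diagonal | diagonal |
|---|---|---|
| 1 | `a_ij` | 1 (constant weights, `M = A`) |
| 2 | `a_ij` | 0.5 if steps > 2 in the epoch, else 2.0 |
| 3 | `a_ij` | as model 2, but corridor rows fixed at `w` |

The step threshold of 2 steps per 10 s separates incidental shuffling
from actual walking. The printed rule is implemented exactly as stated:
*more* than 2 steps halves the self-weight (walking: likely to leave),
2 or fewer doubles it (stationary: likely to stay). Corridors are the
exception motivating model 3 — whether one leaves a corridor within an
epoch depends on corridor length, not on whether steps were taken — so
corridor self-weights are pinned at `w`, with `w = 1` neutral and the
grid 0.25–1.25 (step 0.25) explored by `sweep_corridor_weight()`.
Stairs rows are treated like rooms (step-modulated), not like
corridors: the corridor rationale (length-dominated traversal) does not
obviously apply to a stairwell, and the stairway area in the packaged
map is compact. This was an open reading; treating stairs as corridor
in model 3 is a one-line change (`kind: corridor` in the map).

A missing step-count epoch is treated as 0 steps with a warning — the
conservative "likely stationary" prior — rather than an error, since
device exports do drop epochs.

## From RSSI to a measurement vector

Two anchors are empirically solid for wrist-worn BLE receivers: inside
1 m the reading does not exceed −45 dBm, and below −90 dBm the link
drops. Between them the proximity probability is linear in dBm,
`y = (rssi + 90)/45`, clipped to [0, 1]. The exact functional form in
between is not identifiable from the anchors alone; the linear map is
the simplest monotone choice consistent with the inverse
distance–RSSI rationale, and it is *pluggable* (`loc_config(rssi_map =
...)`) so a log-distance inversion can be swapped in without touching
the filter. Readings below −90 dBm occasionally present in files are
mapped to 0, not rejected.

Areas holding several beacons aggregate by the **maximum** mapped
probability — nearest-beacon logic; summing would make an area more
probable merely for containing more radios. Within an epoch, repeated
readings of one beacon keep the maximum. The per-area vector `y` is
normalized by its sum `c`; `c = 0` means "no detection this epoch" and
is flagged rather than divided by.

Multiple receivers (the deployment wears several) are filtered
independently; `majority_vote()` offers an optional post-hoc fusion.
How the original deployment fused its four receivers is not specified
anywhere authoritative, so the package keeps fusion out of the filter.

## Exception management

1. **Inconsistent measurement** (`c != 0` but the predicted support and
   the measured support are disjoint, so the posterior product is zero
   everywhere): the state is resampled to uniform and the *reported*
   area held at the previous epoch's. The trigger is operationalized as
   the all-zero product — the only machine-checkable reading of "the
   previous estimation does not fit the motion model". Both halves of
   the printed remedy are applied: probabilities reset, report held.
2. **No measurement** (`c = 0`): no update is performed; state and
   report carry forward.
3. **Anti-hopping**: the reported area switches to a new area only once
   it has persisted for `stable_len = 2` consecutive samples (20 s),
   and then retroactively from the first sample of the stable run.
   Whether the original smoothing was online-delayed or retrospective
   is not stated; the retroactive reading was chosen because the
   package processes recordings offline, where a 1-epoch lookahead is
   harmless and gives cleaner transition timing. `norm()` of an
   all-zero vector is undefined by design; every such occurrence must
   route through rule 1 (this is asserted in tests).

## Evaluation machinery

A transition period is the ±1-epoch window around each criterion-trace
area change: the verbal definition ("when the receiver moved from one
room to the next") has no natural epoch extent, and the 10-s sampling
makes one epoch the natural atom — a room change can genuinely be
recorded one sample early or late. Misclassified seconds are
accumulated separately over transition and nontransition epochs and
expressed relative to `T_t`, `T_nt` and the trial total `T`
(`error_report()`); zero-duration denominators yield `NA`, never 0.
The "transition share of trial" statistic divides the *transition*
error seconds by `T` — the quantity's name and the published per-trial
arithmetic both fix that numerator.

Dwelling-time agreement pairs **per visit** (continuous occupancy bout
of the criterion trace), not per area: visit-level pairing is what
produces the ~200 measurement points a multi-trial session yields, and
it exposes the quantization penalty of short visits. The regression
`predicted = p1·truth + p2` reports coefficients with 95% CIs and the
regression's SSE/R²/RMSE; systematic offsets are deliberately left to
the ICC — ICC(A,1), single-rater, absolute-agreement, two-way mixed —
which punishes them. The ICC is computed from the two-way ANOVA mean
squares directly (no external ICC package is required) and is
cross-checked in the tests against an independent `aov()`-route
computation. Stratification at 100 s dwelling (≈10 samples,
quantization error below 10%) separates robust long visits from
noisy short ones.

Confusion matrices are time-weighted and row-normalized by true-area
occupancy, in an all-epochs and a nontransition-only variant.

## The synthetic-trial generator

`simulate_trial()` stands in for recorded walking trials. What it
emulates:

* **Protocol presets.** Trials 1–3 walk a prescribed route through
  every room and social area and back to the start at 1.4 / 0.9 /
  2.0 m/s with dwells of at least 180 / 120 / 60 s; trial 4 draws a
  random route, dwells (30–200 s) and speed. Travel times come from
  per-edge walking distances (metres) on the map.
* **RSSI.** Log-distance path loss (`P_1m = −45` dBm, exponent 2.5 —
  a standard indoor value) plus **multi-wall attenuation**: 14 dB per
  area boundary between walker and beacon. The wall term is what gives
  an in-room beacon its decisive margin over the corridor beacon behind
  the door; without it, graph distance alone under-separates areas and
  no measurement could dominate the floorplan prior, which is not how
  enclosed rooms behave. Gaussian dBm noise (σ = 4), readings below
  −90 dBm dropped (as the radio does), 2% of epochs get a +15 dB glitch
  on a non-adjacent beacon (reflection/scattering), 5% of epochs drop
  out entirely, and cross-floor beacons are suppressed.
* **Motion.** Steps at cadence speed/0.7 m per walking second plus 0–2
  incidental steps (dwelling epochs 0–2 by construction); 100 Hz
  triaxial acceleration as 1 g gravity plus sensor noise plus a
  cadence-frequency oscillation whose amplitude grows with speed.

What it does **not** emulate: real multipath fading and body shadowing
(the dominant error source in the field), receiver-orientation effects,
beacon transmit-power drift, clock skew between streams, and real gait
variability. Passing tests on this generator therefore demonstrate the
*algorithmic* properties — correctness of the recursion, exception
handling, error decomposition, and graceful degradation under the
modelled imperfections — not field accuracy in any particular building.

All generator parameters are exposed; the defaults above are the fixed
study conditions used by the test suite and the acceptance script.
Every stochastic element derives from one seed, and regeneration is
bit-identical.

## Numerical and degenerate-input choices

* The moving SD of the jerk metric is **centered**, uses the sample
  (n−1) denominator, and shrinks its window at the series boundaries;
  none of this is derivable from the metric's verbal definition, so the
  semantics are frozen by an oracle test (naive per-window
  recomputation to 1e−10). A trailing partial 1000-sample block is
  dropped; a series shorter than one block yields an empty result with
  a warning.
* `classify_levels()` seeds k-means with quantile-spread centres rather
  than random restarts: the fit becomes deterministic and independent
  of epoch order (random restarts were observed to break permutation
  equivariance on weakly-clustered metrics). Clusters are relabelled by
  ascending centre, so the level mapping is monotone in the metric.
  Fewer than 3 distinct metric values is a refused degenerate input.
* Epochs are half-open `[t, t + 10 s)`; timestamps off the epoch grid
  are a hard error naming the offending lines. RSSI epochs are
  authoritative; step epochs join on the epoch index.
* MAP ties break to the lowest area index; `smooth_hops()` on an empty
  trace returns an empty trace; an empty RSSI stream yields an empty
  localization.

## Problem sizes in the test suite

The suite exercises the filter against a literal brute-force recursion
on 200 random graph/stream cases (N ≤ 4, T ≤ 6), fuzzes normalization
over a 10,000-epoch stream, checks the anti-hopping invariant over
1,000 random noisy runs, and evaluates the full pipeline on the
packaged 14-area map over 20 simulation seeds × 3 trial presets × 3
motion models, plus the 5-point corridor-weight grid. These sizes were
chosen to make the checks statistically meaningful while keeping the
default test run comfortably interactive.

## Known limitations

* Transition-epoch error is intrinsically high at a 0.1 Hz proximity
  rate: a room change inside a sample interval is unobservable, and
  the anti-hopping rule adds up to one epoch of reporting delay by
  design. The error decomposition separates this from dwelling
  performance rather than hiding it.
* The graph abstraction carries no coordinates; anything requiring
  within-room position is out of scope.
* Activity levels are recording-specific (k-means per recording, as the
  protocol prescribes); they are not comparable across recordings
  without external calibration.
* The beacon-count bookkeeping of real deployments (receivers doubling
  as beacons, beacons shared across floors) is represented only as far
  as the packaged example map needs; the map format, not the code,
  carries such conventions.
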