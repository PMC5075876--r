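---
title: "The looming-detector input circuit: model, assumptions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The looming-detector input circuit: model, assumptions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgmdnet)
```

`lgmdnet` has two halves. The first is a discrete-time retinotopic network
model of the input pathway of a locust lobula giant movement detector (LGMD):
photoreceptor-like P-units on a hexagonal array drive trans-medullary
afferents (TmAs) that excite local LGMD-input units and, through reciprocal
synapses with their neighbours, pass lateral inhibition (L-inhibition) to
neighbouring columns and self-inhibition (S-inhibition) back onto their own
column. The second half quantifies the electron-microscopy connectome that
motivates that wiring: active-zone lengths measured as serial-section spans,
synapse densities per membrane area and per dendrite length, TmA connectivity
matrices, reciprocity, growth-scaled whole-neuron totals, and Mann-Whitney U
comparisons. A seeded synthetic-connectome generator stands in for tissue so
every metric can be tested end to end.

## The retina: a hexagonal array of P-units

`hex_array()` builds a roughly circular patch of units on an axial
("pointy-top") hexagonal lattice, added ring by ring around a central unit;
a partially filled outer ring is completed clockwise starting due up, so any
unit count gives one deterministic layout. The default 250 units at 3.3
degrees between neighbouring centres span roughly plus/minus 30 degrees of
visual field. The 3.3-degree spacing is wider than a real locust
inter-ommatidial angle; it is kept as a parameter, and all geometry uses a
planar small-angle map (azimuth `atan(x/d)`, elevation `atan(y/d)`,
independently) rather than a spherical eye. Silhouettes are rasterized with a
centre-in-polygon rule by default (a centre exactly on the boundary counts as
covered); a fractional rule — at least half of a fixed 13-point stencil over
the unit's hexagonal cell inside the polygon — is available for sensitivity
analysis.

## Stimuli

Three trajectories are provided, all sampled at 1 ms: a loom
(`make_loom()`, default a 75 mm square approaching at 10 m/s from 500 mm over
400 mm, hence 40 frames and a kinematic constant `l_over_v(75, 10)` = 3.75
ms), a near miss (same radial kinematics with a constant lateral offset,
default 100 mm), and a translation (`make_translation()`, default a 70 x 20
mm rectangle — 70 mm along the motion direction, 20 mm vertical — moving at
0.8 m/s for 90 ms at a constant 100 mm, crossing the field centre at 45 ms).
The printed description of the translating stimulus in the source anatomy is
internally inconsistent (its path length and angular velocity cannot be
reconciled with its speed, distance and duration); we honour speed, distance
and duration and leave all three configurable. The per-frame subtense
metadata is the vertical subtense `2*atan(half_height/distance)`, which is
constant for a translation and strictly increasing for a loom.

## The network

One step per millisecond:

1. **P-unit pulses.** A unit emits a unit-amplitude 1 ms pulse at every frame
   where its binary coverage changes (onset or offset; onset-only is an
   option). The first frame is the baseline, so an object standing still
   produces no input until it moves.
2. **Excitation.** Each pulse excites its own LGMD-input unit `E_delay_ms`
   (default 1) later with amplitude 1.
3. **L-inhibition.** When enabled, each pulse dispatches
   `L_total_gain / L_spread` (default 2.0/6, i.e. 200 x 1/6 % of the pulse)
   to each *existing* lattice neighbour — border units dispatch less in
   total, with no renormalization — arriving `L_delay_ms` (default 2) later
   and decaying exponentially with `L_decay_tau_ms` (default 3).
4. **Rectification.** Unit activation is `max(excitation - inhibition, 0)`.
5. **S-inhibition.** When enabled, a unit whose activation exceeds
   `activation_threshold` (default 0) becomes refractory: its combined input
   is clamped to zero for the next `S_persistence_ms` (default 7) steps.
6. **Output.** The LGMD's instantaneous output is the sum of unit
   activations; the headline trace is a leaky integral with
   `output_integrator_tau_ms` (default 8). Both series are always returned.

The excitatory and inhibitory delays and the inhibitory decay shape are not
printed anywhere for the original network; the defaults above (excitation
leads inhibition by 1 ms; exponential decay) are this package's choices, are
reported in every result's metadata, and are freely configurable. The gain
reading "total 200% split equally over six neighbours" follows the printed
product form. Determinism is strict: the network contains no randomness, and
repeated runs are bit-identical.

`condition_battery()` runs the four inhibition conditions (none, L-only,
S-only, both) on one movie; `divergence_time()`, `suppression_index()` and
`persistence_sweep()` compute the derived comparisons.

## What the model reproduces, and what it cannot

Because a unit pulses only when its binary coverage flips, a growing loom
excites each unit at most once. Two consequences follow exactly (to floating
point): S-inhibition alone has no effect on a loom, and inhibition can only
reduce output, giving the pointwise ordering none >= L-only >= both and
none >= S-only >= both for every stimulus. The loom response also outgrows a
translation of matched final image height, because looming pulses concentrate
into a final burst that the leaky integrator sums, while translation spreads
the same kind of pulses thinly over the whole motion.

The same single-event property is a real limitation. For the default
translation, a unit's two input events (edge arrival, edge departure) are
87.5 ms apart, so a refractory clamp of 3-12 ms can never act twice on the
same unit: S-only suppression of the translation response is exactly zero,
and the persistence sweep is flat — its saturation point degenerates to the
smallest persistence swept. Reported behaviour of the original network
(S-effects on translation beginning a few ms after motion onset, suppression
proportional over 3-7 ms of persistence) requires re-excitation of a unit
within a few milliseconds, i.e. a graded luminance-change photoreceptor that
fires on every frame an edge crosses its field. That variant, however, would
destroy the exact loom null above, and no mechanism we could construct
satisfies both observations at once under transition pulses; the package
implements the transition-pulse model and exposes every constant so the
alternative can be explored. For the same reason the measured L-only
suppression of the translating response (about 0.24 of the final output
under the defaults: each transient excitation overlaps decayed inhibition
from only the two or three neighbours that pulsed within the last few
milliseconds) is weaker than the halving reported for the original network,
and the time at which L-inhibition first alters the translation output
(6 ms under the default delays) is earlier than the reported 12 ms —
both quantities depend directly on the unprinted delay and decay constants.
The acceptance suite computes all of these directly and does not hide the
discrepancies. Acceleration-dependent latency shortening, feed-forward
inhibition onto distal dendrites, GABAergic microcircuit dynamics and
spiking biophysics are out of scope.

## The connectome half

`az_length()` converts a serial-section span to nanometres (span x
thickness, 70 nm sections by default). `surface_density()` uses an open
cylinder `pi * d * L` when no measured area exists; measured areas always
take precedence, because printed regional densities are generally not
recoverable from printed diameters and lengths alone. `per_facet()` divides
whole-neuron totals by the 8134 facets of the adult eye, reporting counts to
the nearest integer and areas to one decimal. `grow_dendrites()` applies the
11% last-moult growth only to segments below the per-neuron diameter
thresholds (5 um for LGMD 1, 7 um for LGMD 2), and `total_synapses()`
multiplies segment areas by diameter-class densities, reporting to the
nearest thousand. `mann_whitney_u()` uses midranks, an exact two-sided p by
full enumeration when the pooled sample is at most 16 (ties handled
correctly, which the standard exact routine declines), and a tie- and
continuity-corrected normal approximation otherwise.

"Median connectivity" is the median over TmAs of distinct-partner counts,
and the per-TmA connectivity product is (max partners) x (max synapses per
connection). Records spanning a single section are kept (block-face imaging
misses them; transmission EM sees them); `degrade_records()` applies that
censoring explicitly so its upward bias on mean az length can be measured.

## The synthetic generator

Only medians, ranges and means are known for the real tissue, so the
distribution families are package choices, all exposed in `synth_params()`:
boutons per TmA uniform on 2..5; distinct partners per TmA truncated
geometric on 1..6; synapses per connected pair truncated geometric on 1..7
with the success probability 0.45 chosen so the realized median is robustly
2 at the default 87 TmAs; active-zone spans 1 + Poisson with the rate set by
the target mean az length (107 nm for LGMD 1 volumes, 155 nm for LGMD 2, at
70 nm sections). Every TmA-TmA synapse is dyadic onto the volume's LGMD;
reciprocal pairs carry at least one synapse each way; boutons without a TmA
partner still synapse onto the LGMD, which keeps the median output synapses
per bouton at 1. LGMD 2 volumes additionally exchange synapses with
GABAergic processes. All randomness flows from one integer seed and output
tables are byte-identical per seed.

The generator emulates the *statistical* structure of the terminal
plexus — counts, medians, maxima, span distributions, reciprocity — not its
spatial embedding, bouton morphology or imaging noise. Tests that pass on
synthetic volumes therefore validate the bookkeeping and the estimators,
not the biology of any particular reconstruction.

## Numerical choices and problem sizes

Ties on polygon edges count as covered; degenerate (zero-area) silhouettes
cover nothing rather than erroring. Excitation or inhibition scheduled past
the last frame is discarded so all conditions are compared over the same
axis. The divergence criterion defaults to 1% of the reference peak on the
integrated trace; the sweep saturation point is the smallest persistence
within 1% (relative) of the sweep's maximal suppression. The test and
acceptance workloads use the full 250-unit array with the reference 40 ms
loom and 90 ms translation, the default 87-TmA generator, 100-seed recovery
checks, and exhaustive Mann-Whitney enumeration up to pooled samples of ten;
a full battery runs in well under a second on one core.
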