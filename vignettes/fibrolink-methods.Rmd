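---
title: "Non-local myocyte-fibroblast coupling: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-local myocyte-fibroblast coupling: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibrolink simulates a two-dimensional sheet of human ventricular tissue in
which a scar — a region whose myocytes are completely uncoupled from their
neighbours — is electrically bridged to the surrounding myocardium only by
gap-junction links through a layer of fibroblast units. The links are
spatially non-local: a fibroblast unit sitting on the scar may attach to
grid points up to a cutoff distance `l_max` away, including points outside
the scar. The package provides the cell models, the link-topology
generator, the monodomain solver, the pacing protocols and the analyses
needed to study how such links create a *dynamic border zone* around the
scar and under what conditions rapid pacing then produces reentry.

This vignette records the science and every consequential design decision.
All empirical numbers quoted here are computed by the package's test suite
or by `scripts/acceptance.R`; nothing is asserted that the code does not
reproduce.

## Cell models

**Myocyte.** Each lattice point carries a ten Tusscher–Panfilov (2006,
"TP06") epicardial human ventricular myocyte: 12 membrane currents
(I~Na~, I~to~, I~K1~, I~Kr~, I~Ks~, I~CaL~, I~NaCa~, I~NaK~, I~pCa~,
I~pK~, I~bCa~, I~bNa~), four calcium compartments with analytic buffering,
and dynamic intracellular Na^+^ and K^+^. Units are mV, ms, pA/pF and mM
throughout; the membrane capacitance of a grid unit is `cm = 150` pF.

The package uses the *shallow-restitution* variant of TP06: the default
epicardial conductances with the time constant of the L-type calcium
current's voltage-dependent inactivation gate (f) halved
(`tauf_scale = 0.5`). Restitution variants of this model are defined by
the maximum slope of the *dynamic* restitution curve — steady-state APD90
against steady diastolic interval under sustained pacing at decreasing
cycle length (`dynamic_restitution()`). The package reproduces both
tabulated reference slopes: the default kinetics give a maximum dynamic
slope of 1.14 (reference value 1.1) and the halved f-gate time constant
gives 0.77 (reference value 0.7). This two-point agreement is how the
variant was identified; it is asserted by the acceptance suite. The S1S2
protocol (`s1s2_restitution()`: an S1 train, then one premature S2) is
also provided — note that maximum finite-difference S1S2 slopes are
systematically steeper than dynamic slopes at short coupling intervals
(about 1.3 for the shallow variant at S1 = 1000 ms) and are not the
quantity by which the variants are defined. The shallow variant matters
scientifically: its flat restitution means the plain tissue model does
not break up under rapid pacing, so any reentry observed in the scarred
geometry is attributable to the M–F coupling, not to an intrinsic
myocyte instability.

**Fibroblast.** Fibroblast units follow the MacCannell "active" model:
four currents (time- and voltage-dependent Kv current with activation
gate r and inactivation gate s; an inward-rectifying K~1~ current; an
Na^+^/K^+^ pump; a sodium background), fixed intracellular
concentrations, and capacitance `cf = 50` pF per fibroblast — the scale
of a myofibroblast, the cell type that proliferates in injured tissue.
The unshifted model rests near −49.1 mV at dt = 0.01 ms.

Two resting-potential (V~FR~) variants are used, obtained by shifting
the voltage dependence of the Kv gating functions: *depolarized*
(V~FR~ = −24.5 mV, shift +34.78 mV) and *hyperpolarized*
(V~FR~ = −49.0 mV, shift +0.19 mV). The shifts are found once by
`calibrate_vfr_shift()` — a bracketed root search on the 20 s quiescent
steady state against the shift — and frozen as package constants so that
tissue runs are deterministic; the test suite re-derives them. The
search bracket is restricted to non-negative shifts, where the map from
shift to resting potential is monotone increasing: positive shifts move
Kv activation away from rest and depolarize the cell, while large
negative shifts also depolarize it (by removing Kv through its
inactivation gate), so the map is not monotone over negative shifts.

**Lumping.** A fibroblast *unit* is `nf` identical fibroblasts in
parallel (4, 6 or 8 in the study configurations). All share one membrane
potential, and each carries its own gap junction of conductance `gs` to
every grid point the unit is attached to. Consequently a unit injects
`nf * gs * (Vf - V)` pA into each attached myocyte grid point, while each
fibroblast of the unit receives `sum_k gs * (V_k - Vf)` across its
attachments, normalized by `cf` alone. The two sides are exact negatives
of each other at every instant (asserted per step by the solver). This
reading — effective unit-to-point conductance `nf * gs` — is what makes
the experimentally calibrated statement "8 fibroblasts per unit are
required for conduction" meaningful: more fibroblasts in parallel mean
more junctional conductance. The alternative reading (one junction per
unit, coupling divided by `nf * cf`) would make larger units strictly
worse conductors.

## Tissue model

The myocyte field obeys the monodomain equation: dV/dt equals the ionic
term −I~ion~/C~m~, plus the M–F coupling term, plus ∇·(D∇V). The
diffusion coefficient is `d_reg` = 0.001 cm²/ms outside the scar and
exactly zero inside it. The Laplacian is discretized in flux-conservative
five-point form with *face* diffusivities: a face is zero whenever either
adjacent point is scar, which implements no-flux conditions on the scar
rim exactly and conserves total voltage to machine precision (tested).
Domain edges use mirrored ghost points (no flux). `diffusion_term()` is
the reference R implementation of this operator; the C++ solver is tested
to reproduce it step for step.

Space and time steps default to dx = 0.25 mm and dt = 0.01 ms;
`sim_config()` enforces the explicit-scheme stability bound
4·D·dt/dx² < 1. Forward Euler advances the membrane potential and the
concentrations. Gating variables use Rush–Larsen exponential updates by
default: the TP06 I~Na~ activation gate has τ~m~ ≈ 0.001 ms near rest, so
plain forward-Euler gate updates diverge at any practical dt (a plain
Euler mode exists, `rush_larsen = FALSE`, for the fibroblast and for
experimentation). The 2D solver evaluates the voltage-dependent rate
functions from lookup tables (0.02 mV resolution, linear interpolation;
table-vs-direct agreement is tested to < 0.05 mV along a paced action
potential), which is the standard treatment in lattice monodomain codes.

Two scar modes are provided. *Active* scar cells keep their full ionic
model (they can fire when driven through M–F links); *inactive* scar
cells have I~ion~ ≡ 0 and evolve only through the coupling, behaving as
passive RC nodes (verified against the closed-form RC solution).

Initial conditions are the published resting states of both models,
followed by quiescent equilibration: 2 s for single cells. For 2D runs
the tissue default is 250 ms, which settles the only non-equilibrium
feature — the coupled rest of the link neighbourhoods, whose slowest
relevant time constant is the fibroblast membrane (≈ 25 ms at the study
conductances); longer equilibration changes nothing measurable and
quadruples desk-scale runtimes. The stimulus (not stated in the source
protocol) is −52 pA/pF for 1 ms — about twice diastolic threshold —
applied to a 3-point-deep strip along the pacing edge, or to a 5×5 block
for point pacing.

## Link topology

`generate_links()` implements the random non-local topology: each of
`n_units` fibroblast units receives one uniformly random *proximal*
attachment on the scar, then `k ~ Poisson(lambda)` candidate distal
attachments drawn uniformly from the candidate pool, accepted only if
within Euclidean distance `l_max` (default 2.5 mm) of the proximal point.
Rejected candidates are discarded, not redrawn — with the whole-lattice
pool and `l_max` = 2.5 mm the acceptance probability is ≈ π·l_max²/(area),
so even lambda = 50 leaves most units with a single attachment, matching
the reference degree distributions. Duplicate attachments of a unit to
one grid point are dropped (parallel junctions would merely sum). With
`l_max = 0` or `lambda = 0` every unit has exactly one attachment.

The candidate pool is the **whole lattice** by default (`pool =
"lattice"`): units whose proximal point lies near the rim can attach into
the surrounding tissue, which is precisely the mechanism that couples the
scar interior to the annulus around it — the border zone. A scar-only
pool is available behind the `pool` switch for comparison. Whether the
source study drew candidates from the scar only or from the lattice is
not decidable from its text; the lattice pool is adopted because links
from scar into the surrounding annulus are the stated substrate of the
border zone. Proximal points are sampled uniformly over the whole scar
(not only near its boundary) for the same reason the pool question is
open; uniform sampling is the minimal assumption.

Realisation ids 1–5 map to fixed seeds (202501–202505,
`realisation_seed()`), so "case 1…5" runs are reproducible. Generation is
bit-reproducible given (geometry, n_units, lambda, l_max, seed) and the
generator restores the caller's RNG state.

The generated ensemble is validated two ways: structural constraints are
asserted post-generation (proximal on scar, distances ≤ l_max, no
duplicates), and the degree distribution is compared bin-by-bin against
an independent Monte-Carlo simulation of the definition at 10^5 draws
within 3σ multinomial error.

## Protocols

**Line-scar conduction test.** A straight 5-column scar band crosses a
200 × 60 strip; deterministic bridge links couple its flanks: one unit
per row, proximal at the central scar column, attached to every scar
cell of the band in its row and to the nearest non-scar cell on each
side. A single plane wave is paced from the left edge; the run stops as
soon as the distal flank activates. The wiring density is a
reconstruction choice (the source figure is schematic): one unit per row
keeps the electrotonic load on each flank cell to `nf * gs`, the regime
in which the outcome is decided by the coupling strength; five units per
row converging on the same flank cells (160 nS at the reference
parameters) suppresses the approaching wave outright, and omitting the
in-band attachments under-loads the unit so that conduction already
occurs at 3 nS. With the adopted wiring the package reproduces the
reference thresholds at full scale: Gs = 2 nS blocks and Gs = 4 nS
conducts (delay ≈ 47 ms across the band) at nf = 8, and nf = 8 is the
smallest of {4, 6, 8} that conducts at Gs = 4 nS — both asserted by the
acceptance suite. The conduction chain is: flank activation charges the
unit (τ ≈ C~f~/(Σ gs)), the unit fires the uncoupled scar cells, their
action potentials recharge the unit, and the unit then drives the distal
flank over threshold; each stage fails gracefully below the conductance
threshold.

**Rapid pacing.** `paced_scar_run()` paces the circular-scar geometry
(radius 2 cm on the 200 × 200 lattice; an N = 400 domain is supported by
configuration) from one edge at T = 300 ms for 20 beats (6 s), then two
further periods as a die-out horizon, and classifies the outcome. These
full-study runs are hours-scale on one CPU; the package treats them as
first-class but the automated tests exercise the machinery at reduced
scale (60 × 60 lattices, short trains) and verify the full-scale
machinery through its parts.

**Sweep.** `sweep_spec()` encodes the study grid — lambda ∈ {40, 50, 60},
n_units ∈ {10 000, 20 000, 30 000}, realisations 1–5, Gs ∈ {1, 2, 3, 4}
nS — which enumerates exactly 180 runs (tested; the four conductance
values are fixed by the stated range 0 < Gs ≤ 4 nS and the reported
count). `run_sweep()` executes any such grid resumably (completed rows
are skipped on restart, per-row failures are recorded without aborting
the sweep) with an injectable runner for reduced-scale studies, and
`regime_fractions()` computes the per-axis NR/BR/PR marginals.

## Analyses

Activations are upward crossings of −40 mV with a 50 ms refractory
lockout, interpolated between samples. APD is APD90: from the upstroke
crossing to repolarization through V~rest~ + 0.1·(V~peak~ − V~rest~),
with the resting level and peak measured per beat (the resting level is
the diastolic minimum over the 20 ms before the upstroke, which keeps
the stimulus artefact out of the baseline). Beats that fail to
repolarize before the next activation are flagged, never silently
dropped. The −40 mV threshold and the 90 % criterion are community
defaults for this myocyte model; the source study does not state its
definitions.

Local restitution pairs CL~n~ with APD~n+1~ per cell along the sampling
line — the horizontal radial line from the scar centre toward the pacing
edge — and `apd_dispersion()` is max − min APD~n+1~ over line cells
within ±5 ms of a cycle length of interest. Cells are labelled
border-zone or normal-zone by distance to the scar rim (≤ l_max + 2·dx).

**Regime classification** (`classify_regime()`) codifies what the source
study judged from movies, so the rules are an explicit formalization
rather than the original authors' procedure. An activation is
*retrograde activity* when it is (a) **late** — more than T/2 after the
pacing front was due at that point, the front being referenced per point
from the first beat — and (b) **locally retrograde** — its
activation-time gradient along the pacing axis is negative within a
30 ms same-passage window. The label is **PR** if retrograde activity
reaches beyond the border-zone annulus (distance > l_max + 2·dx from the
rim), collides with a subsequent pacing front (arrives within the window
of the next front's due time), or persists past the die-out horizon
(two periods after the last stimulus); **BR** if retrograde activity
exists but stays confined and dies out; **NR** otherwise. All thresholds
(annulus margin 2·dx, lateness fraction 0.5, window 30 ms, horizon 2T)
are exposed arguments with these defaults. The classifier is
deterministic, works from the activation log alone (so it is independent
of snapshot cadence), and is validated against hand labels on a library
of constructed activation maps: plane wave, obstacle detour, quiescent,
confined retrograde ring, escaping retrograde cluster, and
front-collision — all matched in the test suite.

## What the synthetic configurations do and do not show

The named fixtures (`make_fixture()`) and the reduced-scale tests
exercise every code path on lattices from 60 × 12 to 200 × 200 with
deterministic or seeded-random links. They demonstrate correctness of
the numerics (conservation, antisymmetry, symmetry, convergence, closed
forms), reproduce the desk-scale reference quantities (restitution
slopes, fibroblast resting potentials, conduction thresholds) and
validate the classifier against constructed maps. They do not by
themselves reproduce the 180-run regime statistics or the
realisation-specific APD-dispersion values of the full study, which
require multi-hour 2D runs; the machinery for those runs is complete
(`run_sweep()` on the `paper_circle` fixture with default settings *is*
the full study), and the properties that the statistics rest on are what
the fast suite verifies. Real fibrotic tissue differs from all of these
configurations in ways the model deliberately ignores: no fibrosis-led
conduction slowing outside the scar, no fibroblast–fibroblast coupling,
no distance-dependent junction strength (G~long~ = G~loc~ here), no
mechanics, and motionless links.

## Problem sizes and runtimes

The test suite and the acceptance script choose sizes that keep a full
run on one CPU in the tens of minutes: the restitution scans use 25
beats per cycle length; the conduction tests run the full 200 × 60 strip
for up to 600 ms (blocked runs take the full window, conducting runs
stop at distal activation, ≈ 150 s and ≈ 55 s respectively); the
conduction-velocity scaling check refines the lattice to dx = 0.0625 mm
and dt = 0.0025 ms, where the quartered-diffusivity wavefront is
resolved and the CV ratio converges to 2 within 5 % (at the study
resolution of dx = 0.25 mm the slow wave spans about one grid point and
the discrete ratio is ≈ 2.5 — a resolution effect, not a solver error).

## Known limitations

* The forward-Euler/Rush–Larsen scheme at dt = 0.01 ms carries O(dt)
  bias (quantified: < 1 ms APD change under dt halving; ≈ 0.02 mV
  against the two-capacitor closed form).
* `classify_regime()` needs a clean first paced beat to reference the
  front; runs whose very first beat blocks cannot be classified.
* The classifier's R implementation iterates over activation events and
  is sized for desk-scale maps; full 200 × 200, 20-beat logs classify in
  minutes, not seconds.
* Scar boundaries are staircase approximations of the circle at dx
  resolution; the rim-distance computation treats rim points as the
  scar's boundary polyline.
* The Kv-shift calibration and the conduction thresholds are specific to
  dt = 0.01 ms and the stated stimulus; changing either re-opens the
  calibration.
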