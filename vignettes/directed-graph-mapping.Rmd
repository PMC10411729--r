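---
title: "Directed graph mapping of ventricular tachycardia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed graph mapping of ventricular tachycardia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgmap)
```

## The problem

Torsade de Pointes (TdP) is a polymorphic ventricular tachycardia arising
in long-QT settings.  Two mechanisms compete to explain how an episode
sustains itself once triggered: repeated focal discharges (ectopic beats
born from early afterdepolarizations) and reentry (self-sustained
circulating activation, functional "rotors" or loops around anatomical
obstacles).  Intramural needle mapping records unipolar electrograms at a
3D lattice of electrode terminals; from each trace a local activation time
(LAT) marks the moment the depolarization wavefront passes.  `dgmap` turns
those LATs plus the electrode geometry into directed activation networks
and reads the mechanism off the network's structure: directed cycles are
reentry, nodes with only outgoing arrows are focal origins.

## The activation graph

At a build time $t$, each usable electrode contributes its LAT nearest $t$
(within a window).  For every pair of neighbouring electrodes with LATs
$\mathrm{LAT}_x$, $\mathrm{LAT}_y$ and distance $\Delta d$, an arrow is
drawn from the earlier to the later electrode if and only if the apparent
conduction velocity lies in a physiological band:

$$ CV_{\min} < \frac{\Delta d}{|\Delta \mathrm{LAT}|} < CV_{\max}. $$

Slower apparent velocities mean the two activations belong to different
wavefronts; faster ones mean near-simultaneous activation whose direction
is not resolvable ($\Delta \mathrm{LAT}=0$ draws no edge).  Because LAT
increases strictly along every arrow, a single graph is acyclic even when
reentry is present: somewhere along a circuit a late LAT neighbours an
early one and the velocity gate removes that edge.  A second graph built
at $t+\Delta t$ places that discontinuity elsewhere on the loop, so the
union of the two edge sets (vertices identified by electrode) exposes
reentry as directed cycles.  Frames are built every `step` ms across the
episode.

Defaults and why:

* `cvMin = 0.2`, `cvMax = 2.0` mm/ms — the physiological ventricular
  conduction range; both configurable.
* `deltaT` — half the episode's median activation cycle length, so that
  for a loop of any phase the discontinuity moves to a different part of
  the circuit; resolved per episode at run time.
* `latWindow` — one median cycle length; wide enough to give every
  electrode one LAT per rotation, narrow enough not to mix rotations.
* `step = 50` ms — a few frames per rotation at typical TdP cycle lengths
  (150–300 ms).

## Geometry and neighbourhoods

The lattice mirrors the experimental preparation: horizontal layers 12 mm
apart, ten needles per layer, four terminals per needle spaced 4 mm.  The
absolute needle positions in the original experiments were estimated
visually, so the package defines two documented canonical layouts
(`buildGrid(1)`, `buildGrid(2)`) in a 60 × 60 mm short-axis section with
the LV cavity centred at (40, 30) mm, the RV cavity at (20, 30) mm and two
septal needles along x = 30 mm.  Each needle carries a wall tag (LV, RV,
septum) and the grid stores three vertical cavity axes (LV, RV, both) at
the centroids of the corresponding wall terminals.

Neighbours are the at most `maxNeighbors` nearest electrodes within
`maxDistance = 15` mm, symmetrized by union.  The radius connects
adjacent needles (10–15 mm apart) without bridging a cavity.  The budget
is 16: terminals 4/8/12 mm away along the same needle and in adjacent
layers number about a dozen, so a smaller budget would exhaust itself on
same-needle neighbours and sever the lateral inter-needle links that carry
wavefront propagation — loops could then never close.

## From cycles to distinct reentries

**Enumeration.** `findCycles()` implements exact elementary-cycle
enumeration (depth-first search anchored at each cycle's smallest vertex,
length cap `maxLen = 20`).  Exact enumeration is the reference semantics
and what the test-suite oracles check, but dense idealized activation
patterns admit combinatorially many elementary cycles (hundreds of
thousands in one frame) that all condense to the same physical reentries.
The per-frame pipeline therefore uses a representative set: for every
edge inside a nontrivial strongly connected component, the shortest cycle
through that edge, deduplicated by member set.  Every representative
cycle is an elementary cycle, and the representative set is nonempty
exactly when cycles exist — properties the suite asserts against the
exact enumerator on random graphs.

**Filtering.** Loops describing impossible trajectories are discarded:
(a) cycles whose non-adjacent segments pass within 0.5 mm of each other
after projection onto the cycle's best-fit plane (self-crossings; exact
crossings of 3D segments are measure-zero, hence the tolerance and the
projection), and (b) cycles with a vertex whose two incident segments
meet too acutely — the cosine of the angle between the vectors from the
vertex to its two cycle neighbours exceeds 0.75, a sharp doubling-back.
The angle is deliberately measured between the incident segments at each
vertex, not between successive direction vectors: the latter convention
would reject smooth rings (whose direction turns gradually) and keep
U-turns, the opposite of the intent.

**Condensation.** Cycle centroids are clustered with DBSCAN
(`dEps = 10` mm, `minPts = 2`), implemented in-package with the classical
self-inclusive core rule $|N_{\varepsilon}(p)| \ge minPts$.  A strict
$>$ variant is available (`strict = TRUE`), but with `minPts = 2` the
strict rule would demote a pair of coincident loop detections — the
commonest duplicate — to noise.  Noise points are kept as singleton
reentries, so an episode with one clean loop reports one reentry, not
zero.  Each cluster becomes one distinct reentry (member count, mean
centre).

**Classification.** A loop's projected polygon gets winding numbers
around the LV, RV and combined axes (sign ignored).  Winding around both
single-cavity axes, or around the combined axis while missing both single
axes (a loop circulating through the inter-cavity region without closing
through the septum), is bi-ventricular; around exactly one cavity,
holo-ventricular; otherwise localized.  The combined-axis clause is
needed because a convex ring around both cavities also winds around each
single axis, while a loop threading the septal gap winds around neither.

**Tracking.** No linking rule is inherited from the experimental
analysis, so the package declares one: greedy nearest-centre matching
between consecutive frames within `linkingRadius` (default `dEps`),
unmatched clusters starting new tracks.  Each frame covers one `step`, so
a track's interval is [first frame, last frame + step).  The
simultaneous-loop profile is computed on half-open intervals; fractions
are taken over the total time reentry is present and sum to 100%.

## Focal sources

Nodes with at least one outgoing and no incoming arrow are candidate
focal origins at their LAT.  Wavefronts entering the mapped region also
produce such nodes, so candidates are verified: with electrograms, the
positive excursion in the 30 ms before the LAT must stay at or below 10%
of the trace's mean peak amplitude ("no noticeable upstroke", mirroring
the 10% amplitude fraction of the LAT annotator); without electrograms, a
silence criterion requires no neighbouring activation in the 250 ms
before the candidate — longer than a typical tachycardia cycle, so sites
merely re-entered every rotation are not mistaken for quiescent origins.

Verified sources aggregate into per-electrode heatmaps.  Under spatial
randomness, the count on one electrode of $n$ sources over $e$ electrodes
is Binomial$(n, 1/e)$; `randomnessTable()` compares observed and expected
electrode counts per multiplicity and flags multiplicities observed in
the data but expected on fewer than 0.05 electrodes — occupancy that is
almost certainly impossible under the null, hence evidence of preferred
locations.  No formal goodness-of-fit p-value is attached; the table is
the deliverable.

## LAT annotation

A LAT is marked where the trace's first difference is most negative
within a sliding 200 ms window (at most one annotation per window by
construction; ties resolve to the earliest sample).  Each annotation must
reach 10% of the trace's average peak amplitude within ±10 ms — the
average peak being the mean of per-deflection absolute peaks, the only
self-contained per-electrode reading — and failing annotations are
rescued when a neighbouring electrode holds an accepted LAT within 10 ms
(the rescue tolerance is declared; no quantitative value is inherited).
Manual curation is a programmatic overlay of add/remove edits
(`applyEdits()`), not a GUI.

## Episode statistics

Episodes are labelled non-terminating (NT) at ≥ 10 s duration, otherwise
self-terminating (ST).  Group location is compared with an exact
Mann–Whitney test: $U = \min(U_1, U_2)$ with half credit for ties, and
one-/two-sided p-values from full enumeration of all
$\binom{n_1+n_2}{n_1}$ rank assignments (the normal approximation with
tie correction takes over beyond $10^6$ assignments).  Both sidedness
values are always reported; no claim is made about which convention any
particular published comparison used.

## The synthetic-data module

The generators emulate the mechanisms the detector must separate, with
known ground truth on the canonical grids:

* `genFocal()` — radial spread at constant velocity from a point origin,
  one wavefront per beat.
* `genPlanar()` — a plane wave; the negative control containing neither
  cycles nor interior foci.
* `genRotor()` — an idealized rotor: activation phase equals azimuth
  around a core axis, identical across rotations (no meander).
* `genMacroReentry()` — the same phase law around a cavity axis,
  restricted to the wall electrodes that encircle it (free wall plus
  septum for one cavity; both free walls, septum excluded, for a loop
  around both).
* `genElectrograms()` — RS traces as derivative-of-Gaussian wavelets
  (width 20 ms, unit peak) whose steepest fall sits exactly at the LAT,
  so the annotation rule is exactly invertible on clean traces; QS
  traces (focal origins, radius 6 mm ≈ one terminal spacing) as a
  monophasic negative sigmoidal step with slow recovery and no positive
  excursion.  Additive Gaussian noise is optional and seeded.
* `perturbEvents()` — seeded LAT jitter and whole-electrode dropout.

All generators are pure functions of (grid, parameters, seed).  Study
conditions used by the recovery tests: cycle length 200 ms, conduction
velocity 0.6–0.8 mm/ms, 4–8 rotations or 3–5 beats 300 ms apart — typical
of drug-induced TdP in large-animal preparations.

What passing tests show — and do not.  The generators are idealized:
stationary cores, constant velocity, no anisotropy, no meander, no
far-field potentials, noise only as additive Gaussian jitter.  Recovery
on these fixtures demonstrates the machinery is self-consistent
(ground-truth mechanisms are recovered, controls stay clean); it does not
demonstrate performance on experimental electrograms, where electrode
sparsity, meander and line-of-block pseudo-reentry remain the dominant
difficulties.

## Numerical choices and degenerate inputs

* Simultaneous neighbour LATs never draw an edge (direction undefined,
  velocity infinite).
* Episodes with no reentry time report mean loop count 0 and an undefined
  (NA) holo-ventricular fraction rather than 0/0.
* DBSCAN label assignment for border points reachable from two clusters
  follows discovery order, the classical ambiguity; tests compare against
  the closure semantics, not a fixed labelling.
* The focal-origin hull test uses the electrode bounding box; a convex
  hull would change nothing on these lattices.
* Grid JSON serialization round-trips numerically exactly (no digit
  truncation).

## Limitations

Meander tracking, discrimination of functional from anatomical reentry,
and absolute loop counting are out of scope: at 4–15 mm electrode
spacing the condensation of loops is suitable for comparisons between
episodes of the same preparation, not as an absolute physiological
measurement.  The canonical geometries are reconstructions; analyses of
real recordings should load measured coordinates through the same JSON
geometry interface.
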