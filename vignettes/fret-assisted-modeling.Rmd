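---
title: "FRET-assisted structural modeling with fretsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRET-assisted structural modeling with fretsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretsuite)
```

## The problem

Single-molecule FRET reports state-specific inter-dye distances with
uncertainties that can approach 1 Å, but a typical study measures tens of
distances for a protein with hundreds of residues.  Sparse distance sets
cannot determine a structure on their own; they can, however, *select*
among candidate conformations, *guide* a conformational sampler, and
*validate* the result — provided three questions are answered
quantitatively: which distances are worth measuring, how good is a model
given the data, and how should distance restraints act on a structure whose
dyes are blurred over a positional cloud. `fretsuite` implements one
coherent answer to all three.

## The dye model: accessible volumes

A dye on a flexible linker explores a positional cloud, not a point.
`compute_av()` models that cloud geometrically: a cubic grid (default
spacing 0.9 Å) covers a sphere of radius `linker_length + dye radius`
around the attachment atom; a grid point belongs to the accessible volume
(AV) if a sphere of the dye radius placed there clashes with no protein
heavy atom (standard van-der-Waals radii: C 1.7, N 1.55, O 1.52,
S 1.8 Å), and if the linker can reach it — the shortest path from the
attachment point through grid nodes with at least `linker_width / 2` of
clearance, computed by Dijkstra flood-fill over the 26-connected grid
graph with Euclidean edge lengths, is no longer than the linker.  Obstacles
cannot seal the source: a bubble of one linker width around the attachment
point is always traversable, reflecting that the linker physically emerges
from between the attachment atom's bonded neighbours.  With three dye radii
(default 3.5/4.5/1.5 Å) the AV is the union of the three single-radius
volumes at weight 1/3 each.  The accessible contact volume (ACV) variant
re-weights points whose dye sphere lies within a contact layer (default
3 Å) of the protein surface to a total weight calibrated, in practice,
from residual anisotropy; no default fraction is claimed.

Two observables derive from a pair of AVs.  `mean_RDA` — the
distribution-averaged inter-dye distance, what an intensity-based
measurement reports — is evaluated exhaustively when the point-count
product is at most 10^6 and otherwise by seeded Monte-Carlo pairs (default
100,000).  `Rmp` is the distance between the mean dye positions, the
quantity a mean-position restraint acts on.  The two differ systematically
(`mean_RDA >= Rmp` by Jensen's inequality), which the restraint generator
corrects for explicitly.

Distance uncertainties come from propagating a FRET-efficiency error
through `E(R) = 1/(1 + (R/R0)^6)`: `dR = dE (1+(R/R0)^6)^2 R0^6 / (6 R^5)`
with `dE = 0.06`, the typical efficiency error of modern single-molecule
measurements.  Far from the Förster radius this diverges — the measurement
genuinely carries no distance information there — so `dR` is clamped to
[0.5, 30] Å to keep chi-squared weights finite.  The divergence is a
feature, not a nuisance: it automatically down-weights insensitive pairs,
steering both screening and experiment design toward pairs measured near
`R0`.

## Model quality: chi-squared normalized to a confidence level

A conformer is scored against a measurement set by
`chi2 = sum(((R_model - R_ref) / dR_ref)^2)` with `N_dof = N_measurements -
N_fit.param` degrees of freedom.  The familiar reduced chi-squared
`chi2 / N_dof` has the drawback that one confidence level maps to different
values for different `N_dof`, so models of different complexity cannot
share one axis.  The package therefore normalises by the 68%-confidence
chi-squared bound: `chi2_n = chi2 / qchisq(0.68, N_dof)`.  By
construction `chi2_n = 1` marks the one-sigma level for *any* `N_dof`
(`test-acceptance.R` verifies the identity to 1e-9 for `N_dof` 1–30).
Screening (`screen_ensemble()`) keeps conformers with `chi2_n < 1` and
declares the result converged when all pairwise C-alpha RMSDs inside the
selection are below 3 Å.

Two bookkeeping rules matter.  First, `chi2_r` and `chi2_n` are refused —
not silently computed — when `N_dof <= 0`; an overfitted model has no
defined quality, and the error message says to add cross-validation pairs.
Second, every pair used to *guide* an optimization counts as a fitted
parameter, so quality claims about guided models must come from held-out
pairs (`run_guided()` takes an optional validation set and scores it with
`N_fit.param = number of guiding restraints`).

## Designing the experiment: expected model uncertainty

`expected_rmsd()` answers "how uncertain would the model be if we measured
exactly these pairs?".  Each conformer of a candidate ensemble in turn
plays the true structure: its simulated distances (with the
efficiency-propagated error model evaluated at its own distances) score
every conformer by chi-squared; the survival-function p-values weight the
pairwise RMSD matrix; the per-reference weighted means are averaged over
references.  The self term enters naturally (p = 1, RMSD = 0).  The
estimator is checked exactly against a naive triple loop in the tests.

Three selection algorithms minimise this quantity. Greedy forward
(`select_greedy_forward()`) adds the pair with the largest decrease per
step; greedy backward (`select_greedy_backward()`) starts from the full
pool and removes the least harmful pair, which is thorough but quadratic in
the pool; the conditional-entropy method (`select_mutual_information()`)
discretises each pair's distances over the ensemble into 3 Å bins
(about a typical `dR`; plug-in estimator, bits) and maximises the minimum
conditional entropy with respect to already-chosen pairs, in the spirit of
minimum-redundancy–maximum-relevance feature selection.
`choose_algorithm()` encodes the practical default: greedy forward under
six requested pairs, conditional entropy otherwise, backward only on
request and warned against above 10,000 conformers.  All three are
deterministic; ties break toward the lowest pair id.

`estimate_complexity()` runs the two-stage heuristic for the effective
parameter count of an ensemble: stage 1 selects pairs with
`N_fit.param = 0` until the target uncertainty is reached — the number of
pairs needed is the complexity estimate, each informative pair resolving
one effective coordinate; stage 2 fixes that count and continues the
selection, yielding the recommended total including cross-validation pairs
(always larger, since `N_dof` must be positive).  For rigid-body models the
analytic count `(N_bodies - 1) * 6 - N_bonds`
(`rigid_body_parameters()`) provides a sanity bound.

## Guided sampling

`run_guided()` wraps any topology-preserving proposal engine in a
Metropolis–Hastings loop on `chi2_n`: a proposed conformer gets fresh AVs,
model distances and a score; acceptance follows
`exp((chi2n_prev - chi2n_curr) / kT)` against a uniform draw.  `kT` follows
a triangular annealing schedule — linear ramps from a floor of 1e-3 up to
1 `chi2_n` unit and back, two cycles by default.  The endpoints and cycle
count are the method's convention; the linear ramp shape is this package's
choice, made for reproducibility.  The built-in `toy_hinge_engine()`
rotates the second of two rigid segments about a random axis through the
hinge C-alpha by a uniform angle step, rejecting inter-segment C-alpha
clashes below 3 Å (with an escape rule from already-clashed states so the
chain cannot deadlock).  One proposal corresponds to one Metropolis
decision.

Two numerical choices deserve note.  AVs are cached per labeling site and
recomputed only when the site's local backbone (attachment residue ±2)
moved by more than 0.1 Å — an optimization bounded by that tolerance, and
spot-checked against fresh computation in the tests.  Distance observables
inside one run are sampled with common random numbers (one fixed seed), so
the Monte-Carlo error becomes a smooth systematic offset shared by
neighbouring states instead of state-to-state jitter; without this, the
ranking of nearby conformers on a shallow landscape would be noise.

## Restraints for FRET-restrained MD

For all-atom refinement the package emits restrained-mean-position (RMP)
restraints rather than dye-atom restraints: a pseudoatom sits at each AV
mean position and is pseudobonded to the C-alpha and C-beta atoms of the
attachment residue and two residues to either side — ten anchors mid-chain,
fewer at termini, C-beta skipped for glycine — so restraint forces transmit
to the backbone instead of being absorbed by the soft linker.  The distance
restraint between two pseudoatoms is harmonic–linear: zero force at the
target, harmonic within one standard error, constant beyond, capped at
`F_max = 50 pN` to prevent forced unfolding.  Because measurements are
distribution averages while restraints act between mean positions, the
target is corrected by the model-computed offset:
`R_exp = R_ref - (mean_RDA - Rmp)`, both evaluated on the
restraint-generation conformer.

Collinear restraints could add up beyond the cap, so
`tune_force_constants()` scales constants down per pseudoatom until the
worst-case vector sum of cap forces (directions from current geometry) is
at most `F_max`; anchors then get ten times the site's tuned constant.
`write_restraint_file()` serialises the set as AMBER `&rst` namelists: the
declared dialect places the flat bottom at `R_exp ± dR`, parabolic walls
out to `2 dR` beyond, and force constants converted at 69.48 pN/Å per
kcal·mol⁻¹·Å⁻² under AMBER's `E = rk (r - r0)^2` convention, so the linear
tail reproduces the 50 pN cap.  Whether the cap engages at one or two
standard errors is ambiguous in the field's descriptions; this package uses
one.  MD execution is out of scope: the intended use is to regenerate the
restraints from simulation snapshots at the user's cadence (every 2 ns is
typical), and the JSON sidecar documents the topology-side requirements
(pseudoatoms excluded from nonbonded interactions).

## The synthetic benchmark and what it does (not) show

`hinge_spec()` defines a two-segment toy protein: an ideal C-alpha helix
with exact 3.8 Å virtual bonds and radial pseudo-C-beta stubs, bent at a
hinge residue.  The defaults are chosen once, as the package's study
conditions: 14 + 14 residues (a geometry whose full 0–90° bend range is
free of inter-segment clashes), dye linkers of 10 Å length and 3 Å width
with a single 3.5 Å radius, and `R0 = 30 Å` — both dye choices scaled to
the miniature so that the positional clouds and the sensitive distance
range match the toy's 15–45 Å inter-site distances, exactly as one would
match dye chemistry to a real target.  Reference data are simulated on a
target conformer with `dE = 0.06` error propagation
(`make_benchmark_case()`), optionally with Gaussian noise of that scale.

Problem sizes used by the test-suite were likewise fixed once: AV grids of
1.2–1.5 Å on the toys, 10,000–20,000 Monte-Carlo distance pairs, annealed
runs of 400 iterations, and ten-seed replication for the recovery check
(±40° starts recovering a 30° target hinge within 5°).  The recovered
quantity is the inter-domain *bend* angle; torsion of a segment about its
own axis barely changes inter-dye distances, so FRET cannot and does not
constrain it — a real limitation of distance-only data that the toy makes
visible.

What passing these tests shows: the statistics, estimators, selection
algorithms, sampler and restraint mechanics are internally consistent and
match independent oracles on systems where ground truth is computable.
What it does not show: performance on real proteins, with real side
chains, real dye photophysics (orientation factors, quenching, sticking
beyond the ACV layer), experimental calibration errors, or a production
conformational sampler — the toy proposer explores a two-body hinge, not
protein conformational space.

## Known limitations

* The AV model is geometric; no dye–surface energetics beyond the ACV
  layer weighting, no orientation-factor modeling beyond a fixed `R0`.
* Screening fits one conformer at a time; mixtures (ensemble-averaged
  observables across states) are out of scope.
* The three-radius weighting (equal thirds) and the ACV layer re-weighting
  are this package's explicit conventions; other AV implementations make
  closely related but not identical choices.
* `lddt_ca()` scores C-alpha distances only, with the 15 Å inclusion
  radius and 0.5/1/2/4 Å thresholds as defaults.
* Backward elimination recomputes the expected uncertainty for every
  candidate removal and is impractical for very large ensembles; the
  10,000-conformer warning in `choose_algorithm()` reflects that.
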