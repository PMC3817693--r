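---
title: "Density-guided loop rebuilding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided loop rebuilding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denseloop)
```

## The problem

A weak molecular-replacement (MR) solution provides a model-phased electron
density map that is noisy and biased toward the (partially wrong) search
model, yet still carries enough signal to guide rebuilding. Comparative
models threaded through a sequence alignment have two characteristic error
modes: residues absent from the alignment (gap segments, to be built from
scratch) and residues that are aligned but wrong — either displaced in
space relative to the target structure or carrying a mis-registered
alignment (an insertion slid into a secondary-structure element).

`denseloop` implements two Monte Carlo rebuilding protocols over the gap
segments of a threaded model:

* **Frozen-template protocol (`"2011"`)** — fragment torsions are written
  into a window overlapping the gap, movement propagates to a *cutpoint*,
  and the chain is re-closed geometrically by cyclic coordinate descent
  (CCD). Aligned residues, apart from a small flank (2–5 residues) around
  each gap, never move.
* **Whole-structure protocol (`"2013"`)** — the fragment is built in
  Cartesian space, rigidly superposed onto the current conformation over
  the window's flanking residues, spliced in, and the *entire structure*
  is relaxed by Cartesian minimization of a smooth low-resolution energy
  that includes bond-geometry restraints. The template backbone is free to
  move, which is what lets displaced or mis-registered template regions
  relax into the density.

Both protocols accept or reject proposals by the Metropolis criterion,
`min(1, exp(-dE/T))`, under a geometric cooling schedule.

## The low-resolution energy

The objective is a weighted sum of smooth, analytically differentiable
terms. These are deliberately simple stand-ins with the standard
qualitative behaviour of backbone-level (centroid) scores; every functional
form is C1 and passes finite-difference gradient checks (enforced by the
test suite at every term and for the weighted total).

* **Ramachandran** — `E = -log P(phi, psi)` with `P` a 360-degree-periodic
  mixture of anisotropic Gaussian basins (alpha at (-63, -43), beta at
  (-120, 130), left-alpha at (57, 47); sigmas 12/14, 30/22, 11/11 degrees;
  weights 1, 1, 0.35) over a uniform floor of 0.002. The floor bounds the
  penalty in disallowed regions and keeps the landscape smooth. A proline-
  specific basin is deliberately omitted.
* **Soft-sphere vdW** — purely repulsive `k (r0 - d)^2` below contact, over
  atom pairs two or more residues apart. Side chains are a single soft
  interaction centre at CB (glycine gets a pseudo-CB at the ideal
  tetrahedral position). Radii (N 1.40, CA/C 1.60, O 1.35, CB 1.80 Å) are
  reduced relative to full van der Waals radii so that native backbone
  contacts — in particular helix i,i+4 hydrogen-bond geometry — score
  exactly zero.
* **Backbone hydrogen bond** — donor N–H (amide H constructed on the fly
  from ideal geometry), acceptor carbonyl O:
  `E = -depth · exp(-(d_HO - 1.9)^2 / (2 · 0.3^2)) · cos^2(theta)` with the
  angular switch vanishing for N–H...O angles below 90 degrees; depth 2.
* **Bond geometry (`cart_bonded`)** — harmonic restraints on every backbone
  bond length, bond angle, omega planarity and the carbonyl/CB impropers
  against the packaged ideal internal coordinates (`ideal_geometry()`),
  with `k_len = 100 /Å^2`, `k_ang = 20 /rad^2`, `k_omega = 10 /rad^2`.
  Inter-residue C–N terms are kept across *geometric* breaks (bonded
  neighbours pulled apart, as after a fragment splice or a displaced
  template loop) so that such breaks are penalized and pulled closed by
  minimization; only structural gaps — residues that do not exist yet —
  disconnect the energy. This distinction is what makes the
  whole-structure protocol able to drag a rigidly displaced loop back: its
  junction strain is a large, smooth restoring force.
* **Density** — the fast spline score described below.

Default weights are rama 0.5, vdw 1.0, hbond_bb 1.0, cart_bonded 1.0,
density 0.05. The density weight is the one genuinely empirical number: the
fast score is an unnormalized sum over atoms, so its scale depends on the
map. The field construction standardizes the observed map (zero mean, unit
sd — the global normalization the masked score would have applied, folded
into a constant), and 0.05 then places typical per-proposal density-score
changes in the same few-units range as the geometric terms at the Metropolis
temperature T = 2, which keeps uphill acceptance meaningful. It was chosen
by balancing these scales on the packaged gap-recovery case and is exposed
through `default_weights()`.

## Density scoring

The observed map is an orthogonal P1 grid (`density_map`). Model density is
a sum of single-Gaussian atom kernels with `sigma = resolution / (pi *
sqrt(2))` and amplitudes proportional to electron counts (C 6, N 7, O 8,
CB 6); `simulate_map()` is deterministic and integrates to the summed
amplitudes.

Two scorers are provided:

* **Masked per-residue correlation** (`masked_residue_cc`) — the Pearson
  correlation of simulated vs observed density over voxels within
  `mask_radius` (default 3.2 Å) of each residue's atoms, recomputed from the
  current coordinates on every call. Robust, interpretable — and expensive,
  because the mask changes with every move.
* **Fast unmasked score** (`build_spline_field` + `fast_density_score`) —
  the per-atom cross-correlation `sum_v k(x - v) · rho_obs(v)` is
  precomputed for the whole map by FFT convolution and then evaluated (with
  analytic gradients) by separable tricubic interpolation on prefiltered
  cubic B-spline coefficients. The
  score is the negative sum over atoms; the correlation normalization is
  dropped and absorbed into the density weight. After the one-off field
  construction, each evaluation costs O(atoms), independent of map size —
  the test suite asserts a >5x per-call advantage over the masked scorer on
  a 100-residue fixture, and rank agreement (Spearman >= 0.9) with the
  global unmasked correlation over random perturbations.

**Numerical choices.** The convolution is computed on a grid `oversample = 3`
times finer than the map (map voxels enter as delta weights, so the FFT
product is *exactly* the discrete cross-correlation at the fine nodes). At
the map's own sampling, cubic interpolation of so narrow a kernel
(sigma ≈ 0.68 Å at 3 Å resolution) would carry ~3% off-grid error; at 4x
oversampling the measured error is below 1e-3 of the field maximum, the
bound the tests enforce. The field is stored as cubic B-spline
coefficients (recursive prefilter, pole $\sqrt{3}-2$): the spline then
reproduces node values exactly and is C2, so the analytic gradients agree
with central finite differences everywhere, including across cell
boundaries — a C1 basis such as Catmull–Rom fails that contract at the
knots. Maps are
expected to carry >= 4 sigma of padding (the simulators default to 5 Å) so
that FFT wrap-around stays negligible. Atoms outside the interpolable
interior are clamped to a 2-voxel margin and counted rather than raising an
error, so refinement excursions cannot crash a trajectory.

## Chain closure

`ccd_close()` implements cyclic coordinate descent: for each movable
phi/psi torsion in turn, the closed-form rotation that minimizes the summed
squared deviation of three anchor atoms — mobile, ideal-geometry copies of
N, CA, C of the residue after the cutpoint — from their fixed targets, with
per-step changes capped at 60 degrees and omega held at 180. Because the
mobile copy of that C atom depends on the continuation phi at the junction,
that phi is included as an extra closed-form degree of freedom; each step is
optimal for its torsion, so the anchor deviation is non-increasing sweep to
sweep (asserted by the tests). Bond lengths and angles are untouched (pure
torsion moves); carbonyl O and CB of moved residues are re-idealized after
closure. Defaults: tolerance 0.08 Å RMS over the three anchors, 100 sweeps.

CCD inherits the classic weaknesses of the 2011-era protocol on purpose: no
Ramachandran screening inside closure, and convergence to local minima on
hard (compressed-insertion) gaps. The rebuild driver retries a stalled
closure from jittered torsions up to twice per proposal; proposals that
still fail to close are rejected. The default cutpoint sits at the segment
*end* — one-sided, classic CCD onto the fixed downstream anchor — because
closure onto a freshly rebuilt far-side chain (mid-segment cutpoint)
stalled on a large fraction of proposals in the packaged cases; `"mid"` and
`"start"` remain available in `rebuild_config()`.

## Minimization

`cartesian_minimize()` descends on the Cartesian coordinates of the movable
residues with limited-memory BFGS (`stats::optim(method = "L-BFGS-B")`)
driven by the analytic gradients; energy and gradient are computed together
and memoized across the optimizer's paired calls. Budgets: 400 evaluations
per insertion heal, 2000 for the final relax (package defaults; the test
suite and the acceptance script run reduced budgets, stated below).
Torsion-space minimization is deliberately absent — moving to Cartesian
space with explicit bond restraints is the point of the whole-structure
protocol. `heal_insertion()` raises the cart_bonded weight to at least 1,
makes every residue movable, and flags the result `strained` if any bond
deviates more than 0.05 Å from ideal afterwards.

Minimization during rebuilding is global (the entire structure) with the
cheaper per-insertion budget — matching the protocol's intent — rather than
restricted to a neighbourhood of the gap.

The claim that the smooth centroid surface permits larger density-driven
movements than a stiffer, all-atom-like repulsion is demonstrated by a
controlled probe test (a movable 3-mer pulled by density past a frozen
helix: the soft surface crosses, a 10x stiffer one stalls at the barrier).
On the packaged rebuilding fixtures themselves the soft radii leave
trajectories essentially contact-free, so vdW stiffness does not measurably
change aligned-region displacement there — the barrier effect only engages
where paths graze other atoms.

## The rebuild driver

`run_rebuild()` threads the template, then processes gap segments of up to
`max_gap_len = 8` residues independently, left to right; longer or
unanchored segments are left as recorded breaks with a warning. Fragment
windows are drawn uniformly among windows overlapping the segment within
the flank-extended movable span; fragments come from the profile-free
picker below (25 picks per window). 3-mers serve segments of up to 4
residues, 9-mers the rest. Temperature starts at 2.0 energy units and cools
by 0.95 every 20 cycles. The final whole-structure minimization honours the
protocol contract: under `"2011"` only rebuilt/flank residues move (aligned
template coordinates are bitwise identical afterwards — a test asserts
this); under `"2013"` everything moves. A single seeded RNG drives the
whole trajectory; identical seeds give byte-identical results.

## Profile-free fragment picking

Fragment libraries are fixed-length (3 and 9) windows of backbone torsions
with their source sequences. Picking scores a candidate by the summed
BLOSUM62 substitution score between the query window and the fragment's
source sequence — a similarity, maximized; the "distance" reading is the
negated similarity, available via a flag. Ties break deterministically by
(source id, window position). This is the fast, profile-free alternative to
profile–profile fragment selection: cheaper and somewhat less accurate,
which is acceptable here because density-guided gap rebuilding is strongly
constrained by the anchors. The packaged benchmark quantifies the quality
property: top-25 picks are no worse in torsion RMSD than random picks
whenever the library contains near-native windows.

## The synthetic benchmark

`make_benchmark()` generates three cases (~60 residues each, sized so a
two-protocol multi-seed comparison runs in minutes on one CPU):

* **gap** — a clean 6-residue loop deletion;
* **register** — a 2-residue register-shift misalignment entering a paired
  beta-hairpin strand;
* **loop** — an 8-residue loop rigidly displaced by 4 Å (plus a small
  3-residue deletion so the Monte Carlo machinery is exercised).

Ground truths are built from basin-typical torsions with 3-degree Gaussian
noise; loops draw from a coil/turn pool and are resampled until clash-free.
Because torsion-space construction alone cannot produce *paired* beta
sheets (lever-arm effects), the hairpin cases place the second strand
geometrically (antiparallel, 4.8 Å sheet separation) and let the package's
own healing minimization zip the strands together; the result is accepted
only if it shows at least 4 inter-strand hydrogen-bond wells and an
essentially clash-free core.

Observed maps emulate a model-biased, noisy 2mFo−DFc-style map:
`(1 - b) · density(truth) + b · density(template) + noise` with bias
fraction `b = 0.3` by default. The noise is Gaussian per voxel, low-pass
filtered at the map resolution before scaling — white voxel noise would be
annihilated by the resolution cutoff inside the correlation and would leave
the scorers facing unphysically rough maps — and its amplitude is bisected
until the truth-vs-map correlation hits a requested target (packaged
default 0.6 at 3 Å, a regime in which the template errors matter but the
density still guides rebuilding; the generator supports harder settings
down to ~0.3). Fragment libraries carry a few near-native fragments per gap
window (truth torsions + 5-degree noise) in a tenfold excess of decoys
harvested from unrelated topologies.

What the generator does *not* emulate: crystallographic symmetry and
reciprocal-space noise structure (no structure factors), solvent, side
chains beyond CB, multi-chain packing, and sequence-dependent backbone
geometry. Passing the benchmark therefore demonstrates the machinery —
sampling, closure, minimization, scoring and selection — under controlled
error modes, not performance on real crystallographic data.

## Validation run sizes

The test suite and `scripts/acceptance.R` run the study comparisons at
desk scale: 25 Monte Carlo cycles per segment, 100-evaluation heals,
400-evaluation final relaxes, 6–10 seeds per protocol and case. These are
the package's validation sizes, chosen so the full suite completes in
minutes; the package defaults (200 cycles, 400/2000 evaluations) are what
one would use for production rebuilding.

## Known limitations

* CCD closure can stall below its tolerance on compressed insertions even
  with retries; such proposals are rejected, which can starve the frozen-
  template protocol on register-shift cases — an authentic weakness of
  that protocol, but one amplified here by the simplified energy.
* Template movement in the whole-structure protocol is handled purely by
  minimization, so it inherits minimization's local minima; a displaced
  region further than the density kernel's reach (~2 sigma) from its true
  position is pulled mainly by bond strain, not by density.
* The masked and fast density scores are both all-real-space; neither is
  numerically comparable to reciprocal-space or map-coefficient
  correlations from crystallographic tooling.
* Alternate conformations and insertion codes in PDB input are rejected
  rather than resolved; only single chains and orthogonal P1 maps are
  supported.
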