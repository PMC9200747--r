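---
title: "Diabatic neural-network potentials for photoswitch dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diabatic neural-network potentials for photoswitch dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Photoswitches such as azobenzene convert light into mechanical change: a
photon promotes the molecule from its singlet ground state S0 to the first
excited state S1, the central N=N torsion (the CNNC dihedral) rotates, and
the trajectory returns to S0 near a conical intersection (CI), ending as
either the original or the opposite isomer.  The isomerization quantum
yield — the fraction of excited trajectories that switch — is the key
design observable, and predicting it requires non-adiabatic molecular
dynamics (NAMD): hundreds of surface-hopping trajectories, each needing
excited-state energies, forces and non-adiabatic couplings at every
femtosecond step.  Quantum chemistry at that volume is prohibitive, which
is why machine-learned surrogates are attractive — and why this package
exists.

The difficulty with fitting *adiabatic* surfaces directly is the CI
itself.  Adiabatic energies form non-differentiable cusps there, the gap
must vanish on a high-codimension seam, and since the hopping probability
depends exponentially on the gap near zero, small regression errors
produce qualitatively wrong dynamics (trajectories that never leave S1,
for example).

## The diabatic model

The package therefore fits a *diabatic* Hamiltonian: a symmetric 3x3
matrix function of geometry, `H_d(R)`, whose entries vary smoothly.
Adiabatic quantities are derived, never fitted:

* energies: `U^T H_d U = diag(E_0, E_1, E_2)` with `E_0 <= E_1 <= E_2`;
* the rotated-gradient identity: the matrix `U^T [grad H_d] U` holds, on
  its diagonal, minus the adiabatic forces `-f_n`, and off the diagonal the
  force non-adiabatic coupling vectors `h_nm`;
* the derivative coupling `k_nm = h_nm / (E_m - E_n)`, which physically
  diverges at a CI.  Below a degeneracy tolerance of 1e-6 kcal/mol the
  division is refused and `k` is flagged undefined rather than clamped;
  clamping would silently corrupt fewest-switches hopping.

A CI is not an exceptional configuration for this model but a generic one:
whenever an isolated 2x2 block has equal diagonal entries and vanishing
off-diagonal coupling, the derived surfaces form the conical double cone
exactly.  Three diabatic states are used, so the S0/S1 photochemistry of
both isomers can be covered with the reference ordering: at trans
geometries `(E0, E1) = (d00, d11)`; at cis geometries `(E0, E1) = (d22,
d00)`.

Forces can be obtained two ways, and the package meters the difference.
The rotated-gradient route differentiates every independent diabatic
element — `M_d (M_d + 1)/2 = 6` backward passes for three states — and
also yields the couplings; it is what training uses.  The direct route
differentiates the eigenvalues themselves, one backward pass per requested
state (`M_ad = 2` for S0/S1), and is what dynamics uses when no coupling
is needed.  Every model carries a gradient-evaluation counter so the 6 vs 2
accounting is observable (`grad_counter()`).  Near exact degeneracy
(gap below ten times the degeneracy tolerance) the eigen-derivative is
ill-conditioned and `direct_forces()` falls back to the rotated route.

## Two backbones, one contract

Any model only has to satisfy the `PotentialModel` contract: produce the
3x3 diabatic matrix and, on request, the Cartesian gradients of its six
independent elements (plus a single-backward-pass weighted-combination
gradient).  Three implementations ship:

* `mpnn_model()` — an equivariant message-passing network.  Each atom
  carries rotation-invariant scalar features and rotation-equivariant
  vector features, updated over several rounds from neighbors within a
  cutoff through radial-basis filters and unit displacement vectors, then
  read out per atom into six independent heads and summed (size-extensive
  by construction; off-diagonal heads share no weights with diagonal ones
  and are unconstrained in sign, since couplings must pass through zero).
  Defaults: 64 features, 3 interaction rounds, 5 A cutoff.  Forward,
  position-gradient and parameter-gradient passes are all explicit R code.
* `dense_model()` — an internal-coordinate descriptor network: bond
  stretches and bends (linear and squared) plus torsion cosines
  `cos(k phi)`, k = 1..6, all relative to a molecular template, feeding one
  tanh hidden layer with a linear skip connection.  The squared
  stretch/bend features make harmonic contributions exactly linear in the
  basis, and the torsion harmonics cover force-field-style torsional
  profiles.  Because the descriptors have closed-form Jacobians, the
  mixed second derivatives needed to train on forces and couplings are
  analytic.
* `oracle_model()` — the analytic reference surface below, wrapped in the
  same interface so the full dynamics stack can run on exact surfaces.

The descriptor backbone is the default for training, active learning and
screening at desk scale; the message-passing backbone supports training on
the energy-type loss terms only (force/NACV supervision would require
second-order backpropagation through message passing) and is primarily
exercised through its symmetry, locality and extensivity contracts.

## The training loss

The loss is an exact sum of three terms.  The core term penalizes squared
errors in `E0`, `E1`, the per-atom-mean squared force errors, and the
S0/S1 gap (the gap term is listed separately because hopping dynamics are
exponentially sensitive to it).  The reference term ties the diabatic
diagonal to the labeled energies by isomer basin, as above; it is applied
softly to every frame carrying a cis/trans label (labels are assigned by
the CNNC dihedral at |CNNC| = 90 degrees).  The NACV term penalizes the
rotated off-diagonal against the labeled coupling with the sign resolved
per frame (reference phases are arbitrary per calculation):
`min_s ||h_pred - s h_ref||^2 / N`.  All three use mean-squared error; the
published account of this family of losses does not pin the exact
functional forms, so MSE with per-frame atom normalization is adopted as
the standard choice and documented here as an assumption.

Loss gradients treat the diagonalizer `U` as constant within a step.  For
the energy terms this is exact (Hellmann-Feynman); for the force and NACV
terms it drops the `dU/dtheta` contribution, which vanishes as the fit
converges.  Default weights (1 energy, 1 gap, 0.1 force, 0.2 reference,
0.05 NACV, with heavier reference/NACV weights used in the worked
examples) were fixed from convergence behaviour on the oracle and are all
configurable.  Training uses full-batch Adam with an exponentially decayed
learning rate, early stopping on a validation split, and best-checkpoint
restoration; the force/NACV terms may be estimated on a per-epoch
subsample (`vec_subsample`), which keeps the gradient unbiased while
cutting epoch cost.

## The synthetic oracle

All tests and experiments run against an analytic stand-in for the
reference electronic-structure method: a 10-atom azo rotor (CH3-N=N-CH3
pattern) with a 3-state diabatic surface built in internal coordinates and
differentiated analytically to Cartesians, so labels look exactly like
quantum-chemistry labels (energies, forces, and a force-NACV with
arbitrary sign).

* diagonal profiles are cosine polynomials of the CNNC torsion: the trans
  ground diabat `d00 = 27.5 (1 + cos phi)`, the cis ground diabat
  `d22 = 41 - 29 cos phi` (cis sits 12 kcal/mol above trans, near the
  azobenzene value), and the excited diabat
  `d11 = 42.5 + 17.5 cos phi + 15 cos 2phi` minus a smooth planar dip
  `20 ((1 - cos phi)/2)^8` that produces a removable near-degeneracy on
  the trans side (so planar, non-reactive hops exist alongside the
  twisted, reactive ones);
* each diagonal adds harmonic bends on the two CNN/NNC angles; the ground
  diabats are centred at 120 degrees and the excited diabat at 130
  degrees.  `d00` and `d11` cross at phi = 90 degrees, where the coupling
  `d01 = 5 cos phi` vanishes; because the bend centres differ, the gap
  vanishes only where the crossing *and* a bend-balance condition hold —
  the seam is codimension 2, a curve in (phi, alpha1, alpha2), and the
  model's excited-state bend forces funnel trajectories toward it;
* every remaining coordinate is held by a harmonic bath added to all three
  diagonals equally, so it never affects gaps or couplings.

The amplitudes were chosen once to give azobenzene-like scales — a cis
vertical excitation of ~43 kcal/mol (1.9 eV), a ground-state isomerization
barrier of ~22 kcal/mol from cis, S1 exit times of a few hundred fs and a
cis-to-trans quantum yield around 0.75 at 300 K — and are not adjusted
thereafter.  A "coupling is an odd harmonic of phi" choice deserves a
note: the coupling must be even under reflection of the geometry (mirror
images have identical spectra and any reflection-invariant descriptor set
could never fit an odd function), so the odd *harmonic* `cos phi` is used,
which passes through zero at the crossing as required.  `oracle_family()`
provides five rotors whose excited-state torque or cis-side steepness is
varied, spreading brute-force yields over roughly 0.2-0.9 for screening
exercises.

What the oracle does *not* emulate: chemical realism of the true
azobenzene surface (S2 and higher states, spin contamination,
substituent electronics), label noise, or the cost profile of real
quantum chemistry.  Tests passing on the oracle therefore demonstrate the
machinery — losses, diagonalization, hopping, acquisition — not accuracy
on real molecules.

## Surface hopping

Nuclei follow velocity Verlet (0.5 fs default) on the active adiabatic
surface.  For fewest-switches hopping the two-level electronic amplitudes
are propagated with the time-dependent coupling `v . k01` using an exact
piecewise-constant two-level exponential over 50 substeps per nuclear
step, with energies and couplings linearly interpolated across the step;
eigenvector sign continuity between steps prevents spurious coupling sign
flips.  Hop probabilities are the standard fewest-switches fluxes,
accumulated over substeps and clipped to [0, 1].  Accepted hops rescale
velocities along the coupling direction, solving the energy-conservation
quadratic exactly; insufficient kinetic energy along that direction makes
the hop frustrated, which is recorded and leaves velocities unchanged (no
reversal).  No decoherence correction is applied.  The Zhu-Nakamura branch
uses only adiabatic information: at a local minimum of the gap across
three consecutive steps it evaluates the gap-minimum Landau-Zener
probability `exp(-(pi/2 hbar) sqrt(dE^3 / (d^2 dE/dt^2)))` and rescales
uniformly (no coupling vector exists in this scheme).  Both schemes
reproduce the analytic Landau-Zener transition probability on a
one-dimensional saturating avoided crossing (`tanh_crossing_model()`);
note that a strictly linear crossing confines the upper adiabat and has no
well-defined scattering statistic, which is why the benchmark surface
saturates.

Trajectories start with a vertical excitation of a thermal ground-state
snapshot (Nose-Hoover NVT sampling; unit excitation probability, no
oscillator-strength windowing).  After an accepted hop to S0 the
trajectory relaxes for 200 fs and the final isomer is classified by
|CNNC| < 90 degrees.  Ensembles report the yield with a bootstrap standard
deviation (1000 resamples), the S1 lifetime from a censored-exponential
maximum-likelihood fit to the survival curve, the fraction reaching the
ground state by the horizon, and planar/rotational pathway fractions using
a configurable 150-degree |CNNC| threshold.

## Active learning

`run_active_learning()` implements the committee loop: two descriptor
networks trained with different seeds and batch orders; surface hopping
with the first member from thermal initial conditions; candidate frames
scored by committee variance (for a two-model committee this equals a
quarter of the squared prediction difference) and, in mixed mode, by
predicted-gap proximity to the seam; oracle labels for the top-ranked
candidates; retraining of both members; repeat (five cycles by default).

Three design choices matter and were learned the hard way on the oracle:

* initial conditions come from ground-state *reference* MD, not from the
  untrained model — an untrained surface lets the thermostat wander into
  unphysical regions before the excited-state dynamics even start;
* acquisition walks down the ranking and labels until the budget is
  filled, discarding frames whose labeled ground-state energy exceeds the
  training floor by more than `e_window` (default 300 kcal/mol; 100 in the
  tested campaign).  Early-cycle models drive trajectories into
  bond-breaking territory, and a handful of thousand-kcal frames dominate
  an MSE fit;
* retrains are warm-started with fixed per-member seeds, so across cycles
  the only thing that changes is the data and the held-out metric tracks
  the acquisitions rather than optimizer noise.

The tested campaign starts from basin-only data (300 normal-mode frames),
holds out frames visited by reference dynamics, and runs 3 cycles of up to
200 acquisitions; the held-out gap MAE decreases across cycles with at
most one plateau, and no trajectory aborts occur in any cycle.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: training sets of
~2000 frames (thermal basin samples, rotation/inversion scans, and an
800-frame slice of reference-surface dynamics — the same
dynamics-dominated mix the reference workflow uses, and necessary:
without dynamics frames the thermally displaced seam region is
unconstrained and predicted yields drift) with a 64-unit hidden layer and
600 epochs, weighting forces strongly (w_force = 1) because the post-hop
branching that decides the yield is set by the topography around the
seam, not by the energies alone; 200-trajectory
ensembles on learned surfaces against a 20,000-trajectory compiled
reference ensemble; 2000-trajectory Landau-Zener scattering runs;
active-learning campaigns of 3 cycles x 16 trajectories x up to 200
acquisitions.  These sizes are the package's chosen study conditions, with
stochastic tolerances (bootstrap standard deviations, Monte-Carlo standard
errors) quoted alongside each estimate.

Other numerical choices: eigenvector sign convention (largest-magnitude
entry positive, or continuity along trajectories); Boltzmann constant
0.0019872041 kcal/mol/K, hbar 15.178729 kcal/mol fs, 1 eV = 23.060548
kcal/mol, with kcal/mol, Angstrom, fs, amu fixed package-wide; dihedrals
in (-180, 180] by the right-hand convention (the collinear case is an
error, not a silent NaN); brute-force ensembles resample a 1000-2000
snapshot NVT position pool with fresh Maxwell-Boltzmann velocities, which
decorrelates initial conditions without rerunning the thermostat 20,000
times.

## Known limitations

* The descriptor backbone needs a fixed molecular template; it cannot
  transfer across species.  Chemical transferability is what the
  message-passing backbone is for, but training it on forces/couplings is
  beyond the desk-scale scope here.
* Diabatization cannot remove the curl (non-removable) part of the true
  derivative coupling; the model's `h01` is the gradient-derived part.
* The ensemble observables assume a single S1 state; no S2, no
  intersystem crossing, no solvent.
* The Zhu-Nakamura branch implements the gap-minimum Landau-Zener limit of
  the full multi-parameter expressions.
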