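---
title: "fibrilsite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibrilsite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibrilsite)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not show.
Units everywhere are nm, kJ/mol, eV, degrees and kelvin;
k_B = 0.0083144626 kJ/mol/K and λ·E = 1239.84193 eV·nm.

## Helical fibril models

Amyloid fibrils stack near-identical protofilament layers along a helical
axis. In the Alzheimer tau fold, two C-shaped protofilaments are related
by a 2-fold screw (2₁) axis: the generator operation is a rotation by
`180° + twist` about the fibril axis plus a translation by the rise
(0.48 nm per layer at room temperature), where `twist` is the small
deviation from perfect two-fold staggering. `build_supercell()` applies
this generator `k` times to produce layer `k`, so consecutive layers are
the two screw-related protofilament copies and one operation generates
the whole assembly.

A finite cell of `n` layers is *periodic* (its first periodic image
superposes layer 0 exactly) when the accumulated generator rotation is a
multiple of 360°. With `twist = 360/(screw_order × n)`
(`twist_from_layers()`) this closes for odd `n` under a 2-fold screw —
the 185-layer cell with twist 0.97° is the canonical example — while even
`n` ends anti-aligned; `build_supercell()` therefore flags closure
explicitly rather than assuming it.

Design choices worth stating:

* **Axis determination.** `axis_frame()` uses the screw-generator axis
  stored in the model, which is exact by construction and transformed
  along with the coordinates by `transform_model()`. We deliberately do
  not estimate the axis from a principal-component fit of layer
  centroids: under a 2-fold screw the layer centroids sit off-axis and
  alternate by ~180° around it, so a centroid PC mixes the radial offset
  into the axis direction and is badly biased at small layer counts.
* **Symmetry audit.** `verify_symmetry()` maps each stored layer by the
  generator and reports the RMSD against the next layer (standard
  per-atom RMSD, i.e. the root mean squared atom displacement). For a
  freshly built model the values are at numerical zero (~1e-16 nm);
  under i.i.d. coordinate noise of sd σ applied to the whole model they
  converge to σ√6 for large atom counts, since mapped and stored layers
  carry independent noise in three coordinates each.
* **Bookkeeping.** Residue numbers gain an offset of 1000 per layer in
  the in-memory atom table (`resno_global`); chains cycle A–Z. PDB
  output (via bio3d) keeps per-layer chains and the original residue
  numbers, and records the periodic cell height `n × rise` in CRYST1.

Out of scope by design: energy minimization, NPT relaxation and the
selection of the "least stressed" twist among candidates — those require
an MD engine. The builder exposes twist as a parameter instead.

## Synthetic trajectories with planted binding modes

`generate_ligand_trajectory()` emulates the statistical structure of
unbiased ligand MD around a fibril without simulating any physics. Each
frame places each ligand either

* **in bulk** (probability `bulk_fraction`): uniformly in the padded
  bounding box of the fibril, rejected if within the site cutoff + 0.2 nm
  of any layer's site triad — mimicking the protein's excluded volume and
  guaranteeing that `bulk_fraction = 1` produces no spuriously "bound"
  frames; or
* **bound at the planted site**: the ligand's charge center is drawn
  isotropically (sd `site_spread`, default 0.05 nm) about the site-A
  triad centroid of the middle layer, with a major mode drawn from
  `mode_weights` and a minor conformer from `minor_mode_weights`.

The toy ligand is six labeled pseudo-atoms — bi-thiophene centroid (BTC),
vinylene midpoint (VIN), benzothiazole centroid (BZC), thiazole-ring
centroid (THZ), ethyl terminal carbon (ETC), charge center (CHG) — the
minimum set the classifier and the dihedral operations need. The chain
BTC–VIN–BZC–THZ–ETC carries two proxy dihedrals: (BTC,VIN,BZC,THZ) for
the bi-thiophene inter-ring rotation and (VIN,BZC,THZ,ETC) for the
thiazole–ethyl rotation. Minor conformers set these near 0° or 180° with
±60° jitter, so the sign of the cosine — the classifier's binning rule —
is never ambiguous. The ethyl vector of a bound ligand points into its
mode's quadrant of the site frame, 45° off both axes with ≤18° of angular
jitter, so planted major modes are likewise never flipped by noise. This
is intentional: the generator plants *clean* labels so that classifier
errors, when they occur, are attributable to the classifier.

Default mode weights are UL 30%, UR 47%, DL 4%, DR 19% — the Boltzmann
populations of the four major modes at site A of the tau Alzheimer fold,
with the ranking UR > UL > DR > DL (up favored over down, right over
left). Ground truth travels with the trajectory (`attr(, "truth")`).

What the generator does *not* emulate: solvent, real interaction
energies, correlated frame-to-frame dynamics (frames are i.i.d., so
residence times of synthetic trajectories are geometric rather than
kinetic), partial or distorted binding poses, and ligands interacting
with each other. Tests passing on this generator therefore validate the
*bookkeeping and statistics* of the analysis chain — site location,
frame geometry, label recovery, population estimation — not force-field
realism.

## Site frame and mode classification

A binding site (`site_definition()`) is a triad of residues plus two
anchor atoms and a membership cutoff (0.7 nm, a first-shell contact
distance; configurable). The classification frame (`site_frame()`) is:
z = fibril axis; x = unit projection of (Ile-anchor − His-anchor)
perpendicular to z; y = z × x. The exact anchor atoms are configurable
because different structures (and different figures in the literature)
anchor the in-plane direction differently; the default uses the CA atoms
of the first and third triad residues.

`classify_major_mode()` computes the ethyl vector e = ETC − THZ and bins
its signs: U if e·z ≥ 0 (the measure-zero tie resolves deterministically
to U), R if e·y > 0 (tie to L). `classify_modes()` anchors the frame on
the layer whose triad centroid is nearest the ligand, so ligands bound
anywhere along the fibril are classified in their local frame, and the
whole labeling is equivariant under rigid motions of fibril + ligand.

`planarity()` is Σ|cos θ| over a set of conjugated-backbone dihedrals —
on four dihedrals a planar backbone scores 4 and amyloid-bound
oligothiophenes score around 3.4–3.5. The planarity descriptor family in
the literature is not uniquely defined; scores from differently defined
descriptors are comparable only in order of magnitude, and the package
documents its Σ|cos| convention prominently rather than claiming
equivalence to any particular published scale.

## Density maps

`density_map()` bins ligand reference points on the cross-section plane,
summing along the axis. With `untwist = TRUE` each point is first rotated
about the axis by −(nearest layer index × generator rotation), which
overlays all symmetry-equivalent sites onto the layer-0 position — the
standard way to accumulate per-protofilament ligand density over a
helical assembly. The map conserves counts exactly (bins plus
out-of-domain equals points binned), which the tests assert, and a
bulk-only trajectory produces Poisson-uniform counts.

## Umbrella sampling and WHAM

`generate_umbrella_windows()` draws reaction-coordinate samples from the
biased Boltzmann density `exp(−[U(x) + k(x−c)²/2]/kT)` by Metropolis
Monte Carlo confined to the potential's domain, with 1000 burn-in steps
and 10× thinning. The proposal half-width is `max(0.05, 3·sqrt(kT/k))`
nm: scaled to the window's own width, because a fixed small step mixes
far too slowly in stiff windows (with a fixed 0.05 nm step, stiff windows
fail a Kolmogorov–Smirnov check against the exact biased density; with
the adaptive step ~97% of windows pass at α = 0.01, which the test suite
verifies over 100 seeds).

`wham()` is the standard self-consistent 1-D weighted-histogram
iteration, with defaults bin width 0.02 nm, shift tolerance 1e-8 kJ/mol,
and a 100000-iteration cap (non-convergence is an error carrying the
residual, never a silent result). Coverage is checked as connectivity of
the windows' sampled ranges — a gap wider than one bin means the windows
cannot be tied together; isolated empty interior bins (sampling-tail
artifacts) are simply dropped. The PMF reference convention defaults to
`"bulk"` (mean over the trailing 0.5 nm zeroed, matching profiles whose
pulled coordinate flattens in bulk solvent); `"min"` is available.
Per-bin uncertainties are available on demand through
`wham_uncertainty()` (moving-block bootstrap over each window's series,
50 resamples by default, preserving short-range sampler
autocorrelation) rather than computed always; `binding_energy()`
averages the bulk plateau, which suppresses single-bin noise on that
side.

Two analytic oracle potentials back the recovery tests, both built from
Gaussian wells rather than polynomial wells. The reason is numerical:
a quartic double-well steep enough to be interesting puts slopes of
~300 kJ/mol/nm into 0.02 nm bins, and the log-average of the Boltzmann
weight across such a bin differs from its midpoint value by ~0.6 kJ/mol
— a binning bias no estimator can remove at that bin width. Gaussian
wells keep slopes below ~50 kJ/mol/nm so the oracle tests measure the
estimator, not the binning.

* `default_double_well()`: depths 8 and 5 kJ/mol at 0.7/1.3 nm, width
  0.1 nm, domain 0.4–1.6 nm. Recovery uses 25 windows across 0.5–1.5 nm,
  k = 600 kJ/mol/nm², 5000 samples/window; the maximum aligned error
  against the exact potential is required to stay below 0.3 kJ/mol.
* `binding_well(depth)`: a single Gaussian well (width 0.12 nm at
  0.35 nm) flattening to zero along a 2 nm pulling coordinate, emulating
  a ligand-extraction free-energy profile with a flat bulk tail.

## The end-to-end mode study

`mode_population_study()` chains everything: per mode, generate umbrella
windows from a planted `binding_well()`, reconstruct the PMF by WHAM,
read the binding free energy against the bulk plateau, then convert the
four energies to Boltzmann populations
`p_i = exp(E_i/kT)/Σ exp(E_j/kT)` at 300 K. The planted depths
(`default_mode_depths()`: UR 33.0, UL 31.9, DR 30.7, DL 26.9 kJ/mol) lie
in the 26–33 kJ/mol range characteristic of a strongly fibril-bound
oligothiophene, and their exact Boltzmann populations are 47/30/19/4% —
so recovering "47/30/19/4" from raw umbrella samples exercises sampling,
WHAM, the bulk-reference convention and the softmax in one pass, with a
5-percentage-point acceptance band.

Two sampling-design points matter. First, window centers are spaced
0.035 nm across the steep well wall (0.15–0.78 nm) and more coarsely
over the flat tail: WHAM's window-to-window free-energy shifts
accumulate a random-walk error along the coordinate, and overlap quality
on the wall controls it — with uniform spacing the same budget
occasionally misses the population band. Second, 20000 samples per
window (33 windows, 4 modes) hold the per-mode binding-energy error to a
few tenths of kJ/mol, which maps to ~1–3 percentage points of population
error; this is the dominant cost of the acceptance script (a few minutes
on one CPU).

## Spectra

Snapshot averaging builds a condensed-phase absorption spectrum as
`S(E) = (1/N) Σ_n L(E − E_n)` over per-snapshot vertical excitation
energies, assuming fast intramolecular vibrations (the line shape `L`)
decouple from the slow environmental degrees of freedom sampled by the
snapshots.

* `gaussian_spectrum()`: `L` is a Gaussian, σ = 0.15 eV by convention.
* `vibronic_spectrum()`: `L` is a low-temperature vibronic profile — a
  0-0 line plus progression lines, each with a small intrinsic width —
  anchored by default with its 0-0 line at the snapshot energy. The 0-0
  anchor is the natural choice when the 0-0 transition dominates the
  band; anchoring at the profile's intensity centroid is available by
  flag, since the two conventions shift the absolute band position by
  the profile's mean offset.
* `default_vibronic_profile()`: 0-0 line plus three progression lines at
  0.161/0.174/0.198 eV (1300/1400/1600 cm⁻¹ stretching and angle-bending
  modes), geometrically decaying intensities (ratio 0.35, 0-0 share
  ~66%), 0.02 eV intrinsic width. This is an emulation of the generic
  oligothiophene line shape, not a fitted profile, so curve *shapes*
  computed with it are not reproduction targets; the operator algebra
  (reduction, area conservation, smearing) is.

Numerical conventions: the default grid is 1.5–4.0 eV in 1 meV steps;
λmax is the grid argmax in the energy domain converted to nm (no
dλ/dE Jacobian reweighting, because band maxima are compared directly
between theory and experiment in this field); exact argmax ties —
including flat spectra — resolve to the lower energy (longer wavelength)
and are flagged on the result. Both broadening operators preserve unit
area to <1e-6 on a grid covering ±6σ. `shift_analysis()` reports
Δλ = b − a and the energy gap |hc/a − hc/b|; `conformer_average()` is a
convex pointwise mixture on a shared grid (e.g. 50/50 cis/trans).

Snapshot weighting by oscillator strength is optional (`weights=`) and
off by default: unweighted averaging is the common choice when per-state
strengths are near-constant across snapshots, and nothing in the package
depends on the convention.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run on one CPU in a few
minutes. Sizes were chosen so that every stochastic acceptance check
passes with real margin under its stated tolerance: 25 × 5000 samples
for the double-well (observed errors ~0.15–0.25 kJ/mol against the
0.3 limit across prototype seeds), 4 × 33 × 20000 for the mode study
(observed ≤3 pp against the 5 pp band), 20000 frames for the classifier
(binomial 3σ ≈ 1.1 pp on the largest weight). Every random draw derives
from a single integer seed through a deterministic splitter
(independent streams per sub-task), so identical seeds give bitwise
identical outputs.

## Known limitations

* The fibril builder imposes geometry; it does not relax it. Stress and
  kinks from forced periodicity are out of scope.
* Synthetic trajectories have no kinetics: residence times measure run
  lengths of i.i.d. labels, so only their bookkeeping (run-length ×
  frame interval) is validated, not any rate.
* WHAM here is strictly 1-D; no MBAR generalization, no 2-D profiles.
* The vibronic profile is an emulation (see above); spectra computed
  with it are structurally, not spectroscopically, accurate.
* The planarity score is one convention among several in use.
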