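---
title: "Refining conformer ensembles with confens: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining conformer ensembles with confens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confens)
```

## The problem

Modern conformer generators (CREST, GOAT and kin) emit hundreds to
thousands of candidate structures for a flexible molecule at semi-empirical
cost. Downstream property prediction — Boltzmann-averaged energies, IR/VCD
and UV/ECD spectra, singlet–triplet gaps, transition-state energies —
requires re-evaluating those structures at progressively higher levels of
theory, and carrying a whole raw ensemble through DFT is usually
intractable. `confens` implements the refinement layer of that pipeline:
it reads a multi-structure XYZ ensemble, executes a JSON-described sequence
of refinement steps against a pluggable calculator back end, and after
every step re-weights, prunes, optionally clusters, and optionally
simulates and aligns spectra. A deterministic synthetic calculator ships
with the package, so every part of the machinery runs and is testable
without a quantum-chemistry engine; adapters for real engines only need to
fulfil the small `calculator()` contract (an `evaluate(step, conformer)`
function plus a capability set).

## Data model and units

A `conformer` holds element symbols, Cartesian coordinates (Å), the
electronic energy `E_el`, an optional Gibbs free energy `G`, optional
harmonic wavenumbers, the scalar norm `B_norm` of its rotational-constant
vector, a degeneracy, a population and an active flag. An `ensemble` is an
ordered list of conformers sharing one atom sequence, plus a temperature
and a step log. Internally all energies are kcal/mol, rotational constants
MHz, frequencies cm⁻¹. Bare-number XYZ comment lines are interpreted as
Hartree (the convention of CREST/GOAT ensemble files) and converted with
627.5094740631 kcal/mol per Hartree; this is an assumption about the input
dialect, not something the format guarantees, and the reader leaves the
energy unset when the comment is not a number. Atomic masses are
most-abundant-isotope masses, the standard convention for rotational
constants. A single atom has `B_norm = 0` by convention, and linear
molecules contribute their two finite rotational constants to the norm.

## Thermochemistry: qRRHO with damped low-frequency entropies

Harmonic vibrational entropies diverge as a mode frequency approaches
zero, which makes raw harmonic Gibbs energies of floppy molecules
unreliable. `qrrho_gibbs()` therefore interpolates each mode's entropy
between the harmonic-oscillator and free-rotor expressions using the
damping weight

$$w(\nu) = \frac{1}{1 + (\nu_0/\nu)^\alpha},$$

with defaults $\nu_0 = 100\ \mathrm{cm^{-1}}$ and $\alpha = 4$, and a
free-rotor effective moment damped by
$B_{av} = 10^{-44}\ \mathrm{kg\,m^2}$. These constants follow the damping
scheme this treatment derives from; all three are exposed as arguments.
Damping applies to the entropy only — zero-point energy and thermal
enthalpy stay fully harmonic, which is the original formulation of the
scheme. Imaginary frequencies are dropped with a warning before any
thermochemistry, since transition-state workflows legitimately carry
exactly one and it must not enter the vibrational entropy. Translation
uses Sackur–Tetrode at 1 atm; rotation uses the rigid-rotor expressions
with a symmetry number defaulting to 1.

Populations follow
$p_i = g_i e^{-\Delta E_i/RT} / \sum_j g_j e^{-\Delta E_j/RT}$ with
$R = 1.987204\times10^{-3}$ kcal/(mol K) and energies relative to the
minimum (numerically safe for arbitrarily large absolute energies).
Degeneracies default to 1 — nothing in the refinement pipeline computes
them, so they are user input. The ensemble-averaged energy is the plain
population-weighted sum $E_{av} = \sum_i p_i E_i$.

## Duplicate pruning and energy windows

Two conformers count as the same structure when **both**
$|E_i - E_j| < thrG$ **and** $|B_i - B_j| < thrB$ hold; the
higher-energy member of the pair is discarded. Comparing scalar pairs
(energy, rotational-constant norm) deliberately avoids RMSD alignments,
which dominate the cost of conventional pruning. The scan runs in
ascending energy order with a greedy keep list: the global minimum can
never be discarded, the result is deterministic (energy ties break on
file order), and the procedure is idempotent. The same rule applied as an
all-pairs oracle reproduces the greedy survivors exactly, which the test
suite checks on randomized ensembles up to 200 conformers.

Inequalities are strict on both sides: duplicates require `< thr`, and the
retention window keeps conformers with relative energy strictly below
`thrGmax`. Step-kind defaults are `thrGmax = 6.0` kcal/mol for plain
single points (high-energy structures may relax substantially in a later
optimisation, so the net is cast wide) and `3.5` kcal/mol for steps that
optimise or compute frequencies, which retains everything with
non-negligible room-temperature population. The kinds `opt` and `freq`
are mapped to the 3.5 kcal/mol window as well, treating them like the
post-refinement situation they produce. `thrG = 0.05` kcal/mol and
`thrB = 15` MHz are CREST-like duplicate-detection defaults; all three
values yield to explicit protocol settings.

## Clustering

When an ensemble is too large even for single points, K-means clustering
reduces it while preserving conformational diversity. The feature vector
of a conformer is the descending-sorted eigenvalue spectrum of its
interatomic distance matrix — exactly invariant under rigid motion and
atom relabelling, and computable without alignment. Hydrogens are
excluded by default to focus on the heavy-atom skeleton; `include_hydrogens
= TRUE` switches to the full-atom description. Features are reduced by
PCA to the leading components covering 95% of variance (configurable);
clustering and the silhouette score both operate in that PCA space, which
keeps the two consistent with each other.

The cluster count is scanned over every integer from
$\max(2, \lceil 0.10\,n\rceil)$ to $\lfloor 0.80\,n\rfloor$; each k runs
10 K-means restarts with seeds derived from a master seed (centres drawn
from distinct data rows), and the labelling with the highest mean
silhouette width wins, ties going to the smaller (cheaper) k. Each
cluster is represented by its lowest-energy member, so the reduced
ensemble stays energetically honest — in particular the global minimum is
always a representative. The diagnostic
$\Delta E_{av} = E_{av,\mathrm{full}} - E_{av,\mathrm{representatives}}$
(populations re-Boltzmannised over the representatives) quantifies what
the discretisation costs; it is identically zero when every conformer is
its own cluster and grows as clustering coarsens. With fewer than three
active conformers automatic clustering is skipped with a warning rather
than failing the run.

## Spectra

Stick spectra from each conformer are scaled by population and broadened:
vibrational kinds (IR, VCD) with a Lorentzian

$$L(X) = \sum_i I_i\,\frac{\gamma^2}{\gamma^2 + 4(X - \omega_i\Delta)^2},$$

whose peak height equals $I_i$ and whose half maximum sits at
$\pm\gamma/2$, and electronic kinds (UV, ECD) with an area-normalised
Gaussian of $\sigma = \gamma / (2\sqrt{2\ln 2})$. The shift $\Delta$ is
multiplicative for wavenumbers (the familiar harmonic scale factor) and
additive in nm for electronic spectra — a negative additive shift is a
blue shift. Applying the electronic shift in nm rather than eV is a
deliberate simplification: experimental curves arrive on nm grids, and a
wavelength-additive shift composes with them without resampling; a
`nm_to_ev()` converter is provided for users who think in energy. A
single uniform $\gamma$ broadens all bands of a spectrum.

Alignment against an experimental two-column XY file minimises

$$\mathrm{RMSD} = \sqrt{\frac{\sum_i w(x_i)\,(y_i - y_{exp,i})^2}{\sum_i w(x_i)}}$$

over $(\gamma, \Delta)$ within user-definable bounds. Both curves are
max-normalised ($\max|y| = 1$) first; that makes the similarity index
$S = 1 - \mathrm{RMSD}/\mathrm{max}$ attain its nominal bounds, with
max = 1 for achiral and 2 for signed chiral spectra (two antipodal
unit-normalised signals differ by exactly 2 everywhere). The weighting
function is 1 inside a region of interest, 0 outside the experimental
window, and tapers in between with a Gaussian centred on the nearer
interior bound ($\sigma$ = 10% of the taper width) floored at 0.15, so
the optimiser concentrates on the informative region without entirely
ignoring its flanks; switched off, it degenerates to a step over the
experimental window.

The bounded minimisation uses L-BFGS-B, reparameterised onto the unit
box: a unit step in the multiplicative shift moves bands across the whole
spectrum while a unit step in $\gamma$ is barely visible, and line
searches fail on such anisotropic scales. The fit starts from the bound
midpoints; if it stalls above an RMSD of $10^{-3}$ — the surface holds
shallow local minima whenever sharp bands slide past each other — it
restarts from the best point of a coarse 7 × 25 bounded grid. On
noiseless synthetic data this recovers both parameters to well under 1%
relative error. Default bounds ($\gamma \in [2, 24]$ cm⁻¹,
$\Delta \in [0.94, 1.02]$ for vibrational; $\gamma \in [10, 60]$ nm,
$\Delta \in [-50, 50]$ nm for electronic) and pre-fit widths (8 cm⁻¹ /
25 nm, the `fwhm-vibro` / `fwhm-electro` settings) are pragmatic
conventions, all overridable.

## Protocols and the synthetic calculator

A protocol is a JSON document with a `steps` array; each step carries a
kind (`single_point`, `opt`, `freq`, `opt_freq`), a level label, optional
solvent, charge (default 0) and multiplicity (default 1), optional
threshold/cluster/spectra settings, free-form `extra_input` strings
passed to the calculator, and a temperature override. Unknown keys are
rejected with their path — silent typos in threshold names would
otherwise produce plausible-looking but wrong refinements. Per step, the
runner evaluates active conformers (failures deactivate the conformer and
are listed, rather than aborting a long run), refreshes `B_norm` from any
new geometry, applies qRRHO when frequencies are present, deduplicates,
applies the energy window, optionally clusters, and optionally writes and
fits spectra. A single-point step following a frequency step keeps the
earlier thermal correction on top of the refined electronic energy — the
usual composite-G practice. Reports are tab-separated per-step tables
plus one JSON run summary, none of which embeds timestamps, so a rerun
with the same inputs and seed reproduces every file byte for byte.

The synthetic calculator exists so that the full pipeline is exercisable
and reproducible with no external engine. Its energy is a Lennard-Jones-
like sum over interatomic distances (well at 1.5 Å, matching the fixture
chains) plus 10 kcal/mol per unit of spin multiplicity above singlet,
giving workflows at different multiplicities a closed-form gap to verify
against. Optimisation is step-capped steepest descent on that surface and
never raises the energy; frequencies are eigenvalues of a pairwise-spring
toy Hessian (strictly positive after removing rigid-body modes, mapped to
a cm⁻¹ scale); stick spectra are deterministic functions of the
frequencies and distance-matrix eigenvalues. Because the surface depends
on distances only, its energies are exactly invariant under rigid motion.
One behaviour worth knowing: full descent funnels distinct starting
torsions into few basins, so an `opt` step on synthetic data legitimately
collapses much of an ensemble into duplicates — protocols that want
post-optimisation diversity should cluster before optimising.

## Fixture generators

`make_ensemble()` builds chain-like geometries (alternating C/C/O/N
backbone, 1.5 Å bonds) with seeded random bends and torsions. Torsional
perturbation moves rotational constants and distance-matrix eigenvalues
the way real conformational change does, which is all the pruning and
clustering machinery cares about; the geometries are not meant to be
chemically stable molecules, and passing tests say nothing about basis
sets, solvation or the accuracy of any electronic-structure method.
Energies are drawn uniformly over `[0, energy_spread]` with a minimum
spacing of `min(0.11, energy_spread/n)` kcal/mol between non-duplicate
conformers, so that at default thresholds the planted duplicates — exact
geometric copies with energy jitter below 0.01 kcal/mol — are provably
the only duplicate pairs, making every deduplication decision scoreable.
`make_spectrum_pair()` draws random sticks and convolutes them at a known
$(\gamma^*, \Delta^*)$, providing a ground-truth "experimental" curve for
validating the alignment optimiser end to end. Both generators are pure
functions of their seed.

## Validation sizes and numerical choices

The shipped test suite validates: pruning against the all-pairs oracle on
100 random ensembles of 10–200 conformers; population normalization to
within $10^{-12}$ over 1000 random draws; parameter recovery on 20 seeded
noiseless spectra (tolerance 1%, similarity at least 0.999); the
silhouette scan against an exhaustive, independently coded scan on
30-point constructed blob data; and byte-identical protocol reruns on a
16-conformer synthetic ensemble. These sizes keep the whole suite under a
minute while covering the regimes where the algorithms can disagree with
their oracles. Retention rates of a published three-step refinement of
eight flexible molecules are recomputed from the shipped conformer-count
table; seven of the eight printed percentages match
`round(100 * final/starting)` exactly, and the eighth (45/134 = 33.6%,
printed as 33%) appears to be a rounding slip in the source table, which
the corresponding test documents by failing against the printed value.

Other numerical conventions: PCA components are deterministic up to sign
(scores are used only for distances, which sign cannot affect);
K-means ties on silhouette go to smaller k; a constant feature matrix
yields a single zero component with a warning; an empty taper
(`x_int` bound coinciding with the experimental bound) contributes no
taper region; populations are computed from Gibbs energies whenever every
active conformer has one and from electronic energies otherwise.

## Limitations

No structural alignment or RMSD-based pruning is provided (by design);
SMILES/SDF input, connectivity perception and 3D generation are out of
scope, as are solvation physics, anharmonic corrections, vibronic band
shapes and adapters for specific quantum-chemistry engines. The published
case-study spectra (experimental VCD/ECD of real chiral molecules) require
QM response calculations and are not reproducible with the synthetic
calculator; what the package validates is the refinement and alignment
machinery itself.
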