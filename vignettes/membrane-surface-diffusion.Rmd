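---
title: "Analyzing peripheral-protein surface diffusion on anionic membranes"
author: "peritraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing peripheral-protein surface diffusion on anionic membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritraj)
```

## The problem

Soluble electron carriers such as cytochrome c2 shuttle electrons between
membrane-anchored complexes of an electron transport chain. How fast they
find their next redox partner depends on how they travel: through bulk
solvent in three dimensions, or restricted to the membrane surface in
(quasi) two dimensions. On bioenergetic membranes rich in anionic lipids —
phosphatidylglycerol (PG) and especially cardiolipin (CDL), which carries
two phosphates and a high head-group charge density — a positively charged
protein face can keep the carrier electrostatically tethered to the
surface while still allowing lateral motion, with brief desorbed
excursions. We call this intermittent surface travel *skipping* diffusion.

`peritraj` quantifies this behavior from molecular-dynamics trajectories
through four measurements, plus a synthetic trajectory generator with
exact ground truth that makes every stage testable:

1. **Insertion depth** of the protein relative to the binding-leaflet
   phosphate plane, its bimodal distribution, and a two-state
   BOUND/HOVER segmentation of the time series.
2. **Orientation**: the tilt angles of the heme (porphyrin) plane
   relative to the membrane normal, with axial circular statistics.
3. **Protein–lipid contacts**: per-residue interaction frequencies and
   composition-normalized relative lipid affinities.
4. **Diffusion coefficients** from mean-square displacements via the
   Fickian relation `<x²> = 2 N D t`.

## Measurements and their definitions

### Insertion depth

For each frame, the binding-leaflet phosphate plane is the arithmetic
mean z of the head-group phosphorus atoms assigned to that leaflet;
assignment is by the sign of (z − bilayer midplane) per frame, so the
plane tracks membrane drift rather than relying on static atom lists.
The depth is the z displacement of the *side-chain center of mass* of the
residue whose heavy atom reaches furthest below the plane (or, if no atom
penetrates, the residue closest to it). Side chain means residue heavy
atoms minus backbone N/CA/C/O; glycine, which has no side-chain heavy
atoms, falls back to whole-residue heavy atoms. Negative depth means
inserted. Ties for the deepest atom go to the lower atom index, making
the measure deterministic.

A skipping protein produces a bimodal depth distribution: one mode below
zero (inserted) and one a few Angstrom above it (hovering). The histogram
uses fixed-width bins with an edge pinned at 0 Å so the inserted/hovering
boundary never falls mid-bin; peaks are local maxima of lightly smoothed
counts (moving average, default 3 bins) with a topographic-prominence
floor of 5% of the maximum count, which suppresses noise peaks while
leaving genuine minority modes intact. `segment_states()` turns the
series into a two-state sequence with a threshold placed between the two
modes; runs shorter than `min_dwell` merge into the flanking state
(scanning left to right, so the earlier state wins ties), and the
excursion count is the number of HOVER→BOUND transitions.

### Orientation

The heme plane is fitted per frame by least squares: the ring normal is
the smallest-eigenvalue eigenvector of the centered ring-atom covariance,
with its sign fixed so the z component is non-negative. Three angles
follow, all in degrees in [0, 180): `phi_beta` between the membrane
normal (z) and the ring normal; the *co-normal* is the normalized cross
product z × normal (the line of nodes of the Euler decomposition);
`phi_alpha` between the co-normal and x; and `phi_gamma` between the
co-normal and an in-plane reference vector anchored at the first pyrrole
nitrogen (ring nitrogens sorted by atom name). The co-normal is undefined
when the ring lies flat (normal parallel to z); such frames are flagged
degenerate rather than raising an error, since they are legitimate
geometry. Because a plane normal's sign is arbitrary, summaries use
*axial* circular statistics on doubled angles (period 180°): samples at
10° and 170° average to 0°, not 90°. The distribution mode is the peak of
a 2° histogram.

### Contacts and lipid affinity

A protein residue *coordinates* a lipid when at least one heavy atom lies
within 2.5 Å of a head-group phosphorus or nitrogen atom of that lipid;
it shows *hydrophobic insertion* when an atom drops below the carbonyl
plane of the binding leaflet, attributed to the lipid with the nearest
phosphorus. All distances are minimum-image under the orthorhombic box.
Cardiolipin counts as one molecule even though either of its two
phosphates can trigger a contact — that two-phosphate geometry is exactly
the charge-density effect that favors CDL, and it emerges from the
criterion rather than being double-counted.

The fractional contribution of each lipid type supports three
attributions: **frame** (default; a type contributes in a frame if any of
its lipids touches the protein, renormalized across types), **record**
(share of all contact records), and **molecule** (share of the distinct
lipid molecules ever contacted, i.e. the fraction of protein-bound
lipids). They answer different questions. Frame attribution follows the
"fraction of the trajectory" reading but *saturates* for abundant types
when several lipids are contacted simultaneously: if PG is present in
nearly every contact frame, its frame share compresses toward the other
types', so even a perfectly composition-proportional null does not map to
affinity 1 under frame attribution. Molecule attribution weights every
bound lipid once regardless of residence time, which makes it the
estimator of choice for affinity normalization and the one our recovery
tests use. Relative affinity divides the fractional contribution by the
membrane composition fraction (14% CDL, 30% PE, 46% PG, 10% PC for the
chromatophore membrane); 1 means no preference. Uncertainty comes from
bootstrapping replicate trajectories — percentile intervals by default,
or studentized (bootstrap-t) intervals, which hold closer to nominal
coverage when replicates are few and the per-replicate statistic is
skewed.

### Diffusion

`com_series()` returns the mass-weighted protein center of mass per
frame relative to frame 0, on laterally unwrapped coordinates (the loader
accumulates minimum-image increments so paths are continuous; z is never
wrapped). `compute_msd()` averages squared displacements over replicates,
using x/y for 2D or x/y/z for 3D. The default is a fixed time origin —
the displacement from each replicate's initial position — and
`windowed = TRUE` averages over all time origins at each lag.
`fit_fickian()` fits `msd = slope·t + intercept` by ordinary least
squares and reports `D = slope/(2N)` with both the regression standard
error and the spread of per-replicate fits; the free intercept keeps
landing transients visible instead of folding them into the slope.

The two estimators have very different sampling behavior, which matters
when validating recovery. The fixed-origin MSD of a single replicate at
lag t is an exponential-like variable with relative standard deviation
near 1, and values at different lags are strongly correlated; averaged
over 10 replicates and fitted over the full range, the fitted D has a
relative sampling spread of roughly 30% (measured by re-simulating the
estimator on known Brownian paths). The origin-averaged estimator fitted
over the first 5% of lags spreads about 6% under the same conditions.
Our recovery tests therefore use the windowed short-lag fit; the
fixed-origin curve remains the default output because it is the more
direct reading of displacement from the landing point.

## The synthetic generator

`generate_trajectory()` produces a *kinematic mimic*, not physical
dynamics: no forces, no lipid motion. That is deliberate — the analysis
code consumes geometry and statistics only, and exact ground truth
requires a generator whose every observable is prescribed.

* **Membrane**: head-group pseudo-lipids on a jittered lattice in both
  leaflets (phosphate plane ±19 Å, position jitter 0.8 Å, carbonyl
  particles 3 Å below the phosphates). Type counts follow the
  composition by largest-remainder rounding. CDL carries two phosphorus
  particles, PE/PC a nitrogen; `uniform_headgroups = TRUE` gives every
  type a single phosphorus, making contact opportunity exactly
  proportional to composition — the null membrane used in affinity
  validation. A disc under the protein start can be CDL-enriched by a
  configurable factor, so affinity bias emerges from a real spatial
  mechanism rather than relabeled contacts. Note that with the global
  CDL count fixed by composition, a large disc dilutes the local
  enrichment; validation uses a disc the Brownian path stays inside.
* **Protein**: a rigid body with a ring of lysine-like face residues
  (CA backbone atom plus a splayed CB/CD/NZ side chain whose
  mass-weighted z is zero by construction, so the body's z position *is*
  the realized insertion depth) and a four-nitrogen planar heme proxy
  whose orientation is set per frame from the sampled tilt angles. The
  face has 15 residues, calibrated so a bound protein coordinates about
  eight lipids' worth of residues per frame on the default membrane
  (8.1 ± 0.2 over ten 80 ns replicates).
* **Dynamics**: a two-state continuous-time Markov chain (exponential
  dwells; defaults k_bind 0.25/ns, k_unbind 0.05/ns, i.e. 4 ns hovers,
  20 ns bound stretches, stationary bound fraction 5/6) drives the state;
  depth is the state mean (−1 or +4 Å) plus Gaussian noise (0.8 Å);
  lateral motion is Brownian with state-dependent D (defaults 0.798 and
  0.615 Å²/ns, the magnitudes reported for cytochrome c2 lateral and
  bulk diffusion in simulation studies); tilt angles are
  axial wrapped normals about 77.5/72.2/101.1° with per-angle
  concentrations (40 for phi_beta, 12 for the others) reproducing the
  tighter phi_beta spread. The default run starts 40 Å above the
  midplane and relaxes down with a 12 ns time constant, placing arrival
  near 40 ns; recovery studies disable the descent to get stationary
  statistics from frame 1.
* **Determinism**: identical config and seed give byte-identical output.
  Per-replicate seeds are drawn through the RNG from the base seed, so
  replicate streams are distinct within a family and disjoint across
  nearby base seeds — a plain `seed + replicate` scheme would make two
  adjacent base seeds share almost all replicates, silently correlating
  supposedly independent datasets.

What passing recovery tests on this generator shows — and what it does
not. They show the estimators are correct on data satisfying their
assumptions: rigid protein, static lipids, Markovian switching, Gaussian
fluctuations, Fickian lateral motion. Real trajectories add lipid
diffusion, protein flexibility, anomalous diffusion at short times, and
force-field artifacts; none of these is emulated, so the tests validate
the *analysis*, not the simulation physics.

## Numerical choices and degenerate inputs

* Histogram bins are edge-aligned at 0 Å; a single-valued depth series
  still produces one bin and one peak.
* Peak prominence uses the standard topographic definition (height above
  the higher of the two flanking saddles); plateaus count once.
* Plane fitting rejects fewer than three ring atoms or collinear atoms
  with an error; near-flat rings are flagged degenerate instead.
* The neighbor search is a cell list with at-least-cutoff-sized cells and
  27-cell lookups under periodic wrapping; it is validated against an
  exhaustive all-pairs oracle, and falls back gracefully when the box is
  smaller than three cells.
* Replicates of unequal length are truncated to the shortest with a
  warning; zero-length inputs error early with informative messages.
* PDB round trips are exact to the format's 0.001 Å; the writer patches
  the segment-id column and CRYST1 record that generic writers omit.

## Known limitations

* Only orthorhombic boxes are supported; triclinic cells are not.
* The loader reads multi-MODEL PDB and DCD; XTC is not supported.
* Orientation assumes a single heme; multi-domain or multi-cofactor
  proteins need per-selection runs.
* Frame-based contact attribution saturates under multi-lipid contact
  (see above); compare attributions before interpreting affinities from
  dense interfaces.
* The generator's lipids are static; analyses whose power depends on
  lipid mixing (e.g. residence-time statistics) cannot be validated
  against it.
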