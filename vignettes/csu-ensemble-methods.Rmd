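---
title: "Hinge ensembles, clustering and anisotropic map analysis with csutools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge ensembles, clustering and anisotropic map analysis with csutools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csutools)
```

## The scientific problem

In bacterial chemotaxis the histidine kinase CheA sits at the base of the
chemoreceptor array as part of the core signaling unit (CSU): two receptor
trimers-of-dimers, a CheA dimer and CheW monomers. The catalytic P4 domain
of CheA is conformationally mobile: it hangs from the P3 dimerization
bundle by a short backbone hinge of three residues, and its position
relative to the P5/receptor baseplate varies between classes of
conformations (dipped and undipped). `csutools` implements, at desk scale,
the computational machinery used to characterize this mobility:

1. **Rigid-body hinge sampling** — annealed Monte Carlo over the phi/psi
   dihedrals of the hinge, with the mobile domain held internally rigid
   and the rest of the structure fixed;
2. **Closure filtering** — removal of conformations whose severed-linker
   anchors are too far apart to be bridged by the excised loop;
3. **Ensemble analysis** — QCP minimum-RMSD superposition, PCA of the
   mobile-domain motion, centroid-linkage (UPGMC) hierarchical clustering
   and k-medoids (k = 1) representative selection;
4. **Trajectory statistics** — salt-bridge occupancy with the
   outermost-side-chain-carbon criterion, center-of-mass drift, site
   separations, and honeycomb-lattice geometry;
5. **Density-map tools** — map simulation from atomic models, thresholded
   local cross-correlation, conical Fourier shell correlation (FSC) for
   anisotropic resolution, and FSC-driven anisotropic low-pass filtering.

Because the original inputs (sub-tomogram averages, a fitted CSU model,
long explicit-solvent MD trajectories) are not reproducible at desk
scale, the package ships synthetic-data generators that plant known,
recoverable ground truth. Every stage is validated by recovering what
was planted.

## Hinge model and sampling

A `HingeSpec` names a chain, an inclusive hinge residue range (three
residues in the reference system), the rigid mobile domain downstream of
the hinge, and the sampled dihedrals (by default all six phi/psi of the
hinge). A rotation of dihedral *d* by `delta` degrees moves the
hinge-residue atoms C-terminal of the rotated bond plus the whole mobile
domain; nothing else moves — in particular a scaffold that is C-terminal
in *sequence* but held static does not move. The sign convention is
IUPAC: a positive `delta` increases the measured dihedral; internally
this is a rotation by `-delta` about the bond vector from the second to
the third defining atom. Rotation is an exact isometry of the mobile
body, which the tests assert to 1e-9 angstrom and the acceptance suite
re-checks over a thousand sampled frames at 1e-6 angstrom.

The sampling energy is a deliberately minimal soft-sphere repulsion
between the mobile domain and the static scaffold:
each cross-pair closer than the sum of its van der Waals radii
contributes `scale * (1 - d/(r_i + r_j))^exponent` (defaults: exponent
2, scale 1, radii H 1.20, C 1.70, N 1.55, O 1.52, S 1.80 angstrom).
This models the only role the annealing energy plays in hinge sampling —
steric exclusion — without pretending to be a force field. Hinge
residues are excluded from the energy, mirroring the removal of hinge
side chains in the reference protocol, and pairs within one residue of
each other in sequence are excluded as bonded/1-3 neighbours.

The annealer perturbs all sampled dihedrals with independent Gaussian
steps (default sigma 8 degrees, wrapped to (-180, 180]) and accepts by
Metropolis with either a geometric cooling law (default, initial
temperature 2, final 0.01 in energy units) or a Tsallis-style
generalized visiting schedule (`schedule = "gsa-visiting"`, shape
parameters `visiting_shape = 2.62`, `acceptance_shape = -5`). The
generalized parameters are explicit configuration defaults drawn from
common biomolecular generalized-annealing practice, not a claim about
any particular published run, which is why both schedules are exposed.
Every accepted state (including the start, step 0) is recorded;
identical seeds give byte-identical ensembles. Two-round sampling picks
`n_seeds` well-separated round-1 conformations by greedy maximin on
pairwise all-C-alpha RMSD (starting from the lowest-energy frame), runs
one chain from each, concatenates and deduplicates by exact coordinate
equality.

The closure filter retains frames whose anchor-centroid distance is at
most `max_distance` (default 18 angstrom, the span of the four excised
loop residues — about 4 x 4.5 angstrom of extended chain). The boundary
is inclusive: 18.0 survives, 18.1 does not.

## Dissimilarity, PCA, clustering

Pairwise dissimilarity is the QCP minimum RMSD over **all** C-alpha
atoms. This matters: the mobile domain is internally rigid, so a
mobile-only pairwise RMSD would be identically zero for every pair —
the static scaffold must participate so that the superposition is
anchored and the RMSD measures mobile-domain displacement. The QCP
implementation finds the largest eigenvalue of the quaternion key
matrix by Newton iteration on its quartic characteristic polynomial;
it considers proper rotations only (a mirror image retains non-zero
RMSD), and it agrees with an independent Kabsch/SVD implementation to
1e-8 angstrom over hundreds of random point-set pairs. One numerical
caveat is documented in the tests: for nearly identical large point
sets the characteristic-polynomial root is limited by double precision
to about `sqrt(eps * G / N)` (~1e-6 angstrom for the toy system), which
is why exact-zero assertions use small point sets.

PCA operates on flattened Cartesian C-alpha coordinates of the mobile
domain after (optional) Kabsch alignment of each frame onto the static
region, so the decomposition sees internal motion only. Reported
variance fractions sum to one and projections are centered.

Clustering is agglomerative with the centroid (UPGMC) criterion, run on
squared dissimilarities via `stats::hclust` (the standard formulation
of centroid linkage) with merge heights reported back on the RMSD
scale. Centroid linkage can produce height inversions, so flat clusters
are obtained by cutting on the monotonized (subtree-maximum) heights —
the same convention as the distance criterion of
`scipy.cluster.hierarchy.fcluster`. The cut is placed at
`cutoff_fraction` times the maximum merge distance; the default 0.3 is
the midpoint of the conventional 20-40% band used when the cut is
chosen by dendrogram inspection. Each flat cluster's representative is
its medoid (k-medoids with k = 1), with exact ties broken by the lowest
frame index.

## Trajectory statistics

A salt bridge is counted in a frame when the designated outermost
side-chain carbons of an acidic and a basic residue are strictly closer
than 7.0 angstrom, and a pair is *persistent* when its occupancy
strictly exceeds one third of the frames — a pair at exactly 1/3 is not
persistent. The atom designation table (ASP CG, GLU CD, ARG CZ, LYS CE,
HIS CE1) is exposed in `salt_bridge_params()` because the criterion
names the rule, not the table. The optional hydrogen-bond confirmation
step used in the original workflow is not reimplemented; occupancy and
the strict persistence rule are the deliverable here.

`com_drift()` superposes each frame on an alignment selection (Kabsch)
and reports the mass-weighted centroid displacement of an analysis
selection relative to frame 1, optionally projected on an asymmetry
axis; `site_separation()` is the centroid distance between two
selections; `hex_lattice_constant()` maps a trimer-trimer separation
`d` to the honeycomb vertex-lattice spacing `sqrt(3) * d` (7.4 nm gives
12.8 nm to three significant figures).

## Density maps, conical FSC and anisotropic filtering

`simulate_map()` sums mass-weighted isotropic atomic Gaussians whose
width is tied to the nominal resolution by requiring the single-atom
Fourier amplitude to fall to one half at spatial frequency
1/resolution: `sigma = resolution * sqrt(ln 2) / (sqrt(2) * pi)`. Each
atom integrates to its mass (the grid integral is proportional to the
total mass within 1% when the resolution is at least ~4 voxels; the
hard precondition is the Nyquist bound of 2 voxels). Gaussians are
truncated at 4.5 sigma.

The conical FSC divides reciprocal space into 13 cones of 42 degree
half-angle: the three principal axes plus the ten axes bisecting them,
which in three dimensions are the six face-diagonal and four
body-diagonal directions (axes are unsigned; each cone includes its
antipode). The covering radius of this axis set is about 27.6 degrees,
so 42 degree cones cover every direction — asserted exhaustively on a
64-cubed grid. Within each cone, shells one reciprocal voxel wide
accumulate `FSC = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)`;
empty bins are flagged absent and skipped (interpolated over) during
resolution estimation. The per-cone resolution is the linearly
interpolated first downward crossing of the criterion (default 0.143,
configurable), floored at the Nyquist resolution and flagged when the
curve never crosses.

`anisotropic_lowpass()` attenuates each Fourier voxel by its cone's
low-pass response (hard cutoff or cosine edge); voxels inside several
overlapping cones take the *average* of the overlapping responses —
the natural symmetric choice where the reference protocol says only
that overlaps were adjusted for. A cutoff at or beyond Nyquist passes
all frequencies, which makes the filter exactly transparent when every
cone resolves to Nyquist, and the isotropic special case matches a
direct radial filter to 1e-6. The local cross-correlation
(`local_ccc()`) is a Pearson correlation over voxels that exceed a
solvent threshold (default mean + 1 SD of the experimental map, since
no threshold value is prescribed by the reference workflow) and lie
within a dilation radius of a region of interest.

Maps are read and written as MRC2014 mode-2 (float32) files with the
x-fastest axis order; the voxel size is carried in the cell dimensions
and the origin in the ORIGIN header words.

## What the synthetic data emulates — and what it does not

`make_toy_hinge_protein()` builds an ideal alpha-helical two-domain
system: a static scaffold helix, a three-residue hinge, a rigid mobile
helix, and a second static scaffold placed alongside the mobile
domain's far end whose first backbone nitrogen serves, together with
the mobile domain's last carbonyl carbon, as the closure anchor pair
(initial gap 6 angstrom). Ideal helix parameters (rise 1.5
angstrom/residue, radius 2.3 angstrom, twist 100 degrees/residue) are
used instead of a real fold because planted geometry must be
analytically checkable — consecutive C-alpha distances are 3.83
angstrom by construction. The backbone is N, CA, C, O, CB; no
hydrogens, no protonation, no side-chain rebuilding.

`make_planted_trajectory()` plants charged contacts at exact target
distances in an exact fraction of frames (the fraction times the frame
count must be integral, or the generator refuses), then adds isotropic
Gaussian jitter. `make_half_maps()` plants resolution anisotropy by an
extra per-axis Gaussian blur and adds two independent seeded noise
realizations at a chosen SNR; the truth record carries the effective
per-axis resolution.

Passing the planted-recovery tests demonstrates that the algorithms
recover known structure under controlled, idealized conditions. It does
not demonstrate robustness to features of real data the generators do
not model: missing-wedge artifacts and CTF effects in tomographic maps,
force-field-driven correlated motion, side-chain rearrangement at the
hinge, or solvent effects. In the same spirit, the clash-only sampling
energy is far more permissive than an implicit-solvent potential: on
the toy system the chain wanders widely and the closure filter removes
the majority of frames, whereas with a realistic energy the excluded
population is small. The filter semantics, not the rejection rate, are
the tested contract.

## Numerical and design choices

* **Dihedral sign**: IUPAC, positive `delta` increases the dihedral.
* **Medoid ties**: lowest frame index, deterministically.
* **Cut height**: fraction of the maximum (monotonized) merge distance;
  default 0.3 from the 20-40% convention.
* **FSC criterion**: 0.143 by default, configurable.
* **Cone overlap**: average of overlapping cone responses.
* **CCC solvent threshold**: mean + 1 SD of the experimental map by
  default, configurable.
* **Degenerate inputs**: QCP warns and returns the translation-only
  minimum below 3 points; a single-frame matrix clusters trivially;
  empty clash selections warn and score 0; closure anchors that resolve
  to no atoms are an error.
* **Determinism**: every stochastic routine takes a seed, restores the
  caller's RNG state, and produces byte-identical output under the same
  seed; the pipeline writes a config hash and seed into every CSV
  header.

## Problem sizes

The shipped configurations are sized for a laptop-class run: the demo
pipeline (`default_run_config()`) uses the 35-residue toy system, 2000
annealing steps per chain with 3 second-round seeds, thins the filtered
ensemble to at most 250 frames before the quadratic-cost dissimilarity
matrix, and completes in well under a minute; FSC analyses use 48- or
64-cubed grids. All of these are configuration values, and the
algorithms scale to larger inputs at the expected cost (pairwise RMSD
is O(n^2) in frames, FSC is FFT-bound).

## Limitations

The package does not perform sub-tomogram averaging, template matching,
CTF handling, homology modelling, flexible fitting (only the CCC metric
of fit quality is provided), or molecular dynamics. It therefore cannot
reproduce numbers that depend on those inputs — overall map resolutions,
the specific medoid count of the reference ensemble, or per-residue
salt-bridge tables from long MD runs; its validation standard is exact
recovery of planted ground truth plus agreement with independent
numerical oracles.
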