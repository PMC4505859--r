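---
title: "Methods: coarse-grained protein-PIP2 contact analysis and the synthetic system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained protein-PIP2 contact analysis and the synthetic system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pipbind` analyses coarse-grained trajectories of a peripheral protein over
a bilayer whose upper leaflet carries a fraction of the polyanionic lipid
PIP~2~, and identifies the basic surface residues through which the protein
transiently binds PIP~2~. Because production-quality coarse-grained
trajectories of this kind are rarely shareable, the package also builds
synthetic systems and integrates a deliberately simple Brownian-dynamics
model that reproduces the *phenomenology* such an analysis must cope with --
diffusive approach, electrostatically driven transient binding with many
association and dissociation events, simultaneous contact with several
lipids, and preference for the PIP~2~-containing leaflet -- so that every
analysis stage can be tested end to end.

## The contact model

All analyses derive from one criterion: in a frame, the protein is **bound**
when the minimal distance between any protein bead and any PIP~2~ phosphate
bead is *strictly less than* the contact cutoff (default 0.52 nm). A frame
sitting exactly at the cutoff counts as unbound; this tie rule is applied
everywhere. Distances always use the minimum-image convention in the
orthorhombic periodic box.

From the per-frame scan the package derives:

* **Binding timeline** -- per frame: bound flag, minimal distance, the
  stoichiometry $n_P$ (number of distinct PIP~2~ molecules with a phosphate
  bead within the cutoff of any protein bead), and optionally a pose label.
* **Binding fraction** -- percent of analysed frames bound.
* **Stoichiometry distribution** -- percent of *bound* frames with
  $n_P = 1, 2, 3, 4\ldots$. Normalising over bound frames (not total time)
  is what makes the classes a partition that sums to 100% while the total
  binding fraction is itself below 100%.
* **Residue occupancy** $x_i = n_i / N$ -- $n_i$ counts frames in which at
  least one bead of residue $i$ touches a PIP~2~ phosphate bead; $N$ counts
  frames in which the protein as a whole is bound. A configuration switch
  (`count_mode = "events"`) replaces both counts by contact events so that
  simultaneous multi-lipid contacts weigh more; the frame-count convention
  is the default and the one used in all shipped tables.
* **Lipid census** $N_L$ -- per lipid class (PIP~2~ and DOPC separately),
  each lipid's contact frames are normalised by the frames in which the
  protein contacts *any* lipid of that class; $N_L$ at a threshold counts
  lipids strictly above it. Thresholds nest, so $N_L(10\%) \le N_L(5\%)$.
* **Selection rule** -- a residue is reported as a binding residue when its
  $x_i$ strictly exceeds 5% in at least two simulations, or strictly
  exceeds 10% in any one. Applied to the packaged reference contact matrix
  (three simulations x 15 residues) it returns exactly the 15 residues of
  that table; this is a pure table computation and is used as an exact
  regression anchor.
* **Pose classification** -- two disjoint named residue sets ("site I": the
  basic FERM-ridge-like patch; "site II": the second patch) label each
  bound frame `I_only`, `II_only`, `both` or `neither` according to which
  sites have a residue in phosphate contact. The four labels partition
  bound frames.

Residue-level contacts are measured against PIP~2~ *phosphate* beads by
default, matching the molecule-level criterion; a switch
(`residue_contact_beads = "all"`) uses every PIP~2~ bead instead, since
reasonable analyses differ here.

### Cutoff sensitivity

`cutoff_sweep()` recomputes residue occupancies over a ladder of cutoffs
(default study ladder 0.42--0.62 nm). For the sweep the occupancy is
reported as the fraction of *analysed frames* in contact, not as
$x_i = n_i/N$: under the $x_i$ convention the denominator $N$ (bound
frames) grows with the cutoff too, so monotonicity in the cutoff is not
guaranteed and the columns are not mutually comparable. With the fixed
denominator, enlarging the cutoff can only add contact frames, and each
residue's value is exactly non-decreasing -- which is the property the
sensitivity analysis is meant to exhibit. The robustness diagnostic is the
identity of the top-$k$ residues across the ladder; at the tight end of the
ladder only the rare close-contact tail of the bound state is sampled, so
this diagnostic is computed on occupancies averaged over the available
independent runs.

## The synthetic system

`build_bilayer()` places single-head-bead lipids on two square lattices
(defaults: 0.698 nm^2 per lipid, head-plane separation 4 nm). With 331
lipids per leaflet this reproduces the reference geometry: a 15.2 nm box
edge, and after `assign_pip2(fraction = 0.10)` on the upper leaflet -- with
round-to-nearest counting, the only rule consistent with the reference
composition -- 33 PIP~2~ and 629 DOPC. Replaced lipids keep their position;
their head bead becomes the phosphate reference bead and carries the
head-group charge (default -5 e, a common coarse-grained choice for the
doubly phosphorylated inositol ring; the value is configurable and no claim
is made that it reproduces any specific force field).

Lipids are single beads (optionally a tail is conceptually irrelevant)
because every statistic the package computes touches only head/phosphate
beads and minimal distances, never lipid internal structure.

`build_toy_protein()` puts one backbone bead per residue on a Fibonacci
spherical shell (2% seeded radial jitter, seeded random global rotation,
centre of geometry at the origin). Chosen residues are "basic" and carry a
positive charge; `clustered_residue_ids()` returns a contiguous surface
patch for planting binding sites. `build_elastic_network()` connects every
bead pair closer than 0.9 nm with a 500 kJ mol^-1 nm^-2 harmonic bond at
its build-time rest length. Because the integrator treats the protein as a
single rigid body (see below) the network contributes no forces; it is
exported for topology completeness and doubles as a rigidity audit -- after
any run, rest lengths must still equal the pair distances to 1e-6 nm.

`place_protein()` defines the "membrane surface" as the mean z of the
upper-leaflet head beads (the reference geometry does not pin this down
further) and positions the protein so the z-distance from its lowest bead
to that plane equals the requested gap exactly, x-y centred.

One geometric subtlety matters in a z-periodic box: the *image* of the bare
lower leaflet sits above the protein. If the box is too short, that image
is closer than the intended gap and the protein reaches the wrong leaflet
first. The packaged toy geometry (box 5.6 x 5.6 x 11 nm, bilayer mid-plane
at z = 2.5 nm, gap 1.5 nm) keeps the wrap distance to the bare leaflet
about twice the gap to the PIP~2~ leaflet, while still letting the protein
visit both leaflets -- as it should, since the leaflet-preference
diagnostic depends on both being reachable.

## The Brownian-dynamics toy simulator

The simulator is intentionally *not* a force field. It is an overdamped
Langevin integrator with three bead classes:

* **Protein**: one exactly rigid body. Forces and torques from all
  protein-lipid and protein-ion pairs are summed; the centre of mass takes
  a drift + noise translation with mobility $1/(\zeta_p n_\mathrm{beads})$,
  and the body rotates by a small axis-angle step (Rodrigues formula) with
  free-draining rotational drag $\zeta_p \sum_i |r_i - r_\mathrm{COM}|^2$.
  Because each step applies one proper rotation matrix, intra-protein
  distances are conserved to floating-point accuracy (drift over a full
  run is far below the 1e-6 nm audit tolerance). The body is periodically
  wrapped by its centre of mass so it never fragments across the boundary.
* **Lipid heads**: free lateral diffusion, harmonic z-restraint
  (100 kJ mol^-1 nm^-2) to their leaflet plane. Lipid-lipid nonbonded
  terms are omitted: the heads behave as an ideal 2-D gas, which makes the
  PIP~2~--PIP~2~ RDF an exact uniform null in the absence of a protein --
  a feature, since the no-recruitment comparison then tests the RDF
  machinery against a known truth.
* **Ions** (optional): free 3-D diffusion with ion-lipid and ion-protein
  interactions.

Interactions are screened Coulomb (Yukawa)
$E = k\, q_1 q_2\, e^{-r/\lambda_D} / (\varepsilon r)$ plus a truncated
12-6 Lennard-Jones term, both cut at 1.2 nm with plain truncation (no
shift) -- documented as the package's dialect.

### Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| temperature | 320 K | reference simulation temperature |
| dielectric $\varepsilon$ | 78 | implicit aqueous screening; there is no explicit solvent |
| Debye length $\lambda_D$ | 0.78 nm | ~150 mM monovalent salt |
| LJ $\sigma$ | 0.47 nm | standard coarse-grained bead size |
| LJ $\epsilon$ | 2.0 kJ/mol | weak generic adhesion (~0.75 kT): lets the protein "skate" on the membrane and search laterally, reproducing the substantial neutral-lipid surface residence the reference data shows |
| basic bead charge | +3 e | an effective patch charge: 6 toy beads stand in for a 15-residue basic surface, so per-bead charge is compressed |
| PIP~2~ head charge | -5 e | conventional for the doubly phosphorylated head group |
| timestep | 0.005 ns | keeps per-step lipid noise (~0.05 nm) well below the bound-well width; at larger steps the bound state churns numerically |
| drag (protein/lipid/ion) | 1.5 / 30 / 5 kJ mol^-1 ns nm^-2 | protein reaches the membrane within tens of ns; lipids diffuse slowly enough to hold contacts |
| leaflet restraint | 100 kJ mol^-1 nm^-2 | ~0.16 nm z-fluctuation of head beads |
| run length | 16 000 steps = 80 ns, saved every 40 | the scale on which first binding (~5-40 ns) and multiple unbinding events occur |
| max drift per step | 0.08 nm | caps the deterministic displacement in steep LJ cores; prevents integrator blow-up at the occasional deep-contact overshoot |

These values were fixed while developing the simulator, by requiring the
qualitative phenomenology above, and then frozen before the test suite was
written. They are study conditions, not fitted quantities: no parameter is
tuned to reproduce any published number.

Under these conditions (seeds 1-10) a charged protein binds PIP~2~ for
roughly 10-70% of an 80-ns run with tens of association/dissociation
events, contacts up to ~5 PIP~2~ simultaneously, and its zero-charge
control binds several-fold less -- the electrostatic-driving property. The
mean bound minimal distance settles near 0.46-0.47 nm, just inside the
0.52 nm criterion, because the LJ contact minimum (~0.45 nm for
charge-balanced contact) lies there.

### What the toy does and does not emulate

It emulates: diffusive approach from a controlled gap; transient,
salt-screened electrostatic binding; multi-lipid stoichiometry; lateral
lipid mobility; leaflet asymmetry; periodic-boundary access to both
leaflets; rigid tertiary structure.

It does not emulate: force-field energetics (no claim of MARTINI
compatibility), solvent structure, barostats or thermostats of any
ensemble machinery, lipid-lipid packing or clustering (no lipid-lipid
forces), realistic kinetic rates, or protein flexibility. Consequently,
passing tests demonstrate that the *analysis* is correct and that its
statistical properties hold on data with the right structure -- they say
nothing quantitative about any real protein-membrane system.

## Spatial statistics

* **RDF**: standard pair correlation with self-pairs excluded, normalised
  by shell volume (3-D) or shell area (`lateral` mode, x-y distances) and
  the mean target density; `r_max` must not exceed half the smallest
  relevant box edge (minimum image). 3-D is the default mode, matching
  common trajectory tooling; the lateral mode exists because lipids are
  quasi-planar, and the shipped analyses use it for lipid-lipid profiles.
  A frame-range argument supports dropping an equilibration window (the
  reference analysis used the final 900 of 1000 ns); the default is the
  full range.
* **Principal axis**: leading eigenvector of the bead-coordinate
  covariance, sign-fixed to non-negative z (ties broken by x, then y);
  degenerate clouds (coincident beads, or leading eigenvalues equal within
  tolerance) are flagged, not guessed. For the orientation *distribution*
  the signed variant resolves each frame's sign by temporal continuity
  (maximal dot product with the previous frame), because an axis is a
  line, not a vector: with continuity, an isotropically tumbling body
  yields V_z uniform on [-1, 1], which is the null the tests check by a
  chi-square goodness of fit. A folded (|V_z|) variant is also emitted;
  neither is claimed to be "the" published convention, which is not
  pinned down.
* **COM axis**: unit vector between centres of mass of two residue-set
  unions, equal bead masses unless the topology provides a `mass` column
  (coarse-grained beads are near-uniform in mass).

## Numerical and degenerate-input choices

* Strict `<` at every threshold (binding cutoff, census thresholds,
  selection rule); frames exactly at a boundary fall on the unbound /
  excluded side.
* Never-bound trajectories: binding fraction 0, stoichiometry and pose
  tables come back zero-row with an `empty` attribute (never NaN), the
  residue table carries `undefined = TRUE` with NA occupancies, first
  binding time is NA.
* PIP~2~-free topologies: the analysis pipeline degrades to an explanatory
  note rather than an error; the low-level criterion functions refuse to
  run (validation error), since "no phosphate beads" usually indicates a
  wiring mistake.
* All randomness flows from one integer seed per operation through a
  private RNG stream that never disturbs the caller's RNG state; rebuilt
  outputs are byte-identical. Lipid replacement counts use
  round-to-nearest with halves up.
* GRO output is fixed-column with 3-decimal coordinates; the round-trip
  error bound (5e-4 nm) is asserted, and all readers fail with located
  errors rather than coercing malformed input (including non-ASCII minus
  signs in topology tables).

## Problem sizes used by the shipped tests

The test suite and the acceptance script run the packaged toy conditions:
a 5.6 nm bilayer patch (49 lipids per leaflet, 5 PIP~2~), a 30-residue
protein with a 6-residue planted basic surface split over two patches, and
80-ns runs (401 saved frames). Statistical checks use 10 seed-paired
charged/neutral run pairs, planted-site recovery averages 5 runs, and
oracle comparisons use systems of up to 100 beads against explicit
O(n^2) reference loops. Composition checks build the full-scale 662-lipid
geometry, which is instantaneous; only dynamics is scaled down.

## Known limitations

* The simulator's kinetics are not calibrated; first-binding times and
  event counts are qualitative.
* The lipid census for DOPC applies the same 0.52 nm criterion to DOPC
  head beads (the natural reading, but an assumption).
* Footnote-style lipid normalisation ("contacts of a specific lipid over
  total contacts with that class") is interpreted frame-wise; an
  event-wise variant is available through `count_mode`.
* With very small analysed-frame counts the occupancy ranking is
  tie-dominated; the cutoff-robustness diagnostic therefore pools runs
  (see above) rather than trusting a single short trajectory.
* At the toy patch size, a bound protein visibly perturbs the global
  PIP~2~--PIP~2~ RDF: gathering 2-3 of only 5 PIP~2~ is detectable in a
  5.6 nm box, whereas a full-size bilayer (33 PIP~2~ over 15.2 nm) dilutes
  the same local enrichment. The with/without-protein RDF comparison in
  the analysis workflow is therefore reported descriptively, not asserted
  as a null.
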