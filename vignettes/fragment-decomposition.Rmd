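---
title: "Per-residue interaction-energy decomposition with conjugate caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue interaction-energy decomposition with conjugate caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdecomp)
library(dplyr)
```

## The problem

When a small molecule — here, a steroid-like ligand — binds a protein, the
total binding-site interaction energy is an aggregate that hides which
residues actually hold the ligand in place. Fragment-based decomposition
answers the per-residue question: for each binding-site residue $R_i$, what
is the interaction energy between $R_i$ and the ligand, computed in a way
that respects the electronic environment of $R_i$ inside the chain?

The scheme implemented here is molecular fractionation with conjugate caps
(MFCC). A residue cannot simply be cut out of the chain: severing its two
peptide bonds creates radicals whose energies are meaningless. Instead,
$R_i$ is kept flanked by *conjugate caps* — its sequence neighbours
$R_{i-1}$ and $R_{i+1}$, severed one bond further out and passivated with
hydrogens — and four auxiliary systems are formed:

* $S_1$: caps + $R_i$ + ligand
* $S_2$: caps + $R_i$
* $S_3$: caps + ligand
* $S_4$: caps alone

The residue–ligand interaction energy is the combination

$$E(\mathrm{lig}\!-\!R_i) \;=\; E_{S_1} - E_{S_2} - E_{S_3} + E_{S_4}.$$

Every energy contribution that involves a cap (cap internal energy,
cap–residue, cap–ligand) appears twice with opposite signs, so for any
pairwise-additive energy function the combination reduces *algebraically*
to the direct residue–ligand cross-term. For a quantum-mechanical backend
the cancellation is no longer exact, which is the point: the caps let the
severed residue keep a realistic electronic neighbourhood while the
combination removes their contribution to leading order.

## Design of the fragmentation

**Cap extent.** The caps are the *full* adjacent residues (backbone and
side chain), severed at their distal backbone bonds: the
$C_{i-2}\!-\!N_{i-1}$ bond on the amine side and the
$C_{i+1}\!-\!N_{i+2}$ bond on the carboxyl side. Using whole residues is
the most conservative reading of "caps formed from the immediately
adjacent residues", and it makes the cancellation tests strict — larger
caps mean larger terms that must cancel.

**Passivation.** Each severed bond is capped with a hydrogen placed on the
original bond vector, at 1.01 Å from nitrogen and 1.09 Å from carbon
(standard amide N–H and aliphatic C–H lengths). A chain terminus
contributes a single cap, and a cap whose distal bond does not exist needs
no passivation. Fragment construction is deterministic: identical inputs
give bit-identical geometries, and `assemble_systems()` reuses one
fragment object so cap coordinates are byte-identical across $S_1$–$S_4$.

**Selection.** Residues enter the decomposition when their closest atom
lies within `residue_cutoff` of the ligand (default 10 Å, inclusive, any
atom). Waters within `water_cutoff` (default 2.5 Å) of a selected residue
or of the ligand are treated as bridging waters. With
`water_policy = "all_systems"` identical copies of those waters are placed
in all four systems — so a classical backend cancels them exactly (the
package asserts this numerically) and a quantum backend sees the bridging
environment in every term. The alternative `"none"` omits them everywhere.
Where bridging waters sit within the four systems is genuinely
underdetermined by the method's description; placing them identically
everywhere is the only choice that preserves the cancellation structure,
which is why it is the default.

**Proline and nonstandard residues.** A proline cap is severed at its
backbone nitrogen like any other residue and its ring is kept intact.
Residues lacking N/CA/C backbone atoms raise a topology error rather than
guessing.

## Energy backends

The MFCC core consumes an `energy_backend()`: a function from an atom
table to one energy in kcal/mol plus a pairwise-additivity flag.

The built-in classical backend (`pairwise_backend()`) sums a screened
Coulomb term $k\,q_iq_j/(\varepsilon_r r_{ij})$ with
$k = 332.0637\ \mathrm{kcal\,Å\,mol^{-1}e^{-2}}$ and a Lennard-Jones term
with Lorentz–Berthelot combining. Defaults: $\varepsilon_r = 40$, echoing
the implicit-solvent dielectric used for the quantum single points this
backend stands in for (the choice of 40 rather than ~78 for bulk water is
inherited and configurable), and a small generic per-element LJ table
(H, C, N, O, S) that makes no force-field claim — the backend is a
verification instrument. **No cutoffs** are applied anywhere: a cutoff
would break the algebraic cancellation that the exactness tests rely on.

`external_backend()` documents the file-exchange contract for wiring in a
quantum engine (write fragment PDB + XYZ, read one total energy in
Hartree, convert at 627.509474 kcal/mol per Hartree); nothing in the
package invokes an external engine.

With a pairwise backend and a ligand region map, `decompose_site()` also
attributes each residue energy exactly to the ligand regions (i/ii/iii) by
restricting the cross-pair sum to each region's atoms; ligand atoms
missing from the map (typically hydrogens) follow their nearest mapped
heavy atom so the attribution still sums to the residue energy. For
non-additive backends only a nearest-region tag is reported — per-region
energies are not claimed where they cannot be computed exactly.

## Hydrogen bonds and contacts

Detection is purely geometric: donor–acceptor distance at most 3.4 Å and,
when the donor carries an explicit hydrogen, a D–H···A angle between 90°
and 180°. Both boundaries are inclusive ("maximum of 3.4", "between 90 and
180"), implemented with a $10^{-9}$ numerical slack so an exactly planted
boundary geometry is accepted while anything $10^{-6}$ beyond is rejected.
Donor/acceptor typing substitutes a standard chemical rule for the
commercial tool the original workflow delegated to: N and O bearing a
covalently bonded hydrogen (H within 1.3 Å) donate; N and O — optionally S
— accept. Structures with no explicit hydrogens at all degrade to flagged
distance-only detection rather than silently failing.

Occupancy is the fraction of trajectory frames in which a given
donor–acceptor pair satisfies the criteria, reported as an exact rational
percentage. A water bridges two groups when it simultaneously satisfies
the criteria with at least one atom of each.

Contact typing inside the 4 Å interaction shell is a deliberately simple
ordered rule set (hydrogen bond, then carbon–carbon hydrophobic, then van
der Waals residual) and is documented as approximate relative to
proprietary interaction taxonomies; the rule table is replaceable.

## Trajectory descriptors

RMSD uses Kabsch least-squares superposition (proper rotation, determinant
+1). Defaults follow the common usage for these curves: heavy atoms,
reference = first frame (the original study does not state its reference;
this is recorded as a convention, not a claim). ΔRMSD over a window is
max − min of the values inside the closed window. RMSF superposes every
frame (two passes when fitting to the mean structure), computes per-atom
root-mean-square displacement about the time-mean position, and averages
atoms within each residue; mass weighting is off. Single-frame input warns
and returns zeros rather than erroring.

## Conformational ensembles

The pipeline mirrors ensemble-generation practice: `filter_frames()` drops
frames with non-finite coordinates or mismatched topology (with reasons),
`featurize()` flattens selected coordinates after optional alignment to
the first frame, `reduce_dimensionality()` embeds, `fit_gmm()` clusters,
`representative_conformations()` averages member frames' coordinates after
superposition, and `rank_conformers()` orders conformers by total
decomposed energy with the extremes flagged.

Two reductions are provided. `linear_projection` is principal-component
projection — fully deterministic and the path used by the package's own
tests. `neighbor_graph_nonlinear` is an isomap-style embedding: a
symmetrised k-nearest-neighbour graph, graph-geodesic distances, classical
MDS. It was chosen as the nonlinear method because it is a neighbourhood-
graph technique in the same family as the manifold learner used in the
original workflow, yet deterministic and dependency-light; exact
reproduction of any particular embedding is not claimed, and the
clustering results the package asserts are robust to either choice.
Disconnected neighbour graphs are bridged by their closest cross-component
pair so the embedding is always defined.

Mixtures are fitted with EM (via mclust); `k = "auto"` selects the number
of components by BIC over $k \in 1..8$ and records the criterion trace.
The study this design follows reported 4, 3 and 5 clusters for its three
complexes without stating a criterion; BIC is the standard default. Labels
are hard assignments (argmax responsibility, 1-based). Representative
conformations are raw coordinate means of member frames — no geometry
re-idealization — matching the averaging description the pipeline follows.

## Reported statistics

`ensemble_stats()` always computes both standard-deviation conventions
(population, denominator $n$; sample, denominator $n-1$) because published
energy tables in this area mix them: in the bundled table the FA1 rows
match the population convention and the FA6 DHT/TES rows match the sample
convention. The displayed coefficient of variation uses the configured
convention (default sample); `present_stats()` applies table rounding
(mean 1 d.p., σ 2 d.p., CV 1 d.p.) and can recompute CV from rounded
values to mirror published tables. One bundled row (EST at FA6) prints a
mean of −43.4 that is inconsistent with its own per-conformation values
(they average −51.0); the package flags the row and always reports
recomputed statistics, while the combined two-site means — which the
source derives from its printed means — are computed from the printed
values, as inputs.

Pose classification substitutes a reproducible geometric rule for what is
usually a visual call: a pose joins the site whose defining residues are
closest (closest-atom distance, within `assign_cutoff`), frequencies are
counted per site, and the lowest-score pose per site is surfaced, with the
two most frequent sites as the headline pair. Score ties break by pose
identifier.

## The synthetic generators, and what they do not emulate

All tests run on synthetic complexes:

* `make_peptide()` — polyalanine with idealized geometry (N–CA 1.458,
  CA–C 1.525, C–N 1.329 Å; standard angles; extended or helical
  dihedrals). Chemically plausible, not energy-minimized.
* `make_steroid_like_ligand()` — a rigid planar fused-ring mimic of the
  steroid nucleus: three six-membered rings, one five-membered ring,
  17 carbons plus O3 and O17, with a validated three-region map
  (i = first ring + O3, ii = middle ring, iii = remaining rings + O17).
* `make_complex()` — exact closest-atom contact distance placement
  (root-finding to $10^{-12}$), per-residue zero-sum charges so Coulomb
  sums stay bounded, full parameterization for the pairwise backend.
* `make_clustered_trajectory()` — cluster centers are ligand translations
  with minimum pairwise offset `separation * noise_sigma`; frames add
  isotropic Gaussian noise to every coordinate; planted labels returned.
* `plant_hbond()` — exact planted donor–acceptor distance and D–H···A
  angle (to $10^{-6}$), creating the donor hydrogen when the heavy-atom
  peptide lacks one.
* `make_docked_poses()` — rigid ligand copies jittered around named sites
  with caller-supplied scores.

Defaults mirror the study conditions the analyses assume: 10 Å residue /
2.5 Å water cutoffs, 3.4 Å / 90–180° hydrogen bonds, 4 Å contact shell,
dielectric 40, 300-frame trajectories with 3 planted clusters at 8× noise
separation, 20 docking poses. Noise σ of 0.1 Å was chosen as a
representative per-coordinate thermal jitter for a well-equilibrated
binding site; it is a generator parameter, not a claim about any real
trajectory.

What the generators do **not** emulate: real force-field energetics,
solvation boxes, protein folds (the peptide is a short idealized chain),
anisotropic or time-correlated dynamics, and gradual conformational
drift. Passing tests therefore demonstrate the *algebraic and statistical
correctness* of the machinery — exact cancellation, exact geometry
criteria, recovery of planted structure — not agreement with any
experimental system. Quantities that depend on external structures, MD
engines or quantum chemistry are out of reach at this scale by design;
the published per-conformation energy table bundled with the package is
used as a worked input for the statistics layer.

## Numerical choices

* Boundary comparisons (hydrogen-bond distance/angle, contact shell) use a
  $10^{-9}$ slack: exact planted boundaries pass, $10^{-6}$ violations
  fail.
* MFCC exactness is asserted at $10^{-8}$ kcal/mol over 50 seeded
  complexes (observed error is ~$10^{-10}$, accumulated floating-point
  only).
* Energies are evaluated without cutoffs; distances via cross-product
  matrix algebra with a clamped non-negative square root.
* Degenerate inputs fail loudly: empty atom groups, unsorted radii,
  k larger than the frame count, collinear superposition selections, and
  coordinate fields that overflow fixed-width PDB formatting all raise
  typed errors; empty clusters are skipped with a warning.
* Test problem sizes — 5–12-residue peptides, a 19-atom ligand, 300-frame
  trajectories, 20 recovery seeds, 50 exactness seeds — were chosen as the
  smallest sizes at which every asserted property is non-trivial.

## Known limitations

* Only multi-model PDB trajectories are read; binary MD formats need
  external conversion.
* Donor/acceptor typing and contact typology are rule-based
  approximations; His tautomer names are preserved verbatim, never
  normalized.
* Per-region energy attribution is exact only for pairwise-additive
  backends.
* The isomap-style embedding is a stand-in for any particular nonlinear
  manifold learner; embeddings are not comparable across methods, only
  the downstream cluster structure is.
* `combined_site_mean()` is a two-value magnitude average; it is an
  aggregate for cross-site comparison, not a thermodynamic quantity.
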