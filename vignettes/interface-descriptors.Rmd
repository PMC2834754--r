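---
title: "Profiling protein-protein interfaces with known inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protein-protein interfaces with known inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiprofiler)
```

## The problem

Protein-protein interactions (PPIs) were long considered poor drug targets:
their interfaces are large, flat and featureless compared with enzyme active
sites.  Yet a growing set of PPIs has been disrupted by small molecules
binding directly at the interface.  `ppiprofiler` asks, quantitatively, what
those druggable interfaces look like.  It computes a panel of structural
descriptors from raw PDB coordinates, bundles a curated reference table of
17 protein/protein complexes (14 families, 56 known interface inhibitors),
and scores how closely a query interface resembles that reference
distribution.

The reference complexes split into two classes by the number of continuous
interface segments: **class I** (fewer than six segments) are
protein/peptide-like interactions where a single helix or strand binds in a
groove — small interfaces (mean one-side buried area 532 Å²) with low
hydrogen-bond density (0.42 per 100 Å²) and micromolar affinities; **class
II** (six or more segments) are globular/globular interfaces — larger (769
Å²), denser in hydrogen bonds (0.64), with nano- to sub-nanomolar
affinities.

## The descriptor panel

All descriptors derive from a ΔASA interface definition:

* **Interface size (ASA)** — solvent-accessible surface area is computed by
  the Shrake–Rupley method (probe 1.4 Å, Bondi element radii, 960
  deterministic Fibonacci lattice points per atom, heavy atoms only).  The
  interface is the area each partner loses on complexation; the headline
  descriptor is the mean of the two sides, `(ΔA + ΔB)/2`, matching the
  per-complex scale of the reference table (241–947 Å²).  Atoms losing more
  than 0.1 Å² (a numerical-noise floor at 960 points) are interface atoms.
* **Planarity** — RMS distance of interface atoms from their least-squares
  plane (principal-component fit).
* **Eccentricity** — ratio of in-plane principal *axis lengths*,
  `sqrt(λ₂/λ₁)`; 1 is circular.  The square-root (length, not variance)
  convention is a documented choice; the reference range 0.42–0.89 is
  compatible with either.
* **Gap volume and gap-volume index (GVi)** — a grid estimator of the empty
  volume between the partners' van der Waals surfaces (cells outside every
  atom, within 5 Å of both partners; 1 Å grid).  GVi divides by the total
  two-side ΔASA (the Jones–Thornton convention).  Some printed reference
  GV/ASA/GVi triples are mutually inconsistent under any single formula, so
  the pipeline always recomputes GVi and the bundled table keeps the
  printed values verbatim.
* **Hydrogen-bond density** — cross-interface bonds per 100 Å² of
  one-side-equivalent area, with a 3.2 Å hydrogen–acceptor cutoff.  Crystal
  structures rarely carry hydrogens, so a polar hydrogen is modelled at
  ideal bond length (1.0 Å N–H, 0.96 Å O–H) directed at the candidate
  acceptor, with a ≥90° antecedent–donor–acceptor sanity filter
  (configurable off).  Full sp²/sp³ hydrogen frames are deliberately not
  built: at the 3.2 Å resolution of the rule they change little, and the
  directed-hydrogen model is exact for rotatable donors.
* **Salt bridges** — acidic (Asp/Glu) side-chain oxygen within a strict
  4.0 Å of a basic (Arg/His/Lys) side-chain nitrogen across the interface,
  one bridge per residue pair.  His counts as basic and as charged.
* **Interface segments** — maximal stretches of interface residues allowing
  up to `max_gap = 4` intervening non-interface residues (the bounded-gap
  parameter is exposed because the segment literature does not fix it);
  only interface residues count toward segment length.  Fewer than six
  total segments ⇒ class I.
* **Secondary-structure class** — per-side helix/strand fractions over
  interface residues from a self-contained dihedral-window assigner
  (helix φ ∈ (−120°, −20°), ψ ∈ (−100°, 10°); strand φ ∈ (−180°, −60°),
  ψ > 60° or < −150°; runs shorter than 3 revert to coil; chain breaks are
  coil).  The four-way label uses the 30% rule (H, S, HS, Coil).  A
  hydrogen-bond-pattern refinement was considered and dropped: the coarse
  30% classes do not need it.
* **Pockets** — a united-atom methyl probe (σ 3.6 Å, ε 0.16 kcal/mol,
  Lorentz–Berthelot combination with per-element parameters) is evaluated
  on a 0.9 Å grid; probes with Lennard-Jones energy ≤ −3.5 kcal/mol are
  clustered by single linkage at 1.6 Å, ranked by total energy, at most 10
  kept.  Pockets are detected on the *free receptor* and only those at
  least partly occupied by the superposed inhibitor (a probe point within
  2 Å of a ligand atom) count as interface pockets.  The −3.5 kcal/mol
  default was fixed once against constructed geometry: flat or convex model
  surfaces peak near −3.1 kcal/mol, enclosed cavities reach −7.5, so the
  cutoff admits only genuine concavities.  All pocket constants are
  configuration values; absolute pocket volumes are order-of-magnitude
  quantities, not reproductions of any specific server's numerics.
* **RMSD** — Kabsch (SVD) superposition over Cα atoms paired by chain and
  residue number, measuring the conformational change between unbound and
  complexed forms.
* **Inhibitor coverage (H_ASA)** — of the ASA the target's interface atoms
  lose to the protein partner, the percentage they lose to the bound small
  molecule instead (clamped at 100).  The reference table defines this
  descriptor only by name; the interface-restricted ΔASA ratio used here
  reproduces its boundary behaviour (e.g. full coverage when the ligand
  replicates the partner epitope).

## Statistics and classification

Group comparisons use the summary-statistic t-value
`t = (M₁ − M₂)/sqrt(Var₁/n₁ + Var₂/n₂)` with |t| > 1.34 flagged (≈90%
confidence at the reference group sizes).  Variances always use the n−1
denominator — the reference class-I ASA spread (sd 198) confirms that
convention.  On the bundled panel the segment count separates the classes
at t ≈ −8.1.

Multivariate structure uses PCA on standardised descriptors (they span Å²,
Å³, counts and percentages) via the correlation-matrix eigendecomposition,
with component signs fixed so the largest loading is positive.  k-means
(k = 3, 50 restarts, seeded, labels canonicalised along PC1) runs on the
two leading component scores — the 2D map on which the reference clusters
were originally described.  With the five key descriptors printed per
complex (ASA, segments, gap volume, pocket volume, H-bond density) this
reproduces the reference cluster structure deterministically: all six
class-I complexes in one cluster and the subtilisin/eglin C and
trypsin/trypsin-inhibitor complexes in a second, away from class I.

The sixth key descriptor, the percentage of charged interface residues, is
published only as a dataset-level summary (18.9 ± 13.8%).  Where the full
six-descriptor panel is needed (druggability comparison, sensitivity
analyses) the missing column is drawn per complex from a truncated Gaussian
with those moments, under a fixed seed.  This stand-in is deliberately
labelled synthetic: adding an uninformative random column dilutes the
class-I grouping (it survives in only ~30% of seeds), which is itself
evidence that the real, structure-derived charged fractions carry signal.
`analysis/03_classify_cluster.R` quantifies this sensitivity.

## Druggability comparison

`compare_to_reference()` scores a query panel by per-descriptor
standardised distance `z = |x − mean|/sd` against the 17-complex reference:
z ≤ 0.5 is "very close", z ≤ 1 "close", else "far"; the overall score is
the mean z (lower = more like known-druggable interfaces).  The 0.5/1.0
thresholds operationalise the qualitative close/very-close reporting of the
reference resource and are exposed in the call.  The weak/strong affinity
indication picks the nearer class centroid in standardised space, encoding
the observation that class I binds weakly (micromolar) and class II tightly
(nano/sub-nanomolar); published parameter vectors for weak and strong
transient dimers are not available, so the class centroids stand in for
them.

## The synthetic-structure generator

Because validating a geometry pipeline needs structures with known ground
truth, `build_toy_complex()` generates complexes from ideal backbone
templates (NeRF chaining of bond lengths, angles and φ/ψ: helix −57°/−47°,
strand −120°/+120°) with Cβ pseudo side chains:

* `class_I_helix_groove` — a 14-residue α-helix lying in a walled groove of
  a strand-lattice receptor (wall height = `pocket_depth`); ≤5 total
  interface segments, one-side ΔASA ≈ 540 Å².
* `class_I_strand` — an extended 10-residue peptide on the receptor face.
* `class_II_globular` — two four-run faces joined by long (8-residue)
  loops, so every contacting run is its own segment: 7–10 segments, ΔASA
  ≈ 1000 Å².
* `zipA_like_flat` — a dense, smooth face whose ligand lies *on* the
  surface; its interface pockets are exactly (0, 0), mirroring the known
  flat-interface outlier among the reference targets.

Short (2-residue) inter-run loops in class-I receptors let contacting runs
merge into few segments; long loops in class-II keep them apart — segment
counts are controlled by construction, not tuned.  Engineered
hydrogen-bond sites (Ser Oγ → Asn Oδ1 at 2.75 Å) and salt bridges (Glu Oε1
↔ Lys Nζ at 3.5 Å) are placed with explicit cross-interface geometry;
charged composition is adjusted by renaming residues (truncated side
chains).  The unbound receptor adds seeded Gaussian coordinate jitter
(sd 0.4 Å, giving Cα RMSDs near 0.7 Å, inside the 0.3–2.4 Å reference
range); the inhibitor is a truncated central fragment of the partner.
Everything is byte-deterministic under the seed.

What the toys do **not** emulate: packed hydrophobic cores, rotamer
diversity, waters, crystallographic noise, or realistic absolute
hydrogen-bond densities (the regular lattice geometry concentrates
backbone polar contacts, so toy densities sit above the 0.05–1.1
reference range; only the class I < class II *direction* is asserted).
Passing tests on toys therefore validate the computational definitions and
their relative class behaviour, not absolute agreement with crystal
structures — for which the extended-validation tolerances
(`check_against_reference()`: ASA ±15%, planarity ±0.3 Å, eccentricity
±0.10, segments ±1) exist.

## Numerical choices and degenerate inputs

Problem sizes were chosen for desk-scale runs: 960 sphere points (≈1%
area accuracy; tests that profile many toys use 240), 1.0 Å gap grid
(halving the spacing changes toy gap volumes by <3%), 0.9 Å pocket grid.
Altloc resolution keeps the highest occupancy; NMR entries use model 1;
waters are excluded; hydrogens are kept for hydrogen-bond geometry but
excluded from all surface and volume integrals.  Zero-interface complexes
are valid for ΔASA (empty sets) but raise explicit errors for GVi and
hydrogen-bond density, whose denominators vanish.  Collinear interfaces
make the plane fit error out rather than return an arbitrary frame.
Ties in k-means are resolved by the best of 50 seeded restarts plus
canonical label ordering.

## Known limitations

* Absolute pocket counts/volumes and per-complex descriptor values are not
  bit-compatible with the web tools used to build the reference table
  (different numerics); agreement is expected only within the documented
  tolerances, and acceptance checks therefore target the dataset-level
  aggregates.
* The per-complex charged-residue percentage is simulated, not measured,
  wherever the printed table lacks it (see above).
* No π-stacking, cation-π or water-mediated contacts; distance-only
  hydrogen bonds with modelled hydrogens.
* Coordinates are used as given: no symmetry expansion, no multi-model
  averaging, single-conformer side chains.
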