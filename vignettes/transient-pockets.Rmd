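---
title: "Detecting transient binding pockets in protein conformational ensembles"
author: "TransPocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient binding pockets in protein conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TransPocket)
```

## The problem

Binding pockets breathe. Side chains rotate, loops shift, domains move, and
sub-pockets that are invisible in a single crystal structure can open
transiently and accept a ligand. These transient (cryptic) sub-pockets are
attractive in inhibitor design — particularly when the goal is selectivity
between an on-target (say, a parasite enzyme) and a closely related
off-target (its human homologue) whose static pockets look nearly identical.

TransPocket analyses an *ensemble* of conformations of one protein — crystal
structures of the same or homologous proteins, or snapshots exported from a
simulation as a multi-model PDB — relative to a user-chosen reference
structure and a user-defined binding site, and answers:

* How variable is the binding site across the ensemble (per-residue and
  per-structure RMSD)?
* Which distinct site conformations exist (clustering with medoid
  representatives)?
* Where does the pocket grow or shrink (appearing/disappearing grid regions
  at occurrence thresholds, decomposed into compact sub-pockets with
  per-member opening profiles)?
* Which site residues are conserved across homologues, and which
  differentiate on-targets from an off-target (Jensen–Shannon conservation
  and its differential variant, mapped onto the structure)?

Generating the ensemble itself (molecular dynamics, constraint-based or
perturbation sampling) is out of scope: TransPocket starts from coordinates.

## Workflow and model

### Binding-site definition

The site is defined either by a bound ligand (site residues = reference
residues with any heavy atom within a radius of any ligand heavy atom;
centre = ligand heavy-atom centroid) or by an explicit centre plus radius.
The default radius is 5 Å, the conventional contact shell of a bound
ligand. Hydrogens never count toward the distance test: coordinates from
crystallography rarely include them consistently, and heavy-atom contact is
the common convention.

### Residue mapping across homologues

Ensemble members may come from different species, carry mutations, or have
gaps. Each member chain is paired with its reference chain (same chain id
when present, otherwise best alignment identity) and globally aligned with
Needleman–Wunsch, BLOSUM62 and affine gap penalties (opening 10,
extension 0.5). Site residues map through aligned columns; residues falling
into gaps are reported unmapped and excluded from superposition and RMSD,
with a warning. Nonstandard residues are treated as `X` and score zero
against every letter so they neither attract nor repel the alignment.
Mappings below an identity floor (default 0.2) fail loudly.

### Superposition and RMSD

Each member is rigidly fitted to the reference on the paired backbone atoms
(N, CA, C, and O when present on both sides) of the mapped site residues,
using the Kabsch SVD solution with reflection correction. Two site metrics
are available:

* **backbone** (default): RMSD pooled over paired site backbone atoms;
* **sidechain_center**: RMSD over per-residue geometric centres of
  side-chain heavy atoms — glycine, which has no side chain, contributes
  its backbone heavy atoms instead.

The member-by-member RMSD matrix compares members *after each was
independently fitted to the reference*; there is no pairwise refitting, so
the matrix is symmetric with zero diagonal but is not guaranteed to satisfy
triangle-type inequalities. The per-member mean is computed
per-residue-then-averaged (unweighted over site residues), matching the
residue granularity of the per-residue maximum profile.

### Clustering site conformations

Two methods are provided:

* **Single linkage at a threshold** (default, 3 Å): members belong to one
  cluster iff they are connected by a chain of pairs each within the
  threshold — exactly the connected components of the threshold graph.
  This is the closure of single-linkage clustering; we implement it as
  components because it is deterministic and invariant to member order.
* **Threshold-driven k-means** (typical refinement: 1.5 Å on side-chain
  geometric centres): the smallest k such that every member lies within
  the threshold of its cluster centroid, with centroid distances divided
  by the square root of the residue count so the threshold reads in
  per-residue RMSD units. Initialization is deterministic farthest-point
  seeding from a seeded first pick, so a fixed seed reproduces the result
  bit for bit; with a deterministic initialization, restarts would add
  nothing. When k equals the number of distinct conformations the trivial
  one-cluster-per-conformation solution is returned directly.

Every cluster reports its medoid (minimum summed intra-cluster distance,
ties to the lowest index) as the representative.

### Grid-based cavity detection

Pockets are detected per structure on a grid shared by the whole run: a
cube covering the site sphere plus a margin (default 2 Å), spacing 1 Å by
default (valid range 0.25–2 Å), snapped so the site centre lies on a grid
point. Detection is a LIGSITE-style buriedness scan:

1. **Protein mask.** Points within vdW(element) + probe radius (default
   1.4 Å, a water probe) of any heavy atom are protein. The vdW table is
   Bondi-style (C 1.70, N 1.55, O 1.52, S/P 1.80, halogens per Bondi,
   1.70 Å for unknown elements).
2. **Buriedness.** Every free point inside the site sphere is scanned
   along 7 directions (the 3 axes and 4 cube diagonals) up to a scan depth
   (default 10 Å) each way; a direction counts as buried when protein is
   hit on *both* sides, and a point is buried when at least 5 of 7
   directions are (all parameters configurable).
3. **Component filter.** Buried free points are split into 26-connected
   components and only components intersecting the half-radius sphere
   around the site centre are kept, which discards shallow surface grooves
   away from the site.

Pocket volume is the point count times spacing³ (exactly); surface area
counts 6-adjacent faces between pocket points and solvent (free non-pocket
points or points outside the grid) times spacing². Lining residues have a
side-chain heavy atom within the contact distance (default 4 Å) of a
pocket point, and each pocket point inherits physicochemical labels
(donor/acceptor/positive/negative/hydrophobic) from the side-chain atoms
it contacts, following a fixed residue/atom typing table; a point may
carry several labels.

The scan depth bounds the detectable cavity diameter: points farther than
the scan depth from a wall on some side lose that direction. With the
default 10 Å depth, cavities beyond roughly 6–7 Å radius are progressively
under-counted in their centre. For larger sites, raise `scanDepth` (and
`minBuriedDirections` tolerance if needed).

### Transient regions and sub-pockets

Per-member boolean pocket grids are averaged into a frequency grid
(fraction of members in which each point is pocket; the reference is not
included unless requested, since regions are defined *relative to the
reference*). At an occurrence threshold *f* (defaults 0.25 and 0.50, both
always computed):

* **appearing** points are pocket in at least *f* of the members but not
  in the reference;
* **disappearing** points are pocket in the reference but closed in at
  least *f* of the members;
* **conserved** points have frequency at least 0.9 (configurable).

Appearing and disappearing sets are disjoint by construction. Regions are
split into compact sub-pockets — 26-connected components with at least 5
grid points (≈ 5 Å³ at 1 Å spacing) — labelled by decreasing size with
ties broken by the smallest linear grid index. Each sub-pocket gets a
per-member opening profile: the fraction of its points that are pocket in
that member (its absolute open volume is also written to the CSV, since
either normalization can be argued for).

### Sequence conservation

Per-column conservation uses the Jensen–Shannon divergence between the
column's amino-acid distribution *p* (pseudocount 10⁻⁷ per letter) and the
BLOSUM62 background distribution *q*:

JSD(p, q) = H((p+q)/2) − (H(p) + H(q))/2   (log base 2, bounded by 1 bit),

multiplied by (1 − gap fraction) so gappy columns score low (`X` counts as
a gap). No sequence weighting or window smoothing is applied by default.
Scores are rescaled to the display range [30, 70] by a min–max map — the
maximum column of any non-constant profile lands exactly at 70 and the
minimum exactly at 30; a constant profile degenerates to 50 everywhere.
The exact rescaling function is not canonical; min–max with a midpoint
fallback was chosen as the simplest map that guarantees the documented
endpoints.

For on/off-target analysis the profile is computed twice — once with the
off-target row appended, once without — and the absolute per-column
difference is rescaled the same way. Low values mean the off-target looks
like the on-targets at that column; high values flag
selectivity-determining positions. Scores map onto the reference structure
through the MSA row with the highest identity to the structure-derived
sequence (required to exceed 0.9); structure residues outside the row
(tags, engineered termini) stay unscored.

## The synthetic test bed

Because public structure archives cannot be assumed reachable, the package
ships deterministic generators that emulate the study conditions of a
pocket-dynamics analysis:

* `makeShellStructure(hollowRadius, wallSpacing)` builds a closed wall of
  pseudo-alanine residues (full heavy-atom backbone + CB) anchored on two
  concentric spherical Fibonacci lattices, enclosing a spherical hollow.
  The inner layer sits at `hollowRadius + 4.0` Å: 4.0 Å ≈ probe (1.4) +
  carbon vdW (1.7) + the mean inward reach of the residue template, a
  one-time geometric calibration that makes the detected cavity radius
  match the nominal hollow radius (the detected volume of the standard
  6 Å hollow is within a few percent of 4/3·π·6³ at 1 Å spacing and
  closer at 0.5 Å). Residue orientations come from an internal fixed
  seed, so the structure is bit-identical across calls.
* `makeToyEnsemble()` adds, per member: Gaussian coordinate noise
  (default σ = 0.05 Å, a small crystallographic-scale jitter), a random
  rigid transform (so superposition is actually exercised), optionally a
  planted side sub-pocket (a wall patch of 6.5 Å aperture displaced 4 Å
  outward, in an exact count of members), and optionally k planted site
  conformations realized as cluster-specific 5 Å side-chain (CB) offsets
  with 0.3 Å within-cluster spread — side-chain motion that leaves the
  backbone fit untouched.
* `makeToyMsa()` plants fully conserved columns among random ones and an
  off-target row that deviates from the on-target consensus at chosen
  columns.

What these fixtures do *not* emulate: real packing (the wall is a shell,
not a folded chain), correlated motions, partial occupancy/disorder, and
realistic sequence divergence. Green tests on these fixtures demonstrate
that each algorithmic stage recovers planted ground truth under controlled
conditions — not that any particular biological system behaves this way.

One subtlety is deliberate: the planted-event ground truth is the pocket
of the clean open-state structure *after* superposition onto the
reference. An open member's displaced wall patch participates in the
backbone fit and biases it by a small constant residual; defining the
truth mask in the analysis frame makes the recovery test exact rather than
dependent on that residual. The same effect exists in any real ensemble
analysis where the site itself deforms.

## Numerical choices and degenerate inputs

* Alternate locations: the highest-occupancy conformer wins, ties go to
  the alphabetically first altLoc — one deterministic conformer per file.
* Kabsch on collinear point sets is solved but flagged (`degenerate`
  attribute); fewer than 3 points is an error.
* Residue identity across files is (chain, residue number, insertion
  code); residue-name mismatches at the same key are tolerated and
  recorded as mutations, since homologues and mutants are expected.
* Tie-breaks everywhere go to the lowest index; the default clustering
  seed is 17 and is logged.
* All-gap alignment columns score 0 with a warning; empty sub-pockets are
  an error for opening profiles; a grid larger than 10⁷ points is refused
  with a suggestion to coarsen the spacing.
* DX grids are written with 17 significant digits so a write/read round
  trip is value-faithful; the z index varies fastest per the OpenDX
  convention.

## Typical problem sizes

The bundled analyses run on desk-scale inputs: ensembles of 5–30
structures of a few thousand atoms, grids of 30³–40³ points at 1 Å
spacing. A full pipeline run on a 10-member synthetic ensemble (binding
site of ~500 residues, 39³ grid) takes a few seconds; the test suite
builds all of its fixtures programmatically at run time.

## A complete run

```{r pipeline, eval = FALSE}
toy <- makeToyEnsemble(nMembers = 10, subpocketOpenFraction = 0.6, seed = 3)
msa <- makeToyMsa(nOn = 5, width = 40, conservedColumns = c(5, 12, 20),
                  offDivergentColumns = 12, seed = 3)

res <- runPipeline(list(
  ensemble = toy$ensemble,
  center = c(0, 0, 0), site = list(radius = 16),
  msa = c(msa$msa, Biostrings::AAStringSet(c(off = msa$off))),
  offTarget = "off",
  seed = 17L, outDir = "run1"))

res$clustering
subPocketTable(splitSubpockets(res$transients$regions[["50"]]$appearing))
```

The run directory contains the RMSD matrix and per-residue profiles
(CSV), cluster assignments and representatives, per-structure pocket
statistics, the frequency and appearing/disappearing/conserved grids
(OpenDX, loadable in PyMOL/VMD/ChimeraX), the sub-pocket table with
opening profiles, the conservation table, and a JSON summary. Reruns with
the same config and seed are bit-identical.

## Known limitations

* The buriedness reconstruction is a parameterized interpretation of
  grid-based cavity detection; absolute volumes depend on probe radius,
  burial threshold and scan depth, and should be compared within a run,
  not across tools.
* Surface area is a grid-face count, systematically above smooth-surface
  estimates; it is meant for relative comparisons across members.
* The RMSD matrix after independent fits is not a metric; single-linkage
  components are still well defined, but threshold semantics differ
  slightly from pairwise-refit RMSD.
* Only multi-model PDB is accepted as a trajectory carrier; binary
  trajectory formats should be exported to models first.
* Glycine cannot line a pocket through the side-chain contact rule, since
  it has no side-chain heavy atoms.
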