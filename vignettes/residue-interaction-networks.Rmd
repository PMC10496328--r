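---
title: "Building residue interaction networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building residue interaction networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinet)
```

## The model

A residue interaction network (RIN) reduces a protein's 3D structure to a
graph: one node per residue, one edge per detected non-covalent
interaction. The reduction keeps exactly what many downstream analyses
need — topology and the distribution of specific interaction types —
while discarding the full coordinate complexity. `rinet` detects seven
edge layers (hydrogen bonds, van der Waals contacts, ionic bridges, π–π
stacks, π–cation, hydrophobic interactions, and the Cα contact map) from
purely geometric criteria, and annotates every edge with the
participating atoms, the distance, the orientation angle where one is
defined, and an energy that depends on distance and orientation rather
than being a per-type constant.

The pipeline is:

1. **Parse** (`parse_structure`): fixed-width PDB or the mmCIF
   `_atom_site` loop — the only mmCIF category the method consumes.
   `MODEL`/`ENDMDL` (or `pdbx_PDB_model_num`) delimit models, so NMR
   ensembles and MD trajectories stored as multi-model files work
   directly.
2. **Prepare** (`prepare_model`): waters always removed; HETATM residues
   removed unless requested; alternate locations collapsed to one atom
   per (residue, atom name) by highest occupancy (or file order);
   optionally strip hydrogens or synthesize backbone amide hydrogens.
3. **Annotate** (`annotate_chemistry`): per-residue tables mark donors,
   acceptors, charged groups, aromatic rings, hydrophobic atoms and
   element-based van der Waals radii. Atoms named in a table but missing
   from the structure are skipped; groups and rings missing any member
   are dropped; unknown residue names get no annotation and can therefore
   only form Cα or van der Waals contacts — graceful degradation rather
   than failure.
4. **Detect** (`detect_contacts`): each detector maps its criterion onto
   closed-ball radius queries against a kd-tree built over the relevant
   point subset (acceptor atoms, heavy atoms, hydrophobic atoms, Cα
   atoms; ring and charged-group centroids enter as pseudo-points).
5. **Assemble and export** (`build_rin`, `write_graphml`,
   `write_rin_csv`, `run_all_models`): attributed undirected graph,
   GraphML with declared typed keys or a node/edge CSV pair, one output
   file per model in batch mode.

## Assumptions

* Coordinates are in Å everywhere; no unit conversion exists anywhere in
  the code.
* Residue identity is `(chain, author seq number, insertion code)`,
  author numbering verbatim; node ids are `chain:seq:icode:name`.
* Same-residue atom pairs are never contacts. Sequence-separation gating
  (default ≥ 3) applies **only** to the Cα contact map, so α-helical
  i→i+4 backbone hydrogen bonds survive.
* Bond layers are independent: an atom pair near both the hydrogen-bond
  and the van der Waals criterion yields two typed edges. The `policy`
  parameter (`all`, `best-per-type`, `best-overall`) collapses
  multi-edges when a single-edge-per-pair reading is wanted; this covers
  both possible conventions for "one edge per atom pair vs per residue
  pair".
* All threshold comparisons are closed (`≤`/`≥`): a contact at exactly
  the cutoff is detected, and the spatial index uses closed-ball queries
  so index and criterion can never disagree by an epsilon. The van der
  Waals criterion is evaluated in the summed form `d ≤ rᵢ + rⱼ + tol`
  (algebraically identical to comparing the surface distance, but exact
  in floating point at representative boundary geometries).

## Parameters

All defaults live in `bond_params()` and serialize to a flat `key=value`
config (`write_bond_params`, CLI `--dump-config`). The published method
this package re-implements keeps its exact thresholds and energy tables
in a supplement that is not distributed with the paper; the values here
are standard structural-biology practice, and because every one is a
knob, a user with the original tables can reproduce them exactly.

| parameter | default | meaning |
|---|---|---|
| `hbond.d_max` | 3.5 Å | donor–acceptor distance cutoff |
| `hbond.angle_min_deg` | 120° | D–H···A linearity gate (angle at H, best over the donor's hydrogens) |
| `hbond.require_h` | TRUE | donors must carry an H; see below |
| `vdw.surface_tol` | 0.5 Å | allowed gap beyond touching Bondi surfaces (C 1.70, N 1.55, O 1.52, S 1.80, H 1.10, P 1.80 Å; others 1.70) |
| `ionic.d_max` | 4.5 Å | charged-group centroid distance |
| `pipi.d_max`, `parallel_max_deg`, `tshape_min_deg` | 6.5 Å, 30°, 60° | ring-centroid cutoff; parallel-stack and T-shape windows |
| `pication.d_max`, `alpha_max_deg` | 5.0 Å, 45° | ring–cation cutoff; angle off the ring normal, folded to [0°, 90°] |
| `hydrophobic.d_max` | 4.5 Å | closest side-chain C/S approach |
| `ca_contact.d_max`, `seq_sep_generic` | 8.0 Å, 3 | contact-map cutoff and intra-chain separation |

**Hydrogen handling.** With `require_h = TRUE` (default) a donor without
any attached hydrogen is skipped and the angular gate applies; with
`require_h = FALSE` detection is distance-only and no angle is recorded
(or used by the energy, which then takes orientation factor 1). X-ray
structures usually lack hydrogens, so for those either pass
`--add-backbone-h` — which places an amide H on each non-proline
backbone N with a bonded predecessor, at N–H = 1.01 Å along the bisector
of the N→C(i−1) and N→Cα directions (the standard trans-amide
approximation; prolines, chain starts and residues that already have an
amide H are skipped, which also makes preparation idempotent) — or
`--no-require-h`. No side-chain protonation is attempted; that would
need a pKa engine, which is out of scope.

**Chemistry tables** (`chemistry_tables()`, overridable data): donors are
the backbone N (except proline) plus Arg NE/NH1/NH2, Lys NZ, Asn ND2,
Gln NE2, His ND1/NE2, Ser OG, Thr OG1, Tyr OH, Trp NE1, Cys SG;
acceptors the backbone O/OXT plus Asp/Glu carboxylate oxygens, Asn
OD1/Gln OE1, His ND1/NE2, Ser/Thr/Tyr hydroxyls, Met SD, Cys SG. Cations
are Lys {NZ} and the Arg guanidinium {CZ,NE,NH1,NH2} (protonated His is
available but off by default, since assuming +1 His without pKa logic
overcounts salt bridges at physiological pH). Anions are the Asp/Glu
carboxylates and the C-terminal {C,O,OXT} when OXT is present. Rings:
Phe/Tyr 6-ring, His 5-ring, Trp both rings (contributing independently
to π detection). Hydrophobic atoms are the side-chain carbons (plus Met
SD, Cys SG) of Ala, Val, Leu, Ile, Pro, Phe, Met, Trp, Cys; the
polar-terminal Lys and Arg contribute only their aliphatic stems (CB/CG/CD
and CB/CG). Thr and Tyr are not counted — their short or amphipathic
side chains are dominated by the polar group. The source description we
worked from was ambiguous on exactly this roster; the table is data, so
disagreeing is a one-line override, not a code change.

**Energy forms.** Negative is favorable; every form decays to zero at
large distance and is minimal at its stated optimum: a 12-10
Lennard-Jones-type well with cos⁴θ orientation factor for hydrogen bonds
(−D₀ = −9 kcal/mol at R₀ = 2.8 Å, θ = 180°); a 12-6 well at the Bondi
contact distance for van der Waals (depth ε = 0.1 kcal/mol, uniform — no
per-element well depths without the original tables); screened Coulomb
with distance-dependent dielectric ε(d) = 4d and unit formal charges for
ionic bridges (−5.1875 kcal/mol at 4 Å); inverse-square attractive forms
for the π types, with cos²α orientation for π–cation; a linear ramp for
hydrophobic contacts; 0 for Cα edges, which are topological. These
constants are configurable for the same reason as the thresholds.

## The spatial index

The performance core is a static balanced kd-tree (k = 3): median split
on the axis cycling x→y→z with depth, lower median on even counts, ties
broken by lower point id — so the tree shape is a pure function of the
input and runs are bit-reproducible. Build is O(n log² n) via sorting at
each level; radius queries are O(log n + k) on average. A
candidate-evaluation counter (`eval_counter_total`) counts every point
actually compared against a query center; the acceptance suite uses it
to demonstrate sub-quadratic growth (doubling the residue count
multiplies evaluations by ≈ 2.1–2.4, far from the 4× of an all-pairs
scan) without depending on wall-clock measurements.

One caveat worth stating: kd-tree pruning assumes roughly isotropic
point clouds. A mathematically ideal single α-helix of thousands of
residues is a needle — 4.6 Å across and micrometres long — and on such
degenerate aspect ratios two of the three split axes stop pruning,
pushing candidate growth towards n^(5/3). Proteins of that size are
globular, so the scaling measurement uses the generator's compact
`"globule"` chain (below); the needle case still works, just with a
worse constant.

## The fixture generator

`make_fixture` builds minimal synthetic molecules whose named geometric
parameters are realized exactly by construction: a donor/acceptor pair
with prescribed N···O distance and D–H···A angle (the H position is
solved to machine precision), two Leu side-chain fragments at a
prescribed closest-atom distance, an Arg/Asp charged-group pair at a
prescribed centroid distance (coordinates chosen so the centroids are
exactly representable in floating point, keeping boundary cases exactly
at the cutoff), two Phe rings with prescribed centroid distance and
interplanar angle, a Phe ring with a Lys NZ at a prescribed distance and
off-normal angle, and poly-Ala chains: ideal helix (rise 1.5 Å, twist
100°, Cα radius 2.3 Å), extended (collinear Cα at 3.8 Å), a compact
globule (serpentine Cα walk on a 3.8 Å cubic lattice — an addition to
the originally stated helix/extended pair, used for scaling
measurements), and a two-chain dimer for the inter-chain contact rule.
Fragments carry only the atoms the target detector consults plus a Cα
anchor placed well clear of the interaction, so the expected contact
count is analytically forced, not tuned.

`fixture_catalog()` curates, per bond type, a positive case inside all
thresholds, a negative case outside the distance gate, a negative case
outside the angle gate where one exists, and an exact-boundary case at
the default cutoff (which must be detected: closed comparisons). The
helix entry's expected count (13 contacts for 10 residues) follows from
the helix geometry — |i−j| = 3 and 4 fall at 5.05 Å and 6.20 Å, inside
the 8 Å cutoff; |i−j| ≥ 5 falls at 8.66 Å or beyond.

What a green fixture suite does **not** establish: fixtures are rigid
fragments at exact geometry, with none of the noise, missing atoms,
alternate conformations or near-threshold ambiguity of real crystal
structures. Those aspects are exercised separately — altloc/occupancy
logic on constructed records, and detector-vs-brute-force equivalence on
randomly oriented, randomly packed residue models, where every detector
must reproduce an exhaustive all-pairs reference exactly.

## Betweenness

The trajectory-analysis statistic is betweenness centrality in its
*ratio* form: for node v, the number of shortest paths (over unordered
pairs {s,t}, s ≠ t ≠ v, counting path multiplicity) that pass through v
as an interior vertex, divided by the total number of shortest paths in
the network. Values lie in [0, 1]; disconnected pairs contribute no
paths. Whether the denominator counts ordered or unordered pairs is not
specified by the definition's source; unordered is used — the factor of
2 cancels in the ratio, so the choice is presentational. Paths are
counted on the simple graph obtained by collapsing typed multi-edges:
path multiplicity should reflect topology, not bond multiplicity. For
comparability with graph libraries, `betweenness(rin, method =
"brandes")` gives the standard pair-normalized form; both variants share
one BFS path-counting core, and tests check the ratio form against
literal shortest-path enumeration and the Brandes form against igraph.

## Numerical choices

* Plane fitting for rings: least squares on centered coordinates (the
  singular vector of smallest variance) — robust to the slight
  non-planarity of real rings; the normal's sign is fixed by a
  z-then-y-then-x positivity rule so outputs are deterministic under
  atom permutation. Collinear input is a hard error.
* Angles are degrees at every interface, radians internally.
* Tie-breaks are total: nearest-neighbour ties go to the smaller id;
  policy filtering breaks energy ties by smaller distance, then
  lexicographic atom names; CSV rows are radix-sorted. Two runs on the
  same input are byte-identical (there is no randomness anywhere in the
  main path).
* Degenerate inputs: empty structures are an error at parse time;
  residues emptied by filtering are dropped with a warning; residues
  lacking Cα are skipped (with a warning) by the contact map; a model
  that fails inside batch mode is skipped with a warning while the
  remaining models still run.

## Known limitations

* No side-chain protonation or pKa logic; only backbone amide H
  synthesis. Hydrogen-dependent detection on hydrogen-free structures
  requires one of the two flags discussed above.
* No ligand/nucleic-acid chemistry, no disulfide (covalent) detection,
  no solvent-mediated bridges, no symmetry/assembly expansion, no
  secondary-structure assignment.
* Energy constants are literature-style stand-ins with the right
  functional shape, not fitted values; treat absolute energies as
  rankings, not thermodynamics.
* The mmCIF reader consumes only `_atom_site`; exotic files that encode
  coordinates elsewhere are out of scope.

## A complete run

```{r example}
st   <- make_fixture("CHAIN", n = 30, conformation = "globule")
prep <- prepare_model(st$models[[1]], prep_options(synthesize_backbone_h = TRUE))
contacts <- detect_contacts(prep, bond_params())
rin  <- build_rin(prep, contacts, st$id, 1L, bond_params())
rin
head(sort(betweenness(rin), decreasing = TRUE), 3)
```
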