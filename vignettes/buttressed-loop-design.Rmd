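---
title: "Designing helical repeat proteins with buttressed loops: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing helical repeat proteins with buttressed loops: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buttress)
```

## The design problem

Long loops are where proteins do much of their work — recognition,
catalysis, signaling — and they are also the hardest secondary-structure
element to design, because an isolated loop has little intrinsic reason to
adopt one conformation. The strategy implemented here rigidifies long loops
*collectively*: a tandem helical repeat protein carries one long loop per
repeat unit, and because the units are exact rigid-body copies of one
another, every loop can be stabilized ("buttressed") by hydrogen bonds to
its neighbors and by packing against the underlying helices. The package
implements the geometry engine for this strategy: parametric backbone
generation, motif-guided loop construction with kinematic closure,
hydrogen-bond based selection filters, and bidentate sidechain placement.

## Parametric repeat backbones

A repeat unit is two ideal alpha-helices. Helix H1 (12-28 residues,
phi = -57, psi = -47, omega = 180 degrees, Engh-Huber covalent geometry:
N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A) is built with its axis on
z (N terminus at z = 0) and placed by a radius and an orientation angle
about z. H2 is obtained by applying a six-degree-of-freedom rigid
transform to an identically placed helix; a second six-DOF transform maps
each repeat unit onto the next, and unit k is exactly
`rt_power(T, k - 1)` applied to unit 1. Six-DOF parameters use the
intrinsic z-y-x Euler convention (degrees in configuration files, radians
internally). The convention is ours; because the degrees of freedom are
*sampled*, any fixed convention spans the same design space, but parameter
files are not interchangeable with other tools' conventions.

Within a unit, H1 and H2 are joined by a short loop (3-6 residues, first
closing length kept). The long, buttressed loops bridge H2 of unit k to H1
of unit k+1. Two scaffold filters apply before any loop is built:

* **termini distance** — the C atom of H2's last residue and the N atom of
  the next unit's H1 first residue must be at most 18 A apart (the gap a
  9-14 residue structured loop can productively span);
* **buried core** — at least 28% of residues must be in the core layer.

Burial uses a cone-and-distance neighbor count: residue j is a neighbor of
residue i when CB(j) lies within 10 A of CB(i) *and* within a cone of
half-angle 100 degrees about the CA(i)->CB(i) axis. We read the cone
aperture as the half-angle: with a 50-degree half-angle the default core
threshold (18 neighbors) is geometrically unreachable in any two-helix
repeat bundle, so the wide reading is the only self-consistent one.
Thresholds are configuration fields, not constants.

## Motif libraries

Structured long loops in natural proteins contain beta turns flanked by
strand-like hydrogen bonds and begin with helix-capping interactions.
Both motif flavors are four-residue fragments:

* a **beta turn** is any window whose residue-i carbonyl hydrogen-bonds to
  the residue-i+3 amide;
* a **helix cap** is a window starting at the last helical residue of a
  helix whose post-helix residues hydrogen-bond back to the helix's final
  turn. The capping requirement in the source protocol is not spelled out
  operationally; this rule is our declared operationalization.

Fragments are clustered by greedy farthest-point (K-centers) clustering
under the 16-backbone-atom RMSD after optimal superposition, the standard
fragment metric, at a 0.63 A maximum cluster distance. The first fragment
seeds cluster 1 and ties break toward the lowest index, so clustering is
deterministic for a fixed input order and every member is guaranteed to
lie within the radius of its center. The packaged default libraries are
mined in code from the synthetic fixture set (canonical turn types
I/I'/II/II' and a Schellman-like capped helix) so the pipeline runs
offline; users with a curated PDB set can mine real libraries with
`mine_beta_turns()` / `mine_helix_caps()` and the `mine` CLI verb. Type
VIII turns are omitted from the default turn library because they lack the
i -> i+3 hydrogen bond that every shipped beta-turn motif is required to
satisfy.

## Loop assembly and kinematic closure

A candidate loop torsion list is cap (4 residues) + free residues
(`n_kic` in 5..10, phi/psi drawn from a packaged 10x10-degree Ramachandran
density — a four-basin mixture over the alpha-R, beta, PPII and alpha-L
regions, sampled by inverse CDF) with the four beta-turn torsions
overwriting a uniformly sampled window after the cap. All omega angles are
fixed at 180 and all bond lengths and angles stay ideal. Because the cap
window *starts at the helix C-terminal residue* (that is how cap motifs
are mined), the cap contributes three inserted residues plus the anchor's
exit psi, so `4 + 4 + n_kic` torsion triplets insert `7 + n_kic` residues;
the demo samples `n_kic` of 5-6, giving 12-13 residue loops. The stated
loop-length arithmetic in the source protocol cannot simultaneously
satisfy "4 + 4 + (5..10)" and "9-14 residues"; we follow the stitching
arithmetic and note that overlap convention here.

Closure solves the six pivot torsions — phi and psi of the first, middle
and last inserted residues — so the chain meets the downstream anchor.
The engine is cyclic coordinate descent over the pivots: each step rotates
the downstream block about one pivot bond by the closed-form angle that
best aligns three virtual atoms (the downstream anchor's N, CA, C built
from the chain) with their fixed targets. A solution is accepted when the
seam C-N bond length is within 0.08 A of ideal and both seam angles within
2 degrees. The input pivot values seed the first attempt and subsequent
restarts resample pivots, so re-closing an excised loop with its own
non-pivot torsions recovers the original conformation. An analytic
tripeptide polynomial solver would return all closure solutions at once;
the iterative engine meets the same acceptance contract and is the
packaged choice.

## Hydrogen-bond model and filters

Backbone-backbone hydrogen bonds use the Kabsch-Sander electrostatic
energy (27.888 kcal A/mol times the usual four inverse distances, bond if
E < -0.5 kcal/mol), with amide hydrogens rebuilt deterministically: H in
the C(i-1)-N-CA plane, 1.01 A from N, anti to the bisector (prolines and
chain starts get none; input-file hydrogens are never read, so geometry is
identical across sources). Secondary structure is a reduced DSSP: each
i -> i+4 turn labels residues i..i+3 helical (the single-turn rule keeps
ideal helices >= 90% H at all lengths >= 10, which the stricter
two-consecutive-turn rule cannot do); parallel/antiparallel bridge
patterns label E; everything else L.

Sidechain-backbone bonds use a geometric rule — donor-acceptor below
3.5 A, D-H...A above 120 degrees — because the orientation-dependent
energy the source protocol uses inside its packing steps is not
reproducible here; the rule and both cutoffs are configuration fields.
The *pseudo* hydrogen bond used to trigger rescue (below 3 A, above 120
degrees) is therefore a strict subset of detection: under these geometric
definitions rescue acts as a geometry optimizer (driving donor-acceptor
distances toward their target) rather than as a gatekeeper, and we note
this consequence explicitly.

A propagated loop model must then satisfy, with every threshold
configurable and logged: at least 2 intraloop backbone bonds per loop; at
least 1 interloop backbone bond per neighboring loop pair (the stricter
per-pair reading of the published rule); no more than 5 consecutive
helical residues inside a loop; at least 5 loop residues within 8 A of a
helix Calpha; a direction score between 45 and 135 degrees; a negative
hydrophobic motif score; and no steric clash (non-bonded heavy-atom pairs
below 0.6 times the Bondi vdW-radius sum).

The direction score is the angle between vector **a**, from the center of
mass of the two terminal loop residues to the farthest loop Calpha
(farthest from that same origin — the reference point is stated because it
is otherwise ambiguous), and vector **b**, from the same origin to the
repeat unit's center of mass. We resolve "repeat unit" as the loop's own
unit; `direction_score(..., reference = "protein")` switches to the whole
model. The motif score sums a packaged log-odds table over loop-helix
residue pairs with CB-CB at most 8 A (favorable packing distances
4.5-6.5 A are negative); the original mined pair-statistics database is
not distributable, so the table is a compact substitute with the same sign
convention and the same selection rule (keep only negative totals; an
empty contact set scores 0 and is rejected).

## Bidentate buttressing and rescue

On the propagated model, each loop position of the second repeat unit is
scanned with Asn, Asp, Gln and His rotamers from a compact
backbone-independent chi table (Arg and Lys are excluded — their longer
sidechains' entropic cost would offset the buttressing free energy).
Sidechains are built by natural-extension placement on ideal internal
coordinates, with explicit amide/imidazole hydrogens so the geometric bond
rules apply. A placement is kept only if it forms a bidentate hydrogen
bond — two sidechain-to-backbone bonds from one functional group to a
single neighboring unit (units k-1 or k+1) — otherwise the position
reverts to alanine. If no position succeeds, the rescue path looks for
pseudo-bidentate near-misses and refines chi angles to minimize
`sum(((d - 2.0) / 0.5)^2)` over the near-miss donor-acceptor distances
(a +/-30 degree grid in 2-degree steps per chi, cycled, then a
Nelder-Mead polish, rejecting clashing values), accepting only if a
genuine bidentate bond results. Accepted placements are copied to the
equivalent position of every unit and re-verified per unit; a clash in
any unit drops the placement everywhere, so all units keep identical
sequences. The source protocol's symmetric backbone minimization is
deliberately replaced by this rigid-backbone, sidechain-only refinement.
Hydrophobic loop-helix placements (Val/Leu/Ile/Met/Phe, at least 4
sidechain heavy atoms within 4.5 A of helix atoms) fill remaining
positions.

Models are finally screened by buried unsatisfied polar atoms (at most 3)
and by the mean backbone hydrogen-bond energy of each loop's residues (at
most -1 kcal/mol per residue; the per-residue reading of this filter is
tied to a score scale that is not reproducible here, so the mean is
used and the threshold is a configuration field). For the
buried-unsatisfied count, "buried" means deeply buried — at least 22 cone
neighbors, a separate field from the 18-neighbor core layer — because the
layer that serves the 28% core-fraction filter deliberately includes
boundary-adjacent residues whose backbone polar groups no backbone-only
model can satisfy. Rosetta-internal score filters with no published
formula (packstat, hole score, total score per residue) are carried as
empty report columns so report schemas remain stable.

## Pipeline, seeding and problem sizes

`run_pipeline()` chains scaffold enumeration, short-loop connection,
long-loop sampling and sidechain buttressing; one global RNG is seeded
from the configuration and per-stage child seeds derive from it, so a run
is bit-reproducible and stages can be re-run in isolation. Each stage
writes a TSV report, and a JSON summary records stage attrition, the seed
and a SHA-256 configuration hash that detects any threshold drift.

The packaged demo configuration is one slightly curved scaffold — two
16-residue helices per unit, 8.8 A helix spacing, 8.3 A unit spacing,
2-degree twist, four units — that passes both scaffold filters with
margin, plus 120 loop-sampling attempts and up to 3 loop survivors carried
into sidechain design. These sizes make a full run a few minutes of
single-core compute, which we consider the right scale for a packaged
demonstration; larger campaigns are a matter of widening the DOF grids and
attempt counts in the configuration.

## What the synthetic fixtures do and do not show

Every test input is generated in code: ideal helices, torsion-built
beta-hairpins and turn galleries, two-cluster fragment sets,
helix-loop-helix models with excisable loops, and inverse-geometry
"planted" bidentate fixtures whose partner backbone is superposed onto
targets computed from the sidechain's own functional-group geometry. These
fixtures have exact covalent geometry and known answers, which is what
makes the oracle tests sharp — but they are idealized: real crystal
structures have non-ideal bond geometry, alternate conformations,
missing atoms and hydrogens, and real loop ensembles are broader than a
four-basin Ramachandran mixture. Passing tests therefore demonstrate the
correctness of the geometry and selection machinery, not the biological
success rate of designs; the published experimental validation (solubility,
monodispersity, thermal stability, crystallography) has no in-package
counterpart.

## Known limitations

* No full-atom energy model: clash checking and hydrogen-bond geometry
  stand in for packing and electrostatics.
* No sequence design: outputs are backbones plus scanned buttressing
  sidechains (poly-alanine elsewhere).
* The closure engine returns the solutions its restarts converge to, not
  the complete analytic solution set.
* Crystal-structure comparison (`compare_structures`, the `compare` CLI
  verb) requires the user to supply the deposited structures; nothing is
  downloaded.
* The packaged motif, rotamer, Ramachandran and pair-score tables are
  compact substitutes assembled in code; they preserve the published
  selection rules and sign conventions but not the underlying database
  statistics.
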