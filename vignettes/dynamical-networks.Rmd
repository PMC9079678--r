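---
title: "Dynamical correlation networks: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical correlation networks: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynet)
```

## The model

`dynet` analyses residue-level collective dynamics in molecular-dynamics
trajectories through a weighted network. Each amino acid and each ligand is
one node. Node *i*'s position is its C&alpha; atom (ligands: the heavy-atom
centre of geometry), and the coupling of two nodes is the normalized
fluctuation correlation

$$C_{ij} \;=\; \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle \Delta r_i^2\rangle\,\langle \Delta r_j^2\rangle}},
\qquad \Delta r_i(t) = r_i(t) - \langle r_i\rangle,$$

a Pearson-type correlation of displacement 3-vectors pooled over the x/y/z
axes, so $C_{ij}\in[-1,1]$ with unit diagonal. Correlation alone does not
make an interaction physical, so edges are gated by *contact occupancy*: an
edge joins nodes *i* and *j* only if (a) they are not covalently linked
(adjacent residues on a chain share a peptide bond and are excluded) and
(b) their minimum heavy-atom distance is below 4.5&nbsp;&Aring; in at least
75% of the analysed frames. Edge *strength* is $|C_{ij}|$; for path
computations each edge carries a *length*

$$\ell_{ij} = -\log |C_{ij}|,$$

the standard transform for correlation networks: strongly coupled contacts
are short, weakly coupled ones long, and path lengths add as products of
correlations decay. A path length of 0 means perfect correlation along
every step.

On top of this network the package computes:

* **Summary parameters** — node/edge counts, maximum and average degree,
  hub counts (degree &gt; 10), and maximum normalized edge and node
  betweenness (shortest paths on $\ell$, normalized by the number of
  unordered node pairs excluding endpoints so values fall in $[0,1]$).
* **Girvan–Newman communities** — iterative removal of the edge with the
  highest betweenness, returning the connected-component partition of
  maximum Newman modularity (edge strengths as modularity weights) along
  the removal sequence.
* **Shortest regulation pathways** — Dijkstra on edge lengths from a source
  node (a ligand) to the nearest member of a sink set (the effector
  region), with replicate statistics: mean ± sd of the per-replicate
  shortest-path lengths (SPL) and a consensus path computed on the
  consensus network.
* **Perturbation (weakening)** — deletion of all edges incident to a ligand
  node, keeping the node set fixed; used to probe how much of the community
  integrity and pathway efficiency depends on that ligand's coupling.
* **Transfer efficiency** — for systems sharing a sink definition,
  $100\cdot\sum \mathrm{SPL}_{\mathrm{ref}} / \sum \mathrm{SPL}_{\mathrm{sys}}$:
  the reference scores 100% and systems with longer pathways score lower.

Replicate trajectories are never concatenated by default
(`replicate_mode = "consensus"`): each replicate yields its own network,
SPL statistics come from the replicate ensemble, and community/summary
analyses run on the consensus network (edges present in a strict majority
of replicates, strengths averaged). A `"pooled"` mode that concatenates
frames first is available where a single network is preferred.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| contact cutoff | 4.5 | Å | heavy-atom distance defining a physical contact |
| occupancy threshold | 0.75 | fraction | contact must persist in ≥ 75% of frames; comparison is inclusive so boundary fixtures are deterministic |
| hydrophobic cutoff | 6.5 | Å | side-chain/ligand mass-centre distance |
| electrostatic cutoff | 11 | Å | charged side-chain mass-centre distance; charge–charge terms remain energetically relevant to ~11 Å |
| H-bond distance / angle | 3.5 / 120 | Å / degrees | donor–acceptor distance and donor–hydrogen–acceptor angle |
| population threshold | 0.4 | fraction | “strong interaction” report filter |
| hub-degree cutoff | 10 | edges | hub-count summary row |

All are configurable per run (`run_config()`); the defaults are the
conventional values for this analysis family.

## The synthetic generator

Reference MD trajectories for membrane receptors are rarely archived, so
validation uses a generator with exact ground truth. `planted_spec()`
declares a bead system: blocks of nodes (the planted communities) with
within-block correlation `rho_intra`, between-block correlation
`rho_inter`, and an ordered pathway of nodes whose consecutive pairs get
correlation `pathway_rho` and guaranteed heavy-atom contacts.
`build_geometry()` realizes this on a 4.05-&Aring; lattice: each block's
pathway members form a spine, remaining members are breadth-first filled
onto adjacent sites, pathway-joined blocks abut so exactly one bead pair
bridges them, and unvisited blocks sit &gt; 4.5 &Aring; apart. Every bead
carries a rigid two-atom cluster (1.6 &Aring; apart), so occupancy gating
operates on genuine heavy-atom minimum distances, and residue numbers are
spaced by two — the beads are non-bonded pseudo-residues, which keeps the
covalent-exclusion rule out of the synthetic systems (it is tested
separately on peptide fixtures).

`sample_trajectory()` draws per-frame node displacements from a zero-mean
multivariate Gaussian with the planted node–node correlation, independently
and identically on each axis (isotropic), at amplitude 0.3 &Aring; per
axis. The amplitude is small relative to the 0.45-&Aring; contact margin of
the lattice, so planted contacts persist in essentially all frames and
non-contacts stay far below the occupancy threshold. All randomness derives
from the single spec seed; replicate streams are deterministic offsets of
it.

**Default study conditions.** 40 nodes in 4 blocks, `rho_intra = 0.8`,
`rho_inter = 0.05`, `pathway_rho = 0.9`, 25,000 frames × 5 replicates.
`pathway_rho` exceeds `rho_intra` so the planted chain is the unique
shortest source→sink route — the regulatory chain is the most strongly
coupled structure in the system, which is the scientific situation the
pathway analysis is meant to detect.

**PSD projection.** A template with 0.9 bridges between 0.05-coupled
blocks is not a valid correlation matrix: if the bridge nodes are that
strongly coupled, their neighbourhoods cannot remain near-independent. The
generator therefore projects the template to the nearest positive
semi-definite correlation matrix (eigenvalue clipping at zero, then
re-normalisation to unit diagonal), with a warning. The projection leaves
within-block and pathway values essentially in place but raises
cross-block correlations around the bridges toward ~0.5 — the “information
leak” a genuinely coupled chain must exhibit. The projected matrix is what
the sampler draws from, so it is the ground truth stored in
`build_geometry()$ground_truth$correlation` and the reference for all
recovery checks.

**What the generator does not emulate.** No force field, solvent, membrane
or thermostat; displacements are Gaussian and frame-independent (no
autocorrelation in time); bead clusters are rigid. Passing recovery tests
therefore demonstrates the statistical correctness of the pipeline —
correlation estimation, occupancy gating, community and path recovery —
not the physics of any particular receptor.

## Numerical choices

* **Superposition.** File-based pipelines fit every frame onto the window
  mean (two-pass: fit to frame 1, average, re-fit) using one
  representative atom per node before computing fluctuations. Synthetic
  pipelines default to no superposition: the sampler plants no global
  rigid-body motion, and fitting a 40-node system would inject spurious
  correlations of order $1/N$. Both behaviours are overridable
  (`superpose` in the config).
* **Tie-breaks.** During Girvan–Newman, betweenness ties are resolved by
  the lexicographically smallest (node_i, node_j) pair; in Dijkstra,
  equal-length paths resolve to the lexicographically smallest node-id
  sequence, and ties among sink members resolve the same way. Output is
  deterministic for a given network.
* **Betweenness weighting.** Table-style summaries and the Girvan–Newman
  loop use shortest paths on edge lengths by default (`weighted = TRUE`);
  an unweighted variant is exposed since hop-count betweenness is also in
  common use.
* **Zero-variance nodes** (frozen coordinates) get zero off-diagonal
  correlation with a warning rather than NaN. Edges with $|C_{ij}| = 0$
  cannot carry a finite length and are dropped with a warning.
* **Occupancy pruning.** Exact heavy-atom minimum distances are only
  evaluated for frames where the node-centroid distance minus the two
  rigid-cluster radii could reach the cutoff; other frames cannot contain a
  contact. This keeps 25,000-frame occupancy matrices tractable without
  approximation.
* **Hydrogen placement.** Topologies carry heavy atoms only, so H-bond
  angles use an ideal hydrogen placed 1.0 &Aring; from the donor along the
  direction away from its bonded heavy neighbours; donors with no
  resolvable neighbour are evaluated on distance alone. This is flagged
  approximate — with explicit hydrogens the angle would be exact.
* **Efficiency formula.** The cross-system statistic is fixed as
  $100\cdot\sum\mathrm{SPL}_{\mathrm{ref}}/\sum\mathrm{SPL}_{\mathrm{sys}}$,
  which reproduces the published mutant worked example exactly
  (100 × 7.80/13.21 = 59.05% for the F396A mutant against the
  doubly-bound receptor). For the Y403A mutant the same formula on the
  printed table values gives 56.32% where 56.41% was reported — consistent
  with the published number having been computed from unrounded
  intermediates. The published single-ligand efficiencies (42.55% and
  27.07%) cannot be reproduced from the printed per-system SPLs under any
  evident formula (each single-ligand system has only one printed pathway);
  we therefore implement only the validated formula and surface the
  discrepancy here rather than guess an undocumented one.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the
correlation matrix against `bio3d::dccm`; Dijkstra against exhaustive
simple-path enumeration (200 random graphs of ≤ 8 nodes); betweenness
summaries against brute-force path counting on small graphs; Girvan–Newman
against `igraph::cluster_edge_betweenness` on unambiguous fixtures; and the
full pipeline against planted ground truth at the default study conditions
(40 nodes, 25,000 frames × 5 replicates), where sample correlations match
the planted matrix to within ±0.03, communities recover the planted blocks
at adjusted Rand index ≥ 0.9, and the consensus shortest path equals the
planted chain. Perturbation monotonicity (weakening never shortens SPLs
nor merges communities) is checked over 50 seeded block fixtures. Unit
tests use scaled-down frame counts (400–5,000) with Monte-Carlo tolerances
widened as $1/\sqrt{T}$; the production-scale recovery runs once in the
acceptance suite.

## Limitations

* Pearson-type correlation only: anti-correlated motions contribute via
  $|C_{ij}|$, but non-linear couplings (mutual-information
  generalisations) are out of scope.
* Only the single shortest path per replicate is reported; suboptimal-path
  ensembles are not enumerated.
* The covalent-exclusion rule covers peptide backbone links; covalently
  bound ligands (none in the systems considered) would need explicit
  exclusion pairs.
* Printed pathway tables give SPL statistics for published systems; the
  underlying receptor trajectories are not distributed, so those numbers
  serve as worked-example inputs, not as recomputable endpoints.
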