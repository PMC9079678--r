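# dynet — dynamical correlation networks from MD trajectories

Allosteric regulation — how ligand binding at one site of a receptor
changes behaviour at a distant effector site — leaves a statistical
signature in molecular-dynamics trajectories: the fluctuations of residues
along a communication route become correlated. `dynet` turns trajectories
into residue-level *dynamical correlation networks* and analyses how
information flows through them. It is written for structural
bioinformaticians studying allosteric communication (GPCRs, riboswitches,
enzyme networks) who need a tested, scriptable pipeline rather than a
one-off analysis.

## The model

Every amino acid or ligand is a node; node positions are C&alpha; atoms
(ligands: heavy-atom centre of geometry). The coupling of nodes *i*, *j*
is the normalized fluctuation correlation

    C_ij = <Δr_i · Δr_j> / sqrt(<Δr_i²> <Δr_j²>),   Δr_i(t) = r_i(t) − <r_i>

An edge joins two non-bonded nodes whose heavy atoms are closer than
4.5 Å in at least 75% of frames; its strength is |C_ij| and its length is
−log |C_ij|, so strongly coupled contacts are short. On this network the
package computes Table-style summary parameters (degrees, normalized edge
and node betweenness), Girvan–Newman communities (maximum-modularity
partition along the edge-removal sequence), Dijkstra shortest regulation
pathways from ligand sources to an effector sink set with replicate
mean ± sd SPL statistics, ligand-edge *weakening* perturbations, and the
information-transfer efficiency

    efficiency = 100 × Σ SPL_reference / Σ SPL_system   (reference = 100%)

A synthetic-data module generates bead systems with a planted
block-correlation structure and a planted source→sink pathway, so every
pipeline stage can be validated against exact ground truth. Standard
stability metrics (RMSD, RMSF, pairwise distance-difference maps, PCA) and
interaction fingerprints (hydrophobic 6.5 Å, electrostatic 11 Å, hydrogen
bond 3.5 Å / 120°, with per-pair frame populations) round out the toolkit.

## Worked example

Run the full pipeline on a planted synthetic system (3 blocks of 8 beads,
3 replicate trajectories of 2,000 frames) and trace the regulation pathway
from the ligand bead to the effector bead:

```r
library(dynet)

cfg <- run_config(label = "planted demo",
                  synthetic = list(n_nodes = 24, n_blocks = 3,
                                   n_frames = 2000, n_replicates = 3),
                  seed = 42)
report <- run_pipeline(cfg)
print(report)
#> == dynet report: planted demo ==
#> Network parameters
#>   Number of nodes        24
#>   Edge number            30
#>   Max degree             4
#>   Avg. degree            2.50
#>   Nodes of degree > 10   0
#>   Max edge betweenness   0.514
#>   Max node betweenness   0.589
#> Communities: 4 (0 isolated), modularity 0.599
#> Path from LIG1: SPL 3.07 +/- 0.02 over 3 replicate(s); consensus:
#>   LIG1-ALA3-ALA5-ALA7-ALA17-ALA19-ALA21-ALA23-ALA33-ALA35-ALA37-ALA39
#> Sum of pathway SPLs: 3.071
```

The consensus pathway is exactly the planted chain: the ligand bead, the
spine of each block in order, ending at the effector bead. The SPL of 3.07
is the sum of −log |C| along the 11 pathway edges (planted pathway
correlation 0.9 → ≈ 0.105 per hop, lengthened slightly where the
positive-semi-definite projection softens the inter-block bridges), and
the ±0.02 spread comes from re-estimating the correlations in each
replicate.

Cross-system efficiencies use the published shortest-pathway table for the
muscarinic M2 receptor, shipped with the package:

```r
tab <- m2_spl_table()
bound <- tab$spl[tab$system == "Bound M2"]   # 4.20, 3.60
f396a <- tab$spl[tab$system == "F396A"]     # 5.63, 7.58
round(transfer_efficiency(bound, f396a), 2)
#> [1] 59.05
```

Weakening (`weaken = TRUE` in the config, or `weaken_ligand()` directly)
deletes a ligand's edges and recomputes communities and SPLs, showing how
much network integrity that ligand's coupling provides.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/dynet.R synth --spec spec.yaml --out fixtures/
Rscript inst/cli/dynet.R run   --config run.yaml --out results/
```

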