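# allomap

Allosteric proteins transmit the effect of ligand binding from a
regulatory site to a distant functional site through their structure.
Mapping *which residues carry that signal* is a standard post-simulation
task in structural bioinformatics: build a residue interaction network
from a representative structure, score residues by network centrality,
compare states (apo vs agonist- vs antagonist-bound), and characterise
the ensemble itself through stability observables, essential dynamics and
correlated motions. allomap implements this workflow end to end in base
R, for computational structural biologists who have conformational
ensembles (e.g. from molecular dynamics) and want reproducible,
residue-level communication maps.

## What it computes

* **Residue interaction network** — two coarse-grained centres per
  residue (Cα, plus the side-chain heavy atom furthest from Cα); contact
  when any centre pair is closer than 7 Å; inter-residue hydrogen-bond
  counts stored as edge weights.
* **Centralities** on hop counts, for a network of K residues:
  - degree `C_D(r) = deg(r)`
  - closeness `C_C(r) = [ Σ_q d(q,r) / (K−1) ]⁻¹`
  - betweenness `C_B(r) = 2/((K−1)(K−2)) · Σ_{a<b} σ_ab(r)/σ_ab`
    (Brandes' algorithm, validated against exhaustive path enumeration)
  with hot spots at `C_B ≥ 0.05` and state differences at
  `|ΔC_B| ≥ 0.02` (both inclusive).
* **Stability observables** — Kabsch-fit RMSD series, RMSF about the
  ensemble mean, Shrake–Rupley SASA (nm²), geometric hydrogen-bond
  detection (d ≤ 3.5 Å, deviation ≤ 30°) with per-residue ligand
  occupancy, and lowest-energy representative-frame selection.
* **Essential dynamics** — backbone covariance PCA (eigenvalues in nm²),
  cosine-content filtering (`c_i ≤ 0.2`), free-energy landscapes
  `ΔG = −ln(P/P_max)` in kT over two principal components.
* **Correlated motions** — Cα cross-correlation matrices, correlation
  networks (`|c_ij| ≥ 0.5`, weight `−log|c_ij|`), Girvan–Newman
  communities with a modularity-maximising cut, and community-level
  summary networks.
* **Synthetic generator** — structures and ensembles with planted contact
  topology, planted hydrogen-bond geometries, and block-structured
  displacement correlations, so every stage is testable against known
  ground truth without any external data.

## Worked example

A 30-residue helical system with two planted dynamic blocks
(within-block correlation 0.9, between-block 0):

```r
library(allomap)
spec <- synthetic_spec(30, "ideal_helix", n_frames = 200, sigma = 0.4,
                       seed = 42, blocks = list(1:15, 16:30),
                       rho_within = 0.9, rho_between = 0)
s   <- make_structure(spec)
ens <- make_ensemble(spec, s)

net <- build_network(s, cutoff = 7)
#> residue interaction network: 30 nodes, 110 edges (cutoff 7 A)
ct <- centrality_table(net, state = "demo")
head(ct[order(-ct$C_B), ], 3)
#>    resindex label chain resno C_D       C_C       C_B
#> 18       18   A18     A    18   8 0.4202899 0.1215107
#> 14       14   A14     A    14   8 0.4264706 0.1215107
#> 17       17   A17     A    17   8 0.4264706 0.1215107
nrow(hotspots(ct, threshold = 0.05))
#> [1] 22

p <- backbone_pca(ens)
#> backbone PCA: trace 0.185405 nm^2; leading eigenvalues (nm^2):
#>   0.081923, 0.027201, 0.024700, 0.001664, 0.001573
cosine_content(p, 1)
#> [1] 0.0034   (well under the 0.2 filter: converged-looking sampling)

cij  <- cross_correlation(ens, fit = FALSE)
part <- detect_communities(build_correlation_network(cij, 0.5))
#> community partition: 2 communities, Q = 0.5000
```

Reading the numbers: the interior helix residues (A14–A18) are the
bottlenecks of the contact network — every shortest path between the
chain's halves crosses them, hence the top betweenness 0.122; on a graph
this small many residues clear the 0.05 hot-spot cutoff (22 of 30). The
PCA trace says the total backbone fluctuation is 0.185 nm²; the two
planted correlation blocks are recovered exactly as the two communities,
and Q = 0.5 is the textbook modularity of two clean halves.

For a full multi-state run, `pipeline_config()` + `run_pipeline()` read
PDB/energy inputs per state and write TSV/JSON reports (stability, RMSF,
SASA, occupancy, representative frame, network, centralities, hot spots,
PCA, landscape, correlations, communities, and cross-state ΔC_B tables),
each stamped with the configuration hash; reruns are byte-identical.

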