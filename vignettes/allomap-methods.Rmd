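---
title: "Methods: residue networks, essential dynamics and correlated motions in allomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue networks, essential dynamics and correlated motions in allomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomap)
```

## Scope

allomap is a post-simulation analysis toolkit for mapping intramolecular
communication in proteins. Its inputs are structures (PDB) and
conformational ensembles (multi-model PDB, optionally with a per-frame
energy table); its outputs are residue-level reports: stability
observables, a representative low-energy frame, a coarse-grained residue
interaction network with centrality-based hot spots, essential-dynamics
summaries with free-energy landscapes, and a cross-correlation community
network. Molecular-dynamics setup and force-field evaluation are out of
scope: energies are opaque input scalars and ensembles are consumed as
given.

## The residue interaction network

Each residue is reduced to two centres: the Cα (backbone) and, to
represent the side chain, its side-chain heavy atom furthest from the Cα.
Glycine has no side-chain heavy atom and falls back to the furthest heavy
atom of the whole residue (the carbonyl oxygen in standard geometry); a
residue whose only heavy atom is the Cα uses coincident centres. Two
residues are in contact when any of the four centre pairs lies strictly
below the contact cutoff (default 7 Å). Sequence-adjacent residues are
*included* as contacts — there is no a-priori reason to discard covalent
neighbours from a communication map — but `exclude_neighbours` allows a
sensitivity analysis.

Hydrogen bonds between two residues are counted and stored as the edge
weight. The centrality definitions below measure path lengths in *edges*
(hop counts), so these weights do not enter the centralities; they are
reported for inspection, and this is stated prominently here because the
network is otherwise described as weighted.

### Centralities and hot spots

For a network with $K$ residues,

* degree $C_D(r) = \deg(r)$;
* closeness $C_C(r) = \left[\sum_q d(q,r)/(K-1)\right]^{-1}$ with $d$
  the hop-count shortest-path distance (computed by unit-weight
  Dijkstra/BFS);
* betweenness
  $C_B(r) = \frac{2}{(K-1)(K-2)} \sum_{a<b,\; a,b\neq r}
  \sigma_{ab}(r)/\sigma_{ab}$,
  where $\sigma_{ab}$ counts shortest $a$–$b$ paths and
  $\sigma_{ab}(r)$ those passing through $r$ as an interior node,
  computed by Brandes' accumulation.

On disconnected graphs closeness uses the Wasserman–Faust convention
(computed over the reachable set and scaled by $(n_{reach}-1)/(K-1)$) and
pairs spanning components contribute nothing to betweenness; these cases
are tested even though typical protein networks are connected.

Hot spots are residues with $C_B \ge 0.05$, and state differences report
residues with $|C_B^{(a)} - C_B^{(b)}| \ge 0.02$; both thresholds are
inclusive, with a $10^{-12}$ guard so values constructed exactly at the
boundary are not lost to round-off. The implementation is validated two
ways: against closed forms (path and star graphs, and the path-graph
profile $2i(K-1-i)/((K-1)(K-2))$), and against an exhaustive
all-shortest-paths enumeration oracle (Floyd–Warshall distances plus
bounded DFS path enumeration) on dozens of random graphs with $K \le 12$,
to $10^{-12}$.

## Geometric kernels

**Superposition** is the Kabsch least-squares rigid fit (SVD of the
cross-covariance with a determinant correction, so the rotation is always
proper). Fit selections must contain at least 3 non-collinear atoms;
collinear selections are a hard error because the rotation about the line
is undetermined.

**RMSD series** fits every frame to the reference over the selection and
evaluates the post-fit RMSD on that selection. **RMSF** superposes all
frames first onto frame 1, then once onto the resulting mean structure
(one iteration), and measures
$\mathrm{RMSF}_i = \sqrt{\langle |r_i(t)-\bar r_i|^2\rangle}$. A single
fixed iteration keeps the procedure deterministic; for the ensembles
treated here the mean moves negligibly after one pass.

**SASA** is Shrake–Rupley with a deterministic Fibonacci-spiral lattice
(default 960 points — no RNG, so results are exactly reproducible) on
spheres of radius $r_{vdw} + r_{probe}$ (probe 1.4 Å). The van der Waals
radii are a fixed table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
P 1.80 Å); unknown elements are hard errors naming the element. Hydrogens
are excluded by default (heavy-atom convention); areas are reported in
nm². For an isolated atom the lattice gives the sphere area exactly; the
two-sphere case agrees with the analytic spherical-cap formula to well
under 2%.

**Hydrogen bonds** use the geometric criterion: donor–acceptor distance
≤ 3.5 Å and deviation from linearity ≤ 30°. The deviation is measured at
the donor (H–D–A angle) by default; the published description of this
criterion reads "angle between the donor and acceptor is >30°", which
contradicts the deviation convention of standard trajectory tools and is
treated as a transcription slip — both the cutoff and the angle
definition (`"HDA"`/`"DHA"`) are configurable so either reading can be
audited. Donors are N/O heavy atoms with a hydrogen within 1.25 Å
(covalent attachment by distance, no CONECT records); acceptors are all
N/O heavy atoms; intra-residue pairs are excluded. Both cutoffs are
inclusive with a $10^{-9}$ round-off guard. H-bond *occupancy* of a
residue towards a ligand is the fraction of frames with at least one
protein–ligand bond involving that residue.

## Representative-frame selection

The representative structure is the frame of minimal energy (ties go to
the lowest frame index). The backbone RMSD of every frame to that minimum
is reported, and the 20 lowest-energy frames are emitted together with
their pairwise backbone RMSD matrix so any clustering of the low-energy
set can be inspected — but the selection itself is always the energy
minimum, which is the stated outcome the report must reproduce. When no
energy table is supplied the pipeline warns and uses frame 1.

## Essential dynamics

Frames are superposed (backbone N, CA, C, O), the covariance matrix of
the $3M$-dimensional coordinate vector is diagonalised, and projections
are centred scores. Eigenvalues are reported in nm² and projections in nm
(internal coordinates are Å; the conversion is a fixed factor of 100 and
10 respectively). Variance conservation
($\sum\lambda_i = \mathrm{tr}\,C$ to $10^{-8}$ relative) and projection
orthogonality are tested invariants.

The cosine content of mode $i$,
$c_i = \frac{2}{T}\left[\int_0^T \cos(i\pi t/T)\,p_i(t)\,dt\right]^2 /
\int_0^T p_i^2(t)\,dt$
(trapezoid rule on the frame grid), flags diffusion-like, unconverged
sampling; modes with $c_i \le 0.2$ are admitted to the landscape. When
PC1/PC2 fail the filter, the two lowest-index passing modes are used —
the first 20 modes are checked. A pure half-period cosine gives $c = 1$;
$\sin(\pi t/T)$ gives 0 by orthogonality. (Note that $\sin(2\pi t/T)$ is
*not* orthogonal to the half-period cosine: the definition gives
$64/9\pi^2 \approx 0.72$, a useful second closed form that the tests pin
down.)

The free-energy landscape bins two projections on an $n \times n$ grid
(default 32) and sets $\Delta G = -\ln(P/P_{max})$ in units of $k_BT$
(temperature default 300 K, annotation only — the grid itself is in kT).
The most populated bin sits at 0, empty bins are infinite, and local
minima are finite bins not exceeded in their 8-neighbourhood. Because
counts are integers, a bin at exactly $P_{max}/e$ cannot exist; the
definition is tested exactly at ratio $1/2$ ($\Delta G = \ln 2$) and at
the integer-rounded $1/e$ ratio at $n = 10^5$ samples
($\Delta G = 1$ to $10^{-4}$).

## Correlated motions and communities

The dynamical cross-correlation between residues $i$ and $j$ is
$c_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
(\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle)^{1/2}$
over Cα displacement vectors. By default frames are first superposed onto
the ensemble mean (the convention for raw trajectories). For ensembles
that are already expressed in a common reference frame — as the synthetic
generator produces — `fit = FALSE` measures displacements about the mean
directly. This option exists because the least-squares fit subtracts each
frame's net displacement: when two halves of a molecule fluctuate
coherently but independently, removing the global mean makes them appear
strongly anti-correlated (for two equal blocks at within-block correlation
0.9 the induced between-block value is about −0.84). That is a property
of the fitted estimator, not of the motion, so planted-value validation
runs unfitted.

Pairs with $|c_{ij}| \ge 0.5$ (inclusive) become edges with distance-like
weight $-\log|c_{ij}|$ (0 for perfect coupling) and strength $|c_{ij}|$.
Communities are found by Girvan–Newman: repeatedly remove the edge of
highest weighted edge betweenness (weights as distances, Brandes/Dijkstra
accumulation), and return the dendrogram cut maximising weighted
modularity $Q$ evaluated with the strengths on the original graph.
Distances and strengths are kept separate deliberately: $-\log|c|$ is the
natural path metric but a zero-or-large quantity is meaningless as a
coupling mass in $Q$. Two disconnected 4-cliques give $Q = 1/2$ exactly,
and the returned cut is never worse than the trivial partition. The
cutoffs (0.5 edge filter, $-\log$ weight, modularity cut) are the
standard defaults of this methodology and are all exposed in the
configuration.

## The synthetic generator: what it emulates and what it does not

Real inputs to this kind of analysis are MD trajectories, which are
rarely deposited. The generator replaces them with ensembles whose
downstream statistics have closed-form expectations:

* **Structures** are poly-alanine backbones (N, H, CA, C, O, CB; optional
  terminal glycine) on three trace geometries — an ideal α-helix (radius
  2.3 Å, rise 1.5 Å, 100°/residue, giving the $i,i{+}3$ contacts of a
  helix), a β-strand-like extended chain (zigzag amplitude 0.25 Å so the
  trace is never collinear, with consecutive Cα spacing exactly
  `ca_spacing`), and a two-domain form (two helical halves 40 Å apart,
  beyond any contact cutoff).
* **Ensembles** add zero-mean Gaussian displacements with per-coordinate
  scale σ, drawn once per residue and applied rigidly to all of the
  residue's atoms, with correlation `rho_within` inside each block of a
  residue partition and `rho_between` across blocks (frame 1 is the
  unperturbed reference; the block correlation matrix must be positive
  semi-definite or the request is rejected). Residue-level correlations are
  therefore exact by construction, RMSF has expectation σ√3, and the
  planted blocks are the ground truth for community recovery.
* **Planted hydrogen bonds** position a donor oxygen, its hydrogen and an
  acceptor oxygen so the requested distance and deviation angle hold to
  coordinate round-off; a two-atom ligand variant plants a protein–ligand
  bond that can be switched off in chosen frames to set an exact
  occupancy.

Randomness comes from R's default Mersenne–Twister stream seeded
explicitly per spec; the global RNG state is saved and restored, and an
identical spec yields byte-identical PDB output.

The generator deliberately does **not** emulate: anharmonic or
multi-basin dynamics, side-chain rotamers, solvent, realistic secondary
structure H-bond networks, or time correlation between frames
(displacements are i.i.d. across frames). Passing tests therefore
demonstrate that each stage computes its defining quantity correctly on
inputs with known truth — not that the pipeline's defaults are optimal
for any particular real system.

## Numerical choices and problem sizes

* Contact test strict `<` 7 Å; all report thresholds inclusive `≥` with
  $10^{-9}$–$10^{-12}$ round-off guards.
* Ties: energy minimum → lowest frame index; coarse-grain far atom →
  atom-name order; Girvan–Newman edge removal → first maximal edge in
  canonical order. All tie-breaks are deterministic, so pipeline reruns
  are byte-identical (verified bytewise in tests).
* Altloc resolution keeps the highest occupancy, ties preferring "A";
  insertion codes sort after their base number; waters and ions are
  excluded by default.
* Validation sizes: Monte-Carlo checks use 500–2000 frames and 10–60
  residues (RMSF to 5%, planted eigenvalues to 10%, block correlations to
  ±0.1 over 20 seeds); oracle equivalence uses 50 random graphs with
  $K \le 12$; the end-to-end fixture is two 30-residue, 100-frame states.
  These sizes make every expectation statistically resolvable while the
  whole suite runs in about a minute.

## Limitations

Hop-count centralities ignore the stored H-bond weights by definition;
whether weighting would change hot-spot identities is an open question
the edge table lets users explore. The Pearson-like correlation captures
only linear, instantaneous coupling (no mutual information, no time
lags). Community counts depend on the correlation cutoff; they are
reported, not asserted. PDB is the only trajectory dialect; binary
formats should be converted upstream.
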