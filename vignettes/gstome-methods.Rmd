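---
title: "Methods: alignment-indexed structural analysis of a GST family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-indexed structural analysis of a GST family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstome)
```

## The problem

Glutathione transferases (GSTs) are a multigene superfamily of mostly
homodimeric detoxification enzymes. Each monomer carries a highly specific
glutathione (GSH) binding pocket, the G site, and the two monomers meet at a
class-dependent dimerization interface (DI). Comparing dozens of family
members — predicted models alongside the few crystal structures — requires a
common residue coordinate. This package uses the *MSA number*: the 1-based
column of a precomputed multiple sequence alignment of the family. Every
per-residue quantity (conservation, charge, interface membership, pathway
visits, predicted B-factor) is scattered onto MSA numbers so profiles can be
averaged and compared across the whole family.

The package deliberately consumes its inputs rather than producing them: the
alignment comes from an external aligner, the structures from experiment or a
structure predictor (with the per-residue pLDDT confidence stored in the
temperature-factor column), the ligand copies from a transplantation tool.
What the package contributes is everything downstream.

## Alignment analytics

Conservation of a column is the frequency of its majority amino acid *over
all rows*: gaps count against conservation, so a column is fully conserved
only when one amino acid occupies it in every sequence. Pairwise identity is
an exact-match count; its denominator is configurable and defaults to the
number of columns where at least one of the two rows is non-gap, so
insertions and deletions depress identity. This is the strictest of the
common conventions; `denominator = "shorter"` and `"alignment"` are provided
because published identity figures rarely state which was used. Formal charge
is `count(Lys, Arg) - count(Asp, Glu)`; histidine is excluded by default and
can be counted as +1 with a flag, again because published totals rarely say.

## Conformation comparison

Global deviation is the Kabsch least-squares RMSD over the Cα atoms at
columns non-gap in both sequences. Local deviation is the per-column Cα
distance after that one global superposition. Because any superposed metric
inherits the superposition algorithm's choices, the package also compares
*internal* coordinates: the coarse-grained angles of the Cα trace — the
virtual bond angle θ~n~ (discrete curvature) and virtual torsion γ~n~
(discrete torsion, IUPAC sign) — and the side-chain χ1 dihedral. An
N-residue chain carries N−3 complete (θ, γ) pairs. The χ1 comparison is
reported as the bounded distance `(1 − cos Δχ1)/2`, chosen so that 0 means
the same rotamer and 1 means an opposite (180°) orientation; the underlying
study describes the flip qualitatively and never writes a formula, so this
smooth bounded metric is this package's own definition.

Secondary structure is assigned from the Cα trace alone: helix where
θ ∈ [80°, 105°] and γ ∈ [30°, 70°] over runs of ≥ 4 residues, strand where
θ ∈ [100°, 155°] and |γ| ∈ [140°, 180°] over runs of ≥ 3. These boxes are
canonical Cα-trace geometry (an ideal helix trace sits near θ ≈ 91°,
γ ≈ 50°); published Cα-only assigners use closely related but not publicly
reprinted thresholds, so the boxes here are labelled approximations and are
arguments, not constants.

```{r geometry}
h <- make_ideal_chain("helix", 20, seed = 1)
cga <- coarse_grained_angles(calpha_coords(h$model))
round(c(theta = mean(cga$theta), gamma = mean(cga$gamma)), 1)
table(assign_secondary_structure(cga))
```

## Interface, binding sites, pathways

Two residues are in contact when any heavy-atom pair sits closer than 4.0 Å
(a strict inequality). The DI of a homodimer is every residue with an
inter-chain contact; the G site is every residue in contact with a ligand
copy of one clustered binding position. Ligand copies are grouped by
single-linkage clustering cut at 2.0 Å, under a ligand-to-ligand metric
defined as the mean distance over atoms shared by name (centroid distance
when names do not match); single linkage matches the notion of a distance
threshold "between ligands in a given binding site".

Inter-site communication is analyzed on the residue-interaction graph (unit
edge weights, one extra node for the bound ligand) in the asymmetric
configuration: the cofactor bound in monomer A, monomer B apo. All paths
achieving the minimal source-to-target length are enumerated. "All possible
pathways" is interpreted as all *minimum-length* paths — unrestricted
enumeration is combinatorial, and the reported statistics (path length in
residues) are shortest-path statistics; a distance-weighted mode exists
behind the `weighted` flag. With unit weights the pathway length *is* the
residue count of the path.

Interface area is half the solvent-accessible surface area lost on
dimerization, with SASA from a Shrake–Rupley point sampler (960 points per
atom, probe 1.4 Å, vdW radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å). The
source study computed interface surfaces with a molecular-dynamics package
it does not further specify; the SASA-difference here is this package's own
documented choice, so absolute areas are not comparable figure-for-figure.

```{r sites}
fx <- make_toy_dimer(n_per_chain = 12, interface_size = 4,
                     ligand_copies_per_pocket = 9, seed = 3)
cluster_ligands(fx$model)
interface_residues(fx$model)$n_di
cl <- cluster_ligands(fx$model)
shortest_site_paths(build_residue_graph(fx$model, 1, 2, clusters = cl))
```

## The parameter-free ANM

Thermal B-factors are predicted from an anisotropic network model in which
*every* protein heavy atom (N, C, O, S) is a node and every node pair is
connected by a spring of stiffness Γ~ij~ = γ/R~ij~², with no cutoff — the
distance decay replaces the cutoff parameter, hence "parameter-free". The
mass-weighted Hessian

$$\hat H_{ij}^{\alpha\beta} = \frac{H_{ij}^{\alpha\beta}}{\sqrt{m_i m_j}},
\qquad
H_{ij}^{\alpha\beta} = -\frac{R_{ij}^\alpha R_{ij}^\beta}{R_{ij}^2}\,\Gamma_{ij},
\qquad H_{ii} = -\sum_{j \neq i} H_{ij}$$

is diagonalized densely; the six smallest-magnitude eigenvalues are the
rigid-body modes (five for a collinear network, the documented degenerate
case) and must fall below 10⁻⁸ of the largest eigenvalue, otherwise the
network is reported as degenerate. Per-atom B-factors follow from the 3N−6
internal modes,

$$B_i = \frac{8\pi^2}{3}\,\frac{k_B T}{m_i}
 \sum_{k=1}^{3N-6} \frac{\lvert e_{k,i}\rvert^2}{\tilde\omega_k^2},$$

and are averaged over each residue's heavy atoms (a Cα-only mode exists).
With γ = 1 the absolute scale is arbitrary; Pearson correlations against
experimental profiles — the quantity of interest — are scale-invariant, and
a least-squares calibration of the scale is available when absolute Å²
values are wanted. The dense eigensolver bounds the practical problem size
at a few thousand atoms (a 10,500 × 10,500 eigenproblem); the fixtures used
throughout the documentation and tests are far below that.

```{r anm}
dumb <- make_flexible_dumbbell(n_core = 16, n_linker = 5, seed = 1)
fit <- pfanm(dumb$model)
fit
round(mean(fit$atom_b[dumb$ledger$linker_atoms]) /
      mean(fit$atom_b[dumb$ledger$core_atoms]), 2)
```

The linker-to-core fluctuation ratio above is the basic physical sanity
check: a thin linker must be softer than dense domain cores.

## What the synthetic generators emulate — and what they do not

The generators produce, deterministically from a seed: ideal helix / strand
/ self-avoiding coil Cα traces with stub side chains; homodimers with an
exactly planned interface block, ligand ensembles jittered < 0.5 Å around
two pocket centroids, and a designed contact corridor of known minimal
length; alignments with exact planted invariant columns, gap blocks and
per-row formal charges; and two-domain dumbbells for flexibility checks.
Every planted fact is returned in a `ledger` and asserted against the
analysis modules in the tests, and fixtures are written to PDB/FASTA and
re-read through the public parsers so I/O is exercised on every run.

They do *not* emulate realistic energetics, rotamer libraries, packing
densities or evolutionary covariance. Passing tests therefore demonstrate
that the implemented operations are correct on inputs whose ground truth is
known exactly — not that any biological conclusion about a real family is
reproduced. Reproducing published family-level numbers requires the real
inputs (deposited structures, the family's UniProt sequences and their
alignment); the pipeline accepts them through the same two entry points
(`read_structure()`, `read_alignment()`) whenever they are available, and
`run_gstome()` records per-structure correlations in its manifest.

## Numerical choices and edge cases

* PDB parsing keeps the first-listed alternate conformer, drops hydrogens,
  waters, ions and glycans, and routes GSH-like hetero codes (configurable)
  to the ligand table. Residue identity is the (chain, author number,
  insertion code) triplet, robust to numbering gaps in crystal files.
* pLDDT is read from the Cα record only; residues without a Cα are reported
  `NA`, never interpolated.
* Contact detection uses a cell-list neighbor search whose results are
  tested to equal the all-pairs double loop exactly.
* Angle wrapping: circular differences are mapped to [0°, 180°]; γ lives in
  (−180°, 180°] with the IUPAC sign convention.
* Degenerate inputs fail loudly: coincident Cα atoms, collinear point sets
  in superposition, empty models, all-gap row pairs, more than six near-zero
  modes.
* Problem sizes in the tests and the acceptance script (chains of 10–50
  residues, dimers of 24–30 residues, networks up to ~50 nodes, 36-row
  alignments of 45–80 columns) were chosen as the smallest sizes at which
  every planted feature is non-trivially exercised.

## Known limitations

Hydrogen-bond-based secondary structure (DSSP) is out of scope, as are
flexible/partial structural alignment, force-field interface energies,
structure prediction and ligand transplantation themselves. Harmonic normal
modes cannot reproduce anharmonic loop fluctuations seen experimentally;
correlations with measured B-factors are informative but bounded by that
physics. Multi-assembly crystal files are reduced to a dimer by explicit
chain selection — the package does not guess which chain pair forms the
biological dimer.
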