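---
title: "Decomposing RNA structures into recurrent 3D motifs"
author: "rnamotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing RNA structures into recurrent 3D motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamotifs)
```

## Motivation and model

RNA tertiary structure is built from recurrent modules: regular A-form
stems and irregular loops that kink the backbone, mediate long-range
contacts and form protein binding sites. This package decomposes RNA
chains into such modules, compares them geometrically, and annotates their
molecular environment, including contacts that exist only between crystal
symmetry mates.

A motif is defined as a set of interacting nucleotides **from one chain**,
flanked by Watson-Crick (A·U, G·C) or wobble (G·U) pairs. Three types are
distinguished: stems (tandem arrays of WC/wobble pairs), loops (one or
more single-stranded segments closed by pairs: hairpin loop, internal
loop, k-way junction) and terminal fragments (a single-stranded chain end
with exactly one end paired). The single-chain restriction means a duplex
of two chains pairing only with each other contains base pairs but no
motifs; its strands are chain ends.

### From coordinates to motifs

1. **Pair annotation.** Polar hydrogens are placed at idealized geometry
   (N–H 1.01 Å, in-plane or tetrahedral; rotatable hydroxyls are left
   bare). Hydrogen bonds follow the classic geometric criteria: donor to
   acceptor ≤ 3.9 Å and, when the donor hydrogen exists, H···A ≤ 2.5 Å
   with a D–H···A angle ≥ 90°; donors without placeable hydrogens fall
   back to the heavy-atom rule. A pair is `canonical_wc` or `wobble` when
   the characteristic bond set is present (at least two of O6···N4,
   N1···N3, N2···O2 for G·C; both of N1···N3 and N6···O4 for A·U; both of
   O6···N3 and N1···O2 for G·U), with two geometric gates that suppress
   spurious assignments from bifurcated bonds: C1'–C1' within 9.0–11.5 Å
   and base-plane angle ≤ 30°. The thresholds are package choices — the
   programs that inspired them document the algorithm, not these exact
   numbers — and they are deliberately permissive because the gates carry
   the specificity.
2. **Pseudoknot removal.** Among the candidate WC/wobble pairs of a chain
   the largest mutually non-crossing, vertex-disjoint subset is kept
   (interval dynamic programming; ties prefer the pair opening earlier,
   then the shorter span). Maximizing the number of *retained pairs* is a
   design decision; the criterion used by the original pseudoknot-removal
   tools is not documented precisely enough to copy.
3. **Graph and cycle basis.** Nodes are residues; edges are covalent
   backbone links (O3'–P below 2.0 Å, so chain breaks split the graph)
   and the kept pairs. A minimum cycle basis — E − V + C independent
   cycles of minimal total length — is computed by Horton-style candidate
   enumeration (lexicographic BFS ties) with greedy GF(2) independence.
   In a pseudoknot-free secondary-structure graph, the basis is exactly
   the set of base-pair tandems (4-cycles with two pair edges) plus one
   cycle per loop.
4. **Motifs.** Tandems chained by shared pair edges merge into stems;
   every other cycle becomes a loop whose strand count equals its number
   of pair edges; unpaired chain ends plus their flanking paired residue
   become terminal fragments. Adjacent motifs therefore always share at
   least one residue (their closing pairs), which the tests verify as an
   invariant. A lone pair (no tandem) is not a stem; it survives only as
   the closing pair of the surrounding loops.

### Comparison, clustering, search

Backbone RMSD uses the six sugar-phosphate atoms P, O5', C5', C4', C3',
O3' (the definition of "backbone atoms" is a package choice), after
matching strands by cyclic rotation — strand order is chain-directional,
so rotations are allowed but reversals are not. Clustering of same-
composition motifs is agglomerative with **complete linkage** cut at
1.0 Å: complete linkage is the only standard linkage for which the cut
guarantees that *every* intra-cluster pair is below the threshold, which
is the property the clusters are supposed to certify. Medoids (minimum
summed RMSD, ties to the lowest input index) represent clusters.

The tertiary search compares only backbone geometry — no sequence or
secondary structure — so coarse-grained or incomplete models can be
queried. Candidates are pruned by a pairwise-distance filter (every
pattern distance must occur in the container within a tolerance) and a
triplet filter (some container triplet must match the pattern's
maximal-spread triplet edge-for-edge under one of the six vertex
assignments). Each surviving triplet seeds a rigid superposition; the
match is scored by the RMSD of greedily matched mutually-nearest selected
atoms, and accepted matches are re-superposed on all backbone atoms,
which can only lower the refined RMSD. Defaults: selected atom C3';
distance/triplet tolerance `2 × threshold × sqrt(n)` for an n-residue
pattern and per-atom counterpart cutoff `threshold × sqrt(n)`. Those
bounds are chosen so the filters are *provably* conservative: a
correspondence whose RMSD passes the threshold t satisfies
`sum(d_i^2) ≤ n t²`, so no single atom moves farther than `t √n` and no
pairwise distance changes by more than `2 t √n` — nothing the
exhaustive-correspondence oracle accepts can be filtered out, which a
property test verifies. Alignment search combines several seed triplets,
a chain-order start for same-size fragments, and iterative closest-pair
refinement with a coarse-to-fine pairing cutoff. Queries are limited to
40 residues.

## The synthetic generator

All tests run on generated structures with known ground truth. The
generator builds idealized A-form nucleotides from canonical backbone
torsions (α −68°, β 178°, γ 54°, δ 82°, ε −153°, ζ −71°) by
natural-extension placement; bond angles were calibrated once so that the
screw transform relating consecutive residues has twist 32.7° and rise
2.81 Å (P–P ≈ 5.84 Å). Bases are planar regular-polygon constructions
(hexagon, fused pentagon-hexagon) with exocyclic atoms placed radially and
polar hydrogens in-plane; the sugar ring orientation, glycosidic
rotations, and the duplex dyad were fitted once, offline and
deterministically, to reproduce Watson-Crick hydrogen-bond distances
(residuals ≤ 0.17 Å), C1'–C1' ≈ 10.8 Å, coplanar bases, and a steric
floor that keeps every non-bonded pair below the 0.4 Å overlap that the
clash score counts. A G·U wobble is produced by a small frozen rigid-body
shift of the whole uridine that moves the base into the wobble register
while keeping both backbone links under the 2.0 Å covalent cutoff.

Loops and junction linkers are closed geometrically: joint positions for
P and O3' atoms are solved by fixed-segment-length inverse kinematics
(FABRIK) between the anchor atoms, with context-atom repulsion shaping
the path and a clash-force relaxation refining it; each rigid nucleotide
is then placed on its joints with the residual spin about the P–O3' axis
chosen to minimize steric overlap. Hairpin caps for loop lengths 3–8 are
solved once against a worst-case stem context and shipped as frozen joint
paths, since every stem top is geometrically identical. This closure is
explicitly non-physical — torsions in linkers are not rotameric, bases
need not stack — but it preserves what the tests need: covalent
connectivity, all-atom residues, unambiguous pairing and steric sanity.

**What passing tests do and do not show.** The fixtures emulate clean
geometry: full occupancy, no alternate conformations, no modifications
(unless injected), idealized hydrogen positions and noise that is i.i.d.
Gaussian rather than structured (crystallographic disorder, lattice
strain). Success on fixtures demonstrates algorithmic correctness — pair
patterns, graph decomposition, superposition optimality, filter
soundness — not robustness to every pathology of deposited structures.
The synthetic helix also exaggerates base inclination relative to real
A-RNA (normals ≈ 55–57° from the helix axis), a compromise that keeps
the backbone exactly A-form while satisfying hydrogen-bond and steric
constraints; stacking detection on fixture helices works, but absolute
stacking geometry should not be read as physically calibrated.

## Quality scores

The clash score counts non-bonded pairs overlapping by ≥ 0.4 Å (van der
Waals radii C 1.70, N 1.55, O 1.52, P 1.80 Å …) per 1000 atoms,
excluding pairs within three covalent bonds and donor/acceptor pairs —
a pairwise simplification of dot-based contact analysis, documented as
such. Suites (δ₋₁, ε₋₁, ζ₋₁, α, β, γ, δ across each residue junction)
are classified against a table of 54 favorable conformers by nearest
mean under the maximum circular difference, with a 40° cap; the shipped
table (`inst/extdata/suite_conformers_synthetic.tsv`) is a synthetic
approximation assembled from canonical rotameric states with the A-form
row set to standard values — it is *not* the published consensus table,
and both the table and the cap are replaceable arguments. RSCC
(density-fit) scoring requires experimental structure factors and is a
stub that reports "unavailable" rather than zero.

## Degenerate inputs and numerical choices

Collinear point sets are rejected by the superposition (reflections are
too: the rotation is forced proper, so mirror images keep RMSD > 0).
Cutoffs are strict inequalities where the contract says "below" (contacts
at 3.89 Å count, at 3.91 Å do not). Empty inputs return empty results,
not errors, except where the contract demands an error (empty PDB input,
unparsable ATOM records, queries over 40 nt, loops shorter than 3).
Clustering of a singleton group returns that member as its own medoid.
All tie-breaks (pseudoknot DP, cycle ordering, medoids, triplet seeds,
spin search) are deterministic, so identical inputs give identical
output regardless of residue enumeration order.

## Problem sizes

The shipped tests and the acceptance script use deliberately small
systems — duplexes of 2–7 bp, stem-loops with 2–6 bp stems and 3–8 nt
loops, cloverleafs of ~60–70 nt, search queries of 6–8 nt against ~10
motifs, and 100-motif clustering problems — sizes at which every
brute-force oracle (exhaustive correspondence search, all-pairs clash
scans, 2^n subset enumeration or exact independent sets) is computable,
so each algorithmic shortcut can be checked against an independent
reference implementation.

## Known limitations

- Single-conformer policy: altlocs other than blank/'A' are discarded.
- Only the first MODEL of multi-model files is read.
- Space-group operators are taken from REMARK 290 when present; CRYST1
  alone yields identity (P1) operators. No mmCIF input.
- Base-pair classification is limited to canonical WC and wobble (plus a
  catch-all `other`); no full edge-family taxonomy.
- The suite conformer table is an approximation (see above).
- Stacking annotation is a simplified centroid/normal/offset rule.
- Motifs never span chains or chain breaks, by definition.
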