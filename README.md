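# rnamotifs

Decomposition, comparison and annotation of recurrent RNA 3D motifs.

## The problem

Folded RNA is modular: regular A-form helices alternate with irregularly
shaped loops that mediate most tertiary and protein contacts. Comparing
these modules across structures requires (i) a reproducible definition of a
motif, (ii) geometric tools to compare and cluster motif instances, and
(iii) annotation of each motif's molecular environment — including contacts
that exist only between crystal symmetry mates, which are easy to overlook.
`rnamotifs` implements that workflow for structures in PDB format and is
aimed at structural bioinformaticians analysing RNA and RNA-protein
complexes.

## The model

A *motif* ("brick") is a set of interacting nucleotides from one chain,
flanked by Watson-Crick or wobble base pairs; motifs come in three types:
helical **stems** (arrays of WC/wobble pair tandems), **loops** (hairpin
loops, internal loops, k-way junctions) and single-stranded **terminal
fragments**. For each chain, detected pairs (after pseudoknot removal by a
maximum non-crossing selection) define a secondary-structure graph with
nodes = residues and edges = phosphodiester bonds or WC/wobble pairs. A
**minimum cycle basis** of this graph yields E − V + C independent cycles:
length-4 cycles with two pair edges are base-pair tandems that merge into
stems, every other cycle is a loop, and unpaired chain ends become terminal
fragments. Adjacent motifs share at least one residue by construction.

Motifs of equal composition (type; number, length and cyclic order of
strands) are compared by backbone RMSD (atoms P, O5', C5', C4', C3', O3')
after optimal (Kabsch) superposition, and clustered by complete linkage at
1.0 Å so every intra-cluster pair stays below the threshold. A
tertiary-structure search matches a query fragment (≤ 40 nt) against motif
collections purely geometrically: pairwise-distance and triplet filters on
a selected backbone atom type (C3' by default), triplet-seeded
superposition scored by the RMSD of mutually-nearest atom pairs, then
refinement on all backbone atoms — in *query-in-motif* mode (find the query
inside motifs) or *motif-in-query* mode (cover the query; every motif
residue needs a counterpart). A sequence search supports regular
expressions, IUPAC codes, cyclic permutations of strand order and
case-sensitive matching of modified residues (lower-case parent letters,
e.g. `u` for m5U). Per-residue quality scores are provided: a steric clash
score (non-bonded overlaps ≥ 0.4 Å per 1000 atoms) and the fraction of
backbone *suites* (7 torsions spanning two residues) outside a library of
favorable conformers; density-fit (RSCC) scores are an explicit
"unavailable" stub.

A synthetic structure generator builds full-atom idealized A-form duplexes,
stem-loops and tRNA-like cloverleafs with known ground truth (pairs,
motifs), so the whole pipeline is testable without downloading structures.

## Worked example

```r
library(rnamotifs)

fx <- makeStemLoop(4, "GAAA")        # 12-nt hairpin with ground truth
ann <- annotateStructure(fx$model)
ann$pairs
#>   resA resB        klass nHBonds     c1c1
#> 1  A:1 A:12 canonical_wc       3 10.84881
#> 2 A:11  A:2 canonical_wc       3 10.84881
#> 3 A:10  A:3 canonical_wc       3 10.84881
#> 4  A:4  A:9 canonical_wc       3 10.84881

motifs <- decomposeMotifs(fx$model, pairs = ann$pairs)
for (m in motifs) show(m)
#> RNAMotif stemloop_A_stem1 [stem]: 8 residues in 2 strand(s), lengths 4,4
#> RNAMotif stemloop_A_loop1 [terminal loop]: 6 residues in 1 strand(s), lengths 6
```

The four canonical pairs close a 4-bp stem; the hairpin loop keeps the
closing pair, so the two motifs share two residues (the shared closing
pair), exactly as the decomposition rule requires. Searching the loop
against a motif collection:

```r
hits <- searchStructure(motifs[[2]], motifs, mode = "query_in_motif",
                        rmsdThreshold = 1.0)
hits[[1]]
#> MatchResult vs stemloop_A_loop1: anchor RMSD 0.000 A, refined RMSD 0.000 A, 6 residues
```

A command-line interface wrapping these functions is provided at
`inst/scripts/bricks-cli.R` (subcommands `info`, `annotate`, `decompose`,
`cluster`, `search3d`, `searchseq`, `contacts`, `graph`, `quality`,
`fixtures`).

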