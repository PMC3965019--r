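Package: rnamotifs
Title: Decomposition, Comparison and Annotation of Recurrent RNA 3D Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with recurrent three-dimensional motifs in RNA
    structures. RNA chains read from PDB-format files are annotated with
    hydrogen bonds, Watson-Crick and wobble base pairs and stacking contacts;
    each chain's secondary-structure graph is decomposed via a minimum cycle
    basis into helical stems, loops and terminal fragments. Motifs can be
    clustered by backbone RMSD after optimal superposition, searched by
    tertiary structure (triplet-filtered rigid matching of backbone atoms) or
    by sequence (regular expressions, cyclic segment permutations, modified
    residues), and annotated with their molecular environment: contacts with
    RNA, protein, ions, water and ligands, including crystal symmetry mates,
    summarized as a reduced motif-interaction graph. Per-residue structure
    quality scores (steric clash score, backbone suite conformer outliers) are
    provided, and a synthetic full-atom A-form structure generator supplies
    ground-truth test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralPrediction, Clustering, DataRepresentation
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'chem-tables.R'
    'contacts.R'
    'cycle-basis.R'
    'decompose.R'
    'fixtures-caps.R'
    'fixtures-junction.R'
    'fixtures-templates.R'
    'fixtures.R'
    'geometry.R'
    'pdb-io.R'
    'quality.R'
    'rnamotifs-package.R'
    'search3d.R'
    'secstruct.R'
    'seqsearch.R'
    'structure-select.R'
    'utils-geometry.R'
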