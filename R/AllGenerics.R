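#' @include AllClasses.R
NULL

#' Atom records of an object
#' @param x object with atom records
#' @return data.frame of atom records
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @aliases atoms,StructureModel-method
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname atoms
#' @aliases atoms,RNAMotif-method
setMethod("atoms", "RNAMotif", function(x) x@atoms)

#' Entry identifier
#' @param x object with an entry id
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
setMethod("entryId", "StructureModel", function(x) x@entryId)

#' Crystal frame (unit cell, space group, symmetry operators)
#' @param x a StructureModel
#' @return list with cell/spacegroup/symops, or empty list
#' @export
setGeneric("crystalFrame", function(x) standardGeneric("crystalFrame"))
setMethod("crystalFrame", "StructureModel", function(x) x@crystal)

#' Motif type accessor
#' @param x an RNAMotif
#' @return "stem", "loop" or "terminal"
#' @export
setGeneric("motifType", function(x) standardGeneric("motifType"))
setMethod("motifType", "RNAMotif", function(x) x@type)

#' Motif strands accessor
#' @param x an RNAMotif
#' @return list of character vectors of residue ids
#' @export
setGeneric("strands", function(x) standardGeneric("strands"))
setMethod("strands", "RNAMotif", function(x) x@strands)

#' Residue ids of a motif
#' @param x an RNAMotif
#' @export
setGeneric("motifResidues", function(x) standardGeneric("motifResidues"))
setMethod("motifResidues", "RNAMotif", function(x) x@residues)

#' Closing pairs of a motif
#' @param x an RNAMotif
#' @return data.frame with columns resA, resB
#' @export
setGeneric("closingPairs", function(x) standardGeneric("closingPairs"))
setMethod("closingPairs", "RNAMotif", function(x) x@closingPairs)

#' Cluster members / medoid accessors
#' @param x a MotifCluster
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
setMethod("clusterMembers", "MotifCluster", function(x) x@members)

#' @rdname clusterMembers
#' @export
setGeneric("clusterMedoid", function(x) standardGeneric("clusterMedoid"))
setMethod("clusterMedoid", "MotifCluster", function(x) x@members[[x@medoid]])

setMethod("show", "StructureModel", function(object) {
  rt <- residueTable(object)
  cat("StructureModel '", object@entryId, "': ", nrow(object@atoms),
      " atoms, ", nrow(rt), " residues, ",
      length(unique(rt$chain)), " chain(s)\n", sep = "")
  tab <- table(rt$category)
  cat("  residues by category:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(object@crystal) > 0) {
    cat("  crystal: cell ",
        paste(sprintf("%.2f", object@crystal$cell), collapse = " "),
        "  SG ", object@crystal$spacegroup,
        " (", length(object@crystal$symops), " ops)\n", sep = "")
  } else cat("  crystal: none\n")
})

setMethod("show", "RNAMotif", function(object) {
  cat("RNAMotif ", object@id, " [", motifClassLabel(object), "]: ",
      length(object@residues), " residues in ",
      length(object@strands), " strand(s), lengths ",
      paste(vapply(object@strands, length, 1L), collapse = ","), "\n",
      sep = "")
})

setMethod("show", "MotifCluster", function(object) {
  cat("MotifCluster key=", object@key, ": ", length(object@members),
      " member(s), medoid #", object@medoid, "\n", sep = "")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult vs ", object@motifId,
      sprintf(": anchor RMSD %.3f A, refined RMSD %.3f A, %d residues\n",
              object@anchorRMSD, object@refinedRMSD,
              nrow(object@correspondence)), sep = "")
})

setMethod("show", "ReducedGraph", function(object) {
  cat("ReducedGraph: ", nrow(object@nodes), " motif nodes, ",
      nrow(object@edges), " edges\n", sep = "")
  if (nrow(object@edges) > 0) {
    tab <- table(object@edges$type)
    cat("  edges:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})
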