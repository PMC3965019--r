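#' @import methods
NULL

#' StructureModel: a macromolecular structure
#'
#' Container for the atoms of one model of a macromolecular structure
#' (RNA alone or in complex with protein, ions, waters and ligands), with an
#' optional crystal frame (unit cell, space group and symmetry operators).
#'
#' The \code{atoms} slot is a data.frame with one row per atom and columns
#' \code{chain}, \code{resno}, \code{icode}, \code{resname}, \code{atom},
#' \code{element}, \code{x}, \code{y}, \code{z}, \code{occ}, \code{alt},
#' \code{het} and \code{hydrogen}.
#'
#' @slot entryId character entry identifier
#' @slot atoms data.frame of atom records
#' @slot crystal list with elements \code{cell} (a, b, c, alpha, beta, gamma),
#'   \code{spacegroup} and \code{symops} (list of 3x4 operator matrices in
#'   fractional coordinates), or an empty list when no crystal frame is known
#' @exportClass StructureModel
setClass("StructureModel",
         representation(entryId = "character", atoms = "data.frame",
                        crystal = "list"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ", "alt", "het", "hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) > 0) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      return("non-finite coordinates")
    if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
      return("occupancy outside [0,1]")
    key <- paste(a$chain, a$resno, a$icode, a$atom, a$alt)
    if (anyDuplicated(key))
      return("duplicate atom records within a residue")
  }
  if (length(object@crystal) > 0) {
    if (!all(c("cell", "symops") %in% names(object@crystal)))
      return("crystal frame must contain 'cell' and 'symops'")
    if (length(object@crystal$cell) != 6)
      return("crystal cell must have 6 parameters")
  }
  TRUE
})

#' SymmetryMate: a crystallographic copy of the asymmetric unit
#'
#' @slot operatorIndex integer index of the generating symmetry operator
#' @slot latticeShift integer 3-vector of unit-cell translations
#' @slot model transformed copy of the parent StructureModel
#' @exportClass SymmetryMate
setClass("SymmetryMate",
         representation(operatorIndex = "integer", latticeShift = "integer",
                        model = "StructureModel"))

#' RigidTransform: proper rotation plus translation
#'
#' @slot rotation 3x3 proper orthogonal matrix
#' @slot translation length-3 numeric
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6) return("rotation not orthogonal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' RNAMotif: a typed RNA 3D motif ("brick")
#'
#' A set of interacting nucleotide residues from one chain, flanked by
#' Watson-Crick or wobble base pairs: a helical stem, a loop (hairpin,
#' internal loop or multi-way junction) or a single-stranded terminal
#' fragment. Strands are ordered continuous runs of residues in chain
#' direction; adjacent motifs share their closing-pair residues.
#'
#' @slot id character motif identifier
#' @slot type one of "stem", "loop", "terminal"
#' @slot strands list of character vectors of residue ids (5' to 3')
#' @slot closingPairs data.frame with columns resA, resB of flanking pairs
#' @slot residues character vector of all member residue ids
#' @slot atoms data.frame of member atom records (adds a \code{resid} column)
#' @exportClass RNAMotif
setClass("RNAMotif",
         representation(id = "character", type = "character",
                        strands = "list", closingPairs = "data.frame",
                        residues = "character", atoms = "data.frame"))

setValidity("RNAMotif", function(object) {
  if (!object@type %in% c("stem", "loop", "terminal"))
    return("type must be stem, loop or terminal")
  if (length(object@strands) < 1) return("motif needs at least one strand")
  if (object@type == "stem") {
    if (length(object@strands) != 2)
      return("stem must have exactly two strands")
    if (length(object@strands[[1]]) != length(object@strands[[2]]))
      return("stem strands must have equal length")
    if (length(object@strands[[1]]) < 2)
      return("stem needs at least two base-pair tandems")
  }
  if (object@type == "terminal" && nrow(object@closingPairs) != 1)
    return("terminal fragment has exactly one closing pair")
  if (!setequal(unlist(object@strands), object@residues))
    return("residues must equal union of strands")
  TRUE
})

#' MotifCluster: geometrically similar motifs grouped at an RMSD threshold
#'
#' @slot key composition key shared by all members
#' @slot members list of RNAMotif objects
#' @slot medoid integer index of the medoid member
#' @slot rmsd matrix of pairwise backbone RMSDs (may be 0x0 for singletons)
#' @exportClass MotifCluster
setClass("MotifCluster",
         representation(key = "character", members = "list",
                        medoid = "integer", rmsd = "matrix"))

#' MatchResult: one hit of the tertiary-structure search
#'
#' @slot motifId identifier of the matched motif
#' @slot transform RigidTransform mapping motif coordinates onto the query
#' @slot correspondence data.frame with columns \code{query}, \code{motif}
#'   (residue ids)
#' @slot anchorRMSD closest-pair RMSD over the selected backbone atom type
#' @slot refinedRMSD RMSD after re-superposition on all backbone atoms
#' @exportClass MatchResult
setClass("MatchResult",
         representation(motifId = "character", transform = "RigidTransform",
                        correspondence = "data.frame", anchorRMSD = "numeric",
                        refinedRMSD = "numeric"))

#' ReducedGraph: motif-level interaction graph
#'
#' Nodes are motifs (with a protein-contact flag); edges are typed:
#' \code{shared_residue}, \code{intramolecular_contact} or
#' \code{crystallographic_contact}.
#'
#' @slot nodes data.frame with columns id, type, label, proteinContact
#' @slot edges data.frame with columns from, to, type
#' @exportClass ReducedGraph
setClass("ReducedGraph",
         representation(nodes = "data.frame", edges = "data.frame"))
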