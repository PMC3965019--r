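# Molecular-environment annotation: heavy-atom contacts of motifs with RNA,
# protein, ions, waters and ligands (including crystal symmetry mates), and
# the reduced motif-interaction graph.

CONTACT_CUTOFF <- 3.9  # Angstrom, strict upper bound on heavy-atom distance

# spatial grid lookup: returns data.frame of candidate atom index pairs
gridNeighborPairs <- function(A, B, cutoff) {
  # A, B: coordinate matrices; returns index pairs with distance < cutoff
  if (nrow(A) == 0 || nrow(B) == 0)
    return(cbind(i = integer(0), j = integer(0), d = numeric(0)))
  cell <- cutoff
  keyOf <- function(M) {
    k <- floor(M / cell)
    paste(k[, 1], k[, 2], k[, 3])
  }
  kB <- keyOf(B)
  lut <- split(seq_len(nrow(B)), kB)
  kA <- floor(A / cell)
  out <- vector("list", nrow(A))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    cand <- integer(0)
    for (s in seq_len(nrow(shifts))) {
      key <- paste(kA[i, 1] + shifts[s, 1], kA[i, 2] + shifts[s, 2],
                   kA[i, 3] + shifts[s, 3])
      hit <- lut[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0) next
    d <- sqrt(colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2))
    sel <- d < cutoff
    if (any(sel))
      out[[i]] <- cbind(i = i, j = cand[sel], d = d[sel])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(cbind(i = integer(0), j = integer(0), d = numeric(0)))
  do.call(rbind, out)
}

#' Detect molecular-environment contacts of motifs
#'
#' Two entities are in contact when the smallest distance between their
#' non-hydrogen atoms is below the cutoff (default 3.9 Angstrom). One
#' contact is reported per (motif residue, partner residue/molecule) at the
#' minimal distance, with the partner categorized as rna, protein, ion,
#' water or ligand. Partners from supplied symmetry mates are flagged
#' \code{viaSymmetry}. Contacts within one motif and with covalently
#' adjacent chain neighbors are excluded. RNA and protein contacts carry
#' the number of supporting hydrogen bonds when an hbond table is given.
#'
#' @param motifs list of \linkS4class{RNAMotif}
#' @param model the parent \linkS4class{StructureModel}
#' @param mates optional list of \linkS4class{SymmetryMate}
#' @param cutoff contact cutoff (Angstrom)
#' @param hbonds optional data.frame from \code{\link{detectHBonds}}
#' @return data.frame with columns motifId, resid, partner, partnerCategory,
#'   minDistance, viaSymmetry, nHBonds
#' @export
detectContacts <- function(motifs, model, mates = list(), cutoff = CONTACT_CUTOFF,
                           hbonds = NULL) {
  a <- atoms(model)
  a$resid <- resIdOf(a$chain, a$resno, a$icode)
  a <- a[!a$hydrogen, , drop = FALSE]
  rt <- residueTable(model)
  category <- stats::setNames(rt$category, rt$resid)
  # chain-order position for covalent-adjacency exclusion
  pos <- stats::setNames(seq_len(nrow(rt)), rt$resid)

  partnerTables <- list(list(tag = "", atoms = a))
  for (k in seq_along(mates)) {
    am <- atoms(mates[[k]]@model)
    am$resid <- resIdOf(am$chain, am$resno, am$icode)
    am <- am[!am$hydrogen, , drop = FALSE]
    partnerTables[[length(partnerTables) + 1]] <- list(tag = paste0("sym", k),
                                                       atoms = am)
  }

  out <- list()
  for (motif in motifs) {
    ma <- atoms(motif)
    ma <- ma[!ma$hydrogen, , drop = FALSE]
    inMotif <- motifResidues(motif)
    A <- as.matrix(ma[, c("x", "y", "z")])
    for (pt in partnerTables) {
      B <- as.matrix(pt$atoms[, c("x", "y", "z")])
      prs <- gridNeighborPairs(A, B, cutoff)
      if (nrow(prs) == 0) next
      viaSym <- nzchar(pt$tag)
      rrA <- ma$resid[prs[, "i"]]
      rrB <- pt$atoms$resid[prs[, "j"]]
      keep <- rep(TRUE, nrow(prs))
      if (!viaSym) {
        keep <- keep & !(rrB %in% inMotif)
        # covalent chain neighbors (same chain, adjacent residue rows)
        keep <- keep & !(abs(pos[rrA] - pos[rrB]) == 1 &
                           substr(rrA, 1, 1) == substr(rrB, 1, 1) &
                           !is.na(pos[rrA]) & !is.na(pos[rrB]))
      }
      if (!any(keep)) next
      key <- paste(rrA[keep], rrB[keep], sep = "\r")
      dmin <- tapply(prs[keep, "d"], key, min)
      for (kk in names(dmin)) {
        rs <- strsplit(kk, "\r", fixed = TRUE)[[1]]
        nhb <- NA_integer_
        if (!viaSym && !is.null(hbonds) &&
            category[rs[2]] %in% c("rna", "protein")) {
          nhb <- sum((hbonds$donorRes == rs[1] & hbonds$acceptorRes == rs[2]) |
                     (hbonds$donorRes == rs[2] & hbonds$acceptorRes == rs[1]))
        }
        out[[length(out) + 1]] <- data.frame(
          motifId = motif@id, resid = rs[1],
          partner = if (viaSym) paste0(pt$tag, ":", rs[2]) else rs[2],
          partnerCategory = unname(category[rs[2]]),
          minDistance = unname(dmin[[kk]]), viaSymmetry = viaSym,
          nHBonds = nhb, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(motifId = character(0), resid = character(0),
                      partner = character(0), partnerCategory = character(0),
                      minDistance = numeric(0), viaSymmetry = logical(0),
                      nHBonds = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the reduced motif-interaction graph
#'
#' Nodes are motifs; gray edges join motifs sharing residues, red edges
#' join motifs of the same asymmetric unit with at least one RNA-RNA
#' contact (motif pairs that already share residues are not duplicated),
#' and blue edges mark contacts through crystal symmetry mates. Nodes in
#' contact with protein are flagged.
#'
#' @param motifs list of \linkS4class{RNAMotif}
#' @param contacts data.frame from \code{\link{detectContacts}}
#' @return a \linkS4class{ReducedGraph}
#' @export
buildReducedGraph <- function(motifs, contacts = NULL) {
  ids <- vapply(motifs, function(m) m@id, "")
  nodes <- data.frame(
    id = ids,
    type = vapply(motifs, motifType, ""),
    label = vapply(motifs, motifClassLabel, ""),
    proteinContact = FALSE, stringsAsFactors = FALSE)
  edges <- list()
  n <- length(motifs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (length(intersect(motifResidues(motifs[[i]]),
                           motifResidues(motifs[[j]]))) > 0)
        edges[[length(edges) + 1]] <- data.frame(
          from = ids[i], to = ids[j], type = "shared_residue",
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(contacts) && nrow(contacts) > 0) {
    nodes$proteinContact <- ids %in%
      contacts$motifId[contacts$partnerCategory == "protein"]
    resToMotifs <- list()
    for (i in seq_len(n))
      for (r in motifResidues(motifs[[i]]))
        resToMotifs[[r]] <- c(resToMotifs[[r]], i)
    shared <- vapply(edges, function(e) paste(e$from, e$to), "")
    rnaC <- contacts[contacts$partnerCategory == "rna", , drop = FALSE]
    for (r in seq_len(nrow(rnaC))) {
      i <- match(rnaC$motifId[r], ids)
      partnerRes <- sub("^sym[0-9]+:", "", rnaC$partner[r])
      js <- resToMotifs[[partnerRes]]
      if (is.null(js)) next
      for (j in js) {
        if (!rnaC$viaSymmetry[r] && j == i) next
        a <- min(i, j); b <- max(i, j)
        type <- if (rnaC$viaSymmetry[r]) "crystallographic_contact"
                else "intramolecular_contact"
        if (type == "intramolecular_contact" &&
            paste(ids[a], ids[b]) %in% shared) next
        key <- paste(ids[a], ids[b], type)
        already <- vapply(edges, function(e) paste(e$from, e$to, e$type), "")
        if (key %in% already) next
        edges[[length(edges) + 1]] <- data.frame(
          from = ids[a], to = ids[b], type = type, stringsAsFactors = FALSE)
      }
    }
  }
  edf <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               stringsAsFactors = FALSE)
  rownames(edf) <- NULL
  new("ReducedGraph", nodes = nodes, edges = edf)
}
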