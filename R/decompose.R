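# Motif ("brick") extraction: stems, loops and terminal fragments from the
# minimum cycle basis of the pseudoknot-free secondary-structure graph.

newMotif <- function(id, type, strandIdxList, closingIdx, graph, model = NULL) {
  strandsR <- lapply(strandIdxList, function(ix) graph$resids[ix])
  resids <- unique(unlist(strandsR))
  cp <- if (NROW(closingIdx) == 0)
    data.frame(resA = character(0), resB = character(0), stringsAsFactors = FALSE)
  else
    data.frame(resA = graph$resids[closingIdx[, 1]],
               resB = graph$resids[closingIdx[, 2]], stringsAsFactors = FALSE)
  at <- if (is.null(model)) {
    data.frame()
  } else {
    a <- atoms(model)
    rid <- resIdOf(a$chain, a$resno, a$icode)
    sub <- a[rid %in% resids, , drop = FALSE]
    sub$resid <- rid[rid %in% resids]
    rownames(sub) <- NULL
    sub
  }
  new("RNAMotif", id = id, type = type, strands = strandsR,
      closingPairs = cp, residues = resids, atoms = at)
}

#' Decompose a secondary-structure graph into motifs
#'
#' Length-4 cycles with exactly two pair edges are base-pair tandems;
#' maximal runs of tandems chained by shared pair edges merge into helical
#' stem motifs. Every other cycle becomes a loop motif whose strand count
#' equals its number of pair edges. Unpaired chain ends (plus the adjacent
#' paired residue) become terminal fragments. Adjacent motifs share their
#' closing-pair residues.
#'
#' @param graph graph from \code{\link{buildSecStructGraph}} (pseudoknot-free
#'   pairs)
#' @param cycles minimum cycle basis; computed when NULL
#' @param model optional \linkS4class{StructureModel} to attach coordinates
#' @param idPrefix prefix for motif identifiers
#' @return list of \linkS4class{RNAMotif}
#' @export
decomposeGraph <- function(graph, cycles = NULL, model = NULL, idPrefix = "m") {
  if (is.null(cycles)) cycles <- minimumCycleBasis(graph)
  isStemUnit <- vapply(cycles, function(cc)
    length(cc$edges) == 4 && identical(cc$pairEdgeCount, 2L), logical(1))
  motifs <- list()

  # ---- stems: merge tandems sharing a pair edge ----
  if (any(isStemUnit)) {
    units <- cycles[isStemUnit]
    pairKey <- function(e) paste(e[, 1], e[, 2])
    unitPairs <- lapply(units, function(cc)
      pairKey(cc$edgeNodes[cc$edgeTypes == "pair", , drop = FALSE]))
    allKeys <- unique(unlist(unitPairs))
    ug <- igraph::make_empty_graph(n = length(units), directed = FALSE)
    if (length(units) > 1) {
      el <- list()
      for (i in seq_len(length(units) - 1)) for (j in seq(i + 1, length(units)))
        if (length(intersect(unitPairs[[i]], unitPairs[[j]])) > 0)
          el[[length(el) + 1]] <- c(i, j)
      if (length(el) > 0)
        ug <- igraph::add_edges(ug, as.vector(t(do.call(rbind, el))))
    }
    comp <- igraph::components(ug)$membership
    for (k in sort(unique(comp))) {
      uu <- units[comp == k]
      prs <- unique(do.call(rbind, lapply(uu, function(cc)
        cc$edgeNodes[cc$edgeTypes == "pair", , drop = FALSE])))
      prs <- prs[order(prs[, 1]), , drop = FALSE]
      s1 <- prs[, 1]; s2 <- sort(prs[, 2])
      motifs[[length(motifs) + 1]] <- newMotif(
        sprintf("%s_stem%d", idPrefix, k), "stem",
        list(s1, s2), cbind(c(s1[1], s1[length(s1)]), c(s2[length(s2)], s2[1])),
        graph, model)
    }
  }

  # ---- loops: every non-tandem cycle ----
  li <- 0
  for (cc in cycles[!isStemUnit]) {
    li <- li + 1
    nodes <- cc$nodes
    m <- length(nodes)
    etype <- character(m)
    for (i in seq_len(m)) {
      a <- nodes[i]; b <- nodes[if (i == m) 1 else i + 1]
      isPair <- any(cc$edgeNodes[, 1] == min(a, b) &
                    cc$edgeNodes[, 2] == max(a, b) &
                    cc$edgeTypes == "pair")
      etype[i] <- if (isPair) "pair" else "backbone"
    }
    # rotate so the walk starts right after a pair edge (if any)
    strandsIdx <- list()
    if (all(etype == "backbone")) {
      strandsIdx <- list(sort(nodes))
      closing <- matrix(integer(0), 0, 2)
    } else {
      start <- which(etype == "pair")[1]
      ordN <- c(nodes[-seq_len(start)], nodes[seq_len(start)])
      ordT <- c(etype[-seq_len(start)], etype[seq_len(start)])
      cur <- ordN[1]
      runAcc <- cur
      for (i in seq_len(m)) {
        nxt <- ordN[if (i == m) 1 else i + 1]
        if (ordT[i] == "pair") {
          strandsIdx[[length(strandsIdx) + 1]] <- runAcc
          runAcc <- nxt
        } else {
          runAcc <- c(runAcc, nxt)
        }
        if (i == m) break
      }
      strandsIdx <- lapply(strandsIdx, function(ix) sort(unique(ix)))
      first <- vapply(strandsIdx, min, 1L)
      strandsIdx <- strandsIdx[order(first)]
      closing <- cc$edgeNodes[cc$edgeTypes == "pair", , drop = FALSE]
    }
    motifs[[length(motifs) + 1]] <- newMotif(
      sprintf("%s_loop%d", idPrefix, li), "loop", strandsIdx, closing,
      graph, model)
  }

  # ---- terminal fragments per covalent segment ----
  n <- graph$n
  segStart <- c(1L, which(!graph$backbone) + 1L)
  segEnd <- c(which(!graph$backbone), n)
  paired <- logical(n); paired[c(graph$pairIdx)] <- TRUE
  ti <- 0
  for (s in seq_along(segStart)) {
    ix <- seq(segStart[s], segEnd[s])
    pp <- ix[paired[ix]]
    if (length(pp) == 0) next
    fp <- min(pp); lp <- max(pp)
    for (side in c("5", "3")) {
      run <- if (side == "5" && fp > ix[1]) seq(ix[1], fp)
             else if (side == "3" && lp < ix[length(ix)]) seq(lp, ix[length(ix)])
             else NULL
      if (is.null(run)) next
      ti <- ti + 1
      anchor <- if (side == "5") fp else lp
      mate <- c(graph$pairIdx[graph$pairIdx[, 1] == anchor, 2],
                graph$pairIdx[graph$pairIdx[, 2] == anchor, 1])[1]
      motifs[[length(motifs) + 1]] <- newMotif(
        sprintf("%s_term%d", idPrefix, ti), "terminal", list(run),
        cbind(min(anchor, mate), max(anchor, mate)), graph, model)
    }
  }
  motifs
}

#' Extract RNA motifs from a structure
#'
#' Full pipeline for every eligible chain: base-pair annotation (unless
#' pairs are supplied), pseudoknot removal, secondary-structure graph,
#' minimum cycle basis and motif decomposition.
#'
#' @param model a \linkS4class{StructureModel}
#' @param pairs optional precomputed pair data.frame (resA, resB, klass);
#'   computed via \code{\link{annotateStructure}} when NULL
#' @param chains chains to process (default: all eligible RNA chains)
#' @return list of \linkS4class{RNAMotif}
#' @examples
#' fx <- makeStemLoop(4, "GAAA")
#' motifs <- decomposeMotifs(fx$model)
#' vapply(motifs, motifClassLabel, "")
#' @export
decomposeMotifs <- function(model, pairs = NULL, chains = NULL) {
  if (is.null(pairs)) pairs <- annotateStructure(model)$pairs
  if (is.null(chains)) chains <- eligibleRNAChains(model)
  motifs <- list()
  for (ch in chains) {
    g <- buildSecStructGraph(model, ch, pairs)
    pk <- removePseudoknots(g$pairIdx)
    if (nrow(pk$removed) > 0) {
      g$pairIdx <- pk$kept
      g$E <- sum(g$backbone) + nrow(pk$kept)
    }
    mm <- decomposeGraph(g, model = model,
                         idPrefix = paste0(entryId(model), "_", ch))
    motifs <- c(motifs, mm)
  }
  motifs
}

#' Motif class label
#'
#' Loops are labeled by strand count: one strand is a terminal (hairpin)
#' loop, two an internal loop, k of them a k-way junction ("3wj", "4wj",
#' ...). Stems and terminal fragments are labeled as such.
#'
#' @param motif an \linkS4class{RNAMotif}
#' @return character label
#' @export
motifClassLabel <- function(motif) {
  switch(motifType(motif),
         stem = "stem",
         terminal = "terminal fragment",
         loop = {
           k <- length(strands(motif))
           if (k == 1) "terminal loop"
           else if (k == 2) "internal loop"
           else paste0(k, "wj")
         })
}
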