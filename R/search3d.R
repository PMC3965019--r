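# Tertiary-structure search: distance and triplet filters on a selected
# backbone atom type, superposition seeded from matched triplets, scoring by
# closest-pair RMSD, and refinement on all backbone atoms. Two modes:
# query-in-motif finds instances of the query inside stored motifs;
# motif-in-query covers the query with motifs (every motif residue must
# have a counterpart in the query).

MAX_QUERY_NT <- 40

# selected-atom coordinate set of a query or motif: residue ids + coords
selectedAtoms <- function(x, atomType) {
  a <- if (is(x, "StructureModel")) {
    aa <- atoms(x)
    rt <- residueTable(x)
    aa$resid <- resIdOf(aa$chain, aa$resno, aa$icode)
    aa[aa$resid %in% rt$resid[rt$category == "rna"], , drop = FALSE]
  } else if (is(x, "RNAMotif")) {
    atoms(x)
  } else x
  sel <- a[a$atom == atomType, , drop = FALSE]
  sel <- sel[!duplicated(sel$resid), , drop = FALSE]
  list(resids = sel$resid, xyz = as.matrix(sel[, c("x", "y", "z")]),
      all = a)
}

#' Pairwise-distance compatibility filter
#'
#' TRUE when every selected-atom pairwise distance of the pattern structure
#' has a container distance within \code{tol} (sorted distances + binary
#' search; equivalent to the naive all-pairs check).
#'
#' @param pattern,container coordinate matrices of the selected atoms
#' @param tol distance tolerance (Angstrom)
#' @return logical
#' @export
distanceFilter <- function(pattern, container, tol) {
  dp <- sort(as.vector(stats::dist(pattern)))
  dc <- sort(as.vector(stats::dist(container)))
  if (length(dp) == 0) return(TRUE)
  if (length(dc) == 0) return(FALSE)
  lo <- findInterval(dp - tol, dc)       # count of dc <= dp - tol
  hi <- findInterval(dp + tol, dc)       # count of dc <= dp + tol
  all(hi > lo)
}

tripletSpread <- function(xyz, ix) {
  sum(stats::dist(xyz[ix, , drop = FALSE]))
}

# pick the pattern seed triplet with maximal pairwise-distance spread
seedTriplet <- function(xyz) {
  n <- nrow(xyz)
  combs <- utils::combn(n, 3)
  spread <- apply(combs, 2, function(ix) tripletSpread(xyz, ix))
  combs[, which.max(spread)]
}

# a small diverse set of seed triplets: the maximal-spread one plus
# ends/middle combinations (multiple seeds make the alignment search
# robust for borderline matches)
seedTriplets <- function(xyz) {
  n <- nrow(xyz)
  cand <- list(seedTriplet(xyz), c(1, ceiling(n/2), n))
  if (n >= 4) cand <- c(cand, list(c(1, 2, n), c(1, n - 1, n)))
  cand <- unique(lapply(cand, sort))
  # drop (near-)collinear triplets
  keep <- vapply(cand, function(ix) {
    m <- xyz[ix, , drop = FALSE]
    vnorm(cross3(m[2, ] - m[1, ], m[3, ] - m[1, ])) > 1e-6
  }, logical(1))
  cand[keep]
}

#' Matching triplets of selected atoms
#'
#' Enumerates container triplets whose edge lengths match the pattern seed
#' triplet within \code{tol} under some vertex assignment (all six
#' permutations are tested).
#'
#' @param patternXYZ,containerXYZ coordinate matrices
#' @param tol edge-length tolerance
#' @param seed optional pattern triplet indices (default: maximal spread)
#' @return list of candidates, each with pattern indices \code{p} and
#'   container indices \code{c} in corresponding order
#' @export
tripletFilter <- function(patternXYZ, containerXYZ, tol, seed = NULL) {
  if (is.null(seed)) seed <- seedTriplet(patternXYZ)
  ps <- patternXYZ[seed, , drop = FALSE]
  pe <- c(vnorm(ps[1, ] - ps[2, ]), vnorm(ps[1, ] - ps[3, ]),
          vnorm(ps[2, ] - ps[3, ]))
  n <- nrow(containerXYZ)
  if (n < 3) return(list())
  combs <- utils::combn(n, 3)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  out <- list()
  sortedPe <- sort(pe)
  for (ci in seq_len(ncol(combs))) {
    ix <- combs[, ci]
    cs <- containerXYZ[ix, , drop = FALSE]
    ce <- c(vnorm(cs[1, ] - cs[2, ]), vnorm(cs[1, ] - cs[3, ]),
            vnorm(cs[2, ] - cs[3, ]))
    if (any(abs(sort(ce) - sortedPe) > tol)) next   # cheap necessary check
    for (pi in seq_len(nrow(perms))) {
      q <- perms[pi, ]
      qe <- c(vnorm(cs[q[1], ] - cs[q[2], ]), vnorm(cs[q[1], ] - cs[q[3], ]),
              vnorm(cs[q[2], ] - cs[q[3], ]))
      if (all(abs(qe - pe) <= tol))
        out[[length(out) + 1]] <- list(p = seed, c = ix[q])
    }
  }
  out
}

# greedy mutual-nearest one-to-one pairing between two point sets
mutualNearestPairs <- function(A, B, cutoff) {
  dm <- crossDist(A, B)
  ord <- order(dm)
  usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
  out <- list()
  for (o in ord) {
    if (dm[o] > cutoff) break
    i <- (o - 1) %% nrow(A) + 1
    j <- (o - 1) %/% nrow(A) + 1
    if (usedA[i] || usedB[j]) next
    usedA[i] <- usedB[j] <- TRUE
    out[[length(out) + 1]] <- c(i, j, dm[o])
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

# all backbone atoms of given residues as one matrix, with labels
backboneCoordsOf <- function(allAtoms, resids) {
  sub <- allAtoms[allAtoms$resid %in% resids &
                  allAtoms$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  list(xyz = as.matrix(sub[, c("x", "y", "z")]),
       key = paste(sub$resid, sub$atom))
}

#' Tertiary-structure search
#'
#' Pipeline: distance filter, triplet filter, triplet superposition,
#' closest-pair scoring on the selected atom type, refinement on all
#' backbone atoms. Results are deduplicated per motif (best anchor RMSD)
#' and sorted by refined RMSD.
#'
#' @param query a \linkS4class{StructureModel}, \linkS4class{RNAMotif} or
#'   atom data.frame with a \code{resid} column (at most 40 residues)
#' @param motifs list of \linkS4class{RNAMotif}
#' @param mode \code{"query_in_motif"} (find the query inside motifs) or
#'   \code{"motif_in_query"} (cover the query with motifs; every motif
#'   residue needs a counterpart)
#' @param rmsdThreshold anchor RMSD acceptance threshold (Angstrom)
#' @param atomType selected backbone atom type (default C3')
#' @param tol distance/triplet tolerance; by default the provably sound
#'   bound \code{2 * rmsdThreshold * sqrt(n)} for an n-residue pattern (a
#'   correspondence whose RMSD passes the threshold cannot displace any
#'   atom by more than \code{rmsdThreshold * sqrt(n)}, hence no pairwise
#'   distance by more than twice that)
#' @return list of \linkS4class{MatchResult}, sorted by refined RMSD
#' @export
searchStructure <- function(query, motifs, mode = c("query_in_motif", "motif_in_query"),
                            rmsdThreshold = 1.0, atomType = "C3'", tol = NULL) {
  mode <- match.arg(mode)
  q <- selectedAtoms(query, atomType)
  if (length(q$resids) > MAX_QUERY_NT)
    stop("query exceeds the supported size (up to ", MAX_QUERY_NT,
         " nt residues)")
  if (length(q$resids) < 3) stop("query needs >= 3 residues with ", atomType)
  results <- list()
  for (mi in seq_along(motifs)) {
    motif <- motifs[[mi]]
    m <- selectedAtoms(motif, atomType)
    if (length(m$resids) < 3) next
    if (mode == "motif_in_query") {
      patt <- m; cont <- q
    } else {
      patt <- q; cont <- m
    }
    tolEff <- if (is.null(tol))
      max(1.0, 2 * rmsdThreshold * sqrt(nrow(patt$xyz))) else tol
    if (!distanceFilter(patt$xyz, cont$xyz, tolEff)) next
    cands <- list()
    for (sd in seedTriplets(patt$xyz))
      cands <- c(cands, tripletFilter(patt$xyz, cont$xyz, tolEff, seed = sd))
    if (length(cands) == 0) next
    # chain-order initialization: when the fragments are the same size the
    # index-wise correspondence is a natural extra alignment start
    if (length(m$resids) == length(q$resids))
      cands <- c(cands, list(list(p = seq_along(q$resids),
                                  c = seq_along(m$resids))))
    best <- NULL
    for (cd in cands) {
      # transform moving the MOTIF onto the QUERY
      fit <- try(if (mode == "motif_in_query")
        kabschSuperpose(m$xyz[cd$p, , drop = FALSE], q$xyz[cd$c, , drop = FALSE])
      else
        kabschSuperpose(m$xyz[cd$c, , drop = FALSE], q$xyz[cd$p, , drop = FALSE]),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      tr <- fit$transform
      need <- if (mode == "motif_in_query") length(m$resids) else length(q$resids)
      # counterpart cutoff: no atom pair farther than threshold * sqrt(n)
      # can belong to a correspondence whose RMSD passes the threshold
      pairCutoff <- max(2 * rmsdThreshold, rmsdThreshold * sqrt(need), 1.0)
      # iterative closest-pair refinement: the 3-point seed alignment is
      # crude, so re-superpose on the current correspondence and re-pair
      candBest <- NULL
      cutoffs <- c(2 * pairCutoff, 1.5 * pairCutoff, rep(pairCutoff, 4))
      for (icp in seq_along(cutoffs)) {
        mMoved <- applyTransform(m$xyz, tr)
        prs <- mutualNearestPairs(q$xyz, mMoved, cutoffs[icp])
        if (nrow(prs) < min(3, need)) break
        # only pairings at the standard cutoff can be accepted as matches
        if (cutoffs[icp] <= pairCutoff) {
          prsF <- prs[prs[, 3] <= pairCutoff, , drop = FALSE]
          anchor <- if (nrow(prsF) >= need) sqrt(mean(prsF[, 3]^2)) else Inf
          if (is.finite(anchor) &&
              (is.null(candBest) || anchor < candBest$anchor - 1e-12))
            candBest <- list(anchor = anchor, pairs = prsF, transform = tr)
        }
        rf <- try(kabschSuperpose(m$xyz[prs[, 2], , drop = FALSE],
                                  q$xyz[prs[, 1], , drop = FALSE]),
                  silent = TRUE)
        if (inherits(rf, "try-error")) break
        if (max(abs(rf$transform@rotation - tr@rotation)) < 1e-10 &&
            max(abs(rf$transform@translation - tr@translation)) < 1e-10 &&
            cutoffs[icp] <= pairCutoff) break
        tr <- rf$transform
      }
      if (is.null(candBest) || candBest$anchor > rmsdThreshold) next
      if (is.null(best) || candBest$anchor < best$anchor)
        best <- candBest
    }
    if (is.null(best)) next
    corr <- data.frame(query = q$resids[best$pairs[, 1]],
                       motif = m$resids[best$pairs[, 2]],
                       stringsAsFactors = FALSE)
    # refine on all backbone atoms of corresponding residues
    qa <- q$all; qa <- qa[qa$resid %in% corr$query & qa$atom %in% BACKBONE_ATOMS, ]
    ma <- m$all; ma <- ma[ma$resid %in% corr$motif & ma$atom %in% BACKBONE_ATOMS, ]
    qa$mres <- corr$motif[match(qa$resid, corr$query)]
    keyQ <- paste(qa$mres, qa$atom)
    keyM <- paste(ma$resid, ma$atom)
    common <- intersect(keyQ, keyM)
    refined <- best$anchor
    tr <- best$transform
    if (length(common) >= 3) {
      Qm <- as.matrix(qa[match(common, keyQ), c("x", "y", "z")])
      Mm <- as.matrix(ma[match(common, keyM), c("x", "y", "z")])
      rf <- try(kabschSuperpose(Mm, Qm), silent = TRUE)
      if (!inherits(rf, "try-error")) { refined <- rf$rmsd; tr <- rf$transform }
    }
    results[[length(results) + 1]] <- new("MatchResult",
      motifId = motif@id, transform = tr, correspondence = corr,
      anchorRMSD = best$anchor, refinedRMSD = refined)
  }
  ord <- order(vapply(results, function(r) r@refinedRMSD, 1.0))
  results[ord]
}
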