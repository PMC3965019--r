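# Optimal rigid superposition, backbone RMSD between motifs of equal
# composition, and complete-linkage clustering with medoid selection.

BACKBONE_ATOMS <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' index-corresponding points of P and Q (P is moved onto Q). Reflections
#' are rejected, so mirror images retain a positive RMSD.
#'
#' @param P,Q numeric N x 3 coordinate matrices, N >= 3
#' @return list with \code{transform} (a \linkS4class{RigidTransform}) and
#'   \code{rmsd}
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' R <- rotAxis(c(0, 0, 1), 37 * pi/180)
#' Q <- t(R %*% t(P)) + rep(c(1, 2, 3), each = 10)
#' kabschSuperpose(P, Q)$rmsd   # ~0
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3) stop("at least 3 points are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(crossprod(P0, Q0))
  if (sv$d[2] < 1e-8) stop("degenerate (collinear) point set")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  moved <- sweep(P %*% t(R), 2, -t)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = t),
       rmsd = rmsd)
}

applyTransform <- function(coords, tr) {
  sweep(coords %*% t(tr@rotation), 2, -tr@translation)
}

#' Composition key of a motif
#'
#' Motifs are comparable when they have the same type and the same number,
#' length and (cyclic) order of continuous chain fragments. The key is the
#' type plus the lexicographically smallest cyclic rotation of the
#' strand-length tuple.
#'
#' @param motif an \linkS4class{RNAMotif}
#' @return character key
#' @export
compositionKey <- function(motif) {
  lens <- vapply(strands(motif), length, 1L)
  k <- length(lens)
  rots <- vapply(seq_len(k), function(r) {
    paste(lens[c(seq(r, k), if (r > 1) seq(1, r - 1))], collapse = ",")
  }, "")
  paste0(motifType(motif), ":", min(rots))
}

motifBackboneCoords <- function(motif, rotation = 0, atomSet = BACKBONE_ATOMS) {
  # residue order: strands rotated cyclically, residues 5'->3' within strand
  st <- strands(motif)
  k <- length(st)
  ord <- if (rotation == 0) seq_len(k)
         else c(seq(rotation + 1, k), seq(1, rotation))
  resOrder <- unlist(st[ord])
  a <- atoms(motif)
  out <- lapply(atomSet, function(nm) {
    m <- atomCoords(a, resOrder, nm)
    cbind(m, seq_along(resOrder), match(nm, atomSet))
  })
  do.call(rbind, out)  # x y z residuePos atomPos (NA coords when absent)
}

#' Backbone RMSD between two motifs of equal composition
#'
#' Superposes position-wise corresponding backbone atoms (default P, O5',
#' C5', C4', C3', O3') after matching strands by cyclic rotation; atoms
#' missing on either side are dropped pairwise. The minimum over the valid
#' strand rotations is returned.
#'
#' @param motifA,motifB \linkS4class{RNAMotif} objects with equal
#'   \code{\link{compositionKey}}
#' @param atomSet backbone atom names used for the superposition
#' @return RMSD in Angstrom
#' @export
backboneRMSD <- function(motifA, motifB, atomSet = BACKBONE_ATOMS) {
  if (compositionKey(motifA) != compositionKey(motifB))
    stop("motifs differ in composition: ", compositionKey(motifA), " vs ",
         compositionKey(motifB))
  lensA <- vapply(strands(motifA), length, 1L)
  lensB <- vapply(strands(motifB), length, 1L)
  k <- length(lensA)
  A <- motifBackboneCoords(motifA, 0, atomSet)
  best <- Inf
  for (r in 0:(k - 1)) {
    if (!all(lensB[c(seq(r + 1, length.out = k - r), seq_len(r))] == lensA)) next
    B <- motifBackboneCoords(motifB, r, atomSet)
    ok <- stats::complete.cases(A[, 1:3]) & stats::complete.cases(B[, 1:3])
    if (sum(ok) < 3) next
    fit <- try(kabschSuperpose(A[ok, 1:3, drop = FALSE],
                               B[ok, 1:3, drop = FALSE]), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$rmsd < best) best <- fit$rmsd
  }
  if (!is.finite(best)) stop("no valid strand correspondence")
  best
}

#' Cluster motifs by backbone RMSD
#'
#' Motifs are grouped by composition key; within each group, agglomerative
#' complete-linkage clustering is cut at \code{threshold}, which guarantees
#' that every intra-cluster pairwise RMSD is below the threshold. The medoid
#' (member minimizing summed RMSD to the others, ties to the lowest input
#' index) represents each cluster.
#'
#' @param motifs list of \linkS4class{RNAMotif}
#' @param threshold RMSD cut (Angstrom), default 1.0
#' @param atomSet backbone atoms for RMSD
#' @return list of \linkS4class{MotifCluster}
#' @export
clusterMotifs <- function(motifs, threshold = 1.0, atomSet = BACKBONE_ATOMS) {
  if (length(motifs) == 0) return(list())
  keys <- vapply(motifs, compositionKey, "")
  out <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (length(idx) == 1) {
      out[[length(out) + 1]] <- new("MotifCluster", key = key,
                                    members = motifs[idx], medoid = 1L,
                                    rmsd = matrix(0, 1, 1))
      next
    }
    n <- length(idx)
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dm[i, j] <- dm[j, i] <- backboneRMSD(motifs[[idx[i]]], motifs[[idx[j]]],
                                           atomSet)
    }
    hc <- stats::hclust(stats::as.dist(dm), method = "complete")
    grp <- stats::cutree(hc, h = threshold * (1 - 1e-9))
    for (gk in sort(unique(grp))) {
      sel <- which(grp == gk)
      sub <- dm[sel, sel, drop = FALSE]
      sums <- rowSums(sub)
      med <- which(sums <= min(sums) + 1e-9)[1]  # ties: lowest input index
      out[[length(out) + 1]] <- new("MotifCluster", key = key,
                                    members = motifs[idx[sel]],
                                    medoid = as.integer(med), rmsd = sub)
    }
  }
  out
}
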