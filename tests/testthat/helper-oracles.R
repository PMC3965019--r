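# Independent oracles used across tests. Each is a deliberately naive
# implementation (brute force / exhaustive) kept separate from the package
# code paths it checks.

# brute-force maximum non-crossing, vertex-disjoint subset of pairs
bruteMaxNonCrossing <- function(pairIdx) {
  m <- nrow(pairIdx)
  if (m == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    used <- integer(0)
    for (r in sel) {
      if (pairIdx[r, 1] %in% used || pairIdx[r, 2] %in% used) { ok <- FALSE; break }
      used <- c(used, pairIdx[r, ])
    }
    if (ok && length(sel) > 1) {
      for (x in seq_along(sel)) {
        for (y in seq_along(sel)) {
          if (x == y) next
          i <- pairIdx[sel[x], 1]; j <- pairIdx[sel[x], 2]
          k <- pairIdx[sel[y], 1]; l <- pairIdx[sel[y], 2]
          if (i < k && k < j && j < l) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

# brute-force hydrogen bond scan under the package thresholds
bruteHBondScan <- function(model) {
  inv <- rnamotifs:::hbondInventory(model)
  a <- atoms(model)
  rid <- rnamotifs:::resIdOf(a$chain, a$resno, a$icode)
  hits <- list()
  for (d in inv$donors) for (ac in inv$acceptors) {
    if (d$resid == ac$resid) next
    D <- rnamotifs:::resAtomXYZ(a, rid, d$resid, d$atom)
    A <- rnamotifs:::resAtomXYZ(a, rid, ac$resid, ac$atom)
    if (sqrt(sum((D - A)^2)) > 3.9) next
    hpresent <- d$h[vapply(d$h, function(h)
      !is.null(rnamotifs:::resAtomXYZ(a, rid, d$resid, h)), logical(1))]
    ok <- length(hpresent) == 0
    for (h in hpresent) {
      H <- rnamotifs:::resAtomXYZ(a, rid, d$resid, h)
      if (sqrt(sum((H - A)^2)) <= 2.5 &&
          rnamotifs:::bondAngle(D, H, A) >= 90) { ok <- TRUE; break }
    }
    if (ok) hits[[length(hits) + 1]] <- paste(d$resid, d$atom, ac$resid, ac$atom)
  }
  sort(unlist(hits))
}

# numeric oracle: best RMSD over many random rotations (plus identity)
randomRotationRMSD <- function(P, Q, n = 1000, seed = 42) {
  set.seed(seed)
  best <- Inf
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  for (i in seq_len(n)) {
    M <- matrix(rnorm(9), 3, 3); qr0 <- qr(M)
    R <- qr.Q(qr0) %*% diag(sign(diag(qr.R(qr0))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    r <- sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
    best <- min(best, r)
  }
  best
}

# exhaustive-correspondence 3D search oracle: does any injective residue
# mapping pattern -> container superpose below the threshold?
bruteSearchMatch <- function(patternXYZ, containerXYZ, threshold) {
  np <- nrow(patternXYZ); nc <- nrow(containerXYZ)
  if (np > nc) return(FALSE)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (mp in perms(seq_len(nc), np)) {
    fit <- try(kabschSuperpose(patternXYZ, containerXYZ[mp, , drop = FALSE]),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$rmsd <= threshold) return(TRUE)
  }
  FALSE
}

# naive all-pairs contact scan between a motif and partner atoms
bruteMinDistances <- function(A, B) {
  dm <- rnamotifs:::crossDist(A, B)
  min(dm)
}

# brute-force clash count on small models (all pairs, same exclusions)
bruteClashCount <- function(model) {
  a <- atoms(model)
  if (is.null(a$resid)) a$resid <- rnamotifs:::resIdOf(a$chain, a$resno, a$icode)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  vr <- rnamotifs:::vdwRadius(a$element)
  adj <- rnamotifs:::bondGraph(xyz, a$element)
  da <- rnamotifs:::hbondDonorAcceptorFlags(a)
  n <- nrow(a); count <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (vr[i] + vr[j] - d < 0.4) next
    if (a$resid[i] == a$resid[j] || rnamotifs:::withinNBonds(adj, i, j, 3)) next
    if ((da$donor[i] && da$acceptor[j]) || (da$donor[j] && da$acceptor[i])) next
    if (a$hydrogen[i] && any(da$donor[adj[[i]]]) && da$acceptor[j]) next
    if (a$hydrogen[j] && any(da$donor[adj[[j]]]) && da$acceptor[i]) next
    count <- count + 1L
  }
  count
}

# cell edge along x such that the +a lattice copy sits at the target
# minimal heavy-atom distance from the model
cellEdgeForGap <- function(model, target = 3.5) {
  a <- atoms(model)
  Xh <- as.matrix(a[!a$hydrogen, c("x", "y", "z")])
  minAt <- function(s) min(rnamotifs:::crossDist(sweep(Xh, 2, c(-s, 0, 0)), Xh))
  ext <- max(Xh[, 1]) - min(Xh[, 1])
  uniroot(function(s) minAt(s) - target, c(2, ext + target + 20))$root
}

# fixed-column ATOM line builder (avoids hand-miscounted columns)
pdbLine <- function(serial, name, alt, resname, chain, resno, x, y, z,
                    occ = 1, elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          "ATOM", serial,
          if (nchar(name) >= 4) name else paste0(" ", formatC(name, width = -3)),
          alt, resname, chain, resno, x, y, z, occ, 0, elem)
}

# random nested/crossing pair sets for pseudoknot tests
randomPairSet <- function(n, npairs, seed) {
  set.seed(seed)
  out <- matrix(0L, 0, 2)
  tries <- 0
  while (nrow(out) < npairs && tries < 200) {
    tries <- tries + 1
    ij <- sort(sample.int(n, 2))
    if (ij[2] - ij[1] < 2) next
    out <- unique(rbind(out, ij))
  }
  out
}
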