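# Synthetic full-atom RNA structure generator with ground truth: A-form
# duplexes, stem-loops, cloverleafs, plus perturbation utilities. Loop and
# junction closure is geometric (arc interpolation with greedy chaining),
# not energy-based: sufficient for topology and geometry tests, and
# documented as non-physical.

WC_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

elementOfAtomName <- function(nm) substr(nm, 1, 1)

residueRows <- function(mat, chain, resno, resname, dropPhosphate = FALSE) {
  nm <- rownames(mat)
  if (dropPhosphate) {
    keep <- !nm %in% RNA_PHOSPHATE_ATOMS
    mat <- mat[keep, , drop = FALSE]; nm <- nm[keep]
  }
  data.frame(het = FALSE, atom = nm, alt = "", resname = resname,
             chain = chain, resno = as.integer(resno), icode = "",
             x = unname(mat[, 1]), y = unname(mat[, 2]), z = unname(mat[, 3]),
             occ = 1, element = elementOfAtomName(nm),
             hydrogen = grepl("^H", nm), row.names = NULL,
             stringsAsFactors = FALSE)
}

assembleModel <- function(rows, entryId, crystal = list()) {
  a <- do.call(rbind, rows)
  rownames(a) <- NULL
  new("StructureModel", entryId = entryId, atoms = a, crystal = crystal)
}

levelTransforms <- function(S, maxLevel) {
  out <- vector("list", maxLevel + 1)
  out[[1]] <- identityRT()
  for (i in seq_len(maxLevel)) out[[i + 1]] <- composeRT(out[[i]], S)
  out
}

# template selection: strand 1 or 2, base, wobble flag
pickTemplate <- function(tpl, strand, base, wobble = FALSE) {
  key <- if (wobble && base == "U") "Uw" else base
  if (strand == 1) tpl$res1[[key]] else tpl$res2[[key]]
}

checkComplementary <- function(b1, b2) {
  if (!paste0(b1, b2) %in% ALLOWED_PAIRS)
    stop("non-complementary pair ", b1, "-", b2,
         " (WC or G.U wobble required)")
  if (paste0(b1, b2) %in% c("GU", "UG")) "wobble" else "canonical_wc"
}

#' Synthetic A-form RNA duplex with ground truth
#'
#' Builds a full-atom idealized A-form double helix (twist 32.7 degrees,
#' rise 2.81 Angstrom per step) from embedded nucleotide templates. The two
#' strands are separate chains, so by the single-chain motif definition the
#' duplex contains base pairs but no motifs.
#'
#' @param nBp number of base pairs
#' @param sequence strand-1 sequence, 5' to 3' (length nBp)
#' @param sequence2 optional strand-2 sequence 5' to 3'; defaults to the
#'   Watson-Crick complement; G.U wobble pairs are allowed
#' @param chainIds chain identifiers, default A and B
#' @param entryId entry identifier
#' @param cell optional unit-cell lengths+angles (6-vector) to attach a P1
#'   crystal frame
#' @return list with elements model (\linkS4class{StructureModel}), pairs
#'   (ground-truth pair data.frame) and bricks (empty list: inter-chain
#'   pairs form no single-chain motif)
#' @export
makeHelix <- function(nBp, sequence, sequence2 = NULL,
                      chainIds = c("A", "B"), entryId = "helix",
                      cell = NULL) {
  s1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(s1) != nBp) stop("sequence length must equal nBp")
  if (is.null(sequence2)) {
    s2 <- rev(WC_COMPLEMENT[s1])
  } else {
    s2 <- strsplit(toupper(sequence2), "")[[1]]
    if (length(s2) != nBp) stop("sequence2 length must equal nBp")
  }
  klass <- character(nBp)
  for (i in seq_len(nBp)) klass[i] <- checkComplementary(s1[i], s2[nBp + 1 - i])
  tpl <- ntTemplates()
  lv <- levelTransforms(tpl$S, nBp - 1)
  rows <- list()
  for (i in seq_len(nBp)) {
    wob <- klass[i] == "wobble" && s1[i] == "U"
    m <- applyRT(pickTemplate(tpl, 1, s1[i], wob), lv[[i]]$R, lv[[i]]$t)
    rows[[length(rows) + 1]] <- residueRows(m, chainIds[1], i, s1[i])
  }
  for (j in seq_len(nBp)) {
    lvl <- nBp - j
    wob <- klass[nBp + 1 - j] == "wobble" && s2[j] == "U"
    m <- applyRT(pickTemplate(tpl, 2, s2[j], wob), lv[[lvl + 1]]$R, lv[[lvl + 1]]$t)
    rows[[length(rows) + 1]] <- residueRows(m, chainIds[2], j, s2[j])
  }
  crystal <- if (is.null(cell)) list() else
    list(cell = cell, spacegroup = "P 1",
         symops = list(cbind(diag(3), c(0, 0, 0))))
  model <- assembleModel(rows, entryId, crystal)
  pairs <- data.frame(
    resA = paste0(chainIds[1], ":", seq_len(nBp)),
    resB = paste0(chainIds[2], ":", nBp + 1 - seq_len(nBp)),
    klass = klass, stringsAsFactors = FALSE)
  list(model = model, pairs = pairs, bricks = list())
}

# ---- arc linker ------------------------------------------------------------

arcLength2Angle <- function(ratio) {
  # solve L/d = theta / (2 sin(theta/2)) for theta in (0, 2pi)
  if (ratio <= 1 + 1e-9) return(1e-6)
  f <- function(th) th / (2 * sin(th/2)) - ratio
  stats::uniroot(f, c(1e-6, 2 * pi - 1e-3))$root
}

# Solve a fixed-segment-length polyline from start to end (FABRIK inverse
# kinematics); joints initialized along a bulged circular arc. Optional
# context atoms repel interior joints so the backbone path keeps clear of
# already-placed residues.
fabrikChain <- function(start, end, segLens, bulgeDir, iters = 60,
                        context = NULL, clearance = 5.0) {
  nj <- length(segLens) + 1
  L <- sum(segLens)
  d <- vnorm(end - start)
  if (d > 0.995 * L)
    stop("linker cannot span ", round(d, 1), " A (reach ", round(L, 1), " A)")
  u <- unitv(end - start)
  b <- bulgeDir - u * sum(bulgeDir * u)
  if (vnorm(b) < 1e-6) stop("degenerate bulge direction")
  b <- unitv(b)
  theta <- arcLength2Angle(L / d)
  R <- L / theta
  ctr <- start + 0.5 * (end - start) - sqrt(max(R^2 - (d/2)^2, 0)) * b
  a0 <- atan2(sum((start - ctr) * b), sum((start - ctr) * u))
  a1 <- atan2(sum((end - ctr) * b), sum((end - ctr) * u))
  while (a1 <= a0) a1 <- a1 + 2 * pi
  cum <- c(0, cumsum(segLens)) / L
  joints <- t(vapply(cum, function(t)
    ctr + R * (cos(a0 + t * (a1 - a0)) * u + sin(a0 + t * (a1 - a0)) * b),
    numeric(3)))
  for (it in seq_len(iters)) {
    if (!is.null(context) && nrow(context) > 0 && it <= iters - 2) {
      for (k in seq(2, nj - 1)) {        # repel interior joints
        dv <- crossDist(matrix(joints[k, ], 1), context)
        dmin <- min(dv)
        if (dmin < clearance) {
          away <- joints[k, ] - context[which.min(dv), ]
          if (vnorm(away) > 1e-9)
            joints[k, ] <- joints[k, ] +
              0.5 * (clearance - dmin) * unitv(away)
        }
      }
    }
    joints[nj, ] <- end                       # backward
    for (k in seq(nj - 1, 1))
      joints[k, ] <- joints[k + 1, ] +
        segLens[k] * unitv(joints[k, ] - joints[k + 1, ])
    joints[1, ] <- start                      # forward
    for (k in seq(2, nj))
      joints[k, ] <- joints[k - 1, ] +
        segLens[k - 1] * unitv(joints[k, ] - joints[k - 1, ])
    if (it > iters - 2 && vnorm(joints[nj, ] - end) < 1e-9) break
  }
  list(joints = joints, center = ctr)
}

# place n rigid nucleotide templates between anchorO3 and anchorP (or along
# a straight ray when anchorP is NULL): P and O3' joints from inverse
# kinematics, base oriented away from the local bend center
buildArcChain <- function(tpl, bases, anchorO3, anchorP = NULL,
                          bulgeDir = c(0, 0, 1), rayDir = NULL,
                          aimOut = NULL, context = NULL,
                          relaxIters = 10, initJoints = NULL,
                          returnJoints = FALSE, fixedSpins = NULL) {
  n <- length(bases)
  res <- tpl$res1[bases]
  rho <- vnorm(res[[1]]["O3'", ] - res[[1]]["P", ])
  link <- 1.60
  if (!is.null(context) && nrow(context) > 0) {
    # only nearby context matters for sterics
    ref <- rbind(anchorO3, if (!is.null(anchorP)) anchorP)
    lo <- apply(ref, 2, min) - (n * (rho + link))/2 - 8
    hi <- apply(ref, 2, max) + (n * (rho + link))/2 + 8
    keep <- context[, 1] >= lo[1] & context[, 1] <= hi[1] &
            context[, 2] >= lo[2] & context[, 2] <= hi[2] &
            context[, 3] >= lo[3] & context[, 3] <= hi[3]
    context <- context[keep, , drop = FALSE]
  }
  if (!is.null(initJoints)) {
    joints <- initJoints
    ctr <- NULL
  } else if (is.null(anchorP)) {
    u <- unitv(rayDir)
    joints <- matrix(NA_real_, 2 * n + 1, 3)
    joints[1, ] <- anchorO3
    pos <- anchorO3
    for (k in seq_len(n)) {
      pos <- pos + link * u
      joints[2 * k, ] <- pos
      pos <- pos + rho * u
      joints[2 * k + 1, ] <- pos
    }
    ctr <- NULL
  } else {
    segLens <- c(rbind(rep(link, n), rep(rho, n)), link)
    fk <- fabrikChain(anchorO3, anchorP, segLens, bulgeDir, context = context)
    joints <- fk$joints
    ctr <- fk$center
  }
  # base placement per residue: align P->O3' with the joint axis, then spin
  # about that axis to minimize steric overlap with the surroundings.
  # default base aim: arc-plane normal, so loop bases sit side by side in
  # near-parallel planes (stack-like) instead of fanning into each other
  outDir <- if (!is.null(aimOut)) aimOut
    else if (is.null(ctr)) bulgeDir
    else unitv(cross3(joints[nrow(joints), ] - joints[1, ],
                      joints[2 * max(1, round(n/2)), ] - joints[1, ]))
  baseRot <- vector("list", n)
  computeFrame <- function(k) {
    pk <- joints[2 * k, ]; ok <- joints[2 * k + 1, ]
    w <- unitv(ok - pk)
    tmpl <- res[[k]]
    vPO <- tmpl["O3'", ] - tmpl["P", ]
    ax <- cross3(unitv(vPO), w)
    R1 <- if (vnorm(ax) < 1e-8) diag(3) else
      rotAxis(ax, acos(max(-1, min(1, sum(unitv(vPO) * w)))))
    baseSel <- rownames(tmpl) %in% BASE_ATOM_NAMES
    ctb1 <- as.vector(R1 %*% (colMeans(tmpl[baseSel, , drop = FALSE]) -
                                tmpl["P", ]))
    p1 <- ctb1 - w * sum(ctb1 * w)
    p2 <- outDir - w * sum(outDir * w)
    R2 <- diag(3)
    if (vnorm(p1) > 1e-8 && vnorm(p2) > 1e-8) {
      angle <- atan2(sum(cross3(unitv(p1), unitv(p2)) * w),
                     sum(unitv(p1) * unitv(p2)))
      R2 <- rotAxis(w, angle)
    }
    list(pk = pk, w = w, R21 = R2 %*% R1)
  }
  for (k in seq_len(n)) baseRot[[k]] <- computeFrame(k)
  placeAt <- function(k, spin) {
    br <- baseRot[[k]]
    Rk <- rotAxis(br$w, spin * pi/180) %*% br$R21
    sweep((sweep(res[[k]], 2, res[[k]]["P", ])) %*% t(Rk), 2, -br$pk)
  }
  # bond-count tables across an O3'-P linkage: atoms x (O3'-side residue)
  # and y (P-side residue) are within 3 covalent bonds iff
  # o3side[x] + pside[y] <= 2
  o3side <- c("O3'" = 0, "C3'" = 1, "C2'" = 2, "C4'" = 2)
  pside <- c("P" = 0, "OP1" = 1, "OP2" = 1, "O5'" = 1, "C5'" = 2)
  scoreCtxt <- function(k, others) {
    ctxt <- context
    if (length(others) > 0) ctxt <- rbind(ctxt, do.call(rbind, others))
    if (is.null(ctxt) || nrow(ctxt) == 0) return(NULL)
    # flag context atoms belonging to the covalently adjacent residues
    # (around the previous O3' joint and the next P joint); bonded pairs
    # across the linkage are exempted pairwise in the steric scoring
    prevJ <- joints[2 * k - 1, ]
    nextJ <- if (2 * k + 2 <= nrow(joints)) joints[2 * k + 2, ] else
      c(1e9, 1e9, 1e9)
    dPrev <- crossDist(ctxt, matrix(prevJ, 1))[, 1]
    dNext <- crossDist(ctxt, matrix(nextJ, 1))[, 1]
    attr(ctxt, "nearPrev") <- dPrev < 3.2 & rownames(ctxt) %in% names(o3side)
    attr(ctxt, "nearNext") <- dNext < 3.2 & rownames(ctxt) %in% names(pside)
    ctxt
  }
  exemptPairs <- function(tmplNames, ctxt) {
    # TRUE where (template atom, context atom) are bonded chemistry
    ex <- matrix(FALSE, length(tmplNames), nrow(ctxt))
    np <- attr(ctxt, "nearPrev"); nn <- attr(ctxt, "nearNext")
    if (any(np)) {
      tb <- pside[tmplNames]
      cb <- o3side[rownames(ctxt)]
      ok <- which(np & !is.na(cb))
      for (j in ok) ex[!is.na(tb) & (tb + cb[j]) <= 2, j] <- TRUE
    }
    if (any(nn)) {
      tb <- o3side[tmplNames]
      cb <- pside[rownames(ctxt)]
      ok <- which(nn & !is.na(cb))
      for (j in ok) ex[!is.na(tb) & (tb + cb[j]) <= 2, j] <- TRUE
    }
    ex
  }
  bestSpin <- function(k, ctxt) {
    vrT <- vdwRadius(substr(rownames(res[[k]]), 1, 1))
    vrC <- if (!is.null(ctxt) && nrow(ctxt) > 0)
      vdwRadius(substr(rownames(ctxt), 1, 1)) else numeric(0)
    ex <- if (length(vrC) > 0) exemptPairs(rownames(res[[k]]), ctxt) else NULL
    best <- 0; bestScore <- Inf
    for (spin in seq(0, 345, by = 15)) {
      placed <- placeAt(k, spin)
      score <- spin * 1e-9
      if (length(vrC) > 0) {
        dm <- crossDist(placed, ctxt)
        dm[ex] <- 99
        vsum <- outer(vrT, vrC, "+")
        # primary: overlaps that count as clashes; secondary: soft margin
        score <- score + 100 * sum(pmax(0, vsum - 0.38 - dm)^2) +
          sum(pmax(0, vsum + 0.2 - dm)^2)
      }
      if (score < bestScore) { bestScore <- score; best <- spin }
    }
    best
  }
  segLens <- c(rbind(rep(link, n), rep(rho, n)), link)
  recomputeFrames <- function() {
    for (k in seq_len(n)) baseRot[[k]] <<- computeFrame(k)
  }

  placeAll <- function() {
    spins <- numeric(n)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      spins[k] <- bestSpin(k, scoreCtxt(k, out[seq_len(k - 1)]))
      out[[k]] <- placeAt(k, spins[k])
    }
    for (k in seq_len(n)) {
      spins[k] <- bestSpin(k, scoreCtxt(k, out[-k]))
      out[[k]] <- placeAt(k, spins[k])
    }
    attr(out, "spins") <- spins
    out
  }
  if (!is.null(fixedSpins)) {
    out <- lapply(seq_len(n), function(k) placeAt(k, fixedSpins[k]))
    attr(out, "spins") <- fixedSpins
    if (returnJoints) { attr(out, "joints") <- joints; attr(out, "outDir") <- outDir }
    return(out)
  }
  clashForces <- function(out) {
    # overlap-resolving translation force per residue (heavy atoms)
    forces <- matrix(0, n, 3)
    total <- 0
    for (k in seq_len(n)) {
      placed <- out[[k]]
      heavy <- !grepl("^H", rownames(placed))
      ctxt <- scoreCtxt(k, out[-k])
      if (is.null(ctxt) || nrow(ctxt) == 0) next
      hm <- placed[heavy, , drop = FALSE]
      vrT <- vdwRadius(substr(rownames(hm), 1, 1))
      vrC <- vdwRadius(substr(rownames(ctxt), 1, 1))
      dm <- crossDist(hm, ctxt)
      dm[exemptPairs(rownames(hm), ctxt)] <- 99
      ov <- outer(vrT, vrC, "+") - 0.3 - dm
      idx <- which(ov > 0, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        dir <- hm[i, ] - ctxt[j, ]
        if (vnorm(dir) < 1e-9) next
        forces[k, ] <- forces[k, ] + ov[i, j] * unitv(dir)
        total <- total + ov[i, j]
      }
    }
    list(forces = forces, total = total)
  }
  out <- placeAll()
  if (!is.null(anchorP)) {
    best <- list(out = out, total = clashForces(out)$total,
                 joints = joints)
    # try the opposite arc-plane normal as an alternative start
    if (is.null(aimOut)) {
      outDir <- -outDir
      recomputeFrames()
      alt <- placeAll()
      altT <- clashForces(alt)$total
      if (altT < best$total) {
        best <- list(out = alt, total = altT, joints = joints)
        out <- alt
      } else {
        outDir <- -outDir
        recomputeFrames()
        out <- placeAll()
      }
    }
    relax <- 0
    while (best$total > 1e-6 && relax < relaxIters) {
      relax <- relax + 1
      cf <- clashForces(out)
      for (k in seq_len(n)) {
        joints[2 * k, ] <- joints[2 * k, ] + 0.3 * cf$forces[k, ]
        joints[2 * k + 1, ] <- joints[2 * k + 1, ] + 0.3 * cf$forces[k, ]
      }
      # restore exact segment lengths and anchors
      nj <- nrow(joints)
      for (pass in 1:25) {
        joints[nj, ] <- anchorP
        for (q in seq(nj - 1, 1))
          joints[q, ] <- joints[q + 1, ] +
            segLens[q] * unitv(joints[q, ] - joints[q + 1, ])
        joints[1, ] <- anchorO3
        for (q in seq(2, nj))
          joints[q, ] <- joints[q - 1, ] +
            segLens[q - 1] * unitv(joints[q, ] - joints[q - 1, ])
        if (vnorm(joints[nj, ] - anchorP) < 1e-9) break
      }
      recomputeFrames()
      out <- placeAll()
      tot <- clashForces(out)$total
      if (tot < best$total)
        best <- list(out = out, total = tot, joints = joints)
    }
    out <- best$out
    joints <- best$joints
    attr(out, "clashTotal") <- best$total
  }
  if (!is.null(anchorP)) {
    prev <- anchorO3
    for (k in seq_len(n)) {
      dl <- vnorm(out[[k]]["P", ] - prev)
      if (dl > 1.95 || dl < 1.2)
        stop("linker closure failed (link ", round(dl, 2), " A)")
      prev <- out[[k]]["O3'", ]
    }
    if (vnorm(anchorP - prev) > 1.95)
      stop("linker closure failed at the final link")
  }
  if (returnJoints) {
    attr(out, "joints") <- joints
    attr(out, "outDir") <- outDir
  }
  out
}

# Place a hairpin cap of a given length at a stem top. The stem top frame
# equals the template frame transformed by topRT (level transform, plus any
# arm placement); frozen cap joints exist for loop lengths 3..8, longer
# loops fall back to runtime inverse kinematics.
placeLoopCap <- function(tpl, loopBases, topRT, context, fallbackP,
                         extraRT = NULL) {
  n <- length(loopBases)
  fullRT <- if (is.null(extraRT)) topRT else composeRT(topRT, extraRT)
  anchorO3 <- applyRT(matrix(tpl$res1$A["O3'", ], 1), fullRT$R, fullRT$t)[1, ]
  cap <- FROZEN_CAPS[[as.character(n)]]
  if (is.null(cap)) {
    return(buildArcChain(tpl, loopBases, anchorO3, fallbackP,
                         bulgeDir = as.vector(fullRT$R %*% tpl$screw$axdir),
                         context = context))
  }
  joints <- applyRT(cap$joints, fullRT$R, fullRT$t)
  aim <- as.vector(fullRT$R %*% cap$outDir)
  if (!is.null(cap$spins) && all(loopBases == "A")) {
    # exact reproduction of the offline-solved cap
    return(buildArcChain(tpl, loopBases, anchorO3, fallbackP, aimOut = aim,
                         context = context, initJoints = joints,
                         fixedSpins = cap$spins))
  }
  buildArcChain(tpl, loopBases, anchorO3, fallbackP, aimOut = aim,
                context = context, relaxIters = 3, initJoints = joints)
}

# ---- stem-loop -------------------------------------------------------------

defaultStemSeq <- function(n) {
  paste(rep(c("G", "C"), length.out = n), collapse = "")
}

#' Synthetic stem-loop (hairpin) with ground truth
#'
#' A single chain folding back on itself: an A-form stem of
#' \code{stemBp} pairs capped by a geometrically closed loop. Ground truth:
#' one stem motif (when stemBp >= 2) and one terminal-loop motif sharing
#' the closing pair.
#'
#' @param stemBp stem length in base pairs
#' @param loopSeq loop sequence (>= 3 nt)
#' @param stemSeq optional 5' stem strand sequence (default alternating GC)
#' @param entryId entry identifier
#' @param chain chain id
#' @return list with model, pairs, bricks (ground truth)
#' @examples
#' fx <- makeStemLoop(4, "GAAA")
#' vapply(decomposeMotifs(fx$model), motifClassLabel, "")
#' @export
makeStemLoop <- function(stemBp, loopSeq, stemSeq = NULL, entryId = "stemloop",
                         chain = "A") {
  loop <- strsplit(toupper(loopSeq), "")[[1]]
  if (length(loop) < 3) stop("loop must have at least 3 residues")
  if (!all(loop %in% names(WC_COMPLEMENT))) stop("invalid loop sequence")
  s <- stemBp
  if (is.null(stemSeq)) stemSeq <- defaultStemSeq(s)
  st <- strsplit(toupper(stemSeq), "")[[1]]
  if (length(st) != s) stop("stemSeq length must equal stemBp")
  tpl <- ntTemplates()
  lv <- levelTransforms(tpl$S, max(s - 1, 0))
  l <- length(loop)
  comp <- WC_COMPLEMENT[st]
  # stem strands first (their atoms are the clash context for the loop)
  mats1 <- lapply(seq_len(s), function(i)
    applyRT(tpl$res1[[st[i]]], lv[[i]]$R, lv[[i]]$t))
  mats2 <- lapply(seq_len(s), function(j)
    applyRT(tpl$res2[[comp[s + 1 - j]]], lv[[s - j + 1]]$R, lv[[s - j + 1]]$t))
  stemAtoms <- do.call(rbind, c(mats1, mats2))
  stemAtoms <- stemAtoms[!grepl("^H", rownames(stemAtoms)), , drop = FALSE]
  o3 <- mats1[[s]]["O3'", ]
  loopMats <- placeLoopCap(tpl, loop, powerRT(tpl$S, s - 1), stemAtoms,
                           fallbackP = mats2[[1]]["P", ])
  rows <- list()
  for (i in seq_len(s)) rows[[i]] <- residueRows(mats1[[i]], chain, i, st[i])
  for (k in seq_len(l))
    rows[[s + k]] <- residueRows(loopMats[[k]], chain, s + k, loop[k])
  for (j in seq_len(s))
    rows[[s + l + j]] <- residueRows(mats2[[j]], chain, s + l + j,
                                     comp[s + 1 - j])
  model <- assembleModel(rows, entryId)
  n <- 2 * s + l
  rid <- function(i) paste0(chain, ":", i)
  pairs <- data.frame(resA = rid(seq_len(s)), resB = rid(n + 1 - seq_len(s)),
                      klass = "canonical_wc", stringsAsFactors = FALSE)
  bricks <- list()
  if (s >= 2)
    bricks[[length(bricks) + 1]] <- list(
      type = "stem", label = "stem",
      strands = list(rid(1:s), rid((s + l + 1):n)))
  bricks[[length(bricks) + 1]] <- list(
    type = "loop", label = "terminal loop",
    strands = list(rid(s:(s + l + 1))))
  list(model = model, pairs = pairs, bricks = bricks)
}

# ---- cloverleaf ------------------------------------------------------------

#' Synthetic cloverleaf (tRNA-like) with ground truth
#'
#' Four A-form stems radiating from a four-way junction: an acceptor-like
#' stem whose outer end carries a single-stranded 3' tail, and three
#' hairpin arms. Junction linkers are closed geometrically. Stems use G/C
#' sequences and single-stranded parts use A, so the ground-truth pairing
#' is unambiguous.
#'
#' @param stemLens lengths (bp) of the four stems (acceptor first)
#' @param loopLens lengths of the three hairpin loops
#' @param linkLen unpaired residues in each junction linker
#' @param tailLen 3' tail length
#' @param r0 radial distance of stem inner ends from the junction center
#' @param entryId entry identifier
#' @return list with model, pairs, bricks (ground truth)
#' @export
makeCloverleaf <- function(stemLens = c(4, 3, 3, 3), loopLens = c(5, 5, 5),
                           linkLen = 8, tailLen = 3, r0 = 20,
                           entryId = "cloverleaf") {
  stopifnot(length(stemLens) == 4, length(loopLens) == 3, linkLen >= 1)
  tpl <- ntTemplates()
  sp <- tpl$screw
  chain <- "A"
  angles <- c(180, 90, 0, 270) * pi / 180
  armRT <- function(theta) {
    d <- c(cos(theta), sin(theta), 0)
    ax <- cross3(sp$axdir, d)
    R <- if (vnorm(ax) < 1e-8) {
      if (sum(sp$axdir * d) > 0) diag(3) else rotAxis(c(1, 0, 0) - sp$axdir *
        sum(sp$axdir * c(1, 0, 0)), pi)
    } else rotAxis(ax, acos(max(-1, min(1, sum(sp$axdir * d)))))
    # the axis point at the level-0 pair goes to radius r0 along d
    list(R = R, t = r0 * d - as.vector(R %*% tpl$axisAnchor))
  }
  arts <- lapply(angles, armRT)
  maxLevel <- max(stemLens) - 1
  lv <- levelTransforms(tpl$S, maxLevel)
  placeRes <- function(strand, base, level, art, wobble = FALSE) {
    m <- applyRT(pickTemplate(tpl, strand, base, wobble),
                 lv[[level + 1]]$R, lv[[level + 1]]$t)
    applyRT(m, art$R, art$t)
  }
  stemSeqs <- lapply(stemLens, defaultStemSeq)
  stemSeqs <- lapply(stemSeqs, function(x) strsplit(x, "")[[1]])
  pairRows <- list(); brickList <- list()
  rid <- function(i) paste0(chain, ":", i)
  heavyOf <- function(m) m[!grepl("^H", rownames(m)), , drop = FALSE]

  a <- stemLens[1]
  accSeq <- stemSeqs[[1]]           # res1 strand (3' side), levels 0..a-1
  acc5 <- WC_COMPLEMENT[rev(accSeq)]  # 5' strand, descending levels a-1..0

  # --- phase 1: all stem residues (fixed helix placements) ---
  acc5Mats <- lapply(seq_len(a), function(r)
    placeRes(2, acc5[r], a - r, arts[[1]]))
  acc3Mats <- lapply(seq_len(a), function(i)
    placeRes(1, accSeq[i], i - 1, arts[[1]]))
  armMats <- list()
  for (k in 2:4) {
    sk <- stemLens[k]
    seqk <- stemSeqs[[k]]; compk <- WC_COMPLEMENT[seqk]
    armMats[[k]] <- list(
      s1 = lapply(seq_len(sk), function(i) placeRes(1, seqk[i], i - 1, arts[[k]])),
      s2 = lapply(seq_len(sk), function(j)
        placeRes(2, compk[sk + 1 - j], sk - j, arts[[k]])))
  }
  stemContext <- do.call(rbind, lapply(
    c(acc5Mats, acc3Mats, unlist(lapply(armMats[2:4], function(x)
      c(x$s1, x$s2)), recursive = FALSE)), heavyOf))

  # --- phase 2: hairpin loop caps ---
  capMats <- list()
  ctx <- stemContext
  for (k in 2:4) {
    sk <- stemLens[k]; lk <- loopLens[k - 1]
    pTop <- armMats[[k]]$s2[[1]]["P", ]
    capMats[[k]] <- placeLoopCap(tpl, rep("A", lk), powerRT(tpl$S, sk - 1),
                                 ctx, pTop, extraRT = arts[[k]])
    ctx <- rbind(ctx, do.call(rbind, lapply(capMats[[k]], heavyOf)))
  }

  # --- phase 3: junction linkers (chain order) + tail ---
  linkMats <- list()
  prevO3 <- acc5Mats[[a]]["O3'", ]
  frozenJct <- r0 == 20 && linkLen == 8 && exists("FROZEN_JUNCTION")
  for (k in 2:4) {
    firstP <- armMats[[k]]$s1[[1]]["P", ]
    linkMats[[k]] <- if (frozenJct) {
      fj <- FROZEN_JUNCTION[[k - 1]]
      buildArcChain(tpl, rep("A", linkLen), prevO3, firstP,
                    aimOut = fj$outDir, initJoints = fj$joints,
                    fixedSpins = fj$spins, context = ctx)
    } else buildArcChain(tpl, rep("A", linkLen), prevO3, firstP,
                         bulgeDir = c(0, 0, -1), context = ctx)
    ctx <- rbind(ctx, do.call(rbind, lapply(linkMats[[k]], heavyOf)))
    prevO3 <- armMats[[k]]$s2[[stemLens[k]]]["O3'", ]
  }
  linkMats[[5]] <- if (frozenJct) {
    fj <- FROZEN_JUNCTION[[4]]
    buildArcChain(tpl, rep("A", linkLen), prevO3, acc3Mats[[1]]["P", ],
                  aimOut = fj$outDir, initJoints = fj$joints,
                  fixedSpins = fj$spins, context = ctx)
  } else buildArcChain(tpl, rep("A", linkLen), prevO3, acc3Mats[[1]]["P", ],
                       bulgeDir = c(0, 0, -1), context = ctx)
  ctx <- rbind(ctx, do.call(rbind, lapply(linkMats[[5]], heavyOf)))
  tailMats <- if (tailLen > 0) {
    buildArcChain(tpl, rep("A", tailLen), acc3Mats[[a]]["O3'", ], NULL,
                  bulgeDir = c(0, 0, 1),
                  rayDir = c(cos(angles[1]), sin(angles[1]), 0),
                  context = ctx)
  } else list()

  # --- assemble rows in chain order ---
  rows <- list(); pos <- 0
  addRes <- function(mat, base) {
    pos <<- pos + 1
    rows[[pos]] <<- residueRows(mat, chain, pos, base)
  }
  for (r in seq_len(a)) addRes(acc5Mats[[r]], acc5[r])
  acc5Pos <- seq_len(a)
  armPos <- list()
  for (k in 2:4) {
    sk <- stemLens[k]; lk <- loopLens[k - 1]
    seqk <- stemSeqs[[k]]; compk <- WC_COMPLEMENT[seqk]
    for (m in linkMats[[k]]) addRes(m, "A")
    p1 <- pos + 1
    for (i in seq_len(sk)) addRes(armMats[[k]]$s1[[i]], seqk[i])
    for (m in capMats[[k]]) addRes(m, "A")
    for (j in seq_len(sk)) addRes(armMats[[k]]$s2[[j]], compk[sk + 1 - j])
    armPos[[k]] <- list(s1 = seq(p1, p1 + sk - 1),
                        loop = seq(p1 + sk, p1 + sk + lk - 1),
                        s2 = seq(p1 + sk + lk, p1 + 2 * sk + lk - 1))
    for (i in seq_len(sk))
      pairRows[[length(pairRows) + 1]] <- data.frame(
        resA = rid(armPos[[k]]$s1[i]),
        resB = rid(armPos[[k]]$s2[sk + 1 - i]),
        klass = "canonical_wc", stringsAsFactors = FALSE)
  }
  for (m in linkMats[[5]]) addRes(m, "A")
  p3 <- pos + 1
  for (i in seq_len(a)) addRes(acc3Mats[[i]], accSeq[i])
  acc3Pos <- seq(p3, p3 + a - 1)
  for (r in seq_len(a))
    pairRows[[length(pairRows) + 1]] <- data.frame(
      resA = rid(acc5Pos[r]), resB = rid(p3 + a - r),
      klass = "canonical_wc", stringsAsFactors = FALSE)
  for (m in tailMats) addRes(m, "A")
  n <- pos
  model <- assembleModel(rows, entryId)
  pairs <- do.call(rbind, pairRows)

  # ground-truth bricks
  brickList[[1]] <- list(type = "stem", label = "stem",
                         strands = list(rid(acc5Pos), rid(acc3Pos)))
  for (k in 2:4) {
    ap <- armPos[[k]]
    brickList[[length(brickList) + 1]] <- list(
      type = "stem", label = "stem",
      strands = list(rid(ap$s1), rid(ap$s2)))
    brickList[[length(brickList) + 1]] <- list(
      type = "loop", label = "terminal loop",
      strands = list(rid(seq(max(ap$s1), min(ap$s2)))))
  }
  jstr <- list(
    rid(seq(a, armPos[[2]]$s1[1])),
    rid(seq(max(armPos[[2]]$s2), armPos[[3]]$s1[1])),
    rid(seq(max(armPos[[3]]$s2), armPos[[4]]$s1[1])),
    rid(seq(max(armPos[[4]]$s2), p3)))
  brickList[[length(brickList) + 1]] <- list(
    type = "loop", label = "4wj", strands = jstr)
  if (tailLen > 0)
    brickList[[length(brickList) + 1]] <- list(
      type = "terminal", label = "terminal fragment",
      strands = list(rid(seq(p3 + a - 1, n))))
  list(model = model, pairs = pairs, bricks = brickList)
}

# ---- perturbation utilities ------------------------------------------------

#' Gaussian coordinate perturbation
#'
#' Adds i.i.d. Gaussian displacement (sd = sigma) to every atom.
#'
#' @param model a \linkS4class{StructureModel}
#' @param sigma displacement standard deviation (Angstrom)
#' @param seed RNG seed (the caller's RNG state is preserved)
#' @return perturbed StructureModel
#' @export
perturbModel <- function(model, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  a <- atoms(model)
  if (sigma > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(3 * nrow(a), sd = sigma),
                                   ncol = 3))
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
  }
  new("StructureModel", entryId = model@entryId, atoms = a,
      crystal = model@crystal)
}

#' Gaussian perturbation of a motif's own coordinates
#'
#' Displaces every atom of the motif independently (sd = sigma), leaving
#' topology and residue bookkeeping untouched. Useful for geometric
#' robustness tests where chain connectivity of a full model must be
#' preserved.
#'
#' @param motif an \linkS4class{RNAMotif}
#' @param sigma displacement standard deviation (Angstrom)
#' @param seed RNG seed
#' @return perturbed RNAMotif
#' @export
perturbMotif <- function(motif, sigma, seed = 1) {
  a <- atoms(motif)
  if (sigma > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(3 * nrow(a), sd = sigma),
                                   ncol = 3))
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
  }
  new("RNAMotif", id = motif@id, type = motif@type, strands = motif@strands,
      closingPairs = motif@closingPairs, residues = motif@residues,
      atoms = a)
}

randomRotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr0 <- qr(M)
  Q <- qr.Q(qr0)
  Q <- Q %*% diag(sign(diag(qr.R(qr0))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Random rigid copy of a model
#'
#' Applies a seeded random proper rotation and translation.
#'
#' @param model a \linkS4class{StructureModel}
#' @param seed RNG seed
#' @param maxShift translation range (uniform in [-maxShift, maxShift])
#' @return transformed StructureModel
#' @export
rigidCopy <- function(model, seed = 1, maxShift = 15) {
  rt <- withSeed(seed, list(R = randomRotation(),
                            t = stats::runif(3, -maxShift, maxShift)))
  transformModel(model, rt$R, rt$t)
}

transformModel <- function(model, R, t) {
  a <- atoms(model)
  xyz <- applyRT(as.matrix(a[, c("x", "y", "z")]), R, t)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("StructureModel", entryId = model@entryId, atoms = a,
      crystal = model@crystal)
}

#' Dock a second model near the first at a target minimal distance
#'
#' Translates \code{other} along the line between the two centroids until
#' the minimal heavy-atom distance equals \code{distance} (bisection).
#'
#' @param model,other StructureModels
#' @param distance target minimal heavy-atom distance (Angstrom)
#' @return translated copy of \code{other}
#' @export
dockModels <- function(model, other, distance = 3.5) {
  A <- atoms(model); B <- atoms(other)
  Ah <- as.matrix(A[!A$hydrogen, c("x", "y", "z")])
  Bh <- as.matrix(B[!B$hydrogen, c("x", "y", "z")])
  dir <- unitv(colMeans(Bh) - colMeans(Ah))
  d0 <- vnorm(colMeans(Bh) - colMeans(Ah))
  minDistAt <- function(s) min(crossDist(Ah, sweep(Bh, 2, -s * dir)))
  lo <- -d0                        # centroids coincide: interpenetrating
  hi <- 200
  while (minDistAt(lo) > distance && lo > -d0 - 50) lo <- lo - 10
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (minDistAt(mid) < distance) lo <- mid else hi <- mid
  }
  transformModel(other, diag(3), ((lo + hi) / 2) * dir)
}

#' Append a single hetero atom (water oxygen, ion, probe atom)
#'
#' @param model a \linkS4class{StructureModel}
#' @param resname residue name (e.g. HOH, MG)
#' @param atom atom name
#' @param element element symbol
#' @param xyz length-3 coordinates
#' @param chain chain id for the added residue
#' @param resno residue number (default: one past the chain maximum)
#' @return extended StructureModel
#' @export
addHetAtom <- function(model, resname, atom, element, xyz, chain = "Z",
                       resno = NULL) {
  a <- atoms(model)
  if (is.null(resno)) {
    prev <- a$resno[a$chain == chain]
    resno <- if (length(prev) == 0) 1L else max(prev) + 1L
  }
  row <- data.frame(het = TRUE, atom = atom, alt = "", resname = resname,
                    chain = chain, resno = as.integer(resno), icode = "",
                    x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
                    element = element, hydrogen = element %in% c("H", "D"),
                    stringsAsFactors = FALSE)
  new("StructureModel", entryId = model@entryId, atoms = rbind(a, row),
      crystal = model@crystal)
}
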