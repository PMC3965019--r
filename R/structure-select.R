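# Chain eligibility and symmetry-mate expansion.

O3P_COVALENT_CUTOFF <- 2.0  # Angstrom; O3'(i)-P(i+1) bonded threshold

# logical: is residue i covalently linked to residue i+1 (same chain order)?
covalentLinks <- function(model, resids) {
  if (length(resids) < 2) return(logical(0))
  o3 <- atomCoords(model, resids, "O3'")
  p  <- atomCoords(model, resids, "P")
  n <- length(resids)
  d <- sqrt(rowSums((o3[-n, , drop = FALSE] - p[-1, , drop = FALSE])^2))
  !is.na(d) & d < O3P_COVALENT_CUTOFF
}

# does this residue carry the full heavy-atom complement of its parent base?
isAllAtomRNA <- function(model, rt) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  ok <- logical(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    parent <- rnaParentBase(rt$resname[i])
    if (is.na(parent)) next
    have <- a$atom[rid == rt$resid[i]]
    need <- c(RNA_SUGAR_ATOMS, RNA_BASE_ATOMS[[parent]])
    ok[i] <- all(need %in% have)
  }
  ok
}

#' Select RNA chains eligible for motif extraction
#'
#' A chain is eligible if it contains at least two consecutive, covalently
#' bound (O3'-P below 2 Angstrom), unmodified ribonucleotide residues in
#' all-atom representation (all standard heavy atoms present; the 5'
#' phosphate of the first residue of a stretch is not required, but the
#' linking phosphate is).
#'
#' @param model a \linkS4class{StructureModel}
#' @return character vector of eligible chain identifiers (possibly empty)
#' @examples
#' fx <- makeHelix(4, "GGGG")
#' eligibleRNAChains(fx$model)
#' @export
eligibleRNAChains <- function(model) {
  rt <- residueTable(model)
  rt <- rt[rt$category == "rna", , drop = FALSE]
  if (nrow(rt) == 0) return(character(0))
  out <- character(0)
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  for (ch in unique(rt$chain)) {
    rc <- rt[rt$chain == ch, , drop = FALSE]
    rc <- rc[order(rc$resno, rc$icode), , drop = FALSE]
    if (nrow(rc) < 2) next
    std <- rc$resname %in% STANDARD_RNA
    allatom <- isAllAtomRNA(model, rc)
    hasP <- vapply(rc$resid, function(r)
      all(RNA_PHOSPHATE_ATOMS %in% a$atom[rid == r]), logical(1))
    links <- covalentLinks(model, rc$resid)
    okpair <- std[-nrow(rc)] & std[-1] & allatom[-nrow(rc)] & allatom[-1] &
      hasP[-1] & links
    if (any(okpair)) out <- c(out, ch)
  }
  out
}

# fractionalization matrix (columns = cell vectors in cartesian)
cellMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c2 <- cell[3]
  al <- cell[4] * pi/180; be <- cell[5] * pi/180; ga <- cell[6] * pi/180
  v <- sqrt(max(0, 1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                  2 * cos(al) * cos(be) * cos(ga)))
  matrix(c(a, b * cos(ga), c2 * cos(be),
           0, b * sin(ga), c2 * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c2 * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Generate crystal symmetry mates near the asymmetric unit
#'
#' Applies every symmetry operator of the crystal frame combined with
#' lattice translations over a +/-1 cell shell (after re-centering each
#' image near the model) and keeps every copy that has at least one
#' non-hydrogen atom within \code{cutoff} of the model. The identity copy is
#' never returned.
#'
#' @param model a \linkS4class{StructureModel} with a crystal frame
#' @param cutoff contact distance in Angstrom
#' @return list of \linkS4class{SymmetryMate}
#' @export
expandSymmetry <- function(model, cutoff = 3.9) {
  cr <- model@crystal
  if (length(cr) == 0) stop("no crystal information in model")
  a <- atoms(model)
  M <- cellMatrix(cr$cell)
  Minv <- solve(M)
  X <- t(as.matrix(a[, c("x", "y", "z")]))       # 3 x n cartesian
  F0 <- Minv %*% X                               # fractional
  heavy <- !a$hydrogen
  Xh <- t(X[, heavy, drop = FALSE])
  lo <- apply(Xh, 2, min) - cutoff; hi <- apply(Xh, 2, max) + cutoff
  ctr <- rowMeans(F0)
  mates <- list()
  for (k in seq_along(cr$symops)) {
    op <- cr$symops[[k]]
    Fk <- op[, 1:3] %*% F0 + op[, 4]
    base <- round(ctr - rowMeans(Fk))            # recenter near the model
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      shift <- base + c(sx, sy, sz)
      isIdentity <- max(abs(op[, 1:3] - diag(3))) < 1e-9 &&
        max(abs(op[, 4] + shift)) < 1e-9
      if (isIdentity) next
      Y <- M %*% (Fk + shift)
      Yh <- t(Y[, heavy, drop = FALSE])
      inBox <- Yh[, 1] >= lo[1] & Yh[, 1] <= hi[1] &
               Yh[, 2] >= lo[2] & Yh[, 2] <= hi[2] &
               Yh[, 3] >= lo[3] & Yh[, 3] <= hi[3]
      if (!any(inBox)) next
      dm <- crossDist(Yh[inBox, , drop = FALSE], Xh)
      if (min(dm) > cutoff || cutoff <= 0) next
      am <- a
      am$x <- Y[1, ]; am$y <- Y[2, ]; am$z <- Y[3, ]
      mm <- new("StructureModel",
                entryId = paste0(model@entryId, "_sym", k, "_",
                                 paste(shift, collapse = ",")),
                atoms = am, crystal = list())
      mates[[length(mates) + 1]] <- new("SymmetryMate",
                                        operatorIndex = as.integer(k),
                                        latticeShift = as.integer(shift),
                                        model = mm)
    }
  }
  mates
}
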