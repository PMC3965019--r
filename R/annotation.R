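# Hydrogen placement, hydrogen-bond detection (geometric criteria in the
# style of HB-PLUS), base-pair classification and stacking annotation.

HB_DA_MAX <- 3.9    # donor-acceptor heavy distance (Angstrom)
HB_HA_MAX <- 2.5    # hydrogen-acceptor distance
HB_DHA_MIN <- 90    # D-H...A angle (degrees)

resAtomXYZ <- function(a, rid, resid, name) {
  i <- which(rid == resid & a$atom == name)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

ringFit <- function(a, rid, resid, parent) {
  nm <- RNA_RING_ATOMS[[parent]]
  i <- which(rid == resid & a$atom %in% nm)
  if (length(i) < 4) return(NULL)
  m <- as.matrix(a[i, c("x", "y", "z")])
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Add idealized polar hydrogens
#'
#' Places the standard polar hydrogens of nucleobases and several
#' protein donors (backbone amide, Arg, Lys, Asn, Gln, His, Trp) at
#' idealized geometry (N-H 1.01 Angstrom, in-plane or tetrahedral).
#' Hydrogens already present are never moved; rotatable hydroxyls
#' (2'-OH, Ser/Thr/Tyr) are left unprotonated and handled by the
#' heavy-atom fallback of \code{\link{detectHBonds}}. Residues of unknown
#' chemistry are skipped with a warning.
#'
#' @param model a \linkS4class{StructureModel}
#' @return a new StructureModel with hydrogens appended
#' @export
placePolarHydrogens <- function(model) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  rt <- residueTable(model)
  newrows <- list()
  unknown <- character(0)

  addH <- function(resrow, name, xyz) {
    data.frame(het = FALSE, atom = name, alt = "", resname = resrow$resname,
               chain = resrow$chain, resno = resrow$resno, icode = resrow$icode,
               x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, element = "H",
               hydrogen = TRUE, stringsAsFactors = FALSE)
  }
  bisectorH <- function(n, nb1, nb2) n + 1.01 * unitv(-(unitv(nb1 - n) + unitv(nb2 - n)))
  planarNH2 <- function(n, cref, normal) {
    d <- unitv(n - cref)
    list(as.vector(n + 1.01 * (rotAxis(normal,  60 * pi/180) %*% d)),
         as.vector(n + 1.01 * (rotAxis(normal, -60 * pi/180) %*% d)))
  }

  for (i in seq_len(nrow(rt))) {
    rr <- rt[i, ]
    have <- a$atom[rid == rr$resid]
    g <- function(nm) resAtomXYZ(a, rid, rr$resid, nm)
    if (rr$category == "rna") {
      parent <- rnaParentBase(rr$resname)
      if (is.na(parent)) { unknown <- c(unknown, rr$resname); next }
      rf <- ringFit(a, rid, rr$resid, parent)
      if (is.null(rf)) next
      don <- RNA_HB_DONORS[[parent]]
      for (dn in names(don)) {
        hs <- don[[dn]]
        if (length(hs) == 0 || all(hs %in% have)) next
        D <- g(dn); if (is.null(D)) next
        if (parent == "G" && dn == "N1") {
          h <- bisectorH(D, g("C2"), g("C6"))
          if (!"H1" %in% have) newrows[[length(newrows)+1]] <- addH(rr, "H1", h)
        } else if (parent == "U" && dn == "N3") {
          h <- bisectorH(D, g("C2"), g("C4"))
          if (!"H3" %in% have) newrows[[length(newrows)+1]] <- addH(rr, "H3", h)
        } else {
          cref <- switch(paste0(parent, dn), GN2 = g("C2"), AN6 = g("C6"),
                         CN4 = g("C4"), NULL)
          if (is.null(cref)) next
          hh <- planarNH2(D, cref, rf$normal)
          for (k in seq_along(hs))
            if (!hs[k] %in% have)
              newrows[[length(newrows)+1]] <- addH(rr, hs[k], hh[[k]])
        }
      }
    } else if (rr$category == "protein") {
      # backbone amide
      if (!"H" %in% have && rr$resname != "PRO") {
        N <- g("N"); CA <- g("CA")
        prev <- if (i > 1 && rt$chain[i-1] == rr$chain &&
                    rt$category[i-1] == "protein")
          resAtomXYZ(a, rid, rt$resid[i-1], "C") else NULL
        if (!is.null(N) && !is.null(CA) && !is.null(prev))
          newrows[[length(newrows)+1]] <- addH(rr, "H", bisectorH(N, CA, prev))
      }
      if (rr$resname == "ARG") {
        NE <- g("NE"); CZ <- g("CZ"); CD <- g("CD")
        NH1 <- g("NH1"); NH2 <- g("NH2")
        if (!is.null(NE) && !is.null(CZ) && !is.null(CD) && !"HE" %in% have)
          newrows[[length(newrows)+1]] <- addH(rr, "HE", bisectorH(NE, CD, CZ))
        if (!is.null(CZ) && !is.null(NH1) && !is.null(NH2)) {
          nrm <- unitv(cross3(NH1 - CZ, NH2 - CZ))
          for (nh in c("NH1", "NH2")) {
            hs <- paste0("H", substr(nh, 2, 3), 1:2)
            if (all(hs %in% have)) next
            hh <- planarNH2(g(nh), CZ, nrm)
            for (k in 1:2) if (!hs[k] %in% have)
              newrows[[length(newrows)+1]] <- addH(rr, hs[k], hh[[k]])
          }
        }
      }
      if (rr$resname == "LYS" && !all(c("HZ1","HZ2","HZ3") %in% have)) {
        NZ <- g("NZ"); CE <- g("CE")
        if (!is.null(NZ) && !is.null(CE)) {
          ax <- unitv(NZ - CE)
          p0 <- unitv(cross3(ax, if (abs(ax[1]) < 0.9) c(1,0,0) else c(0,1,0)))
          for (k in 0:2) {
            hn <- paste0("HZ", k + 1)
            if (hn %in% have) next
            d <- as.vector(rotAxis(ax, 2*pi*k/3) %*%
                             (cos(70.5*pi/180)*ax + sin(70.5*pi/180)*p0))
            newrows[[length(newrows)+1]] <- addH(rr, hn, NZ + 1.01*d)
          }
        }
      }
      if (rr$resname %in% c("ASN", "GLN")) {
        nn <- if (rr$resname == "ASN") c("ND2", "CG", "OD1") else c("NE2", "CD", "OE1")
        N <- g(nn[1]); C <- g(nn[2]); O <- g(nn[3])
        hs <- if (rr$resname == "ASN") c("HD21","HD22") else c("HE21","HE22")
        if (!is.null(N) && !is.null(C) && !is.null(O) && !all(hs %in% have)) {
          nrm <- unitv(cross3(N - C, O - C))
          hh <- planarNH2(N, C, nrm)
          for (k in 1:2) if (!hs[k] %in% have)
            newrows[[length(newrows)+1]] <- addH(rr, hs[k], hh[[k]])
        }
      }
      if (rr$resname == "HIS") {
        for (dd in list(c("ND1","CG","CE1","HD1"), c("NE2","CD2","CE1","HE2"))) {
          if (dd[4] %in% have) next
          N <- g(dd[1]); n1 <- g(dd[2]); n2 <- g(dd[3])
          if (!is.null(N) && !is.null(n1) && !is.null(n2))
            newrows[[length(newrows)+1]] <- addH(rr, dd[4], bisectorH(N, n1, n2))
        }
      }
      if (rr$resname == "TRP" && !"HE1" %in% have) {
        N <- g("NE1"); n1 <- g("CD1"); n2 <- g("CE2")
        if (!is.null(N) && !is.null(n1) && !is.null(n2))
          newrows[[length(newrows)+1]] <- addH(rr, "HE1", bisectorH(N, n1, n2))
      }
    }
    # water/ion/ligand: heavy-atom treatment only
  }
  if (length(unknown) > 0)
    warning("skipped hydrogen placement for unknown residue(s): ",
            paste(unique(unknown), collapse = ", "))
  if (length(newrows) == 0) return(model)
  a2 <- rbind(a, do.call(rbind, newrows))
  new("StructureModel", entryId = model@entryId, atoms = a2,
      crystal = model@crystal)
}

# donor/acceptor inventories: one row per donor heavy atom (with its
# hydrogen names) / per acceptor atom
hbondInventory <- function(model) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  rt <- residueTable(model)
  donors <- list(); acceptors <- list()
  addD <- function(resid, atom, hnames)
    donors[[length(donors)+1]] <<- list(resid = resid, atom = atom, h = hnames)
  addA <- function(resid, atom)
    acceptors[[length(acceptors)+1]] <<- list(resid = resid, atom = atom)
  for (i in seq_len(nrow(rt))) {
    rr <- rt[i, ]
    have <- a$atom[rid == rr$resid]
    if (rr$category == "rna") {
      parent <- rnaParentBase(rr$resname)
      if (is.na(parent)) next
      don <- c(RNA_HB_DONORS[[parent]], SUGAR_DONORS)
      for (dn in names(don)) if (dn %in% have) addD(rr$resid, dn, don[[dn]])
      for (an in c(RNA_HB_ACCEPTORS[[parent]], SUGAR_ACCEPTORS))
        if (an %in% have) addA(rr$resid, an)
    } else if (rr$category == "protein") {
      don <- PROTEIN_DONORS$backbone
      if (!is.null(PROTEIN_DONORS[[rr$resname]]))
        don <- c(don, PROTEIN_DONORS[[rr$resname]])
      if (rr$resname == "PRO") don$N <- NULL
      for (dn in names(don)) if (dn %in% have) addD(rr$resid, dn, don[[dn]])
      acc <- c(PROTEIN_ACCEPTORS$backbone, PROTEIN_ACCEPTORS[[rr$resname]])
      for (an in acc) if (an %in% have) addA(rr$resid, an)
    } else if (rr$category == "water") {
      onm <- intersect(c("O", "OW"), have)
      if (length(onm) > 0) { addD(rr$resid, onm[1], character(0)); addA(rr$resid, onm[1]) }
    } else if (rr$category == "ligand") {
      for (an in have[grepl("^O|^N", have)]) { addD(rr$resid, an, character(0)); addA(rr$resid, an) }
    }
  }
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds
#'
#' Geometric criteria: donor-acceptor distance at most 3.9 Angstrom and,
#' when a donor hydrogen is present, hydrogen-acceptor distance at most
#' 2.5 Angstrom with a D-H...A angle of at least 90 degrees. Donors
#' without placeable hydrogens (water, hydroxyls, exotic residues) fall
#' back to the heavy-atom distance criterion with donor/acceptor
#' chemistry.
#'
#' @param model a \linkS4class{StructureModel}, ideally after
#'   \code{\link{placePolarHydrogens}}
#' @return data.frame with columns donorRes, donorAtom, acceptorRes,
#'   acceptorAtom, hydrogen, daDistance, dhaAngle
#' @export
detectHBonds <- function(model) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  inv <- hbondInventory(model)
  empty <- data.frame(donorRes = character(0), donorAtom = character(0),
                      acceptorRes = character(0), acceptorAtom = character(0),
                      hydrogen = character(0), daDistance = numeric(0),
                      dhaAngle = numeric(0), stringsAsFactors = FALSE)
  if (length(inv$donors) == 0 || length(inv$acceptors) == 0) return(empty)
  dxyz <- t(vapply(inv$donors, function(d) resAtomXYZ(a, rid, d$resid, d$atom),
                   numeric(3)))
  axyz <- t(vapply(inv$acceptors, function(d) resAtomXYZ(a, rid, d$resid, d$atom),
                   numeric(3)))
  dres <- vapply(inv$donors, `[[`, "", "resid")
  ares <- vapply(inv$acceptors, `[[`, "", "resid")
  dm <- crossDist(dxyz, axyz)
  hits <- which(dm <= HB_DA_MAX & outer(dres, ares, "!="), arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  out <- vector("list", nrow(hits))
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    don <- inv$donors[[i]]; acc <- inv$acceptors[[j]]
    hpresent <- don$h[vapply(don$h, function(h)
      !is.null(resAtomXYZ(a, rid, don$resid, h)), logical(1))]
    hname <- NA_character_; dha <- NA_real_
    if (length(hpresent) > 0) {
      ok <- FALSE
      for (h in hpresent) {
        H <- resAtomXYZ(a, rid, don$resid, h)
        ha <- vnorm(axyz[j, ] - H)
        ang <- bondAngle(dxyz[i, ], H, axyz[j, ])
        if (ha <= HB_HA_MAX && ang >= HB_DHA_MIN) {
          ok <- TRUE; hname <- h; dha <- ang; break
        }
      }
      if (!ok) next
    }
    out[[r]] <- data.frame(donorRes = don$resid, donorAtom = don$atom,
                           acceptorRes = acc$resid, acceptorAtom = acc$atom,
                           hydrogen = hname, daDistance = dm[i, j],
                           dhaAngle = dha, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

C1C1_RANGE <- c(9.0, 11.5)   # Angstrom, Watson-Crick geometry gate
PLANE_ANGLE_MAX <- 30        # degrees, base coplanarity gate

#' Classify Watson-Crick and wobble base pairs
#'
#' A pair is \code{canonical_wc} for A.U (both of N1...N3 and N6...O4
#' present) or G.C (at least two of the three canonical bonds), and
#' \code{wobble} for G.U (both of O6...N3 and N1...O2), subject to
#' geometric gates: C1'-C1' distance within 9.0-11.5 Angstrom and base
#' plane angle at most 30 degrees. Any other hydrogen-bonded base-base
#' arrangement is reported with klass \code{other}. Modified residues pair
#' through their parent base.
#'
#' @param model a \linkS4class{StructureModel}
#' @param hbonds data.frame from \code{\link{detectHBonds}}
#' @return data.frame with columns resA, resB, klass, nHBonds, c1c1
#' @export
classifyPairs <- function(model, hbonds) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  rt <- residueTable(model)
  parent <- stats::setNames(rnaParentBase(rt$resname), rt$resid)
  empty <- data.frame(resA = character(0), resB = character(0),
                      klass = character(0), nHBonds = integer(0),
                      c1c1 = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hbonds) == 0) return(empty)
  baseAtoms <- unique(c(unlist(RNA_BASE_ATOMS), "O2", "O4", "O6"))
  bb <- hbonds[hbonds$donorAtom %in% baseAtoms &
               hbonds$acceptorAtom %in% baseAtoms &
               !is.na(parent[hbonds$donorRes]) &
               !is.na(parent[hbonds$acceptorRes]), , drop = FALSE]
  if (nrow(bb) == 0) return(empty)
  keyAB <- ifelse(bb$donorRes < bb$acceptorRes,
                  paste(bb$donorRes, bb$acceptorRes, sep = "\r"),
                  paste(bb$acceptorRes, bb$donorRes, sep = "\r"))
  out <- list()
  for (k in unique(keyAB)) {
    rs <- strsplit(k, "\r", fixed = TRUE)[[1]]
    rA <- rs[1]; rB <- rs[2]
    sub <- bb[keyAB == k, , drop = FALSE]
    # bonds as unordered atom-name pairs oriented (rA atom, rB atom)
    atomPairs <- unique(t(apply(sub, 1, function(row) {
      if (row[["donorRes"]] == rA) c(row[["donorAtom"]], row[["acceptorAtom"]])
      else c(row[["acceptorAtom"]], row[["donorAtom"]])
    })))
    c1A <- resAtomXYZ(a, rid, rA, "C1'"); c1B <- resAtomXYZ(a, rid, rB, "C1'")
    c11 <- if (!is.null(c1A) && !is.null(c1B)) vnorm(c1A - c1B) else NA_real_
    pA <- parent[rA]; pB <- parent[rB]
    klass <- "other"
    for (orient in list(c(pA, pB, 1), c(pB, pA, 2))) {
      patKey <- paste0(orient[1], ":", orient[2])
      pat <- WC_PATTERNS[[patKey]]
      if (is.null(pat)) next
      ap <- if (orient[3] == "1") atomPairs else atomPairs[, c(2, 1), drop = FALSE]
      nmatch <- sum(vapply(pat$atoms, function(pp)
        any(ap[, 1] == pp[1] & ap[, 2] == pp[2]), logical(1)))
      if (nmatch >= pat$min) {
        gate <- !is.na(c11) && c11 >= C1C1_RANGE[1] && c11 <= C1C1_RANGE[2]
        if (gate) {
          fA <- ringFit(a, rid, rA, pA); fB <- ringFit(a, rid, rB, pB)
          ang <- acos(min(1, abs(sum(fA$normal * fB$normal)))) * 180/pi
          if (ang <= PLANE_ANGLE_MAX) { klass <- pat$klass; break }
        }
      }
    }
    out[[length(out)+1]] <- data.frame(resA = rA, resB = rB, klass = klass,
                                       nHBonds = nrow(atomPairs), c1c1 = c11,
                                       stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

STACK_CENTROID_MAX <- 5.5
STACK_NORMAL_MAX <- 30
STACK_OFFSET_MAX <- 4.0

#' Annotate putative base stacking (simplified geometric rule)
#'
#' Two bases stack when their ring centroids are within 5.5 Angstrom, their
#' plane normals are within 30 degrees (or 150-180, antiparallel) and the
#' centroid offset projected into the base planes is at most 4.0 Angstrom.
#'
#' @param model a \linkS4class{StructureModel}
#' @return data.frame with columns resA, resB, centroidDistance,
#'   normalAngle, offset
#' @export
detectStacking <- function(model) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  rt <- residueTable(model)
  rt <- rt[rt$category == "rna" & !is.na(rnaParentBase(rt$resname)), , drop = FALSE]
  fits <- lapply(seq_len(nrow(rt)), function(i)
    ringFit(a, rid, rt$resid[i], rnaParentBase(rt$resname[i])))
  keep <- !vapply(fits, is.null, logical(1))
  rt <- rt[keep, , drop = FALSE]; fits <- fits[keep]
  out <- list()
  if (nrow(rt) >= 2) {
    ctr <- t(vapply(fits, `[[`, numeric(3), "centroid"))
    dm <- crossDist(ctr, ctr)
    for (i in seq_len(nrow(rt) - 1)) for (j in seq((i+1), nrow(rt))) {
      if (dm[i, j] > STACK_CENTROID_MAX) next
      n1 <- fits[[i]]$normal; n2 <- fits[[j]]$normal
      ang <- acos(min(1, abs(sum(n1 * n2)))) * 180/pi
      if (ang > STACK_NORMAL_MAX) next
      dvec <- fits[[j]]$centroid - fits[[i]]$centroid
      off <- mean(c(vnorm(dvec - sum(dvec * n1) * n1),
                    vnorm(dvec - sum(dvec * n2) * n2)))
      if (off > STACK_OFFSET_MAX) next
      out[[length(out)+1]] <- data.frame(
        resA = rt$resid[i], resB = rt$resid[j], centroidDistance = dm[i, j],
        normalAngle = ang, offset = off, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(resA = character(0), resB = character(0),
                      centroidDistance = numeric(0), normalAngle = numeric(0),
                      offset = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full annotation pipeline: hydrogens, hydrogen bonds, base pairs
#'
#' @param model a \linkS4class{StructureModel}
#' @param addHydrogens place missing polar hydrogens first
#' @return list with elements model, hbonds, pairs
#' @export
annotateStructure <- function(model, addHydrogens = TRUE) {
  if (addHydrogens) model <- placePolarHydrogens(model)
  hb <- detectHBonds(model)
  list(model = model, hbonds = hb, pairs = classifyPairs(model, hb))
}
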