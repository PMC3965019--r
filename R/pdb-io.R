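# PDB-format structure input/output (fixed-column ATOM/HETATM records,
# CRYST1 cell, REMARK 290 SMTRY symmetry operators, first MODEL only).

resIdOf <- function(chain, resno, icode) {
  ic <- ifelse(is.na(icode) | icode == "" | icode == " ", "", icode)
  paste0(chain, ":", resno, ic)
}

#' Read a structure in PDB format
#'
#' Parses fixed-column ATOM/HETATM records. Only the first MODEL of a
#' multi-model file is kept. Alternate locations: blank and 'A' records are
#' kept (for duplicated atoms the higher occupancy wins, ties go to 'A');
#' other altlocs are dropped, so downstream geometry sees a single conformer.
#' A CRYST1 record (plus REMARK 290 SMTRY operators, when present) is parsed
#' into the crystal frame; without REMARK 290 the operator list defaults to
#' the identity (sufficient for P1).
#'
#' @param input path to a PDB file, or a character vector of PDB lines
#' @param entryId optional entry identifier (defaults to file name)
#' @return a \linkS4class{StructureModel}
#' @examples
#' fx <- makeStemLoop(3, "GAAA")
#' tf <- tempfile(fileext = ".pdb")
#' writeStructure(fx$model, tf)
#' m <- readStructure(tf)
#' nrow(atoms(m))
#' @export
readStructure <- function(input, entryId = NULL) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(entryId)) entryId <- sub("\\.(pdb|ent)$", "", basename(input))
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    if (is.null(entryId)) entryId <- "model"
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty PDB input")

  # restrict to the first MODEL block if MODEL records are present
  mstart <- grep("^MODEL ", lines)
  if (length(mstart) > 0) {
    mend <- grep("^ENDMDL", lines)
    end1 <- if (length(mend) > 0) mend[1] else length(lines)
    keep <- c(seq_len(mstart[1] - 1), seq(mstart[1], end1))
    lines <- lines[intersect(keep, seq_along(lines))]
    lines <- lines[!grepl("^MODEL |^ENDMDL", lines)]
  }

  crystal <- list()
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) > 0) {
    l <- cl[1]
    cell <- suppressWarnings(as.numeric(c(
      substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33),
      substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54))))
    if (any(is.na(cell))) stop("unparsable CRYST1 record: ", l)
    sg <- trimws(substr(l, 56, 66))
    symops <- parseSmtry(lines)
    if (length(symops) == 0) symops <- list(cbind(diag(3), c(0, 0, 0)))
    crystal <- list(cell = cell, spacegroup = sg, symops = symops)
  }

  sel <- grepl("^ATOM  |^HETATM", lines)
  al <- lines[sel]
  if (length(al) == 0) stop("no ATOM/HETATM records in PDB input")
  al <- formatC(al, width = 80, flag = "-")
  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0)
    stop("unparsable ATOM record (coordinates) at line: ", al[bad[1]])
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(al, 77, 78)))
  nm <- trimws(substr(al, 13, 16))
  guess <- toupper(sub("^[0-9']*", "", nm))
  guess <- substr(sub("'.*", "", guess), 1, 1)
  two <- toupper(substr(nm, 1, 2)) %in% names(VDW_RADII)[nchar(names(VDW_RADII)) == 2]
  elem[elem == ""] <- ifelse(grepl("^[0-9]*H", nm[elem == ""]), "H", guess[elem == ""])
  a <- data.frame(
    het = substr(al, 1, 6) == "HETATM",
    atom = nm,
    alt = trimws(substr(al, 17, 17)),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = trimws(substr(al, 27, 27)),
    x = xs, y = ys, z = zs,
    occ = pmin(1, pmax(0, occ)),
    element = elem,
    stringsAsFactors = FALSE)
  if (any(is.na(a$resno)))
    stop("unparsable ATOM record (residue number) at line: ",
         al[which(is.na(a$resno))[1]])
  a$hydrogen <- a$element %in% c("H", "D")

  # altloc policy: keep blank/'A'; resolve duplicates by occupancy then 'A'
  a <- a[a$alt %in% c("", "A"), , drop = FALSE]
  key <- paste(a$chain, a$resno, a$icode, a$atom)
  if (anyDuplicated(key)) {
    ord <- order(key, -a$occ, a$alt != "A")
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$icode, a$atom)), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  rownames(a) <- NULL
  new("StructureModel", entryId = entryId, atoms = a, crystal = crystal)
}

parseSmtry <- function(lines) {
  sl <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(sl) == 0) return(list())
  rows <- do.call(rbind, lapply(sl, function(l) {
    c(as.numeric(substr(l, 19, 19)), as.numeric(substr(l, 20, 23)),
      as.numeric(substr(l, 25, 33)), as.numeric(substr(l, 34, 43)),
      as.numeric(substr(l, 44, 53)), as.numeric(substr(l, 54, 68)))
  }))
  ops <- list()
  for (k in sort(unique(rows[, 2]))) {
    rk <- rows[rows[, 2] == k, , drop = FALSE]
    rk <- rk[order(rk[, 1]), , drop = FALSE]
    if (nrow(rk) != 3) next
    ops[[length(ops) + 1]] <- cbind(rk[, 3:5], rk[, 6])
  }
  ops
}

#' Write a structure in PDB format
#'
#' Emits standard 80-column ATOM/HETATM records with TER records between
#' chains, plus CRYST1 and REMARK 290 SMTRY records when a crystal frame is
#' present.
#'
#' @param model a \linkS4class{StructureModel}
#' @param path output file path; when missing, the lines are returned
#' @return invisibly, the character vector of PDB lines
#' @export
writeStructure <- function(model, path = NULL) {
  a <- atoms(model)
  out <- character(0)
  cr <- model@crystal
  if (length(cr) > 0) {
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cr$cell[1], cr$cell[2], cr$cell[3], cr$cell[4], cr$cell[5], cr$cell[6],
      if (is.null(cr$spacegroup) || !nzchar(cr$spacegroup)) "P 1" else cr$spacegroup,
      1L))
    if (length(cr$symops) > 1 ||
        max(abs(cr$symops[[1]] - cbind(diag(3), 0))) > 1e-9) {
      for (k in seq_along(cr$symops)) {
        op <- cr$symops[[k]]
        for (r in 1:3) {
          out <- c(out, sprintf(
            "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
            r, k, op[r, 1], op[r, 2], op[r, 3], op[r, 4]))
        }
      }
    }
  }
  fmtName <- function(nm, elem) {
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           ifelse(nchar(elem) == 2, formatC(nm, width = -4),
                  paste0(" ", formatC(nm, width = -3))))
  }
  serial <- seq_len(nrow(a))
  recs <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), ((serial - 1) %% 99999) + 1,
    fmtName(a$atom, a$element), a$alt, a$resname, a$chain, a$resno,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, a$occ, 0, a$element)
  # TER between chains
  pieces <- split(recs, factor(a$chain, levels = unique(a$chain)))
  body <- unlist(lapply(pieces, function(p) c(p, "TER")))
  out <- c(out, body, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Residue-level summary of a structure
#'
#' One row per residue in file order, with its category (rna, protein,
#' water, ion, ligand) and, for ribonucleotides, the one-letter code
#' (lower-case marks modified residues).
#'
#' @param model a \linkS4class{StructureModel}
#' @return data.frame with columns resid, chain, resno, icode, resname,
#'   category, oneLetter, nAtoms
#' @export
residueTable <- function(model) {
  a <- atoms(model)
  rid <- resIdOf(a$chain, a$resno, a$icode)
  idx <- !duplicated(rid)
  out <- data.frame(
    resid = rid[idx], chain = a$chain[idx], resno = a$resno[idx],
    icode = a$icode[idx], resname = a$resname[idx],
    stringsAsFactors = FALSE)
  out$category <- residueCategory(out$resname)
  out$oneLetter <- rnaOneLetter(out$resname)
  out$nAtoms <- as.integer(table(factor(rid, levels = out$resid)))
  rownames(out) <- NULL
  out
}

# coordinates of one named atom for each residue id (NA rows when absent)
atomCoords <- function(model, residueIds, atomName) {
  a <- if (is(model, "StructureModel")) atoms(model) else model
  rid <- if (!is.null(a$resid)) a$resid else resIdOf(a$chain, a$resno, a$icode)
  m <- matrix(NA_real_, length(residueIds), 3)
  sel <- a$atom == atomName
  idx <- match(residueIds, rid[sel])
  ok <- !is.na(idx)
  m[ok, ] <- as.matrix(a[sel, c("x", "y", "z")])[idx[ok], , drop = FALSE]
  rownames(m) <- residueIds
  m
}
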