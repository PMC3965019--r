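# Structure-quality scores: steric clash score (non-bonded van der Waals
# overlaps >= 0.4 Angstrom per 1000 atoms), backbone suite-conformer
# outlier fraction, and a real-space correlation (RSCC) interface stub.

CLASH_OVERLAP_MIN <- 0.4

COVALENT_RADII <- c(C = 0.77, N = 0.75, O = 0.73, P = 1.06, S = 1.02,
                    H = 0.32)
covRadius <- function(elem) {
  r <- COVALENT_RADII[elem]
  r[is.na(r)] <- 0.77
  unname(r)
}
vdwRadius <- function(elem) {
  r <- VDW_RADII[elem]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# bond graph by distance criterion; returns adjacency list
bondGraph <- function(xyz, elem) {
  n <- nrow(xyz)
  rad <- covRadius(elem)
  maxBond <- 2 * max(rad) + 0.45
  prs <- gridNeighborPairs(xyz, xyz, maxBond)
  prs <- prs[prs[, "i"] < prs[, "j"], , drop = FALSE]
  cut <- rad[prs[, "i"]] + rad[prs[, "j"]] + 0.4
  prs <- prs[prs[, "d"] <= cut & prs[, "d"] > 0.1, , drop = FALSE]
  adj <- vector("list", n)
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, "i"]; j <- prs[r, "j"]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

withinNBonds <- function(adj, i, j, nmax = 3) {
  fr <- i; seen <- i
  for (step in seq_len(nmax)) {
    fr <- unique(unlist(adj[fr]))
    fr <- setdiff(fr, seen)
    if (j %in% fr) return(TRUE)
    seen <- c(seen, fr)
    if (length(fr) == 0) break
  }
  FALSE
}

#' Steric clash score
#'
#' Number of non-bonded atom pairs overlapping by at least 0.4 Angstrom
#' (sum of van der Waals radii minus distance), per 1000 atoms. Pairs
#' within three covalent bonds and hydrogen-bond donor/acceptor pairs are
#' excluded. A simplification of dot-based contact scoring to pairwise
#' overlap counting.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{RNAMotif}
#' @return non-negative numeric score (0 when there is no overlap)
#' @export
clashScore <- function(x) {
  a <- if (is(x, "RNAMotif")) atoms(x) else atoms(x)
  if (is.null(a$resid)) a$resid <- resIdOf(a$chain, a$resno, a$icode)
  n <- nrow(a)
  if (n == 0) return(0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  elem <- a$element
  vr <- vdwRadius(elem)
  adj <- bondGraph(xyz, elem)
  maxd <- 2 * max(vr) - CLASH_OVERLAP_MIN
  prs <- gridNeighborPairs(xyz, xyz, maxd)
  prs <- prs[prs[, "i"] < prs[, "j"], , drop = FALSE]
  ov <- vr[prs[, "i"]] + vr[prs[, "j"]] - prs[, "d"]
  prs <- prs[ov >= CLASH_OVERLAP_MIN, , drop = FALSE]
  if (nrow(prs) == 0) return(0)
  # exclusions: bonded within 3 bonds; donor/acceptor pairs
  da <- hbondDonorAcceptorFlags(a)
  count <- 0L
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, "i"]; j <- prs[r, "j"]
    if (a$resid[i] == a$resid[j] || withinNBonds(adj, i, j, 3)) next
    if ((da$donor[i] && da$acceptor[j]) || (da$donor[j] && da$acceptor[i])) next
    # hydrogen riding on a donor vs an acceptor is an H-bond, not a clash
    if (a$hydrogen[i] && any(da$donor[adj[[i]]]) && da$acceptor[j]) next
    if (a$hydrogen[j] && any(da$donor[adj[[j]]]) && da$acceptor[i]) next
    count <- count + 1L
  }
  1000 * count / n
}

# flag donor-capable / acceptor-capable heavy atoms by residue chemistry
hbondDonorAcceptorFlags <- function(a) {
  donor <- logical(nrow(a)); acceptor <- logical(nrow(a))
  cat <- residueCategory(a$resname)
  parent <- rnaParentBase(a$resname)
  for (i in seq_len(nrow(a))) {
    nm <- a$atom[i]
    if (cat[i] == "rna" && !is.na(parent[i])) {
      donor[i] <- nm %in% c(names(RNA_HB_DONORS[[parent[i]]]), names(SUGAR_DONORS))
      acceptor[i] <- nm %in% c(RNA_HB_ACCEPTORS[[parent[i]]], SUGAR_ACCEPTORS)
    } else if (cat[i] == "protein") {
      don <- c(names(PROTEIN_DONORS$backbone),
               names(PROTEIN_DONORS[[a$resname[i]]]))
      acc <- c(PROTEIN_ACCEPTORS$backbone, PROTEIN_ACCEPTORS[[a$resname[i]]])
      donor[i] <- nm %in% don
      acceptor[i] <- nm %in% acc
    } else if (cat[i] == "water") {
      donor[i] <- acceptor[i] <- nm %in% c("O", "OW")
    } else if (cat[i] == "ligand") {
      donor[i] <- acceptor[i] <- grepl("^[ON]", nm)
    }
  }
  list(donor = donor, acceptor = acceptor)
}

#' Backbone suite torsions of a chain
#'
#' One suite per junction of consecutive covalently linked residues:
#' (delta-1, epsilon-1, zeta-1, alpha, beta, gamma, delta) in degrees.
#' Suites with missing backbone atoms are skipped with a warning.
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @return data.frame with columns suite (residue id of the second
#'   residue) and the seven torsions
#' @export
suiteTorsions <- function(model, chain) {
  rt <- residueTable(model)
  rt <- rt[rt$chain == chain & rt$category == "rna", , drop = FALSE]
  rt <- rt[order(rt$resno, rt$icode), , drop = FALSE]
  resids <- rt$resid
  links <- covalentLinks(model, resids)
  getter <- function(nm) atomCoords(model, resids, nm)
  cs <- lapply(c("C5'", "C4'", "C3'", "O3'", "P", "O5'"), getter)
  names(cs) <- c("C5'", "C4'", "C3'", "O3'", "P", "O5'")
  out <- list(); skipped <- 0
  for (i in which(links)) {
    need <- rbind(cs[["C5'"]][i, ], cs[["C4'"]][i, ], cs[["C3'"]][i, ],
                  cs[["O3'"]][i, ], cs[["P"]][i + 1, ], cs[["O5'"]][i + 1, ],
                  cs[["C5'"]][i + 1, ], cs[["C4'"]][i + 1, ],
                  cs[["C3'"]][i + 1, ], cs[["O3'"]][i + 1, ])
    if (any(!is.finite(need))) { skipped <- skipped + 1; next }
    out[[length(out) + 1]] <- data.frame(
      suite = resids[i + 1],
      deltaMinus1 = dihedralAngle(need[1, ], need[2, ], need[3, ], need[4, ]),
      epsilonMinus1 = dihedralAngle(need[2, ], need[3, ], need[4, ], need[5, ]),
      zetaMinus1 = dihedralAngle(need[3, ], need[4, ], need[5, ], need[6, ]),
      alpha = dihedralAngle(need[4, ], need[5, ], need[6, ], need[7, ]),
      beta = dihedralAngle(need[5, ], need[6, ], need[7, ], need[8, ]),
      gamma = dihedralAngle(need[6, ], need[7, ], need[8, ], need[9, ]),
      delta = dihedralAngle(need[7, ], need[8, ], need[9, ], need[10, ]),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(skipped, " suite(s) skipped: incomplete backbone")
  if (length(out) == 0)
    return(data.frame(suite = character(0), deltaMinus1 = numeric(0),
                      epsilonMinus1 = numeric(0), zetaMinus1 = numeric(0),
                      alpha = numeric(0), beta = numeric(0),
                      gamma = numeric(0), delta = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference table of favorable backbone suite conformers
#'
#' A synthetic approximation of the consensus rotamer library of favorable
#' RNA backbone conformers: 54 combinations of canonical rotameric states
#' for the seven suite torsions, with the A-form conformer (named
#' \code{1a}) set to standard A-form values. Shipped as a replaceable TSV
#' (\code{inst/extdata/suite_conformers_synthetic.tsv}).
#'
#' @param path optional path to an alternative TSV (name + 7 mean angles)
#' @return data.frame with columns name and the seven torsion means
#' @export
suiteConformerTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "suite_conformers_synthetic.tsv",
                        package = "rnamotifs")
    if (!nzchar(path)) path <- "inst/extdata/suite_conformers_synthetic.tsv"
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Fraction of backbone suites outside all favorable conformers
#'
#' A suite is an outlier when its angular distance (maximum circular
#' difference over the seven torsions) to every conformer mean exceeds
#' \code{cap} degrees.
#'
#' @param torsions data.frame from \code{\link{suiteTorsions}}
#' @param conformers conformer table (default
#'   \code{\link{suiteConformerTable}})
#' @param cap angular cap in degrees (default 40)
#' @return fraction in [0,1], or NA when there are no suites
#' @export
suiteOutlierFraction <- function(torsions, conformers = suiteConformerTable(),
                                 cap = 40) {
  if (nrow(torsions) == 0) return(NA_real_)
  tcols <- c("deltaMinus1", "epsilonMinus1", "zetaMinus1", "alpha", "beta",
             "gamma", "delta")
  tm <- as.matrix(torsions[, tcols])
  cm <- as.matrix(conformers[, setdiff(names(conformers), "name")])
  outlier <- vapply(seq_len(nrow(tm)), function(i) {
    dists <- apply(cm, 1, function(row) max(circularDiff(tm[i, ], row)))
    min(dists) > cap
  }, logical(1))
  mean(outlier)
}

#' Real-space correlation scores (interface stub)
#'
#' Density-fit scores require deposited structure factors and are not
#' computed here; the interface reports them as unavailable. Poor density
#' is conventionally a mean signal below 1 sigma or an RSCC below 0.7.
#'
#' @param ... ignored
#' @return list with available = FALSE and an explanatory message
#' @export
rsccScores <- function(...) {
  list(available = FALSE,
       message = paste("RSCC computation requires experimental electron",
                       "density data; not available in this package.",
                       "Poor density: mean signal below 1 sigma or RSCC",
                       "below 0.7."))
}

#' Quality report for a structure and optionally its motifs
#'
#' @param model a \linkS4class{StructureModel}
#' @param motifs optional list of \linkS4class{RNAMotif} for per-motif
#'   (local) scores
#' @return list with global scores and, when motifs are given, a per-motif
#'   data.frame; RSCC entries are omitted (unavailable), not zero
#' @export
qualityReport <- function(model, motifs = NULL) {
  rt <- residueTable(model)
  chains <- unique(rt$chain[rt$category == "rna"])
  tors <- do.call(rbind, lapply(chains, function(ch)
    suppressWarnings(suiteTorsions(model, ch))))
  global <- list(clashScore = clashScore(model),
                 suiteOutlierFraction =
                   if (is.null(tors)) NA_real_ else suiteOutlierFraction(tors))
  out <- list(global = global, rscc = rsccScores())
  if (!is.null(motifs)) {
    out$perMotif <- data.frame(
      motifId = vapply(motifs, function(m) m@id, ""),
      clashScore = vapply(motifs, clashScore, 1.0),
      stringsAsFactors = FALSE)
  }
  out
}
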