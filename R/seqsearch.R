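# Sequence-based motif search: per-strand patterns (IUPAC or regular
# expressions), cyclic permutations of segment order, case-sensitive
# matching of modified residues, RMSD-based aggregation of hits.

IUPAC_CLASSES <- c(R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]",
                   K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
                   H = "[ACU]", V = "[ACG]", N = "[ACGU]", T = "U")

#' Strand sequences of a motif
#'
#' One string per strand, 5' to 3', in strand order. Modified residues are
#' written as the lower-case letter of their parent base; residues of
#' unknown chemistry become \code{n}.
#'
#' @param motif an \linkS4class{RNAMotif}
#' @return character vector of strand sequences
#' @export
motifSequence <- function(motif) {
  a <- atoms(motif)
  nameOf <- a$resname[!duplicated(a$resid)]
  names(nameOf) <- a$resid[!duplicated(a$resid)]
  vapply(strands(motif), function(st) {
    letters1 <- rnaOneLetter(nameOf[st])
    letters1[is.na(letters1)] <- "n"
    paste(letters1, collapse = "")
  }, "")
}

# expand IUPAC degenerate codes into character classes, preserving any
# regex syntax already present; lower-case input maps to lower-case classes
expandIUPAC <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  out <- character(length(chars))
  inClass <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") inClass <- TRUE
    if (ch == "]") inClass <- FALSE
    up <- toupper(ch)
    if (!inClass && up %in% names(IUPAC_CLASSES)) {
      cls <- IUPAC_CLASSES[[up]]
      out[i] <- if (ch == up) cls else tolower(cls)
    } else out[i] <- ch
  }
  paste(out, collapse = "")
}

#' Match a multi-segment sequence query against a motif
#'
#' TRUE when some cyclic rotation of the motif's strand list matches the
#' query segments position-wise; each segment must match its strand as a
#' full string. IUPAC degenerate codes are expanded; matching is
#' case-insensitive unless \code{caseSensitive} (lower-case letters then
#' match only modified residues).
#'
#' @param segments character vector of per-strand patterns
#' @param motif an \linkS4class{RNAMotif}
#' @param caseSensitive logical
#' @return logical
#' @export
seqMatch <- function(segments, motif, caseSensitive = FALSE) {
  if (length(segments) < 1 || any(!nzchar(segments)))
    stop("query needs at least one non-empty segment")
  seqs <- motifSequence(motif)
  k <- length(seqs)
  if (length(segments) != k) return(FALSE)
  pats <- vapply(segments, expandIUPAC, "")
  pats <- paste0("^(?:", pats, ")$")
  ok <- vapply(pats, function(p) {
    r <- tryCatch(suppressWarnings(regexpr(p, "x", perl = TRUE)),
                  error = function(e) NULL)
    !is.null(r)
  }, logical(1))
  if (!all(ok)) stop("invalid regular expression in query")
  if (!caseSensitive) { seqs <- toupper(seqs); pats <- toupper(pats) }
  for (r in 0:(k - 1)) {
    rot <- seqs[c(seq(r + 1, length.out = k - r), seq_len(r))]
    hit <- all(vapply(seq_len(k), function(i)
      grepl(pats[i], rot[i], perl = TRUE), logical(1)))
    if (hit) return(TRUE)
  }
  FALSE
}

#' Sequence search over a motif collection
#'
#' @param segments character vector of per-strand patterns
#' @param motifs list of \linkS4class{RNAMotif}
#' @param caseSensitive logical
#' @param aggregate group hits within \code{aggregateThreshold} backbone
#'   RMSD (complete linkage; one medoid representative per group)
#' @param aggregateThreshold RMSD for aggregation (Angstrom)
#' @return when \code{aggregate} is FALSE, list of matching motifs; else
#'   list of \linkS4class{MotifCluster} groups
#' @export
searchSequence <- function(segments, motifs, caseSensitive = FALSE,
                           aggregate = FALSE, aggregateThreshold = 1.0) {
  hits <- motifs[vapply(motifs, function(m)
    seqMatch(segments, m, caseSensitive), logical(1))]
  if (!aggregate) return(hits)
  aggregateHits(hits, aggregateThreshold)
}

#' Aggregate sequence-search hits by geometric similarity
#'
#' Hits sharing a composition key are grouped by complete-linkage
#' clustering at the given backbone RMSD; each group is represented by its
#' medoid. Hits of different composition keys are never merged.
#'
#' @param hits list of \linkS4class{RNAMotif}
#' @param threshold backbone RMSD (Angstrom), default 1.0
#' @return list of \linkS4class{MotifCluster}
#' @export
aggregateHits <- function(hits, threshold = 1.0) {
  clusterMotifs(hits, threshold = threshold)
}
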