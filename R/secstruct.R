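# Secondary-structure graphs: residues as nodes, phosphodiester backbone and
# WC/wobble pair edges; pseudoknot removal as a maximum non-crossing subset.

#' Build the secondary-structure graph of one chain
#'
#' Nodes are the chain's ribonucleotide residues in chain order; edges are
#' the covalent backbone (O3'-P linkage below 2 Angstrom; chain breaks leave
#' separate components) and the supplied WC/wobble base pairs.
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param pairs data.frame with resA, resB (and optionally klass) columns;
#'   only intra-chain canonical_wc/wobble pairs are used
#' @return list with elements resids, n, backbone (logical links between
#'   consecutive residues), pairIdx (2-column matrix of node indices),
#'   V, E, C (components)
#' @export
buildSecStructGraph <- function(model, chain, pairs) {
  rtAll <- residueTable(model)
  rt <- rtAll[rtAll$chain == chain & rtAll$category == "rna", , drop = FALSE]
  if (nrow(rt) == 0) stop("no RNA residues in chain ", chain)
  rt <- rt[order(rt$resno, rt$icode), , drop = FALSE]  # chain order
  resids <- rt$resid
  links <- covalentLinks(model, resids)
  pairIdx <- matrix(integer(0), 0, 2)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (!is.null(pairs$klass))
      pairs <- pairs[pairs$klass %in% c("canonical_wc", "wobble"), , drop = FALSE]
    unknown <- setdiff(c(pairs$resA, pairs$resB), rtAll$resid)
    if (length(unknown) > 0)
      stop("pair references unknown residue(s): ",
           paste(unknown, collapse = ", "))
    ia <- match(pairs$resA, resids); ib <- match(pairs$resB, resids)
    keep <- !is.na(ia) & !is.na(ib)   # inter-chain pairs are ignored
    if (any(keep)) {
      score <- if (!is.null(pairs$nHBonds)) pairs$nHBonds[keep] else rep(1L, sum(keep))
      pd <- data.frame(i = pmin(ia[keep], ib[keep]),
                       j = pmax(ia[keep], ib[keep]), s = score)
      pd <- pd[order(pd$i, pd$j, -pd$s), , drop = FALSE]
      pd <- pd[!duplicated(pd[, c("i", "j")]), , drop = FALSE]
      # a residue joins at most one pair: keep the better-supported one
      ord <- order(-pd$s, pd$i, pd$j)
      used <- logical(length(resids)); sel <- logical(nrow(pd))
      for (r in ord) {
        if (!used[pd$i[r]] && !used[pd$j[r]]) {
          sel[r] <- TRUE; used[pd$i[r]] <- used[pd$j[r]] <- TRUE
        }
      }
      pd <- pd[sel, , drop = FALSE]
      pairIdx <- cbind(pd$i, pd$j)
    }
  }
  V <- length(resids)
  E <- sum(links) + nrow(pairIdx)
  g <- secstructIgraph(V, links, pairIdx)
  C <- igraph::count_components(g)
  list(resids = resids, n = V, backbone = links, pairIdx = pairIdx,
       V = V, E = E, C = C)
}

secstructIgraph <- function(V, links, pairIdx) {
  el <- rbind(cbind(which(links), which(links) + 1L), pairIdx)
  igraph::graph_from_edgelist(el, directed = FALSE) +
    igraph::vertices(setdiff(seq_len(V), unique(c(el))))
}

# topology-only graph from a pair index set (continuous backbone)
graphFromTopology <- function(n, pairIdx) {
  list(resids = as.character(seq_len(n)), n = n,
       backbone = rep(TRUE, max(0, n - 1)),
       pairIdx = if (is.null(pairIdx)) matrix(integer(0), 0, 2) else
         cbind(pmin(pairIdx[, 1], pairIdx[, 2]), pmax(pairIdx[, 1], pairIdx[, 2])),
       V = n,
       E = max(0, n - 1) + NROW(pairIdx),
       C = 1L)
}

#' Base-pair indices from a dot-bracket string
#'
#' Supports nested brackets \code{()}, \code{[]}, \code{\{\}} and
#' \code{<>} (the extra bracket types encode pseudoknotted pairs).
#'
#' @param db dot-bracket string
#' @return 2-column matrix of 1-based paired positions
#' @export
dotBracketPairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")
  stacks <- list(); out <- list()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% names(open)) {
      stacks[[ch]] <- c(stacks[[ch]], i)
    } else if (ch %in% open) {
      op <- names(open)[match(ch, open)]
      st <- stacks[[op]]
      if (length(st) == 0) stop("unbalanced dot-bracket string")
      out[[length(out)+1]] <- c(st[length(st)], i)
      stacks[[op]] <- st[-length(st)]
    }
  }
  if (any(vapply(stacks, length, 1L) > 0)) stop("unbalanced dot-bracket string")
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

#' Remove pseudoknots: maximum non-crossing subset of base pairs
#'
#' Retains the largest possible number of mutually non-crossing pairs
#' (no i < k < j < l with pairs (i,j) and (k,l) both kept); each position
#' joins at most one kept pair. Ties are broken deterministically by
#' preferring the pair with the smaller opening index, then the shorter
#' span.
#'
#' @param pairIdx 2-column matrix of paired positions
#' @return list with \code{kept} and \code{removed} (2-column matrices,
#'   rows of the input)
#' @export
removePseudoknots <- function(pairIdx) {
  if (NROW(pairIdx) == 0)
    return(list(kept = matrix(integer(0), 0, 2), removed = matrix(integer(0), 0, 2)))
  pairIdx <- cbind(pmin(pairIdx[, 1], pairIdx[, 2]), pmax(pairIdx[, 1], pairIdx[, 2]))
  pos <- sort(unique(c(pairIdx)))
  n <- length(pos)
  pi2 <- cbind(match(pairIdx[, 1], pos), match(pairIdx[, 2], pos))
  # partners[[i]]: sorted k > i paired with i
  partners <- vector("list", n)
  for (r in seq_len(nrow(pi2))) {
    i <- pi2[r, 1]; k <- pi2[r, 2]
    partners[[i]] <- sort(unique(c(partners[[i]], k)))
  }
  best <- matrix(0L, n + 2, n + 1)  # best[i, j]: interval i..j (i > j -> 0)
  choice <- matrix(0L, n + 2, n + 1)  # 0 = skip i, k = pair (i, k)
  for (i in seq(n, 1)) {
    for (j in seq(i, n)) {
      b <- best[i + 1, j]; ch <- 0L
      for (k in partners[[i]]) {
        if (k > j) break
        v <- 1L + (if (k - 1 >= i + 1) best[i + 1, k - 1] else 0L) +
          (if (k + 1 <= j) best[k + 1, j] else 0L)
        # prefer pairing i over skipping on ties; among partners the
        # smallest k (shortest span) is scanned first and wins ties
        if (v > b || (v == b && ch == 0L)) { b <- v; ch <- k }
      }
      best[i, j] <- b; choice[i, j] <- ch
    }
  }
  keptRows <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i > j || i > n) next
    ch <- choice[i, j]
    if (ch == 0L) { stack[[length(stack)+1]] <- c(i + 1L, j); next }
    row <- which(pi2[, 1] == i & pi2[, 2] == ch)[1]
    keptRows <- c(keptRows, row)
    if (ch - 1 >= i + 1) stack[[length(stack)+1]] <- c(i + 1L, ch - 1L)
    if (ch + 1 <= j) stack[[length(stack)+1]] <- c(ch + 1L, j)
  }
  keptRows <- sort(keptRows)
  list(kept = pairIdx[keptRows, , drop = FALSE],
       removed = pairIdx[setdiff(seq_len(nrow(pairIdx)), keptRows), , drop = FALSE])
}
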