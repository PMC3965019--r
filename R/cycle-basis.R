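# Minimum cycle basis via Horton-style candidate enumeration with a greedy
# GF(2) independence test. Secondary-structure graphs are small (at most a
# few thousand nodes per chain), so the simple cubic-ish algorithm is fine.

#' Minimum cycle basis of a simple undirected graph
#'
#' Returns E - V + C independent cycles of minimum total length
#' (deterministic tie-breaks by lexicographic node order). In a
#' pseudoknot-free secondary-structure graph the basis cycles are the base
#' pair tandems (length-4 cycles) and the loops.
#'
#' @param graph a graph as returned by \code{\link{buildSecStructGraph}},
#'   or a 2-column edge matrix (nodes 1..V)
#' @param V number of vertices (only when \code{graph} is an edge matrix)
#' @return list of cycles; each cycle is a list with \code{nodes} (closed
#'   path, first node not repeated), \code{edges} (indices into the edge
#'   list) and \code{pairEdgeCount} (NA for plain edge-matrix input)
#' @export
minimumCycleBasis <- function(graph, V = NULL) {
  if (is.list(graph) && !is.null(graph$pairIdx)) {
    nb <- which(graph$backbone)
    edges <- rbind(cbind(nb, nb + 1L), graph$pairIdx)
    etype <- rep(c("backbone", "pair"), c(length(nb), nrow(graph$pairIdx)))
    V <- graph$n
  } else {
    edges <- graph
    etype <- rep(NA_character_, NROW(edges))
    if (is.null(V)) V <- max(edges)
  }
  nE <- NROW(edges)
  if (nE == 0) return(list())
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < V) g <- g + igraph::vertices(seq(igraph::vcount(g) + 1, V))
  C <- igraph::count_components(g)
  dim <- nE - V + C
  if (dim <= 0) return(list())

  adj <- lapply(seq_len(V), function(v) integer(0))
  for (e in seq_len(nE)) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  adj <- lapply(adj, sort)
  edgeIndex <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(nE))
    assign(paste(edges[e, 1], edges[e, 2]), e, envir = edgeIndex)
  eIdx <- function(i, j) get(paste(min(i, j), max(i, j)), envir = edgeIndex)

  # BFS with lexicographic tie-break from every vertex
  candidates <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seq_len(V)) {
    parent <- rep(NA_integer_, V); dist <- rep(NA_integer_, V)
    dist[v] <- 0L
    queue <- v; qi <- 1
    while (qi <= length(queue)) {
      u <- queue[qi]; qi <- qi + 1
      for (w in adj[[u]]) if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L; parent[w] <- u; queue <- c(queue, w)
      }
    }
    pathTo <- function(x) {
      p <- x
      while (!is.na(parent[x])) { x <- parent[x]; p <- c(p, x) }
      rev(p)  # v ... x
    }
    for (e in seq_len(nE)) {
      x <- edges[e, 1]; y <- edges[e, 2]
      if (is.na(dist[x]) || is.na(dist[y])) next
      px <- pathTo(x); py <- pathTo(y)
      if (length(intersect(px, py)) != 1) next  # must share only v
      nodes <- c(px, rev(py)[-length(py)])      # v..x, y..(v excluded)
      if (length(nodes) < 3) next
      eds <- integer(length(nodes))
      for (i in seq_along(nodes))
        eds[i] <- eIdx(nodes[i], nodes[if (i == length(nodes)) 1 else i + 1])
      key <- paste(sort(eds), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      candidates[[length(candidates) + 1]] <- list(nodes = nodes, edges = sort(eds))
    }
  }
  lens <- vapply(candidates, function(cc) length(cc$edges), 1L)
  sig <- vapply(candidates, function(cc) paste(cc$edges, collapse = ","), "")
  ord <- order(lens, sig)

  # greedy GF(2) independence (reduced row echelon bookkeeping)
  basis <- list(); redRows <- list(); pivots <- integer(0)
  for (ci in ord) {
    vec <- logical(nE); vec[candidates[[ci]]$edges] <- TRUE
    for (r in seq_along(redRows)) {
      if (vec[pivots[r]]) vec <- xor(vec, redRows[[r]])
    }
    if (!any(vec)) next
    piv <- which(vec)[1]
    basis[[length(basis) + 1]] <- candidates[[ci]]
    redRows[[length(redRows) + 1]] <- vec
    pivots <- c(pivots, piv)
    if (length(basis) == dim) break
  }
  lapply(basis, function(cc) {
    cc$pairEdgeCount <- if (all(is.na(etype))) NA_integer_ else
      sum(etype[cc$edges] == "pair")
    cc$edgeNodes <- edges[cc$edges, , drop = FALSE]
    cc$edgeTypes <- etype[cc$edges]
    cc
  })
}
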