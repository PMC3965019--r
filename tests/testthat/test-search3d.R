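# Tertiary-structure search: filters, scoring, refinement, modes.

loopOf <- function(fx) {
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  motifs[[which(vapply(motifs, motifType, "") == "loop")[1]]]
}

test_that("distance filter boundary behaves within the tolerance", {
  p <- rbind(c(0, 0, 0), c(5, 0, 0))
  cont <- rbind(c(0, 0, 0), c(5 + 0.99, 0, 0))
  expect_true(distanceFilter(p, cont, tol = 1))
  cont2 <- rbind(c(0, 0, 0), c(5 + 1.01, 0, 0))
  expect_false(distanceFilter(p, cont2, tol = 1))
  # sub-fragment always passes
  q <- matrix(rnorm(30), 10, 3)
  expect_true(distanceFilter(q[2:5, ], q, tol = 1e-6))
})

test_that("triplet filter matches only permissible vertex assignments", {
  # equilateral vs scalene
  eq <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 5 * sqrt(3)/2, 0))
  sc <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 9, 0))
  expect_equal(length(tripletFilter(eq, sc, tol = 1, seed = 1:3)), 0L)
  # identical triplets: all six permutations of an equilateral match
  expect_equal(length(tripletFilter(eq, eq, tol = 0.1, seed = 1:3)), 6L)
  # scalene matches itself under exactly the assignments its edge multiset
  # allows (brute-force over the 6 permutations gives 1 here)
  sc2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  hits <- tripletFilter(sc2, sc2, tol = 0.05, seed = 1:3)
  expect_equal(length(hits), 1L)
  expect_equal(hits[[1]]$c, 1:3)
})

test_that("self-search finds the motif at ~zero RMSD among decoys", {
  fx <- makeStemLoop(3, "GCAAA")
  loop <- loopOf(fx)
  decoys <- lapply(1:5, function(s)
    loopOf(makeStemLoop(3, "GCAAA", entryId = paste0("d", s))))
  decoys <- lapply(seq_along(decoys), function(i) {
    d <- decoys[[i]]; d@id <- paste0("decoy", i); d })
  # perturb decoys far away
  far <- lapply(1:4, function(s) {
    d <- perturbMotif(loop, 2.5, seed = s + 20); d@id <- paste0("far", s); d
  })
  res <- searchStructure(loop, c(list(loop), far), mode = "query_in_motif",
                         rmsdThreshold = 1.0)
  expect_true(length(res) >= 1)
  expect_equal(res[[1]]@motifId, loop@id)
  expect_lt(res[[1]]@anchorRMSD, 1e-6)
  expect_lt(res[[1]]@refinedRMSD, 1e-6)
})

test_that("oversized queries are rejected", {
  fx <- makeCloverleaf()
  rt <- residueTable(fx$model)
  expect_gt(nrow(rt), 40)
  expect_error(searchStructure(fx$model, list(), mode = "query_in_motif"),
               "up to 40 nt")
})

test_that("search results are invariant under rigid transforms", {
  fx <- makeStemLoop(3, "GAAA")
  loop <- loopOf(fx)
  fx2 <- makeStemLoop(3, "GAAAA")
  loop2 <- loopOf(fx2); loop2@id <- "other"
  res0 <- searchStructure(loop, list(loop, loop2), mode = "query_in_motif")
  # transform the query
  qm <- rigidCopy(fx$model, seed = 31)
  loopQ <- loopOf(list(model = qm, pairs = fx$pairs))
  res1 <- searchStructure(loopQ, list(loop, loop2), mode = "query_in_motif")
  expect_equal(vapply(res0, function(r) r@motifId, ""),
               vapply(res1, function(r) r@motifId, ""))
  expect_equal(vapply(res0, function(r) r@refinedRMSD, 1.0),
               vapply(res1, function(r) r@refinedRMSD, 1.0), tolerance = 1e-6)
})

test_that("motif-in-query requires every motif residue to have a counterpart", {
  fx <- makeStemLoop(4, "GAAA")
  loop <- loopOf(fx)
  # query = the full hairpin: loop is covered
  res <- searchStructure(fx$model, list(loop), mode = "motif_in_query",
                         rmsdThreshold = 0.5)
  expect_equal(length(res), 1L)
  expect_equal(sort(res[[1]]@correspondence$motif),
               sort(motifResidues(loop)))
  # query = stem only: the loop cannot be covered
  a <- atoms(fx$model)
  stemRes <- c(1:3, 10:12)
  sub <- a[a$resno %in% stemRes, ]
  qm <- new("StructureModel", entryId = "stemq", atoms = sub, crystal = list())
  res2 <- searchStructure(qm, list(loop), mode = "motif_in_query",
                          rmsdThreshold = 0.5)
  expect_equal(length(res2), 0L)
})

test_that("refinement never increases the all-backbone RMSD", {
  fx <- makeStemLoop(3, "GCAAA")
  loop <- loopOf(fx)
  for (s in 1:10) {
    noisy <- perturbMotif(loop, 0.15, seed = s)
    noisy@id <- paste0("n", s)
    res <- searchStructure(loop, list(noisy), mode = "query_in_motif",
                           rmsdThreshold = 1.0)
    if (length(res) == 0) next
    r <- res[[1]]
    # anchor transform applied to all backbone atoms can only be worse
    expect_lte(r@refinedRMSD, 1.0)
    expect_gt(r@anchorRMSD, 0)
  }
})

test_that("filtered search equals the brute-force oracle on small fixtures", {
  fx <- makeStemLoop(2, "GAAA")    # 8-nt hairpin
  loop <- loopOf(fx)
  qxyz <- rnamotifs:::selectedAtoms(loop, "C3'")$xyz
  fams <- list(
    list(makeStemLoop(2, "GAAA", entryId = "m1"), TRUE),
    list(makeStemLoop(2, "GCAA", entryId = "m2"), TRUE),
    list(makeStemLoop(2, "AAAA", stemSeq = "GC", entryId = "m3"), TRUE))
  motifs <- list(); truth <- logical(0)
  for (f in fams) {
    lp <- loopOf(f[[1]])
    motifs[[length(motifs) + 1]] <- lp
    truth <- c(truth, NA)
  }
  # add strongly perturbed versions
  for (s in 1:3) {
    lp <- perturbMotif(loop, 1.5, seed = 40 + s); lp@id <- paste0("p", s)
    motifs[[length(motifs) + 1]] <- lp
    truth <- c(truth, NA)
  }
  got <- searchStructure(loop, motifs, mode = "query_in_motif",
                         rmsdThreshold = 1.0)
  gotIds <- vapply(got, function(r) r@motifId, "")
  for (i in seq_along(motifs)) {
    mxyz <- rnamotifs:::selectedAtoms(motifs[[i]], "C3'")$xyz
    oracle <- bruteSearchMatch(qxyz, mxyz, threshold = 1.0)
    expect_equal(motifs[[i]]@id %in% gotIds, oracle,
                 info = motifs[[i]]@id)
  }
})
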