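# Contact detection (distance rule, categories, symmetry mates) and the
# reduced motif-interaction graph.

test_that("the 3.9 A heavy-atom rule is strict", {
  fx <- makeStemLoop(3, "GAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  loop <- motifs[[which(vapply(motifs, motifType, "") == "loop")]]
  am <- atoms(fx$model); am <- am[!am$hydrogen, ]
  edge <- am[which.max(am$x), ]
  at <- function(gap) c(edge$x + gap, edge$y, edge$z)
  near <- addHetAtom(fx$model, "HOH", "O", "O", at(3.89))
  got <- detectContacts(motifs, near)
  w <- got[got$partnerCategory == "water", ]
  expect_true(nrow(w) >= 1)
  expect_true(all(w$minDistance < 3.9))
  far <- addHetAtom(fx$model, "MG", "MG", "MG", at(3.91))
  got2 <- detectContacts(motifs, far)
  expect_equal(nrow(got2[got2$partnerCategory == "ion", ]), 0L)
})

test_that("contact distances equal a naive all-pairs scan", {
  fx <- makeStemLoop(3, "GCAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  m <- addHetAtom(fx$model, "HOH", "O", "O",
                  colMeans(as.matrix(atoms(fx$model)[, c("x", "y", "z")])) +
                    c(12, 0, 0))
  cts <- detectContacts(motifs, m)
  a <- atoms(m); a$resid <- rnamotifs:::resIdOf(a$chain, a$resno, a$icode)
  for (r in seq_len(nrow(cts))) {
    A <- as.matrix(a[a$resid == cts$resid[r] & !a$hydrogen, c("x", "y", "z")])
    B <- as.matrix(a[a$resid == cts$partner[r] & !a$hydrogen, c("x", "y", "z")])
    expect_equal(cts$minDistance[r], bruteMinDistances(A, B), tolerance = 1e-9)
  }
})

test_that("raising the cutoff never removes contacts", {
  fx <- makeStemLoop(3, "GAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  m <- addHetAtom(fx$model, "HOH", "O", "O",
                  as.numeric(atoms(fx$model)[1, c("x", "y", "z")]) + 3)
  c1 <- detectContacts(motifs, m, cutoff = 3.5)
  c2 <- detectContacts(motifs, m, cutoff = 3.9)
  key <- function(d) paste(d$motifId, d$resid, d$partner)
  expect_true(all(key(c1) %in% key(c2)))
})

test_that("protein contact through a symmetry mate is flagged", {
  fx <- makeStemLoop(3, "GCG")
  a <- atoms(fx$model)
  ah <- a[!a$hydrogen, ]
  # glycine placed one cell away so only the +a mate touches the RNA
  ext <- max(ah$x) - min(ah$x)
  cellA <- ext + 30
  gx <- max(ah$x) + 3.0 - cellA  # mate at +a lands 3.0 A from the RNA edge
  edge <- ah[which.max(ah$x), ]
  gly <- data.frame(het = FALSE, atom = c("N", "CA", "C", "O"), alt = "",
                    resname = "GLY", chain = "P", resno = 1, icode = "",
                    x = gx + c(0, 1.3, 2.1, 3.2), y = edge$y, z = edge$z,
                    occ = 1, element = c("N", "C", "C", "O"),
                    hydrogen = FALSE, stringsAsFactors = FALSE)
  am <- rbind(a, gly)
  m <- new("StructureModel", entryId = "sym", atoms = am,
           crystal = list(cell = c(cellA, 300, 300, 90, 90, 90),
                          spacegroup = "P 1",
                          symops = list(cbind(diag(3), c(0, 0, 0)))))
  motifs <- decomposeMotifs(m, pairs = fx$pairs)
  mates <- expandSymmetry(m, cutoff = 3.9)
  expect_true(length(mates) >= 1)
  cts <- detectContacts(motifs, m, mates = mates)
  prot <- cts[cts$partnerCategory == "protein", ]
  expect_true(nrow(prot) >= 1)
  expect_true(all(prot$viaSymmetry))
})

test_that("reduced graph: hairpin gives two nodes and one shared edge", {
  fx <- makeStemLoop(4, "GAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  rg <- buildReducedGraph(motifs)
  expect_equal(nrow(rg@nodes), 2L)
  expect_equal(nrow(rg@edges), 1L)
  expect_equal(rg@edges$type, "shared_residue")
})

test_that("docked hairpin loops create an intramolecular contact edge", {
  fx1 <- makeStemLoop(3, "GAAA")
  fx2 <- makeStemLoop(3, "GAAA", entryId = "hp2")
  # second hairpin: chain B, flipped to face the first loop, docked at 3.5 A
  a2 <- atoms(fx2$model); a2$chain <- "B"
  m2 <- new("StructureModel", entryId = "hp2",
            atoms = a2, crystal = list())
  m2 <- rnamotifs:::transformModel(m2, rnamotifs:::rotAxis(c(1, 0, 0), pi),
                                   c(0, 0, 60))
  m2 <- dockModels(fx1$model, m2, distance = 3.5)
  joint <- new("StructureModel", entryId = "dock",
               atoms = rbind(atoms(fx1$model), atoms(m2)), crystal = list())
  pairsB <- fx2$pairs
  pairsB$resA <- sub("^A:", "B:", pairsB$resA)
  pairsB$resB <- sub("^A:", "B:", pairsB$resB)
  motifs <- decomposeMotifs(joint, pairs = rbind(fx1$pairs, pairsB))
  cts <- detectContacts(motifs, joint)
  rg <- buildReducedGraph(motifs, cts)
  intra <- rg@edges[rg@edges$type == "intramolecular_contact", ]
  expect_true(nrow(intra) >= 1)
  # isolated motif stays isolated: single hairpin graph has no contact edges
  rg0 <- buildReducedGraph(decomposeMotifs(fx1$model, pairs = fx1$pairs),
                           detectContacts(decomposeMotifs(fx1$model,
                                                          pairs = fx1$pairs),
                                          fx1$model))
  expect_equal(sum(rg0@edges$type != "shared_residue"), 0L)
})

test_that("shared_residue edges equal nonzero residue-set intersections", {
  fx <- makeCloverleaf()
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  rg <- buildReducedGraph(motifs)
  ids <- vapply(motifs, function(m) m@id, "")
  for (i in seq_along(motifs)) for (j in seq_along(motifs)) {
    if (i >= j) next
    shared <- length(intersect(motifResidues(motifs[[i]]),
                               motifResidues(motifs[[j]]))) > 0
    inGraph <- any(rg@edges$type == "shared_residue" &
                   ((rg@edges$from == ids[i] & rg@edges$to == ids[j]) |
                    (rg@edges$from == ids[j] & rg@edges$to == ids[i])))
    expect_equal(inGraph, shared)
  }
})
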