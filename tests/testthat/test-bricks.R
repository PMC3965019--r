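# Motif decomposition: stems, loops, terminal fragments, invariants.

normBricks <- function(bricks) {
  # canonical form: type + sorted strand lengths + residue set
  out <- lapply(bricks, function(b) {
    strands <- if (is(b, "RNAMotif")) strands(b) else b$strands
    type <- if (is(b, "RNAMotif")) motifType(b) else b$type
    list(type = type,
         lens = sort(vapply(strands, length, 1L)),
         residues = sort(unique(unlist(strands))))
  })
  out[order(vapply(out, function(x)
    paste(x$type, paste(x$residues, collapse = ",")), ""))]
}

test_that("12-nt hairpin decomposes into a 4-bp stem and a terminal loop", {
  g <- graphFromTopology(12, dotBracketPairs("((((....))))"))
  motifs <- decomposeGraph(g)
  types <- sort(vapply(motifs, motifType, ""))
  expect_equal(types, c("loop", "stem"))
  stem <- motifs[[which(vapply(motifs, motifType, "") == "stem")]]
  loop <- motifs[[which(vapply(motifs, motifType, "") == "loop")]]
  expect_equal(length(motifResidues(stem)), 8L)
  expect_equal(nrow(closingPairs(stem)), 2L)
  expect_equal(length(motifResidues(loop)), 6L)
  expect_equal(motifClassLabel(loop), "terminal loop")
  # sharing: closing pair residues are in both motifs
  expect_equal(length(intersect(motifResidues(stem), motifResidues(loop))), 2L)
})

test_that("cloverleaf topology decomposes per construction", {
  # acceptor 3bp + three 3bp arms with 4-nt loops, 2-nt linkers, 2-nt tail
  db <- paste0("(((", "..", "(((....)))", "..", "(((....)))", "..",
               "(((....)))", "..", ")))", "..")
  g <- graphFromTopology(nchar(db), dotBracketPairs(db))
  motifs <- decomposeGraph(g)
  labels <- vapply(motifs, motifClassLabel, "")
  expect_equal(sum(labels == "stem"), 4L)
  expect_equal(sum(labels == "terminal loop"), 3L)
  expect_equal(sum(labels == "4wj"), 1L)
  expect_equal(sum(labels == "terminal fragment"), 1L)
  wj <- motifs[[which(labels == "4wj")]]
  expect_equal(vapply(strands(wj), length, 1L), rep(4L, 4))
})

test_that("lone pairs are not stems", {
  g <- graphFromTopology(8, dotBracketPairs("(......)"))
  motifs <- decomposeGraph(g)
  expect_equal(vapply(motifs, motifType, ""), "loop")
  # 1-bp helix fixture: no stem either
  fx <- makeHelix(1, "G")
  expect_equal(length(decomposeMotifs(fx$model, pairs = fx$pairs)), 0L)
})

test_that("bulges give internal loops; junction labels scale with strands", {
  db <- "((..((....))..))"
  g <- graphFromTopology(nchar(db), dotBracketPairs(db))
  motifs <- decomposeGraph(g)
  labels <- vapply(motifs, motifClassLabel, "")
  expect_true("internal loop" %in% labels)
  il <- motifs[[which(labels == "internal loop")[1]]]
  expect_equal(length(strands(il)), 2L)
  db3 <- "((..((...))..((...))..))"
  g3 <- graphFromTopology(nchar(db3), dotBracketPairs(db3))
  labels3 <- vapply(decomposeGraph(g3), motifClassLabel, "")
  expect_true("3wj" %in% labels3)
})

test_that("terminal fragments include the flanking paired residue", {
  db <- "..((....))..."
  g <- graphFromTopology(nchar(db), dotBracketPairs(db))
  motifs <- decomposeGraph(g)
  term <- motifs[vapply(motifs, motifType, "") == "terminal"]
  expect_equal(length(term), 2L)
  lens <- sort(vapply(term, function(m) length(motifResidues(m)), 1L))
  expect_equal(lens, c(3L, 4L))   # 2 + flanking, 3 + flanking
  for (tm in term) expect_equal(nrow(closingPairs(tm)), 1L)
})

test_that("inter-chain duplex pairs produce no single-chain motifs", {
  fx <- makeHelix(4, "GGCC")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  expect_equal(length(motifs), 0L)
})

test_that("coverage and sharing invariants hold on random topologies", {
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(15:40, 1)
    pk <- randomPairSet(n, sample(4:10, 1), rep * 7)
    kept <- removePseudoknots(pk)$kept
    if (nrow(kept) < 2) next
    g <- graphFromTopology(n, kept)
    motifs <- decomposeGraph(g)
    if (length(motifs) == 0) next
    # every paired residue belongs to >= 1 motif
    pairedRes <- as.character(unique(c(kept)))
    inMotifs <- unique(unlist(lapply(motifs, motifResidues)))
    expect_true(all(pairedRes %in% inMotifs))
    # sharing: motifs adjacent through a common closing pair overlap in
    # residues (full sharing on helical fixtures is covered elsewhere;
    # adversarial random sets can contain non-adjacent disjoint motifs)
    for (i in seq_along(motifs)) {
      if (motifType(motifs[[i]]) == "terminal") next
      cpi <- closingPairs(motifs[[i]])
      if (nrow(cpi) == 0) next
      for (j in seq_along(motifs)) {
        if (i == j) next
        cpj <- closingPairs(motifs[[j]])
        if (nrow(cpj) == 0) next
        if (length(intersect(paste(cpi$resA, cpi$resB),
                             paste(cpj$resA, cpj$resB))) > 0)
          expect_gt(length(intersect(motifResidues(motifs[[i]]),
                                     motifResidues(motifs[[j]]))), 0,
                    label = paste("rep", rep, i, j))
      }
    }
  }
})

test_that("decomposition is deterministic under atom-order permutation", {
  fx <- makeStemLoop(4, "GAAA")
  m1 <- decomposeMotifs(fx$model, pairs = fx$pairs)
  a <- atoms(fx$model)
  set.seed(5)
  m2 <- decomposeMotifs(new("StructureModel", entryId = "p",
                            atoms = a[sample(nrow(a)), ], crystal = list()),
                        pairs = fx$pairs)
  expect_equal(normBricks(m1), normBricks(m2))
})

test_that("full pipeline recovers fixture ground truth (annotation included)", {
  fx <- makeStemLoop(4, "GAAA")
  motifs <- decomposeMotifs(fx$model)   # pairs from annotation
  expect_equal(normBricks(motifs), normBricks(fx$bricks))
})
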