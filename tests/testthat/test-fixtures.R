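# Generator self-checks: geometry, determinism, ground-truth recovery.

test_that("helix geometry: rise, linkage, complementarity validation", {
  fx <- makeHelix(4, "GGGG")
  a <- atoms(fx$model)
  p <- as.matrix(a[a$atom == "P" & a$chain == "A", c("x", "y", "z")])
  pp <- sqrt(rowSums(diff(p)^2))
  expect_true(all(pp > 5.6 & pp < 6.0))
  # O3'-P linkage below the covalent cutoff on both strands
  for (ch in c("A", "B")) {
    rt <- residueTable(fx$model)
    resids <- rt$resid[rt$chain == ch]
    expect_true(all(rnamotifs:::covalentLinks(fx$model, resids)))
  }
  expect_error(makeHelix(2, "GG", sequence2 = "GG"), "non-complementary")
  expect_error(makeHelix(3, "GG"), "length")
})

test_that("generators are deterministic and seed-independent in topology", {
  f1 <- makeStemLoop(4, "GAAA")
  f2 <- makeStemLoop(4, "GAAA")
  expect_identical(atoms(f1$model), atoms(f2$model))
  expect_identical(f1$bricks, f2$bricks)
})

test_that("perturb and rigidCopy honor their seeds", {
  fx <- makeStemLoop(3, "GAAA")
  p1 <- perturbModel(fx$model, 0.3, seed = 4)
  p2 <- perturbModel(fx$model, 0.3, seed = 4)
  expect_identical(atoms(p1), atoms(p2))
  p3 <- perturbModel(fx$model, 0.3, seed = 5)
  expect_false(identical(atoms(p1), atoms(p3)))
  expect_identical(atoms(perturbModel(fx$model, 0, seed = 1)),
                   atoms(fx$model))
  r1 <- rigidCopy(fx$model, seed = 9)
  expect_identical(atoms(r1), atoms(rigidCopy(fx$model, seed = 9)))
  # rigid copy preserves all pairwise distances
  A <- as.matrix(atoms(fx$model)[, c("x", "y", "z")])
  B <- as.matrix(atoms(r1)[, c("x", "y", "z")])
  expect_equal(as.vector(dist(A[1:30, ])), as.vector(dist(B[1:30, ])),
               tolerance = 1e-9)
})

test_that("stem-loop ground truth is recovered across loop sizes", {
  normB <- function(bricks) {
    out <- lapply(bricks, function(b) {
      strands <- if (is(b, "RNAMotif")) strands(b) else b$strands
      type <- if (is(b, "RNAMotif")) motifType(b) else b$type
      list(type, sort(vapply(strands, length, 1L)),
           sort(unique(unlist(strands))))
    })
    out[order(vapply(out, function(x) paste(x[[1]], paste(x[[3]], collapse = ",")), ""))]
  }
  for (cfg in list(c(2, 3), c(3, 4), c(4, 6), c(5, 8))) {
    fx <- makeStemLoop(cfg[1], paste(rep("A", cfg[2]), collapse = ""))
    motifs <- decomposeMotifs(fx$model)
    expect_equal(normB(motifs), normB(fx$bricks),
                 info = paste(cfg, collapse = "/"))
  }
  expect_error(makeStemLoop(3, "AA"), "at least 3")
})

test_that("stem-loop survives moderate coordinate noise", {
  fx <- makeStemLoop(4, "GAAA")
  normB <- function(bricks) {
    lapply(bricks, function(b) {
      strands <- if (is(b, "RNAMotif")) strands(b) else b$strands
      sort(unique(unlist(strands)))
    })
  }
  m <- perturbModel(fx$model, 0.1, seed = 12)
  motifs <- decomposeMotifs(m)
  expect_setequal(unlist(normB(motifs)), unlist(normB(fx$bricks)))
})

test_that("cloverleaf: ground truth bricks, clash-free, reduced graph", {
  fx <- makeCloverleaf()
  motifs <- decomposeMotifs(fx$model)
  labels <- sort(vapply(motifs, motifClassLabel, ""))
  expect_equal(sum(labels == "stem"), 4L)
  expect_equal(sum(labels == "terminal loop"), 3L)
  expect_equal(sum(labels == "4wj"), 1L)
  expect_equal(sum(labels == "terminal fragment"), 1L)
  normB <- function(bricks) {
    out <- lapply(bricks, function(b) {
      strands <- if (is(b, "RNAMotif")) strands(b) else b$strands
      type <- if (is(b, "RNAMotif")) motifType(b) else b$type
      list(type, sort(vapply(strands, length, 1L)),
           sort(unique(unlist(strands))))
    })
    out[order(vapply(out, function(x) paste(x[[1]], paste(x[[3]], collapse = ",")), ""))]
  }
  expect_equal(normB(motifs), normB(fx$bricks))
  expect_equal(clashScore(fx$model), 0)
  rg <- buildReducedGraph(motifs)
  expect_equal(nrow(rg@nodes), length(motifs))
  # each hairpin loop shares residues with its stem
  expect_gte(sum(rg@edges$type == "shared_residue"), 8L)
})
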