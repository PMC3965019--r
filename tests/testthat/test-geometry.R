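# Rigid superposition, composition keys, clustering.

test_that("kabsch recovers an exact rigid copy", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  R <- rotAxis(c(0, 0, 1), 37 * pi/180)
  Q <- sweep(P %*% t(R), 2, -c(1, 2, 3))
  fit <- kabschSuperpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-9)
})

test_that("kabsch is optimal against a random-rotation oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  Q <- P; Q[4, ] <- Q[4, ] + c(0, 0, 1)
  fit <- kabschSuperpose(P, Q)
  oracle <- randomRotationRMSD(P, Q, n = 1000)
  expect_lte(fit$rmsd, oracle + 1e-9)
  # on random point sets too
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(18), 6, 3)
    B <- matrix(rnorm(18), 6, 3)
    expect_lte(kabschSuperpose(A, B)$rmsd, randomRotationRMSD(A, B, 200) + 1e-9)
  }
})

test_that("mirror images of a chiral set keep positive RMSD", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P; Q[, 3] <- -Q[, 3]
  expect_gt(kabschSuperpose(P, Q)$rmsd, 0.1)
})

test_that("degenerate point sets are rejected", {
  P <- cbind(1:4, 0, 0); Q <- cbind(4:1, 0, 0)
  expect_error(kabschSuperpose(P, Q + 0), "degenerate|collinear")
  expect_error(kabschSuperpose(P[1:2, ], Q[1:2, ]), "at least 3")
})

test_that("composition keys respect type and cyclic strand order", {
  fx <- makeStemLoop(4, "GAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  types <- vapply(motifs, motifType, "")
  stem <- motifs[[which(types == "stem")]]
  loop <- motifs[[which(types == "loop")]]
  expect_match(compositionKey(stem), "^stem:")
  expect_match(compositionKey(loop), "^loop:6$")
  expect_false(compositionKey(stem) == compositionKey(loop))
  # cyclic rotation: internal loop strands (3,5) vs (5,3) share a key
  mkLoop <- function(lens) {
    st <- list(paste0("A:", seq_len(lens[1])),
               paste0("A:", 100 + seq_len(lens[2])))
    new("RNAMotif", id = "x", type = "loop", strands = st,
        closingPairs = data.frame(resA = "A:1", resB = "A:101"),
        residues = unlist(st), atoms = data.frame())
  }
  expect_equal(compositionKey(mkLoop(c(3, 5))), compositionKey(mkLoop(c(5, 3))))
  expect_false(compositionKey(mkLoop(c(3, 5))) == compositionKey(mkLoop(c(4, 4))))
})

test_that("backbone RMSD: identity, rigid copies and noisy copies", {
  fx <- makeStemLoop(3, "GAAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  loop <- motifs[[which(vapply(motifs, motifType, "") == "loop")]]
  expect_equal(backboneRMSD(loop, loop), 0, tolerance = 1e-12)
  rc <- rigidCopy(fx$model, seed = 5)
  loop2 <- decomposeMotifs(rc, pairs = fx$pairs)[[2]]
  expect_lt(backboneRMSD(loop, loop2), 1e-9)
  # Gaussian noise sigma = 0.3 per coordinate: rmsd concentrates around
  # sigma * sqrt(3) (~0.52 A) after the rigid fit removes a few degrees of
  # freedom; a generous band around that scale holds for most seeds
  rms <- vapply(1:20, function(s) {
    backboneRMSD(loop, perturbMotif(loop, 0.3, seed = s))
  }, 1.0)
  expect_true(mean(rms > 0.35 & rms < 0.68) >= 0.9)
})

test_that("complete-linkage clustering keeps every pair under the threshold", {
  fx <- makeStemLoop(3, "GCAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  loop <- motifs[[which(vapply(motifs, motifType, "") == "loop")]]
  fam <- list(loop)
  for (s in 1:6)
    fam[[length(fam) + 1]] <- perturbMotif(loop, 0.25, seed = s)
  cl <- clusterMotifs(fam, threshold = 1.0)
  for (cc in cl) {
    if (length(clusterMembers(cc)) > 1)
      expect_lt(max(cc@rmsd), 1.0)
    # medoid minimizes summed RMSD (checked exhaustively)
    sums <- rowSums(cc@rmsd)
    expect_lte(sums[cc@medoid], min(sums) + 1e-9)
  }
})

test_that("three identical copies form one cluster; far copies split", {
  fx <- makeStemLoop(3, "GAAA")
  motifs <- decomposeMotifs(fx$model, pairs = fx$pairs)
  loop <- motifs[[which(vapply(motifs, motifType, "") == "loop")]]
  copies <- list(loop,
                 decomposeMotifs(rigidCopy(fx$model, 2), pairs = fx$pairs)[[2]],
                 decomposeMotifs(rigidCopy(fx$model, 3), pairs = fx$pairs)[[2]])
  cl <- clusterMotifs(copies)
  expect_equal(length(cl), 1L)
  expect_equal(length(clusterMembers(cl[[1]])), 3L)
  expect_equal(cl[[1]]@medoid, 1L)
  # strong perturbation splits
  loopFar <- perturbMotif(loop, 1.2, seed = 9)
  if (backboneRMSD(loop, loopFar) >= 1.0) {
    cl2 <- clusterMotifs(list(loop, loopFar))
    expect_equal(length(cl2), 2L)
  }
})
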