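# Hydrogen placement, hydrogen bonds, base-pair classification, stacking.

test_that("polar hydrogens are placed at idealized N-H geometry", {
  fx <- makeHelix(2, "GC")
  a <- atoms(fx$model)
  noH <- new("StructureModel", entryId = "noH", atoms = a[!a$hydrogen, ],
             crystal = list())
  withH <- placePolarHydrogens(noH)
  b <- atoms(withH)
  g1 <- b[b$chain == "A" & b$resno == 1, ]
  expect_true(all(c("H1", "H21", "H22") %in% g1$atom))
  for (h in c("H1", "H21", "H22")) {
    hx <- as.numeric(g1[g1$atom == h, c("x", "y", "z")])
    nn <- as.numeric(g1[g1$atom == ifelse(h == "H1", "N1", "N2"),
                        c("x", "y", "z")])
    expect_equal(sqrt(sum((hx - nn)^2)), 1.01, tolerance = 0.02)
  }
  # already protonated: unchanged atom count
  expect_equal(nrow(atoms(placePolarHydrogens(fx$model))),
               nrow(atoms(fx$model)))
  # water: no hydrogens placed
  w <- addHetAtom(noH, "HOH", "O", "O", c(50, 50, 50))
  expect_equal(sum(atoms(placePolarHydrogens(w))$resname == "HOH"), 1L)
})

test_that("ideal G.C geometry yields exactly the three canonical H-bonds", {
  fx <- makeHelix(1, "G")
  hb <- detectHBonds(fx$model)
  basePairs <- hb[hb$donorAtom %in% c("N1", "N2", "N4") |
                  hb$acceptorAtom %in% c("O6", "N3", "O2"), ]
  key <- paste(pmin(basePairs$donorAtom, basePairs$acceptorAtom),
               pmax(basePairs$donorAtom, basePairs$acceptorAtom))
  expect_setequal(unique(key), c("N4 O6", "N1 N3", "N2 O2"))
})

test_that("hydrogen-bond detection agrees with the brute-force oracle", {
  fx <- makeStemLoop(3, "GCAA")
  hb <- detectHBonds(fx$model)
  got <- sort(paste(hb$donorRes, hb$donorAtom, hb$acceptorRes, hb$acceptorAtom))
  expect_equal(got, bruteHBondScan(fx$model))
})

test_that("distance and angle gates reject non-bonds", {
  # two waters 5 A apart: no bond
  m0 <- makeHelix(2, "GC")$model
  w <- addHetAtom(addHetAtom(m0, "HOH", "O", "O", c(60, 0, 0)),
                  "HOH", "O", "O", c(65, 0, 0))
  hb <- detectHBonds(w)
  wre <- hb[grepl("^Z", hb$donorRes) & grepl("^Z", hb$acceptorRes), ]
  expect_equal(nrow(wre), 0L)
  # D-H pointing away: rejected even though D-A is close
  txt <- paste(
    "ATOM      1  N3    U A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H3    U A   1      -0.700  -0.700   0.000  1.00  0.00           H",
    "ATOM      3  C2    U A   1       0.700  -1.100   0.000  1.00  0.00           C",
    "ATOM      4  C4    U A   1       0.700   1.100   0.000  1.00  0.00           C",
    "ATOM      5  N1    A B   1       3.000   0.000   0.000  1.00  0.00           N",
    sep = "\n")
  m <- readStructure(txt)
  hb2 <- detectHBonds(m)
  expect_false(any(hb2$donorAtom == "N3" & hb2$acceptorAtom == "N1"))
})

test_that("pair classification: WC, wobble, and stacked neighbors", {
  gc <- annotateStructure(makeHelix(2, "GC")$model, addHydrogens = FALSE)
  expect_setequal(gc$pairs$klass, "canonical_wc")
  au <- annotateStructure(makeHelix(2, "AU")$model, addHydrogens = FALSE)
  expect_setequal(au$pairs$klass, "canonical_wc")
  wob <- annotateStructure(makeHelix(2, "GU", sequence2 = "GU")$model,
                           addHydrogens = FALSE)
  expect_true(all(c("wobble") %in% wob$pairs$klass))
  # consecutive residues on one strand never classify as paired
  hel <- annotateStructure(makeHelix(4, "GCGC")$model, addHydrogens = FALSE)
  sameChain <- substr(hel$pairs$resA, 1, 1) == substr(hel$pairs$resB, 1, 1)
  expect_false(any(sameChain))
})

test_that("pair relation is symmetric with identical class", {
  fx <- makeStemLoop(4, "GAAA")
  ann <- annotateStructure(fx$model, addHydrogens = FALSE)
  p <- ann$pairs
  key1 <- paste(p$resA, p$resB); key2 <- paste(p$resB, p$resA)
  expect_equal(length(intersect(key1, key2)), 0L)  # each pair reported once
  # recomputing from a residue-permuted model gives the same pair set
  a <- atoms(fx$model)
  set.seed(3)
  perm <- a[sample(nrow(a)), ]
  m2 <- new("StructureModel", entryId = "perm", atoms = perm, crystal = list())
  p2 <- annotateStructure(m2, addHydrogens = FALSE)$pairs
  norm <- function(d) sort(paste(pmin(d$resA, d$resB), pmax(d$resA, d$resB), d$klass))
  expect_equal(norm(p2[p2$klass != "other", ]), norm(p[p$klass != "other", ]))
})

test_that("fixture duplex pairs are recovered exactly, with no extras", {
  for (seq in c("GGCC", "AUGC", "GCAU")) {
    fx <- makeHelix(4, seq)
    ann <- annotateStructure(fx$model, addHydrogens = FALSE)
    got <- ann$pairs[ann$pairs$klass %in% c("canonical_wc", "wobble"), ]
    norm <- function(d) sort(paste(pmin(d$resA, d$resB), pmax(d$resA, d$resB)))
    expect_equal(norm(got), norm(fx$pairs), info = seq)
  }
})

test_that("stacking: helix neighbors stack, WC partners and far bases do not", {
  fx <- makeHelix(4, "GCGC")
  st <- detectStacking(fx$model)
  key <- paste(st$resA, st$resB)
  expect_true(all(paste(paste0("A:", 1:3), paste0("A:", 2:4)) %in% key))
  p <- annotateStructure(fx$model, addHydrogens = FALSE)$pairs
  expect_false(any(paste(p$resA, p$resB) %in% key |
                   paste(p$resB, p$resA) %in% key))
  # residues far apart never stack
  expect_false(any(st$centroidDistance > 5.5))
})
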