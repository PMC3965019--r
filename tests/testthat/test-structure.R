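# PDB reading/writing, chain eligibility, symmetry expansion.

test_that("hand-written ATOM lines parse into one residue with two atoms", {
  txt <- paste(
    "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00  0.00           P",
    "ATOM      2  O5'   G A   1       2.400   2.000   3.000  1.00  0.00           O",
    sep = "\n")
  m <- readStructure(txt)
  expect_s4_class(m, "StructureModel")
  expect_equal(nrow(atoms(m)), 2L)
  rt <- residueTable(m)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$resname, "G")
  expect_equal(rt$category, "rna")
  expect_equal(length(crystalFrame(m)), 0L)
})

test_that("round-trip write/read preserves counts, names and coordinates", {
  fx <- makeStemLoop(3, "GAAA")
  tf <- tempfile(fileext = ".pdb")
  writeStructure(fx$model, tf)
  m2 <- readStructure(tf)
  a1 <- atoms(fx$model); a2 <- atoms(m2)
  expect_equal(nrow(a2), nrow(a1))
  expect_equal(a2$atom, a1$atom)
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$y, a1$y, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
})

test_that("independent PDB reader agrees on the written file", {
  skip_if_not_installed("bio3d")
  fx <- makeHelix(3, "GCG")
  tf <- tempfile(fileext = ".pdb")
  writeStructure(fx$model, tf)
  ref <- bio3d::read.pdb(tf)
  a <- atoms(fx$model)
  expect_equal(nrow(ref$atom), nrow(a))
  expect_equal(ref$atom$x, a$x, tolerance = 1e-3)
  expect_equal(trimws(ref$atom$elety), a$atom)
})

test_that("format errors are reported with the offending line", {
  expect_error(readStructure("   \n  "), "empty")
  bad <- "ATOM      1  P     G A   1       xxx     2.000   3.000  1.00  0.00           P"
  expect_error(readStructure(bad), "unparsable ATOM")
})

test_that("altloc policy keeps blank/'A' and resolves by occupancy", {
  txt <- paste(
    pdbLine(1, "P", " ", "  G", "A", 1, 1, 2, 3, occ = 0.4, elem = "P"),
    pdbLine(2, "P", "A", "  G", "A", 1, 9, 9, 9, occ = 0.6, elem = "P"),
    pdbLine(3, "P", "B", "  G", "A", 1, 5, 5, 5, occ = 0.9, elem = "P"),
    pdbLine(4, "O5'", "A", "  G", "A", 1, 2.4, 2, 3, occ = 0.7, elem = "O"),
    sep = "\n")
  m <- readStructure(txt)
  a <- atoms(m)
  expect_equal(nrow(a), 2L)             # B dropped; duplicate P resolved
  expect_equal(a$x[a$atom == "P"], 9.0) # higher occupancy wins
})

test_that("only the first MODEL is read", {
  fx <- makeHelix(2, "GC")
  l1 <- writeStructure(fx$model)
  body <- l1[!grepl("^END", l1)]
  txt <- c("MODEL        1", body, "ENDMDL", "MODEL        2", body, "ENDMDL")
  m <- readStructure(paste(txt, collapse = "\n"))
  expect_equal(nrow(atoms(m)), nrow(atoms(fx$model)))
})

test_that("chain eligibility follows the two-residue all-atom rule", {
  fx <- makeHelix(4, "GGGG")
  expect_setequal(eligibleRNAChains(fx$model), c("A", "B"))
  # single ribonucleotide chain: excluded
  a <- atoms(fx$model)
  one <- new("StructureModel", entryId = "one",
             atoms = a[a$chain == "A" & a$resno == 1, ], crystal = list())
  expect_equal(length(eligibleRNAChains(one)), 0L)
  # P-only backbone trace: excluded (not all-atom)
  trace <- a[a$atom == "P", ]
  tm <- new("StructureModel", entryId = "trace", atoms = trace,
            crystal = list())
  expect_equal(length(eligibleRNAChains(tm)), 0L)
})

test_that("eligibility is monotone under atom deletion", {
  fx <- makeHelix(3, "GCG")
  a <- atoms(fx$model)
  set.seed(11)
  for (i in 1:5) {
    sub <- a[sample(nrow(a), nrow(a) - 15), ]
    m <- new("StructureModel", entryId = "sub", atoms = sub, crystal = list())
    el <- eligibleRNAChains(m)
    expect_true(all(el %in% eligibleRNAChains(fx$model)))
  }
})

test_that("CRYST1 parses and survives a round-trip", {
  fx <- makeHelix(3, "GGG", cell = c(100, 90, 80, 90, 90, 90))
  tf <- tempfile(fileext = ".pdb")
  writeStructure(fx$model, tf)
  m2 <- readStructure(tf)
  cr <- crystalFrame(m2)
  expect_equal(cr$cell, c(100, 90, 80, 90, 90, 90))
  expect_equal(length(cr$symops), 1L)
})

test_that("symmetry expansion in P1: a cell-width neighbor appears", {
  fx <- makeHelix(3, "GGG")
  a <- atoms(fx$model)
  # cell sized so the +a lattice copy sits 3 A from the model
  cell <- c(cellEdgeForGap(fx$model, 3.0), 500, 500, 90, 90, 90)
  m <- new("StructureModel", entryId = "p1", atoms = a,
           crystal = list(cell = cell, spacegroup = "P 1",
                          symops = list(cbind(diag(3), c(0, 0, 0)))))
  mates <- expandSymmetry(m, cutoff = 5)
  shifts <- t(vapply(mates, function(x) x@latticeShift, integer(3)))
  expect_true(any(abs(shifts[, 1]) == 1 & shifts[, 2] == 0 & shifts[, 3] == 0))
  expect_true(all(shifts[, 2] == 0 & shifts[, 3] == 0))
  # huge cell: nothing within cutoff
  m2 <- new("StructureModel", entryId = "p1b", atoms = a,
            crystal = list(cell = c(500, 500, 500, 90, 90, 90),
                           spacegroup = "P 1",
                           symops = list(cbind(diag(3), c(0, 0, 0)))))
  expect_equal(length(expandSymmetry(m2, cutoff = 5)), 0L)
  expect_equal(length(expandSymmetry(m, cutoff = 0)), 0L)
  expect_error(expandSymmetry(makeHelix(2, "GC")$model), "no crystal")
})

test_that("symmetry expansion is invariant under a full lattice shift", {
  fx <- makeHelix(3, "GGG")
  a <- atoms(fx$model)
  cell <- c(cellEdgeForGap(fx$model, 3.0), 400, 400, 90, 90, 90)
  cf <- list(cell = cell, spacegroup = "P 1",
             symops = list(cbind(diag(3), c(0, 0, 0))))
  m <- new("StructureModel", entryId = "p1", atoms = a, crystal = cf)
  a2 <- a; a2$x <- a2$x + cell[1]   # shift by one full cell
  mShift <- new("StructureModel", entryId = "p1s", atoms = a2, crystal = cf)
  d1 <- vapply(expandSymmetry(m, 5), function(x)
    min(rnamotifs:::crossDist(
      as.matrix(atoms(x@model)[, c("x", "y", "z")]),
      as.matrix(a[, c("x", "y", "z")]))), 1.0)
  d2 <- vapply(expandSymmetry(mShift, 5), function(x)
    min(rnamotifs:::crossDist(
      as.matrix(atoms(x@model)[, c("x", "y", "z")]),
      as.matrix(a2[, c("x", "y", "z")]))), 1.0)
  expect_equal(sort(d1), sort(d2), tolerance = 1e-6)
})
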