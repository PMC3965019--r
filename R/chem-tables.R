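# Residue and atom chemistry tables. Modified ribonucleotides map to a
# lower-case parent letter (RNAView-style one-letter convention), so "u"
# stands for m5U, m2U and any other uridine modification.

STANDARD_RNA <- c("A", "C", "G", "U")

# modified ribonucleotide -> parent base (not exhaustive; extend as needed)
MODIFIED_RNA <- c(
  "1MA" = "A", "2MA" = "A", "6MA" = "A", "MIA" = "A", "T6A" = "A", "RIA" = "A",
  "A2M" = "A", "MA6" = "A", "12A" = "A", "I"   = "A", "2MG" = "G", "7MG" = "G",
  "M2G" = "G", "OMG" = "G", "YG"  = "G", "G7M" = "G", "GTP" = "G", "GDP" = "G",
  "1MG" = "G", "QUO" = "G", "YYG" = "G", "5MC" = "C", "OMC" = "C", "4OC" = "C",
  "5IC" = "C", "CBV" = "C", "M4C" = "C", "5MU" = "U", "H2U" = "U", "PSU" = "U",
  "4SU" = "U", "OMU" = "U", "2MU" = "U", "70U" = "U", "DHU" = "U", "UR3" = "U",
  "3MU" = "U", "S4U" = "U"
)

AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "CSO", "HYP", "MLY"
)

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "D2O")

MONATOMIC_IONS <- c(
  "MG", "NA", "K", "ZN", "MN", "CL", "CA", "FE", "FE2", "CO", "NI", "CU",
  "CD", "SR", "CS", "BR", "F", "BA", "RB", "LI", "HG", "PB", "PT", "AU",
  "AG", "TL", "IOD", "YB", "OS", "IR", "SM", "EU", "LU", "AL", "GA", "IN"
)

#' Classify a residue name into a molecular category
#'
#' Categories follow the convention used for contact annotation: \code{rna},
#' \code{protein}, \code{water}, \code{ion} or \code{ligand}.
#'
#' @param resname character vector of 3-or-fewer-letter residue names
#' @return character vector of categories
#' @export
residueCategory <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("ligand", length(resname))
  out[resname %in% c(STANDARD_RNA, names(MODIFIED_RNA))] <- "rna"
  out[resname %in% AMINO_ACIDS] <- "protein"
  out[resname %in% WATER_NAMES] <- "water"
  out[resname %in% MONATOMIC_IONS] <- "ion"
  out
}

#' One-letter code for a ribonucleotide residue name
#'
#' Standard residues give upper-case letters; known modified ribonucleotides
#' give the lower-case letter of the parent base; anything else gives
#' \code{NA}.
#'
#' @param resname character vector of residue names
#' @return character vector of one-letter codes
#' @export
rnaOneLetter <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep(NA_character_, length(resname))
  std <- resname %in% STANDARD_RNA
  out[std] <- resname[std]
  mod <- resname %in% names(MODIFIED_RNA)
  out[mod] <- tolower(MODIFIED_RNA[resname[mod]])
  out
}

# parent base letter (upper case) for standard or modified ribonucleotides
rnaParentBase <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep(NA_character_, length(resname))
  std <- resname %in% STANDARD_RNA
  out[std] <- resname[std]
  mod <- resname %in% names(MODIFIED_RNA)
  out[mod] <- MODIFIED_RNA[resname[mod]]
  out
}

# expected heavy atoms for an unmodified ribonucleotide (all-atom check);
# the 5' phosphate group is listed separately since chain-initial residues
# may legitimately lack it.
RNA_SUGAR_ATOMS <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
RNA_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2")
RNA_BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "N6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "O6", "N2"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

# base ring atoms used for plane/centroid computations
RNA_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# hydrogen-bond donor atoms (heavy) with attached polar hydrogens, and
# acceptor atoms, per parent base; sugar/phosphate entries shared.
RNA_HB_DONORS <- list(
  A = list("N6" = c("H61", "H62")),
  G = list("N1" = "H1", "N2" = c("H21", "H22")),
  C = list("N4" = c("H41", "H42")),
  U = list("N3" = "H3")
)
RNA_HB_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"),
  G = c("O6", "N7", "N3"),
  C = c("O2", "N3"),
  U = c("O2", "O4")
)
SUGAR_DONORS <- list("O2'" = character(0))     # hydroxyl H not placed
SUGAR_ACCEPTORS <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2")

PROTEIN_DONORS <- list(
  backbone = list("N" = "H"),
  ARG = list("NE" = "HE", "NH1" = c("HH11", "HH12"), "NH2" = c("HH21", "HH22")),
  LYS = list("NZ" = c("HZ1", "HZ2", "HZ3")),
  ASN = list("ND2" = c("HD21", "HD22")),
  GLN = list("NE2" = c("HE21", "HE22")),
  HIS = list("ND1" = "HD1", "NE2" = "HE2"),
  TRP = list("NE1" = "HE1"),
  SER = list("OG" = character(0)),
  THR = list("OG1" = character(0)),
  TYR = list("OH" = character(0)),
  CYS = list("SG" = character(0))
)
PROTEIN_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

# van der Waals radii (Angstrom) for clash scoring
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73,
               "NA" = 2.27, K = 2.75, ZN = 1.39, MN = 1.73, CA = 2.31,
               FE = 1.63)
VDW_DEFAULT <- 1.70

# Watson-Crick / wobble hydrogen-bond patterns between parent bases.
# Each row: donor-side base, donor/acceptor atom in first base, partner atom.
WC_PATTERNS <- list(
  "G:C" = list(atoms = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")), min = 2, klass = "canonical_wc"),
  "A:U" = list(atoms = list(c("N1", "N3"), c("N6", "O4")), min = 2, klass = "canonical_wc"),
  "G:U" = list(atoms = list(c("O6", "N3"), c("N1", "O2")), min = 2, klass = "wobble")
)
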