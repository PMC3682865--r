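## Built-in chemical reference data: residue topology (hydrogen -> parent
## heavy atom), atom-name dialect tables, aromatic ring definitions,
## van der Waals radii, a minimal partial-charge set, force-field-style
## atom typing, and the random-coil shift table.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Translate residue codes between 1- and 3-letter form
#' @param x Character vector of residue codes.
#' @return Translated codes; unknown residues become "X" / "UNK".
#' @export
threeToOne <- function(x) {
  out <- .AA1[match(toupper(x), .AA3)]
  out[is.na(out)] <- "X"
  out
}

#' @rdname threeToOne
#' @export
oneToThree <- function(x) {
  out <- .AA3[match(toupper(x), .AA1)]
  out[is.na(out)] <- "UNK"
  out
}

## Side-chain heavy atoms per residue (backbone N, CA, C, O implicit).
.SIDE_HEAVY <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

## Hydrogens in PDB-v3 / NMRStar spelling with their parent heavy atom.
## The backbone amide H (parent N) is present for all residues but PRO;
## HA (GLY: HA2/HA3) sits on CA.
.hyd <- function(...) {
  v <- c(...)
  if (is.null(v))
    return(data.frame(name = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  stopifnot(length(v) %% 2 == 0)
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(name = m[, 1], parent = m[, 2], stringsAsFactors = FALSE)
}

.SIDE_H <- list(
  ALA = .hyd("HB1", "CB", "HB2", "CB", "HB3", "CB"),
  ARG = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG",
             "HD2", "CD", "HD3", "CD", "HE", "NE",
             "HH11", "NH1", "HH12", "NH1", "HH21", "NH2", "HH22", "NH2"),
  ASN = .hyd("HB2", "CB", "HB3", "CB", "HD21", "ND2", "HD22", "ND2"),
  ASP = .hyd("HB2", "CB", "HB3", "CB"),
  CYS = .hyd("HB2", "CB", "HB3", "CB", "HG", "SG"),
  GLN = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG",
             "HE21", "NE2", "HE22", "NE2"),
  GLU = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG"),
  GLY = .hyd(),
  HIS = .hyd("HB2", "CB", "HB3", "CB", "HD1", "ND1", "HD2", "CD2",
             "HE1", "CE1", "HE2", "NE2"),
  ILE = .hyd("HB", "CB", "HG12", "CG1", "HG13", "CG1",
             "HG21", "CG2", "HG22", "CG2", "HG23", "CG2",
             "HD11", "CD1", "HD12", "CD1", "HD13", "CD1"),
  LEU = .hyd("HB2", "CB", "HB3", "CB", "HG", "CG",
             "HD11", "CD1", "HD12", "CD1", "HD13", "CD1",
             "HD21", "CD2", "HD22", "CD2", "HD23", "CD2"),
  LYS = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG",
             "HD2", "CD", "HD3", "CD", "HE2", "CE", "HE3", "CE",
             "HZ1", "NZ", "HZ2", "NZ", "HZ3", "NZ"),
  MET = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG",
             "HE1", "CE", "HE2", "CE", "HE3", "CE"),
  PHE = .hyd("HB2", "CB", "HB3", "CB", "HD1", "CD1", "HD2", "CD2",
             "HE1", "CE1", "HE2", "CE2", "HZ", "CZ"),
  PRO = .hyd("HB2", "CB", "HB3", "CB", "HG2", "CG", "HG3", "CG",
             "HD2", "CD", "HD3", "CD"),
  SER = .hyd("HB2", "CB", "HB3", "CB", "HG", "OG"),
  THR = .hyd("HB", "CB", "HG1", "OG1",
             "HG21", "CG2", "HG22", "CG2", "HG23", "CG2"),
  TRP = .hyd("HB2", "CB", "HB3", "CB", "HD1", "CD1", "HE1", "NE1",
             "HE3", "CE3", "HZ2", "CZ2", "HZ3", "CZ3", "HH2", "CH2"),
  TYR = .hyd("HB2", "CB", "HB3", "CB", "HD1", "CD1", "HD2", "CD2",
             "HE1", "CE1", "HE2", "CE2", "HH", "OH"),
  VAL = .hyd("HB", "CB", "HG11", "CG1", "HG12", "CG1", "HG13", "CG1",
             "HG21", "CG2", "HG22", "CG2", "HG23", "CG2")
)

## Full hydrogen table for one residue: backbone + side chain, v3 names.
.residueHydrogens <- function(res) {
  res <- toupper(res)
  if (!res %in% .AA3) stop("unknown residue type: ", res)
  bb <- if (res == "GLY") {
    .hyd("H", "N", "HA2", "CA", "HA3", "CA")
  } else if (res == "PRO") {
    .hyd("HA", "CA")
  } else {
    .hyd("H", "N", "HA", "CA")
  }
  rbind(bb, .SIDE_H[[res]])
}

.residueHeavyAtoms <- function(res) {
  res <- toupper(res)
  if (!res %in% .AA3) stop("unknown residue type: ", res)
  c("N", "CA", "C", "O", .SIDE_HEAVY[[res]])
}

## Aromatic ring member sets and relative ring-current intensities.
## TRP contributes two rings (five- and six-membered), HIS one.
.RING_DEFS <- list(
  PHE = list(list(members = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  intensity = 1.00)),
  TYR = list(list(members = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  intensity = 0.84)),
  HIS = list(list(members = c("CG", "ND1", "CD2", "CE1", "NE2"),
                  intensity = 0.90)),
  TRP = list(list(members = c("CG", "CD1", "NE1", "CE2", "CD2"),
                  intensity = 1.04),
             list(members = c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
                  intensity = 1.02))
)

## van der Waals radii (Angstrom) by element, for surface computation
## and the clash term of the nonbonded structure-quality score.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

## Minimal unit-scaled partial charge set (elementary charges): backbone
## polar group plus charged side-chain termini. Atoms not listed carry
## zero charge for the electric-field term.
.PARTIAL_CHARGES <- c(
  C = 0.597, O = -0.568, N = -0.416, H = 0.272,
  OD1 = -0.5, OD2 = -0.5, OE1 = -0.5, OE2 = -0.5,
  NZ = 0.7, HZ1 = 0.1, HZ2 = 0.1, HZ3 = 0.1,
  NH1 = 0.45, NH2 = 0.45
)

.elementOf <- function(atom_name) {
  nm <- toupper(gsub("[^A-Z]", "", atom_name))
  first <- substr(gsub("^[0-9]+", "", toupper(atom_name)), 1, 1)
  if (first == "H") return("H")
  if (startsWith(nm, "S")) return("S")
  first
}

## Amber-flavoured atom typing keyed by (residue, v3 atom name). Coarse
## but deterministic; feeds the ff_atom_type feature and auto-clustering.
.ffAtomType <- function(residue_type, atom_name) {
  res <- toupper(residue_type)
  v3 <- tryCatch(convertAtomName(res, atom_name, to = "pdbv3"),
                 error = function(e) toupper(atom_name))
  aromatic <- character(0)
  if (res %in% names(.RING_DEFS))
    aromatic <- unique(unlist(lapply(.RING_DEFS[[res]], `[[`, "members")))
  if (v3 == "N") return("N")
  if (v3 == "CA") return("CX")
  if (v3 == "C") return("C")
  if (v3 == "O") return("O")
  if (v3 == "H") return("H")
  if (v3 == "HA" || v3 %in% c("HA2", "HA3")) return("H1")
  el <- .elementOf(v3)
  if (el == "S") return(if (res == "MET") "S" else "SH")
  if (el == "O") {
    if (v3 %in% c("OD1", "OD2", "OE1", "OE2"))
      return(if (res %in% c("ASN", "GLN")) "O" else "O2")
    return("OH")
  }
  if (el == "N") {
    if (v3 == "NZ") return("N3")
    if (v3 %in% c("NE", "NH1", "NH2")) return("N2")
    if (res == "HIS") return("NB")
    if (v3 == "NE1") return("NA")
    return("N")
  }
  if (el == "C") {
    if (v3 %in% aromatic) return("CA")
    if (v3 %in% c("CG", "CD") && res %in% c("ASN", "ASP", "GLN", "GLU"))
      return("C")
    if (v3 == "CZ" && res == "ARG") return("CA")
    return("CT")
  }
  if (el == "H") {
    hyd <- .residueHydrogens(res)
    parent <- hyd$parent[match(v3, hyd$name)]
    if (is.na(parent)) return("HC")
    pel <- .elementOf(parent)
    if (pel == "N") return("H")
    if (pel == "O") return("HO")
    if (pel == "S") return("HS")
    if (parent %in% aromatic) return("HA")
    return("HC")
  }
  "DU"
}

## Random-coil chemical shifts (ppm, DSS-referenced, standard published
## backbone values). Columns H, HA, CA, CB, C, N; GLY has no CB and PRO
## no amide H.
.RANDOM_COIL <- local({
  m <- rbind(
    ALA = c(8.24, 4.32, 52.5, 19.1, 177.8, 123.8),
    ARG = c(8.23, 4.34, 56.0, 30.9, 176.3, 120.5),
    ASN = c(8.40, 4.74, 53.4, 38.7, 175.2, 118.7),
    ASP = c(8.34, 4.64, 54.2, 41.1, 176.3, 120.4),
    CYS = c(8.32, 4.55, 58.2, 28.0, 174.6, 118.8),
    GLN = c(8.32, 4.34, 55.7, 29.4, 176.0, 119.8),
    GLU = c(8.42, 4.35, 56.6, 29.9, 176.6, 120.2),
    GLY = c(8.33, 3.96, 45.1, NA, 174.9, 108.8),
    HIS = c(8.42, 4.73, 55.0, 29.0, 174.1, 118.2),
    ILE = c(8.00, 4.17, 61.1, 38.8, 176.4, 119.9),
    LEU = c(8.16, 4.34, 55.1, 42.4, 177.6, 121.8),
    LYS = c(8.29, 4.32, 56.2, 33.1, 176.6, 120.4),
    MET = c(8.28, 4.48, 55.4, 32.9, 176.3, 119.6),
    PHE = c(8.30, 4.62, 57.7, 39.6, 175.8, 120.3),
    PRO = c(NA, 4.42, 63.3, 31.7, 177.3, 128.1),
    SER = c(8.31, 4.47, 58.3, 63.8, 174.6, 115.7),
    THR = c(8.15, 4.35, 61.8, 69.8, 174.7, 113.6),
    TRP = c(8.25, 4.66, 57.5, 29.6, 176.1, 121.3),
    TYR = c(8.28, 4.55, 57.9, 38.8, 175.9, 120.3),
    VAL = c(8.03, 4.12, 62.2, 32.9, 176.3, 119.2)
  )
  colnames(m) <- c("H", "HA", "CA", "CB", "C", "N")
  m
})

#' Random-coil chemical shift lookup
#'
#' Baseline shift of a backbone nucleus in an unstructured peptide.
#' Pure table lookup over the 20 standard residues for atoms
#' N, CA, CB, C, H and HA (GLY HA2/HA3 share the HA value).
#'
#' @param residue_type 3-letter residue code.
#' @param atom_name Atom name (either naming dialect).
#' @return Shift in ppm.
#' @export
randomCoilShift <- function(residue_type, atom_name) {
  res <- toupper(residue_type)
  if (!res %in% rownames(.RANDOM_COIL))
    stop("no random-coil entry for residue ", residue_type)
  v3 <- tryCatch(convertAtomName(res, atom_name, to = "pdbv3"),
                 error = function(e) toupper(atom_name))
  if (v3 %in% c("HA2", "HA3")) v3 <- "HA"
  if (!v3 %in% colnames(.RANDOM_COIL))
    stop("no random-coil entry for atom ", atom_name, " in ", residue_type)
  val <- .RANDOM_COIL[res, v3]
  if (is.na(val))
    stop("no random-coil entry for (", residue_type, ", ", atom_name, ")")
  unname(val)
}
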