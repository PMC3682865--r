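## Atom nomenclature conversion between the NMRStar / PDB-v3 spelling
## (trailing position digit, e.g. "HB2") and the PDB-v2 spelling
## (leading digit, e.g. "2HB"). The mapping is a per-residue bijection
## built from the hydrogen topology: hydrogens sharing one parent heavy
## atom form a numbered group whose v2 prefix is the rank of the v3
## trailing digit within the group (so SER HB2/HB3 become 1HB/2HB while
## ALA's methyl HB1/HB2/HB3 become 1HB/2HB/3HB); hydrogens that are the
## only one on their parent keep their name (e.g. HIS HD1, TRP HE1).
## Heavy atom names are invariant.

.nameTableCache <- new.env(parent = emptyenv())

.residueNameTable <- function(res) {
  res <- toupper(res)
  if (!is.null(.nameTableCache[[res]])) return(.nameTableCache[[res]])
  hyd <- .residueHydrogens(res)
  v2 <- hyd$name
  for (p in unique(hyd$parent)) {
    idx <- which(hyd$parent == p)
    if (length(idx) >= 2) {
      nm <- hyd$name[idx]
      digit <- as.integer(sub("^.*?([0-9])$", "\\1", nm))
      stem <- sub("[0-9]$", "", nm)
      if (anyNA(digit) || length(unique(stem)) != 1L)
        stop("inconsistent hydrogen group on ", res, " ", p)
      rank <- rank(digit)
      v2[idx] <- paste0(rank, stem)
    }
  }
  heavy <- .residueHeavyAtoms(res)
  tab <- data.frame(
    v3 = c(heavy, hyd$name),
    v2 = c(heavy, v2),
    stringsAsFactors = FALSE
  )
  .nameTableCache[[res]] <- tab
  tab
}

#' Convert atom names between naming dialects
#'
#' Deterministic per-residue bijection between the NMRStar/PDB-v3 atom
#' vocabulary (\code{"HB2"}) and the PDB-v2 vocabulary (\code{"2HB"}).
#' Input names are accepted in either dialect.
#'
#' @param residue_type 3-letter code of a standard amino acid.
#' @param atom_name Atom name in either dialect.
#' @param to Target dialect: \code{"pdbv2"} (leading-digit style) or
#'   \code{"pdbv3"}/\code{"nmrstar"} (trailing-digit style).
#' @return The converted atom name.
#' @export
#' @examples
#' convertAtomName("ALA", "HB2", to = "pdbv2")   # "2HB"
#' convertAtomName("SER", "1HB", to = "pdbv3")   # "HB2"
convertAtomName <- function(residue_type, atom_name,
                            to = c("pdbv2", "pdbv3", "nmrstar")) {
  to <- match.arg(to)
  res <- toupper(residue_type)
  if (!res %in% .AA3)
    stop("not a standard amino acid: ", residue_type)
  nm <- toupper(trimws(atom_name))
  tab <- .residueNameTable(res)
  i <- match(nm, tab$v3)
  if (is.na(i)) i <- match(nm, tab$v2)
  if (is.na(i))
    stop("unknown atom name '", atom_name, "' for ", res,
         "; known names: ", paste(unique(c(tab$v3, tab$v2)), collapse = ", "))
  if (to == "pdbv2") tab$v2[i] else tab$v3[i]
}

#' Atom vocabulary of a residue type
#'
#' @param residue_type 3-letter code.
#' @param dialect \code{"pdbv2"} or \code{"pdbv3"}.
#' @return Character vector of atom names.
#' @export
residueAtomNames <- function(residue_type, dialect = c("pdbv3", "pdbv2")) {
  dialect <- match.arg(dialect)
  tab <- .residueNameTable(toupper(residue_type))
  if (dialect == "pdbv2") tab$v2 else tab$v3
}
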