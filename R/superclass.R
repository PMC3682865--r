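## Atom super classes: the partition of atom names that decides which
## regression model an atom belongs to. The default scheme is the
## 10-class set (N, CA, CB, C, H, HA, HB, HD, HG, HEHZ) with the
## published per-class atom-name vocabularies, stored literally in
## their mixed leading-/trailing-digit spelling; lookups test both the
## normalized leading-digit spelling and the raw name.

.DEFAULT_SUPER_CLASSES <- list(
  N    = c("N"),
  CA   = c("CA"),
  CB   = c("CB"),
  C    = c("C"),
  H    = c("H"),
  HA   = c("HA", "1HA", "2HA"),
  HB   = c("HB", "1HB", "2HB"),
  HD   = c("2HD", "HD1", "HD2", "1HD1", "1HD2", "2HD2"),
  HG   = c("HG", "1HG1", "1HG2", "2HG", "2HG1", "HG1"),
  HEHZ = c("HE", "HE1", "HE2", "HE3", "2HE", "1HE", "1HE2", "2HE2",
           "HH2", "HZ", "1HZ", "HZ2", "HZ3")
)

#' The default 10-class atom super-class scheme
#'
#' @return A [SuperClassScheme-class] with classes N, CA, CB, C, H, HA,
#'   HB, HD, HG and HEHZ.
#' @export
defaultSuperClassScheme <- function() {
  new("SuperClassScheme", labels = names(.DEFAULT_SUPER_CLASSES),
      members = .DEFAULT_SUPER_CLASSES, provenance = "default")
}

#' Assign an atom to its super class
#'
#' The atom name is looked up in the scheme's vocabularies both as
#' given and in its leading-digit (PDB-v2) spelling for the residue.
#' Names in no class (e.g. O, side-chain carbons beyond CB) yield
#' `NA`.
#'
#' @param atom_name Atom name in either dialect.
#' @param residue_type 3-letter residue code (used for dialect
#'   normalization; non-standard residues are looked up as-is).
#' @param scheme A [SuperClassScheme-class]; default the 10-class
#'   scheme.
#' @return Class label, or `NA_character_`.
#' @export
#' @examples
#' assignSuperClass("CA", "ALA")      # "CA"
#' assignSuperClass("2HD2", "LEU")    # "HD"
#' assignSuperClass("HZ3", "LYS")     # "HEHZ"
assignSuperClass <- function(atom_name, residue_type,
                             scheme = defaultSuperClassScheme()) {
  nm <- toupper(trimws(atom_name))
  cand <- nm
  if (toupper(residue_type) %in% .AA3) {
    v2 <- tryCatch(convertAtomName(residue_type, nm, to = "pdbv2"),
                   error = function(e) NULL)
    if (!is.null(v2)) cand <- unique(c(v2, nm))
  }
  for (lbl in scheme@labels)
    if (any(cand %in% scheme@members[[lbl]])) return(lbl)
  NA_character_
}

#' Super-class assignment over a record table
#'
#' @param recs data.frame with atom_name and residue_type columns.
#' @param scheme A [SuperClassScheme-class].
#' @return Character vector of class labels (NA where unassigned).
#' @export
assignSuperClasses <- function(recs, scheme = defaultSuperClassScheme()) {
  mapply(assignSuperClass, recs$atom_name, recs$residue_type,
         MoreArgs = list(scheme = scheme), USE.NAMES = FALSE)
}

#' Automatically cluster atom types into super classes
#'
#' Greedy, element-segregated merging of force-field atom types into
#' classes of comparable size: hydrogen, carbon and nitrogen types are
#' never mixed. Within each element, every type starts as its own
#' class and the smallest class is repeatedly merged into the class
#' with the nearest type name (string distance, ties to the larger
#' class, then first in order) until the requested class count is
#' reached and no class is smaller than `1/sizeFactor` times the mean
#' class size where achievable.
#'
#' @param counts Named integer vector: shift counts per force-field
#'   atom type.
#' @param elements Named character vector: element per atom type (types
#'   are grouped by it). If NULL, the leading letter of the type name.
#' @param nClasses Target total class count.
#' @param sizeFactor Maximal tolerated class-size spread factor
#'   (default 4).
#' @return A [SuperClassScheme-class] with provenance "auto"; members
#'   are atom-type names.
#' @export
autoClusterScheme <- function(counts, elements = NULL, nClasses = 10,
                              sizeFactor = 4) {
  stopifnot(length(counts) > 0, !is.null(names(counts)))
  if (length(counts) < nClasses)
    stop("fewer atom types (", length(counts),
         ") than requested classes (", nClasses, ")")
  if (is.null(elements))
    elements <- substr(gsub("^[0-9]+", "", toupper(names(counts))), 1, 1)
  if (is.null(names(elements))) names(elements) <- names(counts)
  els <- unique(elements[names(counts)])
  ## allocate classes per element proportionally to total counts, >= 1
  tot <- vapply(els, function(e)
    sum(counts[names(counts)[elements[names(counts)] == e]]), numeric(1))
  alloc <- pmax(1L, round(nClasses * tot / sum(tot)))
  names(alloc) <- els
  ## fix rounding so the total is exactly nClasses, respecting the
  ## per-element type counts
  ntypes <- vapply(els, function(e)
    sum(elements[names(counts)] == e), integer(1))
  alloc <- pmin(alloc, ntypes)
  while (sum(alloc) > nClasses) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < nClasses) {
    room <- ntypes - alloc
    i <- which(room > 0)[which.max(tot[which(room > 0)])]
    alloc[i] <- alloc[i] + 1L
  }
  members <- list()
  for (e in els) {
    types <- names(counts)[elements[names(counts)] == e]
    cls <- lapply(types, function(t) t)
    sizes <- as.numeric(counts[types])
    target <- alloc[[e]]
    ## merge smallest class into its nearest-name neighbour until the
    ## per-element class budget is met; the size band is then reported
    ## but cannot be enforced below the budget
    while (length(cls) > target) {
      i <- which.min(sizes)
      rep_i <- cls[[i]][1]
      cand <- setdiff(seq_along(cls), i)
      dist <- vapply(cand, function(j)
        min(utils::adist(rep_i, cls[[j]])), numeric(1))
      best <- cand[order(dist, -sizes[cand], cand)][1]
      cls[[best]] <- sort(c(cls[[best]], cls[[i]]))
      sizes[best] <- sizes[best] + sizes[i]
      cls[[i]] <- NULL
      sizes <- sizes[-i]
    }
    if (length(sizes) > 1L && min(sizes) * sizeFactor < max(sizes))
      warning("auto clustering: class sizes for element ", e,
              " exceed the spread factor ", sizeFactor)
    for (k in seq_along(cls)) {
      lbl <- paste0(e, k)
      members[[lbl]] <- cls[[k]]
    }
  }
  new("SuperClassScheme", labels = names(members), members = members,
      provenance = "auto")
}

#' Serialize / read a super-class scheme as plain text
#'
#' One class per line: `label: name, name, ...`.
#'
#' @param scheme A [SuperClassScheme-class].
#' @param path File path.
#' @return `writeScheme` the path invisibly; `readScheme` the scheme.
#' @export
writeScheme <- function(scheme, path) {
  lines <- vapply(scheme@labels, function(l)
    paste0(l, ": ", paste(scheme@members[[l]], collapse = ", ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScheme
#' @export
readScheme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  members <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed scheme line: ", ln)
    members[[trimws(parts[1])]] <-
      toupper(trimws(strsplit(parts[2], ",")[[1]]))
  }
  new("SuperClassScheme", labels = names(members), members = members,
      provenance = "user")
}
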