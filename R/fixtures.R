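## Synthetic fixtures: toy proteins built from ideal internal
## coordinates by a stated backbone dihedral program, with
## ground-truth chemical shifts generated as
## random-coil base + secondary-structure offset + ring current +
## hydrogen-bond term + a linear feature term + Gaussian noise.
## Every geometric property of a fixture is recomputable from its
## construction parameters, so the generator doubles as the oracle
## for the geometry features, and deterministic file corruptions
## exercise the fault-tolerant parser.

## ideal geometry constants (Angstrom / degrees)
.BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_N_H = 1.010,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_N_H = 119.5, omega = 180)

## side-chain z-matrix rows: atom, parent, angleRef, torsionRef, bond,
## angle(angleRef-parent-atom), torsion(torsionRef-angleRef-parent-atom).
## Fixed rotamers (chi1 = -60 where applicable).
.zrow <- function(atom, parent, aref, tref, bond, angle, torsion)
  list(atom = atom, parent = parent, aref = aref, tref = tref,
       bond = bond, angle = angle, torsion = torsion)

.CB_HA <- list(
  .zrow("CB", "CA", "N", "C", 1.530, 110.5, 122.5),
  .zrow("HA", "CA", "N", "C", 1.090, 108.5, -119.3))

.ZMAT <- list(
  GLY = list(
    .zrow("HA2", "CA", "N", "C", 1.090, 108.5, 122.5),
    .zrow("HA3", "CA", "N", "C", 1.090, 108.5, -119.3)),
  ALA = c(.CB_HA, list(
    .zrow("HB1", "CB", "CA", "N", 1.090, 109.5, 180),
    .zrow("HB2", "CB", "CA", "N", 1.090, 109.5, 60),
    .zrow("HB3", "CB", "CA", "N", 1.090, 109.5, -60))),
  SER = c(.CB_HA, list(
    .zrow("OG", "CB", "CA", "N", 1.417, 110.8, -60),
    .zrow("HB2", "CB", "CA", "N", 1.090, 109.4, 60),
    .zrow("HB3", "CB", "CA", "N", 1.090, 109.4, 180),
    .zrow("HG", "OG", "CB", "CA", 0.960, 108.5, 180))),
  VAL = c(.CB_HA, list(
    .zrow("CG1", "CB", "CA", "N", 1.530, 110.5, -60),
    .zrow("CG2", "CB", "CA", "N", 1.530, 110.5, 60),
    .zrow("HB", "CB", "CA", "N", 1.090, 108.5, 180),
    .zrow("HG11", "CG1", "CB", "CA", 1.090, 110.0, 180),
    .zrow("HG12", "CG1", "CB", "CA", 1.090, 110.0, 60),
    .zrow("HG13", "CG1", "CB", "CA", 1.090, 110.0, -60),
    .zrow("HG21", "CG2", "CB", "CA", 1.090, 110.0, 180),
    .zrow("HG22", "CG2", "CB", "CA", 1.090, 110.0, 60),
    .zrow("HG23", "CG2", "CB", "CA", 1.090, 110.0, -60))),
  LEU = c(.CB_HA, list(
    .zrow("CG", "CB", "CA", "N", 1.530, 116.3, -60),
    .zrow("HB2", "CB", "CA", "N", 1.090, 109.4, 60),
    .zrow("HB3", "CB", "CA", "N", 1.090, 109.4, 180),
    .zrow("CD1", "CG", "CB", "CA", 1.530, 110.7, 180),
    .zrow("CD2", "CG", "CB", "CA", 1.530, 110.7, 60),
    .zrow("HG", "CG", "CB", "CA", 1.090, 109.0, -60),
    .zrow("HD11", "CD1", "CG", "CB", 1.090, 110.0, 180),
    .zrow("HD12", "CD1", "CG", "CB", 1.090, 110.0, 60),
    .zrow("HD13", "CD1", "CG", "CB", 1.090, 110.0, -60),
    .zrow("HD21", "CD2", "CG", "CB", 1.090, 110.0, 180),
    .zrow("HD22", "CD2", "CG", "CB", 1.090, 110.0, 60),
    .zrow("HD23", "CD2", "CG", "CB", 1.090, 110.0, -60))),
  PHE = c(.CB_HA, list(
    .zrow("CG", "CB", "CA", "N", 1.510, 113.8, -60),
    .zrow("HB2", "CB", "CA", "N", 1.090, 109.4, 60),
    .zrow("HB3", "CB", "CA", "N", 1.090, 109.4, 180),
    .zrow("CD1", "CG", "CB", "CA", 1.400, 120.8, 90),
    .zrow("CD2", "CG", "CB", "CA", 1.400, 120.8, -90),
    .zrow("CE1", "CD1", "CG", "CB", 1.390, 120.0, 180),
    .zrow("CE2", "CD2", "CG", "CB", 1.390, 120.0, 180),
    .zrow("CZ", "CE1", "CD1", "CG", 1.390, 120.0, 0),
    .zrow("HD1", "CD1", "CG", "CB", 1.080, 120.0, 0),
    .zrow("HD2", "CD2", "CG", "CB", 1.080, 120.0, 0),
    .zrow("HE1", "CE1", "CD1", "CG", 1.080, 120.0, 180),
    .zrow("HE2", "CE2", "CD2", "CG", 1.080, 120.0, 180),
    .zrow("HZ", "CZ", "CE1", "CD1", 1.080, 120.0, 180))),
  LYS = c(.CB_HA, list(
    .zrow("CG", "CB", "CA", "N", 1.530, 114.0, -60),
    .zrow("HB2", "CB", "CA", "N", 1.090, 109.0, 60),
    .zrow("HB3", "CB", "CA", "N", 1.090, 109.0, 180),
    .zrow("CD", "CG", "CB", "CA", 1.530, 111.0, 180),
    .zrow("HG2", "CG", "CB", "CA", 1.090, 109.0, 60),
    .zrow("HG3", "CG", "CB", "CA", 1.090, 109.0, -60),
    .zrow("CE", "CD", "CG", "CB", 1.530, 111.0, 180),
    .zrow("HD2", "CD", "CG", "CB", 1.090, 109.0, 60),
    .zrow("HD3", "CD", "CG", "CB", 1.090, 109.0, -60),
    .zrow("NZ", "CE", "CD", "CG", 1.490, 111.0, 180),
    .zrow("HE2", "CE", "CD", "CG", 1.090, 109.0, 60),
    .zrow("HE3", "CE", "CD", "CG", 1.090, 109.0, -60),
    .zrow("HZ1", "NZ", "CE", "CD", 1.010, 109.5, 180),
    .zrow("HZ2", "NZ", "CE", "CD", 1.010, 109.5, 60),
    .zrow("HZ3", "NZ", "CE", "CD", 1.010, 109.5, -60))))

.FIXTURE_RESIDUES <- names(.ZMAT)

#' Specify a synthetic fixture protein
#'
#' @param sequence One-letter sequence over the supported residue
#'   types (G, A, S, V, L, F, K); length >= 2.
#' @param program Backbone dihedral program: `"helix"`
#'   (phi -57, psi -47), `"extended"` (phi -135, psi 135), `"mixed"`
#'   (helix first half, extended second), or `"custom"` with explicit
#'   `phi`/`psi` vectors (degrees).
#' @param phi,psi Optional per-residue dihedral vectors (degrees),
#'   required for `"custom"`.
#' @param sigma Gaussian noise standard deviation on the generated
#'   shifts (ppm); must be >= 0.
#' @param betaDensity Coefficient of the linear feature term
#'   (ppm per heavy-atom density count); default 0.01.
#' @param seed Integer RNG seed for the noise.
#' @param id Fixture identifier (used as pdb_id).
#' @return A `FixtureSpec` list.
#' @export
fixtureSpec <- function(sequence, program = c("helix", "extended",
                                              "mixed", "custom"),
                        phi = NULL, psi = NULL, sigma = 0,
                        betaDensity = 0.01, seed = 1L, id = "FIX1") {
  program <- match.arg(program)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L) stop("fixture sequence must have length >= 2")
  if (sigma < 0) stop("sigma must be >= 0")
  res <- oneToThree(strsplit(sequence, "")[[1]])
  bad <- setdiff(res, .FIXTURE_RESIDUES)
  if (length(bad))
    stop("unsupported fixture residue type(s): ",
         paste(unique(bad), collapse = ", "))
  if (program == "custom") {
    if (is.null(phi) || is.null(psi) || length(phi) != n ||
        length(psi) != n)
      stop("custom program needs phi and psi vectors of length ", n)
  } else {
    base <- switch(program,
                   helix = c(-57, -47),
                   extended = c(-135, 135))
    if (program == "mixed") {
      h <- n %/% 2
      phi <- c(rep(-57, h), rep(-135, n - h))
      psi <- c(rep(-47, h), rep(135, n - h))
    } else {
      phi <- rep(base[1], n); psi <- rep(base[2], n)
    }
  }
  structure(list(sequence = sequence, residues = res, program = program,
                 phi = phi, psi = psi, sigma = sigma,
                 betaDensity = betaDensity, seed = as.integer(seed),
                 id = id),
            class = "FixtureSpec")
}

#' Build the fixture structure from its spec
#'
#' Places the backbone from ideal bond lengths and angles following
#' the spec's phi/psi program (trans peptide, omega 180), then side
#' chains and hydrogens in fixed ideal rotamers. A non-bonded contact
#' below 0.7 A is an impossible-geometry error.
#'
#' @param spec A `FixtureSpec`.
#' @param pdbPath Optional path: also write the structure as a PDB
#'   file.
#' @return A [ProteinStructure-class].
#' @export
buildStructure <- function(spec, pdbPath = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  n <- length(spec$residues)
  pos <- list()   # per residue: named list of coordinates
  aN <- .BB$a_N_CA_C
  ## seed residue 1 in the xy-plane
  pos[[1]] <- list(
    N = c(0, 0, 0),
    CA = c(.BB$b_N_CA, 0, 0))
  ar <- aN * pi / 180
  pos[[1]]$C <- pos[[1]]$CA + .BB$b_CA_C * c(-cos(ar), sin(ar), 0)
  for (i in seq_len(n)) {
    p <- pos[[i]]
    if (i < n) {
      pos[[i + 1L]] <- list()
      pos[[i + 1L]]$N <- .placeAtom(p$N, p$CA, p$C, .BB$b_C_N,
                                    .BB$a_CA_C_N, spec$psi[i])
      pos[[i + 1L]]$CA <- .placeAtom(p$CA, p$C, pos[[i + 1L]]$N,
                                     .BB$b_N_CA, .BB$a_C_N_CA, .BB$omega)
      pos[[i + 1L]]$C <- .placeAtom(p$C, pos[[i + 1L]]$N,
                                    pos[[i + 1L]]$CA, .BB$b_CA_C,
                                    .BB$a_N_CA_C, spec$phi[i + 1L])
      pos[[i + 1L]]$H <- .placeAtom(p$CA, p$C, pos[[i + 1L]]$N,
                                    .BB$b_N_H, .BB$a_C_N_H, 0)
    }
    pos[[i]]$O <- .placeAtom(p$N, p$CA, p$C, .BB$b_C_O, .BB$a_CA_C_O,
                             spec$psi[i] + 180)
    if (i == 1L)
      pos[[1L]]$H <- .placeAtom(pos[[1L]]$C, pos[[1L]]$CA, pos[[1L]]$N,
                                .BB$b_N_H, 118, 180)
    ## side chain: choose the chi1 rotamer (-60, 180, +60) with the
    ## largest minimum nonbonded contact to residues placed so far;
    ## contacts below 2.0 A (a physical steric clearance) disqualify
    ## a rotamer unless none clears it
    otherRes <- setdiff(seq_len(min(i + 1L, length(pos))), i)
    placed <- if (length(otherRes))
      do.call(rbind, lapply(pos[otherRes], function(p)
        do.call(rbind, p))) else NULL
    zmat <- .ZMAT[[spec$residues[i]]]
    movingAtoms <- vapply(zmat, `[[`, "", "atom")
    movingAtoms <- movingAtoms[!movingAtoms %in% c("HA", "HA2", "HA3")]
    best <- NULL; bestScore <- -Inf
    for (chi1Off in c(0, -120, 120)) {
      cand <- pos[[i]]
      for (z in zmat) {
        tor <- z$torsion + if (z$parent == "CB") chi1Off else 0
        cand[[z$atom]] <- .placeAtom(cand[[z$tref]], cand[[z$aref]],
                                     cand[[z$parent]], z$bond, z$angle,
                                     tor)
      }
      score <- Inf
      if (!is.null(placed) && length(movingAtoms)) {
        sc <- do.call(rbind, cand[movingAtoms])
        score <- min(apply(sc, 1, function(v)
          min(sqrt(colSums((t(placed) - v)^2)))))
      }
      if (score > bestScore) { bestScore <- score; best <- cand }
      if (score >= 2.0) break
    }
    pos[[i]] <- best
  }
  rows <- list()
  order1 <- c("N", "CA", "C", "O", "H")
  for (i in seq_len(n)) {
    nm <- c(intersect(order1, names(pos[[i]])),
            setdiff(names(pos[[i]]), order1))
    for (atom in nm) {
      xyz <- pos[[i]][[atom]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = "A", chain_index = 1L, residue_index = i,
        residue_seq = i, residue_type = spec$residues[i],
        atom_name = atom, element = .elementOf(atom),
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dmin <- Inf
  for (i in seq_len(nrow(xyz) - 1L)) {
    d <- sqrt(colSums((t(xyz[(i + 1L):nrow(xyz), , drop = FALSE]) -
                       xyz[i, ])^2))
    dmin <- min(dmin, d)
  }
  if (dmin < 0.7)
    stop("impossible fixture geometry: atom clash at ",
         format(dmin, digits = 3), " A")
  s <- new("ProteinStructure", pdbId = spec$id, atoms = at,
           metadata = list(nModels = 1L, fixture = TRUE))
  if (!is.null(pdbPath)) writePDB(s, pdbPath)
  s
}

## side-chain base shifts (ppm) per residue and atom-name stem; values
## are constant within (residue, super class) because equivalent
## protons share one resonance in the generator
.FIXTURE_SC_BASE <- list(
  ALA = c(HB = 1.39),
  SER = c(HB = 3.88, HG = 5.33),
  VAL = c(HB = 2.13, HG = 0.94),
  LEU = c(HB = 1.62, HG = 1.64, HD = 0.90),
  PHE = c(HB = 3.04, HD = 7.30, HE = 7.39, HZ = 7.34),
  LYS = c(HB = 1.81, HG = 1.45, HD = 1.70, HE = 3.00, HZ = 7.52))

## secondary-structure offsets (ppm) for backbone super classes
.FIXTURE_SS_OFFSET <- list(
  helix = c(N = -1.5, CA = 3.1, CB = -0.5, C = 1.5, H = -0.1, HA = -0.35),
  strand = c(N = 1.0, CA = -1.5, CB = 2.0, C = -1.0, H = 0.2, HA = 0.40),
  coil = c(N = 0, CA = 0, CB = 0, C = 0, H = 0, HA = 0))

.fixtureBase <- function(residue_type, atom_name) {
  v <- tryCatch(randomCoilShift(residue_type, atom_name),
                error = function(e) NA_real_)
  if (!is.na(v)) return(v)
  stem <- sub("[0-9]+$", "", toupper(atom_name))
  sc <- .FIXTURE_SC_BASE[[toupper(residue_type)]]
  if (!is.null(sc) && stem %in% names(sc)) return(unname(sc[[stem]]))
  NA_real_
}

#' Generate ground-truth shifts for a fixture structure
#'
#' Per atom with a super class and a base value:
#' `shift = base(residue, atom) + ss_offset(class, secondary
#' structure) + ring_current + betaDensity * atomic_density +
#' N(0, sigma^2)` (seeded) -- a random-coil base plus the ring-current
#' semi-classical term plus a linear term in chosen features (the
#' one-hot secondary-structure offsets and the atomic density). The
#' deterministic part is retained for recovery tests.
#'
#' @param structure The fixture [ProteinStructure-class].
#' @param spec Its `FixtureSpec`.
#' @param starPath Optional path: also write an NMRStar file.
#' @param dialect NMRStar dialect for the file.
#' @return List: `shifts` (parser-compatible table), `truth`
#'   (deterministic components per atom).
#' @export
buildShifts <- function(structure, spec, starPath = NULL,
                        dialect = "3.1") {
  stopifnot(inherits(spec, "FixtureSpec"))
  a <- atoms(structure)
  ft <- computeFeatureTable(structure,
                            c("secondary_structure", "atomic_density",
                              "ring_current"),
                            context = list())
  cls <- assignSuperClasses(a)
  base <- mapply(.fixtureBase, a$residue_type, a$atom_name,
                 USE.NAMES = FALSE)
  keep <- which(!is.na(cls) & !is.na(base))
  ssOff <- vapply(keep, function(i) {
    off <- .FIXTURE_SS_OFFSET[[ft$secondary_structure[i]]]
    if (cls[i] %in% names(off)) off[[cls[i]]] else 0
  }, numeric(1))
  det <- base[keep] + ssOff + ft$ring_current[keep] +
    spec$betaDensity * ft$atomic_density[keep]
  set.seed(spec$seed)
  noise <- stats::rnorm(length(keep), 0, spec$sigma)
  shifts <- data.frame(
    entity = 1L, residue_index = a$residue_index[keep],
    residue_type = a$residue_type[keep], atom_name = a$atom_name[keep],
    shift = det + noise, ambiguity = 1L, stringsAsFactors = FALSE)
  truth <- data.frame(
    residue_index = a$residue_index[keep], atom_name = a$atom_name[keep],
    super_class = cls[keep], base = base[keep], ss_offset = ssOff,
    ring_current = ft$ring_current[keep],
    density_term = spec$betaDensity * ft$atomic_density[keep],
    deterministic = det, stringsAsFactors = FALSE)
  if (!is.null(starPath))
    writeNMRStar(shifts, starPath, dialect = dialect,
                 entryId = spec$id)
  list(shifts = shifts, truth = truth)
}

## ---- deterministic file corruptions ---------------------------------

.shiftRowLines <- function(lines) {
  grep("^      [0-9]+ ", lines)
}

#' Corrupt an NMRStar fixture file
#'
#' Applies one deterministic corruption; all other content stays
#' byte-identical. Modes: `stray_token` (bare token inserted
#' mid-loop), `duplicate_frame` (assigned-shift frame duplicated),
#' `nonnumeric_shift` (shift value of row 5 replaced by text),
#' `dialect_v3_names` (atom names rewritten in the other naming
#' dialect), `one_residue_insertion` (sequence indices after the
#' midpoint shifted by one, emulating an extra residue on the shift
#' side).
#'
#' @param path Input NMRStar file.
#' @param mode Corruption mode.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
corruptFile <- function(path, mode = c("stray_token", "duplicate_frame",
                                       "nonnumeric_shift",
                                       "dialect_v3_names",
                                       "one_residue_insertion"),
                        out) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  rows <- .shiftRowLines(lines)
  if (!length(rows)) stop("no shift rows found in ", path)
  is31 <- any(grepl("_Atom_chem_shift\\.", lines))
  seqField <- if (is31) 3L else 2L
  atomField <- if (is31) 5L else 4L
  splitRow <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]
  joinRow <- function(tok) paste0("      ", paste(tok, collapse = " "))
  if (mode == "stray_token") {
    at <- rows[min(6L, length(rows))]
    lines <- append(lines, "      SPURIOUS", after = at)
  } else if (mode == "duplicate_frame") {
    start <- grep("^save_assigned", lines)[1]
    ends <- grep("^save_$", lines)
    end <- ends[ends > start][1]
    frame <- lines[start:end]
    frame[1] <- paste0(frame[1], "_dup")
    lines <- c(lines, "", frame)
  } else if (mode == "nonnumeric_shift") {
    at <- rows[min(5L, length(rows))]
    lines[at] <- sub("[0-9]+\\.[0-9]+", "BADVAL", lines[at])
  } else if (mode == "dialect_v3_names") {
    for (at in rows) {
      tok <- splitRow(lines[at])
      res <- tok[atomField - 1L]
      nm <- tok[atomField]
      cur <- tryCatch(convertAtomName(res, nm, to = "pdbv3"),
                      error = function(e) nm)
      other <- tryCatch(convertAtomName(res, nm, to = "pdbv2"),
                        error = function(e) nm)
      tok[atomField] <- if (identical(nm, cur)) other else cur
      lines[at] <- joinRow(tok)
    }
  } else if (mode == "one_residue_insertion") {
    seqs <- vapply(rows, function(at)
      as.integer(splitRow(lines[at])[seqField]), integer(1))
    mid <- floor(max(seqs) / 2) + 1L
    for (k in seq_along(rows)) {
      if (seqs[k] >= mid) {
        tok <- splitRow(lines[rows[k]])
        tok[seqField] <- as.character(seqs[k] + 1L)
        lines[rows[k]] <- joinRow(tok)
      }
    }
  }
  writeLines(lines, out)
  invisible(out)
}

#' Build a deterministic set of fixture proteins with shift files
#'
#' Generates `nProteins` toy proteins with seeded random sequences
#' over the supported residue types, cycling through the helix,
#' extended and mixed dihedral programs (the programmed dihedrals are
#' the exact geometry; sequence variation provides the cross-protein
#' variation), writes paired PDB and NMRStar files, and returns the
#' pairs table for [buildDataset()].
#'
#' @param dir Output directory.
#' @param nProteins Number of proteins; default 24.
#' @param lengthRange Residue-count range; default 35..45.
#' @param sigma Shift noise sd (ppm).
#' @param seed Integer master seed.
#' @param permuteShifts Randomly permute all shift values across the
#'   set after generation (for label-permutation controls).
#' @return List: `pairs` (data.frame pdb_id, bmrb_id, pdb_path,
#'   star_path), `truth` (per-protein ground-truth tables),
#'   `specs`.
#' @export
buildFixtureSet <- function(dir, nProteins = 24L,
                            lengthRange = c(35L, 45L), sigma = 0,
                            seed = 1L, permuteShifts = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  letters7 <- threeToOne(.FIXTURE_RESIDUES)
  programs <- c("helix", "extended", "mixed")
  pairs <- list(); truth <- list(); specs <- list()
  shiftTabs <- list()
  for (k in seq_len(nProteins)) {
    set.seed(as.integer(seed) * 1000L + k)
    attempt <- 0L
    repeat {
      len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
      sq <- paste(sample(letters7, len, replace = TRUE), collapse = "")
      prog <- programs[(k - 1L) %% 3L + 1L]
      id <- sprintf("FX%02d", k)
      spec <- fixtureSpec(sq, program = prog, sigma = sigma,
                          seed = as.integer(seed) * 1000L + k, id = id)
      st <- tryCatch(buildStructure(spec), error = function(e) NULL)
      if (!is.null(st)) break
      attempt <- attempt + 1L
      if (attempt > 20L) stop("could not build a clash-free fixture")
    }
    pdbPath <- file.path(dir, paste0(id, ".pdb"))
    starPath <- file.path(dir, paste0(id, ".str"))
    writePDB(st, pdbPath)
    ## ground truth is generated from the structure as written: the
    ## PDB file is the fixture, so threshold-sensitive geometric terms
    ## (hydrogen bonds at the secondary-structure criterion) must be
    ## computed at the file's 0.001 A coordinate precision
    bs <- buildShifts(parsePDB(pdbPath), spec, starPath = NULL)
    shiftTabs[[id]] <- bs$shifts
    truth[[id]] <- bs$truth
    specs[[id]] <- spec
    pairs[[k]] <- data.frame(pdb_id = id, bmrb_id = sprintf("%d", 4000 + k),
                             pdb_path = pdbPath, star_path = starPath,
                             stringsAsFactors = FALSE)
  }
  if (permuteShifts) {
    all <- unlist(lapply(shiftTabs, `[[`, "shift"))
    set.seed(as.integer(seed) + 777L)
    perm <- sample(all)
    off <- 0L
    for (id in names(shiftTabs)) {
      nk <- nrow(shiftTabs[[id]])
      shiftTabs[[id]]$shift <- perm[(off + 1L):(off + nk)]
      off <- off + nk
    }
  }
  out <- do.call(rbind, pairs)
  for (k in seq_len(nrow(out)))
    writeNMRStar(shiftTabs[[out$pdb_id[k]]], out$star_path[k],
                 dialect = "3.1", entryId = out$pdb_id[k])
  list(pairs = out, truth = truth, specs = specs)
}
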