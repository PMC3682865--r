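## The feature engine: a string-keyed registry connecting feature names
## to computers. Covers semi-classical shift contributions (random
## coil, ring current, electric field, hydrogen bond), sequential,
## structural, force-field and experimental descriptors. Every
## computer returns one value per atom of the structure; per-residue
## and per-structure quantities are broadcast to their atoms.

.featureRegistry <- new.env(parent = emptyenv())

#' Register a feature computer
#'
#' A computer is `function(structure, ctx)` returning a vector along
#' the structure's atom table. `ctx` carries the chain-level context
#' (conditions, alignment score, structure score) and a per-structure
#' cache.
#'
#' @param name Feature name string.
#' @param kind `"numeric"` or `"categorical"`.
#' @param fn Computer function.
#' @param overwrite Allow replacing an existing registration.
#' @return The name, invisibly.
#' @export
registerFeature <- function(name, kind = c("numeric", "categorical"), fn,
                            overwrite = FALSE) {
  kind <- match.arg(kind)
  if (!overwrite && !is.null(.featureRegistry[[name]]))
    stop("feature '", name, "' is already registered")
  .featureRegistry[[name]] <- list(kind = kind, fn = fn)
  invisible(name)
}

#' The feature registry
#'
#' @param name Optional single feature name to look up; unknown names
#'   are a configuration error.
#' @return With `name`: the registry entry (kind, fn). Without: named
#'   list of all entries.
#' @export
featureRegistry <- function(name = NULL) {
  if (is.null(name)) {
    out <- mget(ls(.featureRegistry), envir = .featureRegistry)
    return(out)
  }
  entry <- .featureRegistry[[name]]
  if (is.null(entry))
    stop("unknown feature '", name, "'; registered features: ",
         paste(sort(ls(.featureRegistry)), collapse = ", "))
  entry
}

## per-structure cache helper
.cached <- function(ctx, key, expr) {
  if (is.null(ctx$cache[[key]])) ctx$cache[[key]] <- force(expr)
  ctx$cache[[key]]
}

## ---- covalent bonds (distance criterion over covalent radii) --------

.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

.bondList <- function(structure) {
  a <- atoms(structure)
  n <- nrow(a)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rc <- .COV_RADII[a$element]
  rc[is.na(rc)] <- 0.77
  out <- list()
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    hit <- j[d <= rc[i] + rc[j] + 0.4 & d > 0.4]
    if (length(hit))
      out[[length(out) + 1L]] <- cbind(i, hit)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

.bondNeighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

## atoms within `k` covalent bonds of `i` (excluding i)
.withinBonds <- function(nb, i, k) {
  seen <- i
  frontier <- i
  for (step in seq_len(k)) {
    frontier <- setdiff(unique(unlist(nb[frontier])), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, i)
}

## ---- aromatic ring systems ------------------------------------------

#' Aromatic ring systems of a structure
#'
#' Detects the rings of PHE, TYR, HIS and TRP (TRP contributes two)
#' and returns centroid, unit normal and relative ring-current
#' intensity for each. Collinear (degenerate) ring geometry is an
#' error.
#'
#' @param structure A [ProteinStructure-class].
#' @return List of rings: residue_type, chain_index, residue_index,
#'   members, centroid, normal, intensity, memberIdx.
#' @export
ringSystems <- function(structure) {
  a <- atoms(structure)
  out <- list()
  resKey <- paste(a$chain_index, a$residue_index)
  for (key in unique(resKey)) {
    rows <- which(resKey == key)
    res <- a$residue_type[rows[1]]
    if (!res %in% names(.RING_DEFS)) next
    for (def in .RING_DEFS[[res]]) {
      idx <- rows[match(def$members, a$atom_name[rows])]
      if (anyNA(idx)) next
      xyz <- as.matrix(a[idx, c("x", "y", "z")])
      centroid <- colMeans(xyz)
      cc <- sweep(xyz, 2, centroid)
      sv <- svd(cc)
      if (sv$d[2] < 1e-6)
        stop("degenerate (collinear) ring in residue ", res, " ", key)
      normal <- sv$v[, 3]
      normal <- normal / sqrt(sum(normal^2))
      out[[length(out) + 1L]] <- list(
        residue_type = res, chain_index = a$chain_index[rows[1]],
        residue_index = a$residue_index[rows[1]], members = def$members,
        centroid = centroid, normal = normal, intensity = def$intensity,
        memberIdx = idx)
    }
  }
  out
}

#' Ring-current shift at a point
#'
#' Point-dipole model: the contribution of each aromatic ring is
#' `B * i * (1 - 3 cos^2 theta) / r^3`, summed over rings, where `r`
#' is the distance to the ring centroid (Angstrom), `theta` the angle
#' between the ring normal and the centroid-to-atom vector, `i` the
#' ring's relative intensity and `B` the target factor in ppm A^3.
#' Atoms closer than 0.5 A to a centroid are geometrically
#' implausible and raise an error.
#'
#' @param pos Length-3 position (Angstrom).
#' @param rings List of rings as from [ringSystems()].
#' @param B Target factor (ppm A^3); default 30.42.
#' @return Shift contribution in ppm.
#' @export
ringCurrentShift <- function(pos, rings, B = 30.42) {
  total <- 0
  for (ring in rings) {
    v <- pos - ring$centroid
    r <- sqrt(sum(v * v))
    if (r < 0.5)
      stop("atom within 0.5 A of an aromatic ring centroid (r = ",
           format(r), " A)")
    cth <- sum(v * ring$normal) / r
    total <- total + B * ring$intensity * (1 - 3 * cth * cth) / r^3
  }
  total
}

#' Electric-field shift contribution of one atom
#'
#' Uniaxial model `delta = epsilon * E_z` with
#' `E_z = sum_q q * cos(alpha) / r^2` over source charges beyond a
#' two-bond exclusion; `alpha` is the angle between the target's bond
#' axis (from its single bonded partner towards the target) and the
#' target-to-source direction. Only atoms with exactly one covalent
#' bond (hydrogens, carbonyl-type oxygens) are valid targets.
#'
#' @param structure A [ProteinStructure-class].
#' @param atomIdx Row index of the target atom.
#' @param charges Named charge table (atom name -> e); defaults to the
#'   built-in minimal set.
#' @param epsilon Coefficient in ppm per field unit; default 1.
#' @param nb Optional precomputed bond-neighbour list (internal reuse).
#' @return Shift contribution in ppm.
#' @export
electricFieldShift <- function(structure, atomIdx,
                               charges = .PARTIAL_CHARGES, epsilon = 1.0,
                               nb = NULL) {
  a <- atoms(structure)
  if (is.null(nb))
    nb <- .bondNeighbors(.bondList(structure), nrow(a))
  partners <- nb[[atomIdx]]
  if (length(partners) != 1L)
    stop("electric-field target must have exactly one covalent bond; atom ",
         a$atom_name[atomIdx], " has ", length(partners))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  axis <- .unit(xyz[atomIdx, ] - xyz[partners, ])
  excl <- c(atomIdx, .withinBonds(nb, atomIdx, 2L))
  q <- charges[a$atom_name]
  q[is.na(q)] <- 0
  src <- setdiff(which(q != 0), excl)
  Ez <- 0
  for (s in src) {
    v <- xyz[s, ] - xyz[atomIdx, ]
    r <- sqrt(sum(v * v))
    if (r < 1e-6) next
    Ez <- Ez + q[[s]] * sum(v * axis) / r / r^2
  }
  unname(epsilon * Ez)
}

#' Hydrogen-bond shift contribution of a donor hydrogen
#'
#' Distance model `delta = a / r^3 - b` for the nearest acceptor (O or
#' N beyond a two-bond exclusion) within the threshold, else 0.
#'
#' @param structure A [ProteinStructure-class].
#' @param hIdx Row index of the hydrogen.
#' @param a_coef Coefficient a (ppm A^3); default 19.2.
#' @param b_coef Offset b (ppm); default 2.3.
#' @param threshold Acceptor distance threshold (A); default 3.5.
#' @param nb Optional precomputed bond-neighbour list (internal reuse).
#' @return Shift contribution in ppm.
#' @export
hbondEffectShift <- function(structure, hIdx, a_coef = 19.2, b_coef = 2.3,
                             threshold = 3.5, nb = NULL) {
  at <- atoms(structure)
  if (at$element[hIdx] != "H") stop("hbond effect target must be a hydrogen")
  if (is.null(nb))
    nb <- .bondNeighbors(.bondList(structure), nrow(at))
  excl <- c(hIdx, .withinBonds(nb, hIdx, 2L))
  acc <- setdiff(which(at$element %in% c("O", "N")), excl)
  if (!length(acc)) return(0)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[hIdx, ])^2))
  r <- min(d)
  if (r > threshold) return(0)
  a_coef / r^3 - b_coef
}

## ---- torsions, secondary structure, distances -----------------------

.backboneIdx <- function(a, ci, ri, name) {
  i <- which(a$chain_index == ci & a$residue_index == ri &
             a$atom_name == name)
  if (length(i)) i[1] else NA_integer_
}

#' Backbone and chi1 torsion angles per residue
#'
#' Standard IUPAC convention, degrees in (-180, 180]. Angles whose
#' four-atom chain is incomplete (chain termini, missing side chain)
#' are NA.
#'
#' @param structure A [ProteinStructure-class].
#' @return data.frame: chain_index, residue_index, phi, psi, chi1.
#' @export
torsionAngles <- function(structure) {
  a <- atoms(structure)
  res <- unique(a[, c("chain_index", "residue_index", "residue_type")])
  res <- res[order(res$chain_index, res$residue_index), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  P <- function(i) if (is.na(i)) NULL else xyz[i, ]
  chi1Ref <- c(ALA = NA, ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG",
               GLN = "CG", GLU = "CG", GLY = NA, HIS = "CG", ILE = "CG1",
               LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG", PRO = "CG",
               SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG",
               VAL = "CG1")
  n <- nrow(res)
  phi <- psi <- chi1 <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ci <- res$chain_index[k]; ri <- res$residue_index[k]
    Ni <- .backboneIdx(a, ci, ri, "N")
    CAi <- .backboneIdx(a, ci, ri, "CA")
    Ci <- .backboneIdx(a, ci, ri, "C")
    Cprev <- .backboneIdx(a, ci, ri - 1L, "C")
    Nnext <- .backboneIdx(a, ci, ri + 1L, "N")
    if (!anyNA(c(Cprev, Ni, CAi, Ci)))
      phi[k] <- dihedralAngle(P(Cprev), P(Ni), P(CAi), P(Ci))
    if (!anyNA(c(Ni, CAi, Ci, Nnext)))
      psi[k] <- dihedralAngle(P(Ni), P(CAi), P(Ci), P(Nnext))
    ref <- chi1Ref[res$residue_type[k]]
    if (!is.na(ref)) {
      CBi <- .backboneIdx(a, ci, ri, "CB")
      Gi <- .backboneIdx(a, ci, ri, ref)
      if (!anyNA(c(Ni, CAi, CBi, Gi)))
        chi1[k] <- dihedralAngle(P(Ni), P(CAi), P(CBi), P(Gi))
    }
  }
  data.frame(chain_index = res$chain_index,
             residue_index = res$residue_index,
             phi = phi, psi = psi, chi1 = chi1)
}

#' Detect hydrogen bonds
#'
#' Geometric criterion: H to acceptor (O or N, beyond two covalent
#' bonds) distance below 2.5 A and donor-H-acceptor angle above 120
#' degrees.
#'
#' @param structure A [ProteinStructure-class].
#' @return data.frame: hIdx, donorIdx, acceptorIdx, distance, angle.
#' @export
detectHBonds <- function(structure) {
  at <- atoms(structure)
  bonds <- .bondList(structure)
  nb <- .bondNeighbors(bonds, nrow(at))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  hyd <- which(at$element == "H")
  out <- list()
  accAll <- which(at$element %in% c("O", "N"))
  for (h in hyd) {
    don <- nb[[h]]
    if (length(don) != 1L) next
    excl <- c(h, .withinBonds(nb, h, 2L))
    acc <- setdiff(accAll, excl)
    if (!length(acc)) next
    d <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[h, ])^2))
    for (j in which(d < 2.5)) {
      ang <- .bondAngle(xyz[don, ], xyz[h, ], xyz[acc[j], ])
      if (ang > 120)
        out[[length(out) + 1L]] <- data.frame(
          hIdx = h, donorIdx = don, acceptorIdx = acc[j],
          distance = d[j], angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(hIdx = integer(0), donorIdx = integer(0),
                      acceptorIdx = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

#' Detect disulfide bonds
#'
#' SG-SG pairs with distance in \[1.8, 2.5\] A.
#'
#' @param structure A [ProteinStructure-class].
#' @return data.frame: idx1, idx2, distance.
#' @export
detectDisulfides <- function(structure) {
  at <- atoms(structure)
  sg <- which(at$atom_name == "SG")
  out <- list()
  if (length(sg) >= 2L) {
    xyz <- as.matrix(at[sg, c("x", "y", "z")])
    for (i in seq_len(length(sg) - 1L)) for (j in (i + 1L):length(sg)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d >= 1.8 && d <= 2.5)
        out[[length(out) + 1L]] <- data.frame(idx1 = sg[i], idx2 = sg[j],
                                              distance = d)
    }
  }
  if (!length(out))
    return(data.frame(idx1 = integer(0), idx2 = integer(0),
                      distance = numeric(0)))
  do.call(rbind, out)
}

#' Secondary-structure assignment from backbone hydrogen bonds
#'
#' Pattern-based: a residue is "helix" when it sits in a run supported
#' by i -> i+4 backbone N-H...O=C hydrogen bonds, "strand" when its
#' amide donates or its carbonyl accepts a backbone hydrogen bond to a
#' residue at least five positions away, else "coil". Deterministic;
#' every residue is labeled.
#'
#' @param structure A [ProteinStructure-class].
#' @return data.frame: chain_index, residue_index, ss (helix, strand,
#'   coil).
#' @export
secondaryStructure <- function(structure) {
  a <- atoms(structure)
  res <- unique(a[, c("chain_index", "residue_index")])
  res <- res[order(res$chain_index, res$residue_index), ]
  hb <- detectHBonds(structure)
  ss <- rep("coil", nrow(res))
  key <- paste(res$chain_index, res$residue_index)
  if (nrow(hb)) {
    ## backbone amide H donors to backbone carbonyl O acceptors
    isBB <- a$atom_name[hb$hIdx] == "H" & a$atom_name[hb$acceptorIdx] == "O"
    bb <- hb[isBB, , drop = FALSE]
    if (nrow(bb)) {
      di <- match(paste(a$chain_index[bb$hIdx], a$residue_index[bb$hIdx]),
                  key)
      ai <- match(paste(a$chain_index[bb$acceptorIdx],
                        a$residue_index[bb$acceptorIdx]), key)
      sameChain <- a$chain_index[bb$hIdx] == a$chain_index[bb$acceptorIdx]
      sep <- a$residue_index[bb$hIdx] - a$residue_index[bb$acceptorIdx]
      ## helical i+4 -> i hydrogen bond marks residues i..i+4
      hel <- which(sameChain & sep == 4L)
      for (r in hel) {
        lo <- ai[r]; hi <- di[r]
        if (!is.na(lo) && !is.na(hi)) ss[lo:hi] <- "helix"
      }
      far <- which(abs(sep) >= 5L | !sameChain)
      for (r in far) {
        for (k in c(di[r], ai[r]))
          if (!is.na(k) && ss[k] == "coil") ss[k] <- "strand"
      }
    }
  }
  data.frame(chain_index = res$chain_index,
             residue_index = res$residue_index, ss = ss,
             stringsAsFactors = FALSE)
}

#' Atomic density around an atom
#'
#' Count of heavy atoms within `radius`, excluding the atom itself and
#' its covalently bonded partners.
#'
#' @param structure A [ProteinStructure-class].
#' @param atomIdx Target atom row index (vectorized).
#' @param radius Sphere radius in Angstrom; default 5.
#' @return Integer count(s).
#' @export
atomicDensity <- function(structure, atomIdx, radius = 5) {
  stopifnot(radius > 0)
  at <- atoms(structure)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bonds <- .bondList(structure)
  nb <- .bondNeighbors(bonds, nrow(at))
  heavy <- which(at$element != "H")
  vapply(atomIdx, function(i) {
    cand <- setdiff(heavy, c(i, nb[[i]]))
    if (!length(cand)) return(0L)
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    sum(d <= radius)
  }, integer(1))
}

#' Explicit backbone distances per residue
#'
#' Euclidean distances between backbone atoms of a residue and its
#' sequence neighbours; missing atoms give NA.
#'
#' @param structure A [ProteinStructure-class].
#' @return data.frame: chain_index, residue_index, dist_N_CA,
#'   dist_CA_C, dist_C_O, dist_N_C_prev, dist_CA_CA_prev,
#'   dist_CA_CA_next.
#' @export
backboneDistances <- function(structure) {
  a <- atoms(structure)
  res <- unique(a[, c("chain_index", "residue_index")])
  res <- res[order(res$chain_index, res$residue_index), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  D <- function(i, j) {
    if (is.na(i) || is.na(j)) return(NA_real_)
    sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  n <- nrow(res)
  out <- data.frame(chain_index = res$chain_index,
                    residue_index = res$residue_index,
                    dist_N_CA = NA_real_, dist_CA_C = NA_real_,
                    dist_C_O = NA_real_, dist_N_C_prev = NA_real_,
                    dist_CA_CA_prev = NA_real_, dist_CA_CA_next = NA_real_)
  for (k in seq_len(n)) {
    ci <- res$chain_index[k]; ri <- res$residue_index[k]
    Ni <- .backboneIdx(a, ci, ri, "N"); CAi <- .backboneIdx(a, ci, ri, "CA")
    Ci <- .backboneIdx(a, ci, ri, "C"); Oi <- .backboneIdx(a, ci, ri, "O")
    CAp <- .backboneIdx(a, ci, ri - 1L, "CA")
    CAn <- .backboneIdx(a, ci, ri + 1L, "CA")
    Cp <- .backboneIdx(a, ci, ri - 1L, "C")
    out$dist_N_CA[k] <- D(Ni, CAi)
    out$dist_CA_C[k] <- D(CAi, Ci)
    out$dist_C_O[k] <- D(Ci, Oi)
    out$dist_N_C_prev[k] <- D(Ni, Cp)
    out$dist_CA_CA_prev[k] <- D(CAi, CAp)
    out$dist_CA_CA_next[k] <- D(CAi, CAn)
  }
  out
}
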