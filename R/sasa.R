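## Solvent-accessible surface area by sphere sampling (Shrake-Rupley):
## each atom's vdW sphere is inflated by the probe radius and sampled
## with a fixed, deterministic golden-spiral point set; the accessible
## fraction is the share of points not buried in any neighbour sphere.
## Sample directions are expressed in a molecule-fixed frame (principal
## axes with a canonical sign convention), so the sampled areas are
## invariant under rigid-body motion of the whole structure.

## deterministic molecule-fixed orthonormal frame; rotates with the
## coordinates, so directions defined in it are rigid-motion equivariant
.bodyFrame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(diag(3))
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  R <- ev$vectors
  ## canonical signs: each axis positive along the first off-centroid atom
  ref <- cc[which(rowSums(cc^2) > 1e-8)[1], ]
  if (is.na(ref[1])) return(diag(3))
  for (k in 1:2) {
    s <- sum(R[, k] * ref)
    if (abs(s) > 1e-9 && s < 0) R[, k] <- -R[, k]
  }
  ## right-handed third axis
  R[, 3] <- c(R[2, 1] * R[3, 2] - R[3, 1] * R[2, 2],
              R[3, 1] * R[1, 2] - R[1, 1] * R[3, 2],
              R[1, 1] * R[2, 2] - R[2, 1] * R[1, 2])
  R
}

#' Solvent-accessible surface area
#'
#' @param structure A [ProteinStructure-class].
#' @param probe Probe radius in Angstrom; default 1.4 (water).
#' @param nPoints Sample points per atom sphere; default 240.
#' @return List with `atom` (per-atom area, A^2, along the atom table)
#'   and `residue` (per-atom vector holding the atom's residue total,
#'   the "residue SAS").
#' @export
solventAccessibleSurface <- function(structure, probe = 1.4,
                                     nPoints = 240L) {
  a <- atoms(structure)
  n <- nrow(a)
  radii <- .VDW_RADII[a$element]
  if (anyNA(radii))
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[is.na(radii)]), collapse = ", "))
  R <- radii + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- .spherePoints(nPoints) %*% t(.bodyFrame(xyz))
  area <- numeric(n)
  for (i in seq_len(n)) {
    if (n > 1L) {
      d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
      nbr <- which(d < R[i] + R & seq_len(n) != i)
    } else nbr <- integer(0)
    sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nbr) {
      dj <- sqrt(colSums((t(sp) - xyz[j, ])^2))
      acc <- acc & dj >= R[j]
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / nPoints
  }
  resKey <- paste(a$chain_index, a$residue_index)
  resSum <- tapply(area, resKey, sum)
  list(atom = area, residue = as.numeric(resSum[resKey]))
}
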