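## Default feature set: registration of all built-in computers, the
## feature-definition file format, and the per-structure feature table
## orchestrator.

.resJoin <- function(structure, tab, col) {
  a <- atoms(structure)
  key <- paste(a$chain_index, a$residue_index)
  tkey <- paste(tab$chain_index, tab$residue_index)
  tab[[col]][match(key, tkey)]
}

.registerDefaultFeatures <- function() {
  reg <- function(name, kind, fn)
    registerFeature(name, kind, fn, overwrite = TRUE)

  ## sequential
  reg("residue_type", "categorical", function(s, ctx) atoms(s)$residue_type)
  reg("prev_residue_type", "categorical", function(s, ctx) {
    a <- atoms(s)
    tab <- unique(a[, c("chain_index", "residue_index", "residue_type")])
    prev <- tab$residue_type[match(paste(tab$chain_index,
                                         tab$residue_index - 1L),
                                   paste(tab$chain_index,
                                         tab$residue_index))]
    prev[is.na(prev)] <- "NTER"
    tab$prev <- prev
    .resJoin(s, tab, "prev")
  })
  reg("next_residue_type", "categorical", function(s, ctx) {
    a <- atoms(s)
    tab <- unique(a[, c("chain_index", "residue_index", "residue_type")])
    nxt <- tab$residue_type[match(paste(tab$chain_index,
                                        tab$residue_index + 1L),
                                  paste(tab$chain_index,
                                        tab$residue_index))]
    nxt[is.na(nxt)] <- "CTER"
    tab$nxt <- nxt
    .resJoin(s, tab, "nxt")
  })
  reg("sequence_length", "numeric", function(s, ctx) {
    a <- atoms(s)
    len <- tapply(a$residue_index, a$chain_index,
                  function(x) length(unique(x)))
    as.numeric(len[as.character(a$chain_index)])
  })
  reg("alignment_score", "numeric", function(s, ctx)
    rep(as.numeric(ctx$alignment_score %||% 100), nrow(atoms(s))))

  ## structural
  torsFeat <- function(col) function(s, ctx) {
    tors <- .cached(ctx, "torsions", torsionAngles(s))
    .resJoin(s, tors, col)
  }
  reg("phi", "numeric", torsFeat("phi"))
  reg("psi", "numeric", torsFeat("psi"))
  reg("chi1", "numeric", torsFeat("chi1"))
  reg("secondary_structure", "categorical", function(s, ctx) {
    ss <- .cached(ctx, "secstruct", secondaryStructure(s))
    .resJoin(s, ss, "ss")
  })
  distFeat <- function(col) function(s, ctx) {
    bd <- .cached(ctx, "bbdist", backboneDistances(s))
    .resJoin(s, bd, col)
  }
  for (col in c("dist_N_CA", "dist_CA_C", "dist_C_O", "dist_N_C_prev",
                "dist_CA_CA_prev", "dist_CA_CA_next"))
    reg(col, "numeric", distFeat(col))
  reg("atom_sas", "numeric", function(s, ctx)
    .cached(ctx, "sasa", solventAccessibleSurface(s))$atom)
  reg("residue_sas", "numeric", function(s, ctx)
    .cached(ctx, "sasa", solventAccessibleSurface(s))$residue)
  reg("atomic_density", "numeric", function(s, ctx)
    as.numeric(atomicDensity(s, seq_len(nrow(atoms(s))))))
  reg("has_hbond", "numeric", function(s, ctx) {
    hb <- .cached(ctx, "hbonds", detectHBonds(s))
    as.numeric(seq_len(nrow(atoms(s))) %in% c(hb$hIdx, hb$acceptorIdx))
  })
  reg("has_disulfide", "numeric", function(s, ctx) {
    a <- atoms(s)
    dsb <- .cached(ctx, "disulfides", detectDisulfides(s))
    bonded <- unique(c(dsb$idx1, dsb$idx2))
    resB <- unique(paste(a$chain_index[bonded], a$residue_index[bonded]))
    as.numeric(paste(a$chain_index, a$residue_index) %in% resB)
  })

  ## force-field based
  reg("ff_atom_type", "categorical", function(s, ctx) {
    a <- atoms(s)
    mapply(function(r, n) tryCatch(.ffAtomType(r, n),
                                   error = function(e) "DU"),
           a$residue_type, a$atom_name, USE.NAMES = FALSE)
  })
  reg("structure_energy", "numeric", function(s, ctx)
    rep(as.numeric(ctx$structure_energy %||% NA_real_),
        nrow(atoms(s))))

  ## experimental
  for (nm in c("has_h_shifts", "has_c_shifts", "has_n_shifts"))
    local({
      key <- nm
      reg(key, "numeric", function(s, ctx)
        rep(as.numeric(get0(key, envir = ctx, ifnotfound = NULL) %||% NA_real_), nrow(atoms(s))))
    })
  for (nm in c("temperature", "ph", "pressure"))
    local({
      key <- nm
      reg(key, "numeric", function(s, ctx)
        rep(as.numeric(get0(key, envir = ctx, ifnotfound = NULL) %||% NA_real_), nrow(atoms(s))))
    })
  for (nm in c("solvent", "spectrometer"))
    local({
      key <- nm
      reg(key, "categorical", function(s, ctx) {
        v <- get0(key, envir = ctx, ifnotfound = NULL)
        v <- if (is.null(v) || is.na(v)) "missing" else as.character(v)
        rep(v, nrow(atoms(s)))
      })
    })

  ## semi-classical
  reg("random_coil", "numeric", function(s, ctx) {
    a <- atoms(s)
    mapply(function(r, n) tryCatch(randomCoilShift(r, n),
                                   error = function(e) NA_real_),
           a$residue_type, a$atom_name, USE.NAMES = FALSE)
  })
  reg("ring_current", "numeric", function(s, ctx) {
    a <- atoms(s)
    rings <- .cached(ctx, "rings", ringSystems(s))
    xyz <- as.matrix(a[, c("x", "y", "z")])
    vapply(seq_len(nrow(a)), function(i) {
      mine <- vapply(rings, function(r) i %in% r$memberIdx, logical(1))
      ringCurrentShift(xyz[i, ], rings[!mine])
    }, numeric(1))
  })
  reg("electric_field", "numeric", function(s, ctx) {
    a <- atoms(s)
    bonds <- .cached(ctx, "bonds", .bondList(s))
    nb <- .bondNeighbors(bonds, nrow(a))
    vapply(seq_len(nrow(a)), function(i) {
      if (length(nb[[i]]) != 1L) return(NA_real_)
      tryCatch(electricFieldShift(s, i, nb = nb),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  reg("hbond_effect", "numeric", function(s, ctx) {
    a <- atoms(s)
    bonds <- .cached(ctx, "bonds", .bondList(s))
    nb <- .bondNeighbors(bonds, nrow(a))
    vapply(seq_len(nrow(a)), function(i) {
      if (a$element[i] != "H") return(0)
      tryCatch(hbondEffectShift(s, i, nb = nb), error = function(e) 0)
    }, numeric(1))
  })
  invisible(NULL)
}

#' Default feature definition
#'
#' The full built-in feature list in canonical order.
#'
#' @return Character vector of feature names.
#' @export
defaultFeatureDefinition <- function() {
  c("residue_type", "prev_residue_type", "next_residue_type",
    "sequence_length", "alignment_score",
    "phi", "psi", "chi1", "secondary_structure",
    "dist_N_CA", "dist_CA_C", "dist_C_O", "dist_N_C_prev",
    "dist_CA_CA_prev", "dist_CA_CA_next",
    "atom_sas", "residue_sas", "atomic_density",
    "has_hbond", "has_disulfide",
    "ff_atom_type", "structure_energy",
    "has_h_shifts", "has_c_shifts", "has_n_shifts",
    "temperature", "ph", "pressure", "solvent", "spectrometer",
    "random_coil", "ring_current", "electric_field", "hbond_effect")
}

#' Read a feature-definition file
#'
#' Plain text, one feature name per line; lines beginning with '#' are
#' ignored, so pre-defined features can be excluded by commenting them
#' out. Every name must resolve in the feature registry.
#'
#' @param path File path.
#' @return Character vector of feature names.
#' @export
readFeatureDefinition <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  feats <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(feats))
    stop("duplicate feature names in definition: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  for (f in feats) featureRegistry(f)   # configuration-time validation
  feats
}

#' Write a feature-definition file
#'
#' @param features Character vector of feature names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureDefinition <- function(features, path) {
  writeLines(features, path)
  invisible(path)
}

#' Compute the feature table of a structure
#'
#' One row per atom, one column per requested feature. Chain-level
#' context (experimental conditions, alignment score, structure score)
#' is broadcast; missing numeric context stays NA and is imputed at
#' training time with a parallel missing-indicator.
#'
#' @param structure A [ProteinStructure-class].
#' @param features Feature names (default the full definition).
#' @param context Named list: alignment_score, temperature, ph,
#'   pressure, solvent, spectrometer, has_h_shifts, has_c_shifts,
#'   has_n_shifts, structure_energy.
#' @return data.frame of features along the atom table.
#' @export
computeFeatureTable <- function(structure,
                                features = defaultFeatureDefinition(),
                                context = list()) {
  ctx <- list2env(as.list(context), parent = emptyenv())
  ctx$cache <- new.env(parent = emptyenv())
  out <- vector("list", length(features))
  names(out) <- features
  for (f in features) {
    entry <- featureRegistry(f)
    v <- entry$fn(structure, ctx)
    if (length(v) != nrow(atoms(structure)))
      stop("feature '", f, "' returned ", length(v), " values for ",
           nrow(atoms(structure)), " atoms")
    if (entry$kind == "categorical") v <- as.character(v)
    out[[f]] <- v
  }
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}

#' Kinds of a feature set
#'
#' @param features Feature names.
#' @return Named character vector "numeric"/"categorical".
#' @export
featureKindsOf <- function(features) {
  vapply(features, function(f) featureRegistry(f)$kind, character(1))
}
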