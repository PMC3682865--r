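## Independent oracles used across tests. These deliberately avoid the
## package's own code paths.

## Exhaustive global alignment: enumerate all alignments of a and b
## under match +1 / mismatch 0 / gap -1 and return the best score and
## the identity (matches / columns) of a best-identity optimal
## alignment. Only feasible for very short sequences.
bruteForceAlign <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, identity = -1)
  rec <- function(i, j, score, matches, cols) {
    if (i > length(av) && j > length(bv)) {
      ident <- 100 * matches / cols
      if (score > best$score ||
          (score == best$score && ident > best$identity))
        best <<- list(score = score, identity = ident)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + (av[i] == bv[j]),
          matches + (av[i] == bv[j]), cols + 1)
    if (i <= length(av)) rec(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(bv)) rec(i, j + 1, score - 1, matches, cols + 1)
    invisible()
  }
  rec(1, 1, 0, 0, 0)
  best
}

## Brute-force maximal subset with all pairwise identities <= cutoff
## (oracle for greedy homology culling); identities supplied as a
## matrix.
bruteForceCullCount <- function(idMat, cutoff) {
  n <- nrow(idMat)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      pr <- utils::combn(sel, 2)
      for (k in seq_len(ncol(pr)))
        if (idMat[pr[1, k], pr[2, k]] > cutoff) { ok <- FALSE; break }
    }
    if (ok) best <- length(sel)
  }
  best
}

## circular difference between angles in degrees (handles the
## -180/+180 boundary)
angDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

## random amino-acid sequence
randomSeq <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

## a minimal single-atom structure for surface / density tests
isolatedAtomStructure <- function(element = "C", name = "C") {
  new("ProteinStructure", pdbId = "ISO", atoms = data.frame(
    chain_id = "A", chain_index = 1L, residue_index = 1L,
    residue_seq = 1L, residue_type = "UNK", atom_name = name,
    element = element, x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
}

## structure from a bare coordinate table
structureFromCoords <- function(df, pdbId = "TST") {
  need <- c("chain_id", "chain_index", "residue_index", "residue_seq",
            "residue_type", "atom_name", "element", "x", "y", "z")
  for (nm in setdiff(need, names(df))) {
    df[[nm]] <- switch(nm, chain_id = "A", chain_index = 1L,
                       residue_index = 1L, residue_seq = 1L,
                       residue_type = "UNK", stop("missing ", nm))
  }
  new("ProteinStructure", pdbId = pdbId, atoms = df[need])
}
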