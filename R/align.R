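## Global sequence alignment and percent identity. A Needleman-Wunsch
## style global alignment with match +1, mismatch 0 and linear gap -1
## (via Biostrings with a unit substitution matrix); identity is
## matched columns / total alignment columns x 100, so any gap or
## mismatch breaks a 100% identity.

.alignAlphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.unitSubMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      mm <- matrix(0L, length(.alignAlphabet), length(.alignAlphabet),
                   dimnames = list(.alignAlphabet, .alignAlphabet))
      diag(mm) <- 1L
      m <<- mm
    }
    m
  }
})

#' Globally align two amino-acid sequences
#'
#' @param seqA,seqB One-letter residue strings over the 20 standard
#'   amino acids plus 'X'.
#' @return List with `alignedA`, `alignedB` (equal-length strings with
#'   '-' gaps), `identity` (percentage in \[0, 100\]) and `score`.
#' @export
#' @examples
#' globalAlign("MKV", "MKVLL")$identity  # 60
globalAlign <- function(seqA, seqB) {
  seqA <- toupper(trimws(seqA)); seqB <- toupper(trimws(seqB))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  chars <- unique(strsplit(paste0(seqA, seqB), "")[[1]])
  badc <- setdiff(chars, .alignAlphabet)
  if (length(badc))
    stop("sequence contains non-amino-acid letters: ",
         paste(badc, collapse = ""))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = .unitSubMatrix(),
    gapOpening = 0, gapExtension = 1)
  a <- as.character(Biostrings::alignedPattern(al))
  b <- as.character(Biostrings::alignedSubject(al))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  ident <- 100 * sum(av == bv & av != "-") / length(av)
  list(alignedA = a, alignedB = b, identity = ident,
       score = Biostrings::score(al))
}

#' Percent identity of two sequences under global alignment
#'
#' @inheritParams globalAlign
#' @return Percentage in \[0, 100\].
#' @export
alignmentIdentity <- function(seqA, seqB) globalAlign(seqA, seqB)$identity

## Column map between two aligned (gapped) strings: for each position
## of sequence A, the matching residue position of sequence B (NA at
## gaps). Used to re-anchor shift residue indices on the structure.
.alignmentIndexMap <- function(alignedA, alignedB) {
  av <- strsplit(alignedA, "")[[1]]; bv <- strsplit(alignedB, "")[[1]]
  ia <- cumsum(av != "-"); ib <- cumsum(bv != "-")
  map <- rep(NA_integer_, sum(av != "-"))
  for (k in seq_along(av))
    if (av[k] != "-" && bv[k] != "-") map[ia[k]] <- ib[k]
  map
}
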