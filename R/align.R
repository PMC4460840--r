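#' Alignment scoring scheme
#'
#' Scores for global pairwise alignment of homologous mitochondrial genes.
#' A gap run of length k costs `gap_open + k * gap_extend` (both entered as
#' negative numbers). Defaults: match +1, mismatch -1, gap open -2, gap
#' extend -0.5.
#'
#' @param match,mismatch,gap_open,gap_extend Numeric scores.
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -0.5) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Global alignment of two homologous sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), returned as a paired, gapped column
#' representation suitable for the divergence statistic.
#'
#' @param a,b DNA strings (non-empty).
#' @param kind Feature kind of the homolog (`"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control"`, `"noncoding"`).
#' @param gene Gene token carried through to the result.
#' @param scoring An [align_scoring()] scheme.
#' @return A `homolog_alignment` (see [homolog_alignment()]).
#' @export
align_homologs <- function(a, b, kind = "PCG", gene = NA_character_,
                           scoring = align_scoring()) {
  if (!nchar(a) || !nchar(b)) stop("align_homologs: empty input sequence")
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- scoring$match
  mat["N", ] <- 0; mat[, "N"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend)
  )
  res <- homolog_alignment(
    gene = gene,
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    kind = kind
  )
  attr(res, "score") <- Biostrings::score(aln)
  res
}

#' Score of a column alignment under a scoring scheme
#'
#' Recomputes the affine-gap score of an explicit alignment: matches and
#' mismatches per column, plus `gap_open + k * gap_extend` per maximal
#' gap run of length k.
#'
#' @param aln A `homolog_alignment`.
#' @param scoring An [align_scoring()].
#' @return Numeric score.
#' @export
alignment_score <- function(aln, scoring = align_scoring()) {
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  ungapped <- !gap_a & !gap_b
  n_match <- sum(ungapped & ca == cb)
  n_mismatch <- sum(ungapped & ca != cb)
  runs_a <- count_runs(gap_a)
  runs_b <- count_runs(gap_b)
  n_match * scoring$match + n_mismatch * scoring$mismatch +
    (runs_a$n_runs + runs_b$n_runs) * scoring$gap_open +
    (runs_a$total + runs_b$total) * scoring$gap_extend
}

count_runs <- function(mask) {
  if (!length(mask) || !any(mask)) return(list(n_runs = 0L, total = 0L))
  r <- rle(mask)
  list(n_runs = sum(r$values), total = sum(r$lengths[r$values]))
}
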