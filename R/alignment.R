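#' @importFrom Biostrings pairwiseAlignment pattern subject score
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET_X <- c(AA_ALPHABET20, "X")

.blosum62 <- local({
  e <- new.env()
  function() {
    if (is.null(e$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$m <- get("BLOSUM62", envir = e)
    }
    e$m
  }
})

.check_aa <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(sprintf("%s must be a non-empty amino-acid string", what), call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET_X)
  if (length(bad))
    stop(sprintf("invalid amino-acid symbol '%s' in %s", bad[1], what), call. = FALSE)
  invisible(chars)
}

#' Global pairwise alignment of two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed with
#' [Biostrings::pairwiseAlignment()]. A gap run of length L costs
#' `gap_open + L * gap_extend`. The default scoring (BLOSUM62, open 10,
#' extend 0.5) is used throughout the package for germline assignment,
#' Kabat numbering and identity matrices.
#'
#' @param seq_a,seq_b Amino-acid strings (one-letter codes, `X` allowed).
#' @param substitution_matrix Square scoring matrix; defaults to BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties (subtracted from score).
#' @return An object of class `ab_alignment`: a list with elements
#'   `aligned_a`, `aligned_b` (equal-length gapped strings) and `score`.
#' @examples
#' aln <- global_align("ACDE", "ACE")
#' percent_identity(aln)
#' @export
global_align <- function(seq_a, seq_b,
                         substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5) {
  .check_aa(seq_a, "seq_a")
  .check_aa(seq_b, "seq_b")
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b,
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  out <- list(
    aligned_a = as.character(Biostrings::pattern(pa)),
    aligned_b = as.character(Biostrings::subject(pa)),
    score = Biostrings::score(pa)
  )
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  class(out) <- "ab_alignment"
  out
}

#' @export
print.ab_alignment <- function(x, ...) {
  cat("Global alignment (score ", format(x$score), ", ",
      format(round(percent_identity(x), 2)), "% identity)\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identity is counted over residue-residue columns only: columns where either
#' row carries a gap are excluded from the denominator, matching the quantity
#' a standard percent-identity matrix reports.
#'
#' @param alignment An `ab_alignment` from [global_align()].
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "ab_alignment"))
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both))
    stop("alignment has no residue-residue columns; identity undefined", call. = FALSE)
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Pairwise percent-identity matrix
#'
#' @param sequences Named character vector (or named list) of amino-acid
#'   strings; at least two.
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix with 100 on the diagonal, dimnames taken
#'   from `sequences`.
#' @export
build_identity_matrix <- function(sequences, ...) {
  sequences <- unlist(sequences)
  if (length(sequences) < 2L)
    stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  m <- matrix(100, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- percent_identity(global_align(sequences[[i]], sequences[[j]], ...))
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}
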