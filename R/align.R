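# Pairwise alignment utilities: affine-gap global alignment, percent
# identity, and windowed identity tracks. Alignment itself is delegated to
# Biostrings::pairwiseAlignment with a +5/-4 nucleotide matrix in which N
# scores as a mismatch against everything (including N).

regel_submat <- function(match = 5, mismatch = -4) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

as_plain_seq <- function(x) {
  if (inherits(x, "upstream_region")) x$sequence else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

#' Global alignment with affine gap scoring
#'
#' Needleman-Wunsch alignment under match/mismatch scoring and affine gaps
#' (a gap of length k costs `gap_open + k * gap_extend`). N scores as a
#' mismatch against every base including N.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch Per-base scores (defaults +5/-4).
#' @param gap_open,gap_extend Gap penalties, given as negative scores
#'   (defaults -10/-1).
#' @return A list with gapped strings `a` and `b` and the alignment `score`.
#' @export
global_align <- function(a, b, match = 5, mismatch = -4,
                         gap_open = -10, gap_extend = -1) {
  a <- as_plain_seq(a); b <- as_plain_seq(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    regel_error("global_align requires non-empty sequences",
                "regel_validation_error")
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = regel_submat(match, mismatch),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = BiocGenerics::score(aln))
}

#' Percent identity of an aligned pair
#'
#' Identical non-gap columns divided by the number of columns where at least
#' one sequence has a base (columns that are gap in both are ignored).
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return A fraction in `[0, 1]`.
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  stopifnot(is.character(aligned_a), is.character(aligned_b))
  if (nchar(aligned_a) != nchar(aligned_b)) {
    regel_error("aligned strings must have equal length",
                "regel_validation_error")
  }
  ca <- strsplit(toupper(aligned_a), "")[[1]]
  cb <- strsplit(toupper(aligned_b), "")[[1]]
  informative <- !(ca == "-" & cb == "-")
  if (!any(informative)) return(0)
  sum(ca == cb & ca != "-") / sum(informative)
}

#' Windowed identity track along a global alignment
#'
#' Globally aligns the two sequences, then reports per-window column identity
#' (identical non-gap columns over informative columns), suitable for
#' identity-plot style rendering. A window larger than the alignment yields a
#' single value equal to [percent_identity()].
#'
#' @param a,b [upstream_region] objects or nucleotide strings.
#' @param window Window size in alignment columns.
#' @param step Step between window starts (default `window`).
#' @return A data.frame with `position` (alignment column midpoint, 1-based)
#'   and `identity`.
#' @export
identity_track <- function(a, b, window, step = window) {
  stopifnot(window >= 1L, step >= 1L)
  aln <- global_align(a, b)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  L <- length(ca)
  if (window >= L) {
    return(data.frame(position = ceiling((L + 1) / 2),
                      identity = percent_identity(aln$a, aln$b)))
  }
  starts <- seq.int(1L, L - window + 1L, by = step)
  ident <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    informative <- !(ca[idx] == "-" & cb[idx] == "-")
    if (!any(informative)) return(0)
    sum(ca[idx] == cb[idx] & ca[idx] != "-") / sum(informative)
  }, numeric(1))
  data.frame(position = starts + floor(window / 2), identity = ident)
}
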