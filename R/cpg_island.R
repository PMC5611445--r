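# Sliding-window CpG-island detection under the observed/expected CpG
# dinucleotide criteria (window O/E > 0.6 and GC > 0.5, islands > 200 bp).

#' Parameters for CpG-island detection
#'
#' @param window Sliding window size in bp (default 100).
#' @param shift Window step in bp (default 1).
#' @param min_length Minimum island length in bp (default 200).
#' @param min_obs_exp Minimum windowed observed/expected CpG ratio
#'   (exclusive; default 0.6).
#' @param min_gc Minimum windowed GC fraction (exclusive; default 0.5).
#' @return An object of class `cpg_params`.
#' @export
cpg_params <- function(window = 100L, shift = 1L, min_length = 200L,
                       min_obs_exp = 0.6, min_gc = 0.5) {
  window <- as.integer(window); shift <- as.integer(shift)
  min_length <- as.integer(min_length)
  stopifnot(window >= 10L, shift >= 1L, min_length >= window,
            min_obs_exp > 0, min_obs_exp <= 2, min_gc > 0, min_gc <= 1)
  structure(list(window = window, shift = shift, min_length = min_length,
                 min_obs_exp = min_obs_exp, min_gc = min_gc),
            class = "cpg_params")
}

#' Count CpG dinucleotides
#'
#' Number of positions i with a C immediately followed by a G (5' to 3').
#'
#' @param seq Nucleotide string.
#' @return Integer count.
#' @export
count_cpg <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L) return(0L)
  ch <- strsplit(toupper(seq), "")[[1]]
  sum(ch[-length(ch)] == "C" & ch[-1] == "G")
}

#' Observed/expected CpG ratio
#'
#' The Gardiner-Garden and Frommer statistic
#' `N_CpG * L / (N_C * N_G)`; 0 when the sequence has no C or no G.
#'
#' @param seq Nucleotide string.
#' @return The ratio (numeric scalar).
#' @export
obs_exp_ratio <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(toupper(seq), "")[[1]]
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  if (nc == 0L || ng == 0L) return(0)
  count_cpg(seq) * length(ch) / (nc * ng)
}

#' Detect CpG islands by sliding window
#'
#' Slides a window of `params$window` bp by `params$shift`; a window
#' qualifies when its observed/expected CpG ratio exceeds `min_obs_exp` and
#' its GC fraction exceeds `min_gc`. All positions covered by a qualifying
#' window are marked; maximal marked runs of at least `min_length` bp are
#' reported as islands. Island intervals are the union of their qualifying
#' windows (no extension or smoothing). N bases count as neither C nor G and
#' break CpG pairs.
#'
#' @param seq Nucleotide string (a scanned region, e.g. a promoter slice).
#' @param params A [cpg_params] object.
#' @return A data.frame with columns `start`, `end` (0-based half-open, in
#'   the scanned region's coordinates), `mean_obs_exp`, `mean_gc` (means over
#'   the qualifying windows inside the island), sorted by `start`.
#' @export
detect_cpg_islands <- function(seq, params = cpg_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_obs_exp = numeric(0), mean_gc = numeric(0))
  L <- nchar(seq)
  w <- params$window
  if (L < w) {
    warning("region shorter than the scanning window; no islands reported",
            call. = FALSE)
    return(empty)
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  isC <- ch == "C"; isG <- ch == "G"
  cg <- c(isC[-L] & isG[-1], FALSE)          # cg[i]: CpG starting at i
  cumC <- cumsum(isC); cumG <- cumsum(isG); cumCG <- cumsum(cg)
  starts <- seq.int(1L, L - w + 1L, by = params$shift)
  ends <- starts + w - 1L
  nC <- cumC[ends] - c(0L, cumC)[starts]
  nG <- cumG[ends] - c(0L, cumG)[starts]
  nCG <- cumCG[ends - 1L] - c(0L, cumCG)[starts]  # pairs fully inside
  oe <- ifelse(nC > 0L & nG > 0L, nCG * w / (nC * nG), 0)
  gc <- (nC + nG) / w
  ok <- oe > params$min_obs_exp & gc > params$min_gc
  if (!any(ok)) return(empty)
  marked <- logical(L)
  for (k in which(ok)) marked[starts[k]:ends[k]] <- TRUE
  r <- rle(marked)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_length
  if (!any(keep)) return(empty)
  out <- lapply(which(keep), function(i) {
    inside <- ok & starts >= run_start[i] & ends <= run_end[i]
    data.frame(start = run_start[i] - 1L, end = run_end[i],
               mean_obs_exp = mean(oe[inside]), mean_gc = mean(gc[inside]))
  })
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}
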