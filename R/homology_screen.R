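# Windowed dot-plot homology screening: window scoring on every diagonal,
# gap-merged diagonal segments, element presence calling under the
# conserved-region length rule, and iterative homology annotation with a
# decreasing identity schedule.

#' Dot-plot scoring parameters
#'
#' Defaults reproduce the dotmatcher-style screen: 25 bp windows scored
#' +5/-4 with a hit threshold of 45 (at least 17 of 25 identical bases).
#'
#' @param window Window size in bp.
#' @param threshold Minimum summed window score for a hit.
#' @param match,mismatch Per-base scores; N scores as mismatch.
#' @return An object of class `dotplot_params`.
#' @export
dotplot_params <- function(window = 25L, threshold = 45, match = 5,
                           mismatch = -4) {
  window <- as.integer(window)
  stopifnot(window >= 1L, threshold <= window * match)
  structure(list(window = window, threshold = threshold,
                 match = match, mismatch = mismatch),
            class = "dotplot_params")
}

encode_bases <- function(seq, n_code) {
  # integer codes; N gets a sequence-specific code so N never matches anything
  x <- utf8ToInt(toupper(seq))
  x[x == utf8ToInt("N")] <- n_code
  x
}

#' Compute a windowed dot plot
#'
#' Scores every aligned window pair of `a` (rows) and `b` (columns) on the
#' forward strand: a hit is recorded at the window midpoint pair `(i, j)`
#' when the summed per-base score over the window reaches the threshold.
#'
#' @param a,b Nucleotide strings or [upstream_region] objects.
#' @param params A [dotplot_params] object.
#' @return An object of class `dotplot`: list with `params`, `len_a`,
#'   `len_b`, and `hits`, a data.frame of 1-based window midpoints `i` (on
#'   `a`), `j` (on `b`) and window `score`.
#' @export
compute_dotplot <- function(a, b, params = dotplot_params()) {
  a <- as_plain_seq(a); b <- as_plain_seq(b)
  w <- params$window
  la <- nchar(a); lb <- nchar(b)
  empty <- data.frame(i = integer(0), j = integer(0), score = numeric(0))
  if (la < w || lb < w) {
    warning("sequence shorter than the dot-plot window; empty plot",
            call. = FALSE)
    return(structure(list(params = params, len_a = la, len_b = lb,
                          hits = empty), class = "dotplot"))
  }
  av <- encode_bases(a, -1L)
  bv <- encode_bases(b, -2L)
  half <- w %/% 2L
  res_i <- list(); res_j <- list(); res_s <- list(); nres <- 0L
  for (k in (1L - (la - w + 1L)):(lb - w + 1L - 1L)) {
    # window pair (sa, sb = sa + k)
    sa_lo <- max(1L, 1L - k)
    sa_hi <- min(la - w + 1L, lb - w + 1L - k)
    if (sa_lo > sa_hi) next
    t0 <- sa_lo; t1 <- sa_hi + w - 1L
    eq <- av[t0:t1] == bv[(t0 + k):(t1 + k)]
    cs <- c(0L, cumsum(eq))
    m <- cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
    score <- m * params$match + (w - m) * params$mismatch
    hit <- score >= params$threshold
    if (any(hit)) {
      sa <- (sa_lo:sa_hi)[hit]
      nres <- nres + 1L
      res_i[[nres]] <- sa + half
      res_j[[nres]] <- sa + k + half
      res_s[[nres]] <- score[hit]
    }
  }
  hits <- if (nres) {
    data.frame(i = unlist(res_i), j = unlist(res_j), score = unlist(res_s))
  } else empty
  hits <- hits[order(hits$i, hits$j), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(params = params, len_a = la, len_b = lb, hits = hits),
            class = "dotplot")
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("<dotplot> %d x %d bp, window %d, threshold %g: %d hits\n",
              x$len_a, x$len_b, x$params$window, x$params$threshold,
              nrow(x$hits)))
  invisible(x)
}

#' Merge dot-plot hits into diagonal segments
#'
#' Hits whose drawn window extents on the first sequence are separated by
#' at most `max_gap` bp and whose diagonals drift by at most `diag_drift`
#' are chained into one segment: the along-sequence gap tolerance absorbs
#' short mutation clusters (each hit covers a full window, so the visible
#' gap between two hits is their midpoint distance minus the window), while
#' the diagonal drift tolerance keeps a conserved region together across
#' small indels (which offset the diagonal without interrupting homology).
#' Segment extent is the span
#' covered by the hit windows, trimmed at each end by the terminal window's
#' mismatch count, so an exactly matching embedded block measures exactly
#' its own length and window overhang does not over-extend the region.
#'
#' @param plot A [compute_dotplot()] result.
#' @param max_gap Gap tolerance in bp along the first sequence (default 10).
#' @param diag_drift Tolerated diagonal offset between chained hits, bp
#'   (default `max_gap`); 0 restricts merging to a single diagonal.
#' @return A data.frame with `start_a`, `start_b` (1-based), `length`,
#'   `n_hits`, `mean_window_score`, sorted by decreasing length.
#' @export
extract_diagonal_segments <- function(plot, max_gap = 10L,
                                      diag_drift = max_gap) {
  stopifnot(inherits(plot, "dotplot"), max_gap >= 0L, diag_drift >= 0L)
  h <- plot$hits
  empty <- data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0), n_hits = integer(0),
                      mean_window_score = numeric(0))
  if (nrow(h) == 0L) return(empty)
  w <- plot$params$window
  half <- w %/% 2L
  # per-hit match count recovered from the window score
  score_span <- plot$params$match - plot$params$mismatch
  h$m <- round((h$score - w * plot$params$mismatch) / score_span)
  h$diag <- h$j - h$i
  h <- h[order(h$i, h$j), , drop = FALSE]
  n <- nrow(h)
  # union-find over hits; link pairs close in i with compatible diagonals
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(n)) {
    p <- k - 1L
    while (p >= 1L && h$i[k] - h$i[p] <= max_gap + w) {
      if (abs(h$diag[k] - h$diag[p]) <= diag_drift) {
        rk <- find(k); rp <- find(p)
        if (rk != rp) parent[rk] <- rp
      }
      p <- p - 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  segs <- lapply(split(seq_len(n), root), function(idx) {
    s <- h[idx, , drop = FALSE]
    first <- which.min(s$i); last <- which.max(s$i)
    trim_l <- w - s$m[first]; trim_r <- w - s$m[last]
    len <- max(1L, max(s$i) - min(s$i) + w - trim_l - trim_r)
    data.frame(start_a = min(s$i) - half + trim_l,
               start_b = s$j[first] - half + trim_l,
               length = len,
               n_hits = nrow(s),
               mean_window_score = mean(s$score))
  })
  out <- do.call(rbind, segs)
  out <- out[order(-out$length, out$start_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call presence of a regulatory element in an upstream region
#'
#' Dot-plots the query's search window (the element's expected window padded
#' by `search_pad` on both sides) against the reference element sequence.
#' The element is `present` when the longest gap-merged diagonal segment
#' exceeds `min_conserved_length`; `no_coverage` when the covered search
#' window is shorter than `min_coverage_frac` of the expected window and no
#' qualifying segment exists; `absent` otherwise.
#'
#' @param query An [upstream_region].
#' @param ref An [element_definition].
#' @param params Dot-plot parameters.
#' @param min_conserved_length Conserved-segment length that must be
#'   exceeded for a present call (default 100 bp).
#' @param search_pad Padding around the expected window, bp (default 2000).
#' @param min_coverage_frac Coverage fraction below which an unsupported
#'   call becomes `no_coverage` (default 0.5).
#' @param max_gap Diagonal gap tolerance passed to
#'   [extract_diagonal_segments()].
#' @return An object of class `presence_call`: list with `species_id`,
#'   `element_id`, `state`, `located_interval` (anchored, half-open, or
#'   NULL), `best_segment_length`, `covered_length`.
#' @export
call_element_presence <- function(query, ref, params = dotplot_params(),
                                  min_conserved_length = 100L,
                                  search_pad = 2000L,
                                  min_coverage_frac = 0.5,
                                  max_gap = 10L) {
  stopifnot(inherits(query, "upstream_region"),
            inherits(ref, "element_definition"))
  sw <- c(ref$expected_window[1] - search_pad,
          ref$expected_window[2] + search_pad)
  expected_width <- diff(ref$expected_window)
  call0 <- function(state, interval = NULL, best = NA_integer_, cov = 0L) {
    structure(list(species_id = query$species_id,
                   element_id = ref$element_id, state = state,
                   located_interval = interval,
                   best_segment_length = best, covered_length = cov),
              class = "presence_call")
  }
  slice <- tryCatch(slice_upstream(query, sw[1], sw[2]),
                    regel_coverage_error = function(e) NULL)
  if (is.null(slice)) return(call0("no_coverage"))
  cov <- nchar(slice)
  best <- NA_integer_; interval <- NULL
  if (cov >= params$window) {
    plot <- compute_dotplot(slice, ref$reference_sequence, params)
    segs <- extract_diagonal_segments(plot, max_gap = max_gap)
    if (nrow(segs) > 0L) {
      best <- segs$length[1]
      slice_from <- attr(slice, "from")
      interval <- c(slice_from + segs$start_a[1] - 1L,
                    slice_from + segs$start_a[1] - 1L + segs$length[1])
    }
  }
  if (!is.na(best) && best > min_conserved_length) {
    return(call0("present", interval, best, cov))
  }
  if (cov < min_coverage_frac * expected_width) {
    return(call0("no_coverage", NULL, best, cov))
  }
  call0("absent", NULL, best, cov)
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s / %s: %s (best segment %s bp, coverage %d bp)\n",
              x$species_id, x$element_id, x$state,
              ifelse(is.na(x$best_segment_length), "-",
                     x$best_segment_length), x$covered_length))
  invisible(x)
}

#' Annotate an element by iterative homology matching
#'
#' Locally aligns the reference element against the query search window and
#' accepts the hit at the first threshold of a decreasing identity schedule
#' that its percent identity meets (the iterative assemble-at-decreasing-
#' stringency rule, 85% down to 60% by default).
#'
#' @param query An [upstream_region].
#' @param ref An [element_definition].
#' @param identity_schedule Strictly decreasing fractions in (0, 1].
#' @param search_pad Padding around the expected window, bp.
#' @return NULL if no threshold is met; otherwise a list with `interval`
#'   (anchored, half-open), `identity`, and `threshold` (the schedule entry
#'   accepted).
#' @export
annotate_element_by_homology <- function(query, ref,
                                         identity_schedule = seq(0.85, 0.60,
                                                                 by = -0.05),
                                         search_pad = 2000L) {
  stopifnot(inherits(query, "upstream_region"),
            inherits(ref, "element_definition"),
            all(identity_schedule > 0), all(identity_schedule <= 1),
            all(diff(identity_schedule) < 0))
  sw <- c(ref$expected_window[1] - search_pad,
          ref$expected_window[2] + search_pad)
  slice <- tryCatch(slice_upstream(query, sw[1], sw[2]),
                    regel_coverage_error = function(e) NULL)
  if (is.null(slice)) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    ref$reference_sequence, as.character(slice), type = "local",
    substitutionMatrix = regel_submat(), gapOpening = 10, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  if (nchar(pa) == 0L) return(NULL)
  pid <- percent_identity(pa, pb)
  hit_thr <- identity_schedule[identity_schedule <= pid]
  if (length(hit_thr) == 0L) return(NULL)
  sub_start <- BiocGenerics::start(Biostrings::subject(aln))
  sub_end <- BiocGenerics::end(Biostrings::subject(aln))
  slice_from <- attr(slice, "from")
  list(interval = c(slice_from + sub_start - 1L, slice_from + sub_end),
       identity = pid, threshold = hit_thr[1])
}
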