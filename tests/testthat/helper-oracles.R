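# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive explicit loops, not the package
# code paths they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(seq, n_mut) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# naive window-pair dot plot: score every (sa, sb) window pair explicitly
bf_dotplot_hits <- function(a, b, window, threshold, match = 5,
                            mismatch = -4) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  half <- window %/% 2
  out <- list()
  for (sa in seq_len(length(ca) - window + 1)) {
    for (sb in seq_len(length(cb) - window + 1)) {
      xa <- ca[sa:(sa + window - 1)]; xb <- cb[sb:(sb + window - 1)]
      m <- sum(xa == xb & xa != "N")
      score <- m * match + (window - m) * mismatch
      if (score >= threshold) {
        out[[length(out) + 1]] <- c(sa + half, sb + half, score)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), score = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "j", "score")
  df[order(df$i, df$j), ]
}

# naive CpG-island caller: per-window loop, explicit run merging
bf_cpg_islands <- function(seq, window = 100, shift = 1, min_length = 200,
                           min_oe = 0.6, min_gc = 0.5) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  if (L < window) return(data.frame(start = integer(0), end = integer(0)))
  marked <- logical(L)
  for (s in seq(1, L - window + 1, by = shift)) {
    win <- ch[s:(s + window - 1)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncg <- sum(win[-window] == "C" & win[-1] == "G")
    oe <- if (nc > 0 && ng > 0) ncg * window / (nc * ng) else 0
    gc <- (nc + ng) / window
    if (oe > min_oe && gc > min_gc) marked[s:(s + window - 1)] <- TRUE
  }
  out <- list()
  s <- NA
  for (i in seq_len(L + 1)) {
    m <- if (i <= L) marked[i] else FALSE
    if (m && is.na(s)) s <- i
    if (!m && !is.na(s)) {
      if (i - s >= min_length) {
        out[[length(out) + 1]] <- c(s - 1, i - 1)
      }
      s <- NA
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  df <- as.data.frame(do.call(rbind, out)); names(df) <- c("start", "end")
  df
}

BF_IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

bf_iupac_positions <- function(pattern, seq, max_mismatch) {
  pch <- strsplit(pattern, "")[[1]]; sch <- strsplit(seq, "")[[1]]
  k <- length(pch)
  hits <- integer(0); mms <- integer(0)
  for (s in seq_len(length(sch) - k + 1)) {
    mm <- 0
    for (p in seq_len(k)) {
      if (!(sch[s + p - 1] %in% BF_IUPAC[[pch[p]]])) mm <- mm + 1
    }
    if (mm <= max_mismatch) { hits <- c(hits, s); mms <- c(mms, mm) }
  }
  data.frame(position = hits, mismatches = mms)
}

# exhaustive enumeration of global alignments under affine gap scoring
bf_global_score <- function(a, b, match = 5, mismatch = -4,
                            gap_open = -10, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  gap_cost <- function(in_gap) if (in_gap) gap_extend else gap_open + gap_extend
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i <= length(ca)) {
      best <- max(best, gap_cost(state == "a") + rec(i + 1, j, "a"))
    }
    if (j <= length(cb)) {
      best <- max(best, gap_cost(state == "b") + rec(i, j + 1, "b"))
    }
    best
  }
  rec(1, 1, "d")
}

# exhaustive Dollo minimization: any valid loss set consists of branches
# with no present descendant; enumerate all subsets of those candidates
bf_dollo_min_losses <- function(tree, tip_state, gain_node) {
  n_tip <- length(tree$tip.label)
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids(node), tips_below))
  }
  clade <- tips_below(gain_node)
  nodes_below <- function(node) {
    c(node, unlist(lapply(kids(node), nodes_below)))
  }
  cand <- Filter(function(nd) {
    tb <- tips_below(nd)
    !any(tip_state[tb] == "present") && any(tip_state[tb] == "absent")
  }, nodes_below(gain_node))
  absent <- intersect(which(tip_state == "absent"), clade)
  if (!length(absent)) return(0L)
  below <- lapply(cand, tips_below)
  best <- Inf
  for (mask in 0:(2^length(cand) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0)
    covered <- unique(unlist(below[sel]))
    if (all(absent %in% covered) && length(sel) < best) best <- length(sel)
  }
  as.integer(best)
}
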