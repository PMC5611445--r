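# Motif catalog: IUPAC consensus scanning, direct-repeat search, and
# per-species motif state classification against mutagenesis-derived
# critical cores.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

validate_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  ch <- strsplit(pattern, "")[[1]]
  if (length(ch) == 0L || !all(ch %in% names(IUPAC_SETS))) {
    regel_error(sprintf("invalid IUPAC pattern: '%s'", pattern),
                "regel_alphabet_error")
  }
  pattern
}

iupac_revcomp <- function(pattern) {
  ch <- strsplit(validate_iupac(pattern), "")[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Construct a motif definition
#'
#' @param motif_id Motif name (e.g. `"CRE-3"`).
#' @param consensus IUPAC consensus string.
#' @param core Integer vector of 0-based critical-core positions within the
#'   consensus (mutagenesis-backed positions whose damage disrupts binding).
#' @param core_rule How core damage is scored: `"mismatch"`, `"gc_to_at"`,
#'   `"tata"`, or `"none"` (see the packaged catalog for the semantics).
#' @param orientation `"as_given"`, `"reverse_complement"`, or `"both"`.
#' @param element Element the motif belongs to (`"enhancer"`, `"promoter"`,
#'   `"prr"`).
#' @param offset Optional 0-based start of the motif within the element's
#'   reference sequence.
#' @param type `"simple"` (fixed-offset consensus) or `"direct_repeat"`.
#' @param half_site,spacer Direct-repeat half-site pattern and spacer width
#'   (direct_repeat type only).
#' @param source Free-text citation tag.
#' @return An object of class `motif_definition`.
#' @export
motif_definition <- function(motif_id, consensus = NULL, core = integer(0),
                             core_rule = c("mismatch", "gc_to_at", "tata",
                                           "none"),
                             orientation = c("as_given", "reverse_complement",
                                             "both"),
                             element = NA_character_, offset = NA_integer_,
                             type = c("simple", "direct_repeat"),
                             half_site = NULL, spacer = NA_integer_,
                             source = "") {
  type <- match.arg(type)
  core_rule <- match.arg(core_rule)
  orientation <- match.arg(orientation)
  core <- as.integer(core)
  if (type == "simple") {
    consensus <- validate_iupac(consensus)
    if (length(core) && (any(core < 0L) || any(core >= nchar(consensus)))) {
      regel_error(sprintf("%s: core positions outside the consensus",
                          motif_id), "regel_validation_error")
    }
  } else {
    half_site <- validate_iupac(half_site)
    stopifnot(!is.na(spacer), spacer >= 0L)
  }
  structure(list(motif_id = motif_id, consensus = consensus, core = core,
                 core_rule = core_rule, orientation = orientation,
                 element = element, offset = as.integer(offset), type = type,
                 half_site = half_site, spacer = as.integer(spacer),
                 source = source),
            class = "motif_definition")
}

#' Load the packaged motif catalog
#'
#' Reads the editable YAML catalog of enhancer and promoter consensus motifs
#' (with critical cores traceable to site-directed mutagenesis results) and
#' the direct-repeat screening patterns used for the PRR.
#'
#' @param path Path to a catalog YAML; defaults to the packaged catalog.
#' @return A named list of [motif_definition] objects
#'   (class `motif_catalog`).
#' @export
load_default_catalog <- function(path = system.file("extdata",
                                                    "motif_catalog.yaml",
                                                    package = "regelscreen")) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw$motifs, function(m) {
    motif_definition(
      motif_id = m$motif_id,
      consensus = m$consensus,
      core = if (is.null(m$core)) integer(0) else unlist(m$core),
      core_rule = if (is.null(m$core_rule)) "none" else m$core_rule,
      orientation = if (is.null(m$orientation)) "as_given" else m$orientation,
      element = m$element,
      offset = if (is.null(m$offset)) NA_integer_ else m$offset,
      type = if (is.null(m$type)) "simple" else m$type,
      half_site = m$half_site,
      spacer = if (is.null(m$spacer)) NA_integer_ else m$spacer,
      source = if (is.null(m$source)) "" else m$source)
  })
  names(defs) <- vapply(defs, `[[`, character(1), "motif_id")
  structure(defs, class = "motif_catalog")
}

iupac_mismatch_counts <- function(pattern, seq_chars) {
  # mismatch count of pattern at every start; N in the sequence mismatches
  # every pattern letter (including pattern N, which means "any real base")
  k <- nchar(pattern)
  L <- length(seq_chars)
  if (L < k) return(integer(0))
  pch <- strsplit(pattern, "")[[1]]
  n_starts <- L - k + 1L
  mism <- integer(n_starts)
  idx <- seq_len(n_starts)
  for (p in seq_len(k)) {
    allowed <- IUPAC_SETS[[pch[p]]]
    mism <- mism + !(seq_chars[idx + p - 1L] %in% allowed)
  }
  mism
}

#' Scan a sequence for an IUPAC pattern
#'
#' Reports every start position where the pattern matches with at most
#' `max_mismatch` mismatching bases. N in the scanned sequence always counts
#' as a mismatch. Reverse-strand hits are found by scanning the forward
#' sequence with the reverse-complemented pattern; positions always refer to
#' the forward strand.
#'
#' @param pattern IUPAC consensus string.
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param max_mismatch Maximum mismatches per hit (default 0).
#' @param orientation `"as_given"`, `"reverse_complement"`, or `"both"`.
#' @return A data.frame with `position` (1-based start on the forward
#'   strand), `strand` (`"+"`/`"-"`), and `mismatches`.
#' @export
iupac_match <- function(pattern, seq, max_mismatch = 0L,
                        orientation = c("as_given", "reverse_complement",
                                        "both")) {
  orientation <- match.arg(orientation)
  pattern <- validate_iupac(pattern)
  seq <- toupper(as_plain_seq(seq))
  if (grepl("[^ACGTN]", seq)) {
    regel_error("iupac_match: sequence contains characters outside A/C/G/T/N",
                "regel_alphabet_error")
  }
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  if (orientation %in% c("as_given", "both")) {
    mism <- iupac_mismatch_counts(pattern, ch)
    hit <- which(mism <= max_mismatch)
    if (length(hit)) {
      out[[length(out) + 1L]] <-
        data.frame(position = hit, strand = "+", mismatches = mism[hit])
    }
  }
  if (orientation %in% c("reverse_complement", "both")) {
    mism <- iupac_mismatch_counts(iupac_revcomp(pattern), ch)
    hit <- which(mism <= max_mismatch)
    if (length(hit)) {
      out[[length(out) + 1L]] <-
        data.frame(position = hit, strand = "-", mismatches = mism[hit])
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find direct repeats of a half-site consensus
#'
#' Reports positions where two half-site matches occur separated by exactly
#' `spacer` bases (e.g. spacer 1 for DR-1, 4 for a TRE half-site pair), with
#' the per-half mismatch counts.
#'
#' @param seq Nucleotide string.
#' @param half_site IUPAC half-site consensus (default `"AGGTCA"`).
#' @param spacer Exact number of bases between the two half-sites.
#' @param max_mismatch_per_half Maximum mismatches allowed in each half.
#' @return A data.frame with `position` (1-based start of the first half),
#'   `mm1`, `mm2`.
#' @export
find_direct_repeat <- function(seq, half_site = "AGGTCA", spacer = 1L,
                               max_mismatch_per_half = 0L) {
  stopifnot(spacer >= 0L)
  half_site <- validate_iupac(half_site)
  seq <- toupper(as_plain_seq(seq))
  ch <- strsplit(seq, "")[[1]]
  k <- nchar(half_site)
  mism <- iupac_mismatch_counts(half_site, ch)
  ok <- mism <= max_mismatch_per_half
  n <- length(ok)
  first <- seq_len(max(0L, n - k - spacer))
  keep <- first[ok[first] & ok[first + k + spacer]]
  data.frame(position = keep, mm1 = mism[keep],
             mm2 = mism[keep + k + spacer])
}

#' Classify the state of an observed motif instance
#'
#' `observed` is the motif-spanning slice of an alignment row in the
#' reference frame: one character per consensus position, `-` where the
#' query base is deleted. States follow the mutagenesis logic: `deleted`
#' when gaps cover at least `deleted_gap_frac` of the span, `disrupted` when
#' the critical core is damaged under the motif's core rule, `variant` for
#' non-core mismatches only, `intact` for a clean match, `not_found` when
#' nothing aligns.
#'
#' @param observed Character string over A/C/G/T/N/- (may be empty).
#' @param definition A [motif_definition].
#' @param deleted_gap_frac Gap fraction of the span that triggers `deleted`
#'   (default 0.5).
#' @return An object of class `motif_call`: list with `motif_id`, `state`,
#'   `observed`, `mismatch_positions`, `core_mismatch_positions` (0-based).
#' @export
classify_motif_state <- function(observed, definition,
                                 deleted_gap_frac = 0.5) {
  stopifnot(inherits(definition, "motif_definition"),
            definition$type == "simple")
  observed <- toupper(observed)
  if (grepl("[^ACGTN-]", observed)) {
    regel_error("observed motif contains characters outside A/C/G/T/N/-",
                "regel_alphabet_error")
  }
  span <- nchar(definition$consensus)
  call0 <- function(state, mm = integer(0), core_mm = integer(0)) {
    structure(list(motif_id = definition$motif_id, state = state,
                   observed = observed, mismatch_positions = mm,
                   core_mismatch_positions = core_mm),
              class = "motif_call")
  }
  obs <- strsplit(observed, "")[[1]]
  if (length(obs) < span) obs <- c(obs, rep("-", span - length(obs)))
  if (length(obs) > span) obs <- obs[seq_len(span)]
  n_gap <- sum(obs == "-")
  if (n_gap == span || nchar(observed) == 0L) return(call0("not_found"))
  if (n_gap / span >= deleted_gap_frac) return(call0("deleted"))
  cons <- strsplit(definition$consensus, "")[[1]]
  mm_flag <- vapply(seq_len(span), function(p) {
    obs[p] == "-" || obs[p] == "N" || !(obs[p] %in% IUPAC_SETS[[cons[p]]])
  }, logical(1))
  mm <- which(mm_flag) - 1L
  core <- definition$core
  core_mm <- switch(definition$core_rule,
    none = integer(0),
    mismatch = intersect(mm, core),
    gc_to_at = {
      cm <- core[cons[core + 1L] %in% c("G", "C", "S") &
                 (obs[core + 1L] %in% c("A", "T") | obs[core + 1L] == "-")]
      sort(cm)
    },
    tata = intersect(mm, core))
  disrupted <- switch(definition$core_rule,
    none = FALSE,
    mismatch = length(core_mm) > 0L,
    gc_to_at = length(core_mm) > 0L,
    tata = length(core_mm) >= 3L ||
      any(obs[2:5] %in% c("G", "C")))
  if (disrupted) return(call0("disrupted", mm, core_mm))
  if (length(mm)) return(call0("variant", mm, integer(0)))
  call0("intact")
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("<motif_call> %s: %s (%s)\n", x$motif_id, x$state, x$observed))
  invisible(x)
}

#' Scan a located element for its catalogued motifs
#'
#' Globally aligns the element's reference sequence against the located
#' query element and reads each fixed-offset motif off the alignment in the
#' reference frame, so small indels elsewhere in the element do not shift
#' the motif windows. Direct-repeat catalog entries are skipped (they are
#' screening patterns, not fixed instances).
#'
#' @param query An [upstream_region] or a plain nucleotide string holding
#'   the query sequence.
#' @param ref The element's [element_definition] (reference sequence whose
#'   coordinates the catalog offsets refer to).
#' @param catalog A `motif_catalog` (default: packaged catalog).
#' @param located_interval Anchored half-open interval of the element in the
#'   query, e.g. from [call_element_presence()] or
#'   [annotate_element_by_homology()]; NULL means the element was not found
#'   and every motif is reported `not_found`.
#' @param species_id Species label for the output.
#' @param deleted_gap_frac Passed to [classify_motif_state()].
#' @return A data.frame with `species_id`, `motif_id`, `state`, `observed`,
#'   `n_mismatch`, `n_core_mismatch`.
#' @export
scan_species_motifs <- function(query, ref, catalog = load_default_catalog(),
                                located_interval = NULL,
                                species_id = NULL,
                                deleted_gap_frac = 0.5) {
  stopifnot(inherits(ref, "element_definition"))
  defs <- Filter(function(m) identical(m$element, ref$element_id) &&
                   m$type == "simple" && !is.na(m$offset), catalog)
  if (is.null(species_id)) {
    species_id <- if (inherits(query, "upstream_region"))
      query$species_id else NA_character_
  }
  if (!length(defs)) {
    return(data.frame(species_id = character(0), motif_id = character(0),
                      state = character(0), observed = character(0),
                      n_mismatch = integer(0), n_core_mismatch = integer(0)))
  }
  ref_len <- nchar(ref$reference_sequence)
  if (is.null(located_interval)) {
    obs_by_ref <- NULL
  } else {
    elem_seq <- if (inherits(query, "upstream_region")) {
      # pad the located interval so the reference can align end-to-end even
      # when the located segment covers only part of the element
      pad <- max(50L, ref_len %/% 2L)
      as.character(slice_upstream(query, located_interval[1] - pad,
                                  located_interval[2] + pad))
    } else as_plain_seq(query)
    aln <- Biostrings::pairwiseAlignment(
      ref$reference_sequence, elem_seq, type = "global-local",
      substitutionMatrix = regel_submat(), gapOpening = 10, gapExtension = 1)
    ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    rb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    obs_by_ref <- rb[ra != "-"]       # one query char (or -) per ref position
  }
  rows <- lapply(defs, function(m) {
    if (m$offset + nchar(m$consensus) > ref_len) return(NULL)
    if (is.null(obs_by_ref)) {
      call <- structure(list(motif_id = m$motif_id, state = "not_found",
                             observed = "", mismatch_positions = integer(0),
                             core_mismatch_positions = integer(0)),
                        class = "motif_call")
    } else {
      obs <- paste(obs_by_ref[(m$offset + 1L):(m$offset + nchar(m$consensus))],
                   collapse = "")
      call <- classify_motif_state(obs, m, deleted_gap_frac)
    }
    data.frame(species_id = species_id, motif_id = m$motif_id,
               state = call$state, observed = call$observed,
               n_mismatch = length(call$mismatch_positions),
               n_core_mismatch = length(call$core_mismatch_positions))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
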