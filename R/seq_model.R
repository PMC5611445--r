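# Sequence data model: upstream regions anchored on the ATG start codon.
#
# Coordinate convention used throughout the package: 0-based, half-open,
# with the A of the start codon at position 0. Upstream positions are
# negative (-1 is the base immediately 5' of the A). A region with
# anchor_offset = a covers anchored positions [-a, length - a).

REGEL_ALPHABET <- c("A", "C", "G", "T", "N")

regel_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "regel_error")))
}

#' Normalize a nucleotide string to the A/C/G/T/N alphabet
#'
#' Upper-cases the input and maps IUPAC ambiguity letters other than N
#' (R, Y, S, W, K, M, B, D, H, V) to N with a warning. Any character outside
#' the IUPAC nucleotide alphabet is an error.
#'
#' @param seq A character scalar.
#' @param context Label used in warning/error messages.
#' @return The normalized sequence.
#' @export
normalize_sequence <- function(seq, context = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTNRYSWKMBDHV]", seq)) {
    regel_error(sprintf("%s contains non-nucleotide characters", context),
                "regel_alphabet_error")
  }
  if (grepl("[RYSWKMBDHV]", seq)) {
    n <- nchar(gsub("[^RYSWKMBDHV]", "", seq))
    warning(sprintf("%s: %d ambiguous IUPAC base(s) mapped to N", context, n),
            call. = FALSE)
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  }
  seq
}

#' Construct an upstream region
#'
#' @param species_id Character scalar naming the species.
#' @param sequence Nucleotide string; normalized to upper-case A/C/G/T/N.
#' @param anchor_offset Position of the first base of the ATG start codon
#'   within `sequence` (equivalently, the upstream extent in bp). Defaults to
#'   the sequence length, i.e. the record ends right at the start codon.
#' @return An object of class `upstream_region`.
#' @export
upstream_region <- function(species_id, sequence,
                            anchor_offset = nchar(sequence)) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            nzchar(species_id))
  sequence <- normalize_sequence(sequence, context = species_id)
  if (nchar(sequence) == 0L) {
    regel_error(sprintf("empty sequence for '%s'", species_id),
                "regel_validation_error")
  }
  anchor_offset <- as.integer(anchor_offset)
  if (is.na(anchor_offset) || anchor_offset < 0L ||
      anchor_offset > nchar(sequence)) {
    regel_error(sprintf("anchor_offset out of range for '%s'", species_id),
                "regel_validation_error")
  }
  structure(list(species_id = species_id, sequence = sequence,
                 anchor_offset = anchor_offset),
            class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  cat(sprintf("<upstream_region> %s: %d bp, anchored coords [%d, %d)\n",
              x$species_id, nchar(x$sequence), -x$anchor_offset,
              nchar(x$sequence) - x$anchor_offset))
  invisible(x)
}

#' Read upstream regions from a FASTA file
#'
#' The first whitespace-separated token of each header is the species id; an
#' optional `anchor=<int>` key gives the anchor offset (default: the sequence
#' ends at the start codon, i.e. anchor = sequence length).
#'
#' @param path Path to a FASTA file.
#' @return A named list of [upstream_region] objects.
#' @export
read_upstream_fasta <- function(path) {
  if (!file.exists(path)) {
    regel_error(sprintf("no such file: %s", path), "regel_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    regel_error(sprintf("malformed FASTA in %s: %s",
                                        path, conditionMessage(e)),
                                "regel_parse_error")
                  })
  if (length(set) == 0L) {
    regel_error(sprintf("no FASTA records in %s", path), "regel_parse_error")
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    regel_error(sprintf("duplicate species_id in %s: %s", path,
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                "regel_validation_error")
  }
  regions <- vector("list", length(set))
  for (k in seq_along(set)) {
    seq <- as.character(set[[k]])
    if (nchar(seq) == 0L) {
      regel_error(sprintf("empty record '%s' in %s", ids[k], path),
                  "regel_parse_error")
    }
    m <- regmatches(headers[k], regexpr("anchor=\\d+", headers[k]))
    anchor <- if (length(m)) as.integer(sub("anchor=", "", m)) else nchar(seq)
    regions[[k]] <- upstream_region(ids[k], seq, anchor)
  }
  names(regions) <- ids
  regions
}

#' Write upstream regions to a FASTA file
#'
#' Headers carry the species id and an `anchor=<int>` key; sequences are
#' wrapped at 60 columns. Round-trips with [read_upstream_fasta()].
#'
#' @param regions A list of [upstream_region] objects.
#' @param path Output path.
#' @export
write_upstream_fasta <- function(regions, path) {
  stopifnot(is.list(regions), length(regions) > 0L)
  seqs <- vapply(regions, function(r) r$sequence, character(1))
  hdrs <- vapply(regions, function(r)
    sprintf("%s anchor=%d", r$species_id, r$anchor_offset), character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Extract a slice of an upstream region in anchored coordinates
#'
#' The interval is half-open `[from_pos, to_pos)` with the A of the ATG at 0.
#' If the interval extends past the available coverage the covered part is
#' returned and flagged via the `truncated` attribute; attributes `from` and
#' `to` report the anchored interval actually covered.
#'
#' @param region An [upstream_region].
#' @param from_pos,to_pos Anchored interval bounds, `from_pos < to_pos`.
#' @return A character scalar with attributes `truncated`, `from`, `to`.
#' @export
slice_upstream <- function(region, from_pos, to_pos) {
  stopifnot(inherits(region, "upstream_region"))
  if (!(from_pos < to_pos)) {
    regel_error("empty or inverted interval: from_pos must be < to_pos",
                "regel_validation_error")
  }
  lo <- -region$anchor_offset
  hi <- nchar(region$sequence) - region$anchor_offset
  cf <- max(from_pos, lo)
  ct <- min(to_pos, hi)
  if (cf >= ct) {
    regel_error(sprintf("interval [%d, %d) has no overlap with coverage [%d, %d)",
                        from_pos, to_pos, lo, hi),
                "regel_coverage_error")
  }
  out <- substr(region$sequence,
                region$anchor_offset + cf + 1L,
                region$anchor_offset + ct)
  structure(out, truncated = (cf > from_pos || ct < to_pos),
            from = cf, to = ct)
}

#' Reverse complement of a nucleotide string
#'
#' Standard complement (N is self-complementary), reversed. Applying it twice
#' returns the input.
#'
#' @param seq A string over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, upper case.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    regel_error("reverse_complement: sequence contains characters outside A/C/G/T/N",
                "regel_alphabet_error")
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Define a reference regulatory element
#'
#' @param element_id One of `"enhancer"`, `"prr"`, `"cpg_island"`, `"promoter"`.
#' @param reference_species Species the reference sequence comes from (use
#'   `"synthetic"` for generated templates).
#' @param reference_sequence Nucleotide string of the reference element.
#' @param expected_window Length-2 integer vector: anchored half-open interval
#'   where the element is expected. Must start 5' of position 0.
#' @return An object of class `element_definition`.
#' @export
element_definition <- function(element_id, reference_species,
                               reference_sequence, expected_window) {
  element_id <- match.arg(element_id,
                          c("enhancer", "prr", "cpg_island", "promoter"))
  reference_sequence <- normalize_sequence(reference_sequence,
                                           context = element_id)
  stopifnot(nchar(reference_sequence) > 0L,
            length(expected_window) == 2L,
            expected_window[1] < expected_window[2],
            expected_window[1] < 0)
  structure(list(element_id = element_id,
                 reference_species = reference_species,
                 reference_sequence = reference_sequence,
                 expected_window = as.integer(expected_window)),
            class = "element_definition")
}

#' Read a species metadata table
#'
#' Tab-separated with header columns `species_id`, `taxon_group`,
#' `ucp1_status`.
#'
#' @param path Path to the TSV; defaults to the packaged survey metadata.
#' @return A data.frame.
#' @export
read_species_meta <- function(path = system.file("extdata", "species_meta.tsv",
                                                 package = "regelscreen")) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "taxon_group", "ucp1_status")
  if (!all(need %in% names(meta))) {
    regel_error("metadata table must have species_id, taxon_group, ucp1_status",
                "regel_parse_error")
  }
  if (anyDuplicated(meta$species_id)) {
    regel_error("duplicate species_id in metadata", "regel_validation_error")
  }
  meta
}
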