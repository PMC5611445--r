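# Majority-rule consensus over a multi-species alignment restricted to
# intact-gene species, and per-motif conservation summaries.

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @return A named character vector of equal-length gapped rows over
#'   A/C/G/T/N/-.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  validate_alignment(rows)
  rows
}

#' Write an alignment (or consensus) to FASTA
#'
#' @param rows Named character vector of gapped rows.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(rows, path) {
  set <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

validate_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) > 0L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    regel_error("alignment rows have unequal lengths",
                "regel_validation_error")
  }
  if (any(grepl("[^ACGTN-]", rows))) {
    regel_error("alignment rows contain characters outside A/C/G/T/N/-",
                "regel_validation_error")
  }
  invisible(rows)
}

#' Simple-majority consensus of an alignment
#'
#' Per column, the most frequent symbol among the included rows if its
#' frequency strictly exceeds 50%, else `N`. Each species votes once; gaps
#' are first-class symbols by default (`count_gaps = TRUE`), so a
#' gap-majority column yields `-`. With `count_gaps = FALSE`, gapped rows
#' are excluded from that column's vote (an all-gap column yields `-`).
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param include Species ids to vote (e.g. intact-gene species only).
#' @param count_gaps Whether gaps participate in the vote.
#' @return A list with `consensus` (string) and `support` (per-column
#'   fraction of the votes won by the consensus symbol).
#' @export
majority_consensus <- function(aln, include = names(aln),
                               count_gaps = TRUE) {
  validate_alignment(aln)
  if (length(include) == 0L) {
    regel_error("include set is empty", "regel_validation_error")
  }
  if (!all(include %in% names(aln))) {
    regel_error("include contains species absent from the alignment",
                "regel_validation_error")
  }
  rows <- aln[unique(include)]
  mat <- do.call(rbind, strsplit(rows, ""))
  n_col <- ncol(mat)
  cons <- character(n_col)
  supp <- numeric(n_col)
  for (j in seq_len(n_col)) {
    col <- mat[, j]
    if (!count_gaps) col <- col[col != "-"]
    if (length(col) == 0L) { cons[j] <- "-"; supp[j] <- 0; next }
    tab <- table(col)
    top <- which.max(tab)
    frac <- tab[[top]] / length(col)
    if (frac > 0.5) { cons[j] <- names(tab)[top]; supp[j] <- frac }
    else { cons[j] <- "N"; supp[j] <- frac }
  }
  list(consensus = paste(cons, collapse = ""), support = supp)
}

#' Summarise motif conservation by gene status
#'
#' Cross-tabulates per-species motif states against the species' gene
#' status (intact vs pseudogene), reporting per motif and status class the
#' fraction of species in each state. Species whose motif was `not_found`
#' are excluded from the denominators; motifs observed in no species are
#' dropped with a message.
#'
#' @param calls Data.frame with columns `species_id`, `motif_id`, `state`
#'   (e.g. rbind of [scan_species_motifs()] results).
#' @param meta Data.frame with `species_id` and `ucp1_status`.
#' @return A data.frame with `motif_id`, `ucp1_status`, `n`, and fraction
#'   columns `intact`, `variant`, `disrupted`, `deleted`.
#' @export
motif_conservation_summary <- function(calls, meta) {
  stopifnot(all(c("species_id", "motif_id", "state") %in% names(calls)),
            all(c("species_id", "ucp1_status") %in% names(meta)))
  calls <- merge(calls, meta[, c("species_id", "ucp1_status")],
                 by = "species_id")
  all_motifs <- unique(calls$motif_id)
  calls <- calls[calls$state != "not_found", , drop = FALSE]
  dropped <- setdiff(all_motifs, calls$motif_id)
  if (length(dropped)) {
    message("motifs observed in no species: ", paste(dropped, collapse = ", "))
  }
  states <- c("intact", "variant", "disrupted", "deleted")
  groups <- split(calls, list(calls$motif_id, calls$ucp1_status),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    fr <- vapply(states, function(s) mean(g$state == s), numeric(1))
    cbind(data.frame(motif_id = g$motif_id[1],
                     ucp1_status = g$ucp1_status[1], n = nrow(g)),
          as.data.frame(as.list(fr)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$motif_id, out$ucp1_status), , drop = FALSE]
  rownames(out) <- NULL
  out
}
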