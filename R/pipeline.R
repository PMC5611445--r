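# End-to-end orchestration: simulate or load upstream regions, locate
# elements, scan CpG islands and motifs, build the consensus, assemble the
# presence matrix, and map gains/losses on the species tree.

write_stage_tsv <- function(df, out_dir, name, run_tag) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, name)
  con <- file(path, "w")
  writeLines(run_tag, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the comparative screening pipeline
#'
#' Either simulates a dataset (when `config` is a [sim_config]) or consumes
#' `regions` / `tree` / `meta` supplied directly, then runs every stage:
#' element presence calling (dot-plot homology for enhancer, PRR, and
#' promoter; sliding-window detection for the CpG island), motif-state
#' scanning over located enhancers and promoters, majority consensus over
#' intact-gene species (simulated runs use the truth alignment restricted
#' to the enhancer columns), the presence matrix with tallies, and Dollo
#' gain/loss mapping per element.
#'
#' @param config A [sim_config], or NULL when `regions` are supplied.
#' @param regions Named list of [upstream_region] (ignored when simulating).
#' @param tree Rooted `phylo` tree (defaults to the simulation tree).
#' @param meta Species metadata data.frame.
#' @param elements Element library (named list of [element_definition]).
#' @param catalog Motif catalog.
#' @param dot_params,cpg_par Stage parameter objects.
#' @param min_conserved_length,search_pad Presence-call settings.
#' @param out_dir Optional directory for TSV/FASTA artifacts.
#' @param seed Seed recorded in the run log and used for simulation.
#' @return A list with `presence` (matrix), `calls`, `motif_states`,
#'   `cpg_islands`, `consensus`, `gain_loss`, `tallies`, and (simulated
#'   runs) `truth`.
#' @export
run_pipeline <- function(config = sim_config(), regions = NULL, tree = NULL,
                         meta = NULL, elements = NULL,
                         catalog = load_default_catalog(),
                         dot_params = dotplot_params(),
                         cpg_par = cpg_params(),
                         min_conserved_length = 100L, search_pad = 2000L,
                         out_dir = NULL, seed = NULL) {
  truth <- NULL
  if (is.null(regions)) {
    stopifnot(inherits(config, "sim_config"))
    if (is.null(seed)) seed <- config$seed
    sim <- simulate_dataset(config, seed = seed)
    regions <- sim$regions
    truth <- sim$truth
    if (is.null(meta)) meta <- sim$meta
    if (is.null(tree)) tree <- config$tree
    if (is.null(elements)) {
      elements <- default_element_library(
        build_root_template(config$catalog, config$span, config$gc))
    }
    catalog <- config$catalog
  }
  if (is.null(elements)) elements <- default_element_library()
  if (is.null(seed)) seed <- NA_integer_
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  run_tag <- sprintf("# regelscreen %s | seed=%s | window=%d threshold=%g minlen=%d",
                     as.character(utils::packageVersion("regelscreen")),
                     seed, dot_params$window, dot_params$threshold,
                     min_conserved_length)

  # stage: element presence + located intervals
  calls <- list(); located <- list()
  for (sp in names(regions)) {
    located[[sp]] <- list()
    for (el in names(elements)) {
      if (el == "cpg_island") next
      pc <- call_element_presence(regions[[sp]], elements[[el]],
                                  params = dot_params,
                                  min_conserved_length = min_conserved_length,
                                  search_pad = search_pad)
      calls[[length(calls) + 1L]] <- pc
      if (pc$state == "present") located[[sp]][[el]] <- pc$located_interval
    }
  }

  # stage: CpG islands over the proximal scan span
  cpg_rows <- list()
  for (sp in names(regions)) {
    win <- elements$cpg_island$expected_window
    slice <- tryCatch(slice_upstream(regions[[sp]], win[1], win[2]),
                      regel_coverage_error = function(e) NULL)
    state <- "no_coverage"; islands <- NULL
    if (!is.null(slice) &&
        nchar(slice) >= max(cpg_par$window,
                            0.5 * diff(elements$cpg_island$expected_window))) {
      islands <- suppressWarnings(detect_cpg_islands(as.character(slice),
                                                     cpg_par))
      state <- if (nrow(islands)) "present" else "absent"
      if (nrow(islands)) {
        cpg_rows[[length(cpg_rows) + 1L]] <- cbind(species_id = sp, islands)
      }
    }
    calls[[length(calls) + 1L]] <- structure(
      list(species_id = sp, element_id = "cpg_island", state = state,
           located_interval = NULL, best_segment_length = NA_integer_,
           covered_length = if (is.null(slice)) 0L else nchar(slice)),
      class = "presence_call")
  }
  cpg_islands <- if (length(cpg_rows)) do.call(rbind, cpg_rows) else
    data.frame(species_id = character(0), start = integer(0),
               end = integer(0), mean_obs_exp = numeric(0),
               mean_gc = numeric(0))

  # stage: motif states over located enhancers and promoters
  motif_states <- do.call(rbind, lapply(names(regions), function(sp) {
    do.call(rbind, lapply(c("enhancer", "promoter"), function(el) {
      scan_species_motifs(regions[[sp]], elements[[el]], catalog,
                          located_interval = located[[sp]][[el]],
                          species_id = sp)
    }))
  }))

  presence <- build_presence_matrix(calls, species = names(regions),
                                    elements = names(elements))

  # stage: consensus over intact-gene species
  consensus <- NULL
  if (!is.null(truth) && !is.null(meta)) {
    aln <- truth_alignment(truth)
    enh <- truth$template$elements[
      truth$template$elements$element_id == "enhancer", ]
    cc <- attr(aln, "column_coords")
    keep <- cc >= enh$root_start & cc < enh$root_end
    enh_aln <- vapply(aln, function(r)
      paste(strsplit(r, "")[[1]][keep], collapse = ""), character(1))
    include <- meta$species_id[meta$ucp1_status == "intact"]
    if (length(include)) {
      consensus <- majority_consensus(enh_aln, include = include)
    }
  }

  # stage: gain/loss per element (skipped when no tip is present)
  gain_loss <- list()
  for (el in names(elements)) {
    gl <- tryCatch(dollo_losses(tree, presence, el),
                   regel_error = function(e) NULL)
    if (!is.null(gl)) gain_loss[[el]] <- gl
  }

  tallies <- do.call(rbind, lapply(names(elements), function(el) {
    tl <- count_matrix_tallies(presence, meta, el)
    data.frame(element_id = el, n_present = tl$n_present,
               n_with_coverage = tl$n_with_coverage, n_total = tl$n_total)
  }))

  if (!is.null(out_dir)) {
    pc_df <- as.data.frame(presence)
    write_stage_tsv(pc_df, out_dir, "presence_matrix.tsv", run_tag)
    write_stage_tsv(motif_states, out_dir, "motif_states.tsv", run_tag)
    write_stage_tsv(cpg_islands, out_dir, "cpg_islands.tsv", run_tag)
    write_stage_tsv(tallies, out_dir, "tallies.tsv", run_tag)
    if (!is.null(consensus)) {
      write_alignment_fasta(
        c(consensus_eutherian = consensus$consensus),
        file.path(out_dir, "consensus.fasta"))
    }
    for (el in names(gain_loss)) {
      write_gain_loss(gain_loss[[el]], tree,
                      tsv_path = file.path(out_dir,
                                           paste0("gain_loss_", el, ".tsv")),
                      nwk_path = file.path(out_dir,
                                           paste0("gain_loss_", el, ".nwk")))
    }
    write_upstream_fasta(regions, file.path(out_dir, "regions.fasta"))
  }

  list(presence = presence, calls = calls, motif_states = motif_states,
       cpg_islands = cpg_islands, consensus = consensus,
       gain_loss = gain_loss, tallies = tallies, truth = truth)
}

#' Matrix-only stage: tallies and gain/loss from a pre-filled survey
#'
#' Runs the phylogenetic and tally stages directly from a presence matrix
#' (e.g. the packaged survey transcription), without sequence data.
#'
#' @param survey A `presence_matrix` (default: the packaged curated survey).
#' @param tree Rooted species tree (default: the packaged mammal tree).
#' @param meta Metadata (default: the packaged survey metadata).
#' @param elements Elements to process.
#' @param out_dir Optional output directory.
#' @return A list with `tallies` (per element and taxon filters) and
#'   `gain_loss`.
#' @export
run_matrix_stage <- function(survey = ucp1_survey(), tree = mammal_tree(),
                             meta = read_species_meta(),
                             elements = c("enhancer", "prr", "cpg_island"),
                             out_dir = NULL) {
  tallies <- do.call(rbind, lapply(elements, function(el) {
    all <- count_matrix_tallies(survey, meta, el)
    eut <- count_matrix_tallies(survey, meta, el, groups = EUTHERIAN_GROUPS)
    data.frame(element_id = el,
               n_present_eutherian = eut$n_present,
               n_with_coverage_eutherian = eut$n_with_coverage,
               n_eutherian = eut$n_total,
               n_present_total = all$n_present, n_total = all$n_total)
  }))
  gain_loss <- list()
  for (el in elements) {
    gl <- tryCatch(dollo_losses(tree, survey, el),
                   regel_error = function(e) NULL)
    if (!is.null(gl)) gain_loss[[el]] <- gl
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(tallies, file.path(out_dir, "tallies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (el in names(gain_loss)) {
      write_gain_loss(gain_loss[[el]], tree,
                      tsv_path = file.path(out_dir,
                                           paste0("gain_loss_", el, ".tsv")))
    }
  }
  list(tallies = tallies, gain_loss = gain_loss)
}
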