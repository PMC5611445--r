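# Species x element presence matrix and Dollo parsimony gain/loss mapping
# on a rooted species tree (single gain, irreversible losses; no_coverage
# species are missing data and never force a loss).

PRESENCE_STATES <- c("present", "absent", "no_coverage")

#' Assemble a presence matrix from individual calls
#'
#' @param calls Either a list of `presence_call` objects or a data.frame
#'   with columns `species_id`, `element_id`, `state`.
#' @param species,elements Optional full sets; missing (species, element)
#'   pairs are filled as `no_coverage` with a message.
#' @return A data.frame of class `presence_matrix` with columns
#'   `species_id`, `element_id`, `state`.
#' @export
build_presence_matrix <- function(calls, species = NULL, elements = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(x) {
      data.frame(species_id = x$species_id, element_id = x$element_id,
                 state = x$state)
    }))
  }
  stopifnot(all(c("species_id", "element_id", "state") %in% names(calls)),
            all(calls$state %in% PRESENCE_STATES))
  key <- paste(calls$species_id, calls$element_id)
  if (anyDuplicated(key)) {
    dup <- calls[key %in% key[duplicated(key)], , drop = FALSE]
    if (nrow(unique(dup)) != length(unique(paste(dup$species_id,
                                                 dup$element_id)))) {
      regel_error("conflicting duplicate presence calls",
                  "regel_validation_error")
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  species <- if (is.null(species)) unique(calls$species_id) else species
  elements <- if (is.null(elements)) unique(calls$element_id) else elements
  full <- expand.grid(species_id = species, element_id = elements,
                      stringsAsFactors = FALSE)
  out <- merge(full, calls, by = c("species_id", "element_id"),
               all.x = TRUE, sort = FALSE)
  n_missing <- sum(is.na(out$state))
  if (n_missing) {
    message(n_missing, " (species, element) pair(s) without a call filled as no_coverage")
    out$state[is.na(out$state)] <- "no_coverage"
  }
  out <- out[order(out$element_id, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("presence_matrix", "data.frame")
  out
}

matrix_states <- function(matrix, element_id) {
  m <- matrix[matrix$element_id == element_id, , drop = FALSE]
  if (nrow(m) == 0L) {
    regel_error(sprintf("no calls for element '%s'", element_id),
                "regel_validation_error")
  }
  stats::setNames(m$state, m$species_id)
}

branch_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  lab <- tree$node.label[node - n_tip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", node) else lab
}

tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

#' Infer the gain branch of an element under a single-gain model
#'
#' Returns the branch subtending the most recent common ancestor of all
#' tips where the element is present (for a single present tip, its
#' terminal branch).
#'
#' @param tree A rooted `phylo` tree whose tip labels match the matrix
#'   species ids.
#' @param matrix A [build_presence_matrix()] result.
#' @param element_id Element to map.
#' @return A list with `node` (the child end of the gain branch) and
#'   `branch` (its label).
#' @export
infer_gain_branch <- function(tree, matrix, element_id) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    regel_error("tree must be rooted", "regel_validation_error")
  }
  states <- matrix_states(matrix, element_id)
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra)) {
    regel_error(sprintf("species not in the tree: %s",
                        paste(extra, collapse = ", ")),
                "regel_validation_error")
  }
  present <- names(states)[states == "present"]
  if (length(present) == 0L) {
    regel_error(sprintf("element '%s' is present in no tip", element_id),
                "regel_validation_error")
  }
  node <- if (length(present) == 1L) {
    match(present, tree$tip.label)
  } else {
    ape::getMRCA(tree, present)
  }
  list(node = node, branch = branch_label(tree, node))
}

#' Map losses of an element under Dollo parsimony
#'
#' Given the (inferred or supplied) gain branch, finds the minimal set of
#' loss branches such that a tip lacks the element iff it descends from a
#' loss. Tips with `no_coverage` are missing data: they are compatible with
#' either state and never force a loss. A loss is placed on the highest
#' branch of each maximal present-free subtree that contains at least one
#' covered absent tip.
#'
#' @param tree Rooted `phylo` tree.
#' @param matrix A [build_presence_matrix()] result.
#' @param element_id Element to map.
#' @param gain Optional result of [infer_gain_branch()]; inferred when NULL.
#' @return An object of class `gain_loss_map`: list with `element_id`,
#'   `gain_branch`, `gain_node`, `loss_branches`, `loss_nodes`,
#'   `n_independent_losses`, and `ambiguous_placement` (losses whose branch
#'   choice is not unique because of missing-data tips).
#' @export
dollo_losses <- function(tree, matrix, element_id, gain = NULL) {
  if (is.null(gain)) gain <- infer_gain_branch(tree, matrix, element_id)
  states <- matrix_states(matrix, element_id)
  n_tip <- length(tree$tip.label)
  tip_state <- rep("missing", n_tip)
  idx <- match(names(states), tree$tip.label)
  tip_state[idx[states == "present"]] <- "present"
  tip_state[idx[states == "absent"]] <- "absent"

  # present tips must all descend from the gain branch
  desc <- if (gain$node <= n_tip) gain$node else {
    prune <- ape::extract.clade(tree, gain$node)
    match(prune$tip.label, tree$tip.label)
  }
  outside_present <- setdiff(which(tip_state == "present"), desc)
  if (length(outside_present)) {
    regel_error(sprintf("present tip(s) outside the gain clade: %s",
                        paste(tree$tip.label[outside_present],
                              collapse = ", ")),
                "regel_dollo_error")
  }

  # post-order subtree summary: has_present / has_absent below each node
  has_present <- logical(n_tip + tree$Nnode)
  has_absent <- logical(n_tip + tree$Nnode)
  has_present[seq_len(n_tip)] <- tip_state == "present"
  has_absent[seq_len(n_tip)] <- tip_state == "absent"
  depth <- integer(n_tip + tree$Nnode)
  queue <- n_tip + 1L                     # root
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    kids <- tree_children(tree, node)
    depth[kids] <- depth[node] + 1L
    queue <- c(queue, kids)
  }
  edges <- tree$edge[order(-depth[tree$edge[, 2]]), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; ch <- edges[e, 2]
    has_present[par] <- has_present[par] || has_present[ch]
    has_absent[par] <- has_absent[par] || has_absent[ch]
  }

  loss_nodes <- integer(0)
  ambiguous <- logical(0)
  walk <- function(node) {
    if (!has_present[node]) {
      if (has_absent[node]) {
        loss_nodes <<- c(loss_nodes, node)
        # placement is ambiguous if the subtree mixes covered-absent and
        # missing-data tips (a deeper loss explains the data equally well)
        kids <- tree_children(tree, node)
        amb <- length(kids) > 0L && any(!has_absent[kids])
        ambiguous <<- c(ambiguous, amb)
      }
      return(invisible())
    }
    for (ch in tree_children(tree, node)) walk(ch)
  }
  walk(gain$node)

  structure(list(element_id = element_id, gain_branch = gain$branch,
                 gain_node = gain$node,
                 loss_branches = vapply(loss_nodes, function(n)
                   branch_label(tree, n), character(1)),
                 loss_nodes = loss_nodes,
                 n_independent_losses = length(loss_nodes),
                 ambiguous_placement = ambiguous),
            class = "gain_loss_map")
}

#' @export
print.gain_loss_map <- function(x, ...) {
  cat(sprintf("<gain_loss_map> %s: gain on '%s', %d independent loss(es)\n",
              x$element_id, x$gain_branch, x$n_independent_losses))
  if (x$n_independent_losses) {
    cat("  losses:", paste(x$loss_branches, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tally presence calls
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param meta Optional metadata data.frame (`species_id`, `taxon_group`,
#'   `ucp1_status`) used for filtering.
#' @param element_id Element to tally.
#' @param groups Optional taxon groups to keep (e.g. eutherian superorders).
#' @param status Optional `ucp1_status` filter.
#' @return A list with `n_present`, `n_with_coverage`, `n_total`.
#' @export
count_matrix_tallies <- function(matrix, meta = NULL, element_id,
                                 groups = NULL, status = NULL) {
  m <- matrix[matrix$element_id == element_id, , drop = FALSE]
  if (!is.null(meta)) {
    keep <- meta$species_id
    if (!is.null(groups)) keep <- keep[meta$taxon_group %in% groups]
    if (!is.null(status)) {
      keep <- intersect(keep,
                        meta$species_id[meta$ucp1_status %in% status])
    }
    m <- m[m$species_id %in% keep, , drop = FALSE]
  }
  list(n_present = sum(m$state == "present"),
       n_with_coverage = sum(m$state != "no_coverage"),
       n_total = nrow(m))
}

EUTHERIAN_GROUPS <- c("Xenarthra", "Afrotheria", "Laurasiatheria",
                      "Euarchontoglires")

#' Load the packaged regulatory-element survey table
#'
#' A transcription of the 139-species survey of enhancer, PRR, and CpG
#' island presence (`Yes` = present, `X` = absent, `/` = no coverage),
#' returned as a long-format [build_presence_matrix()].
#'
#' With `curated = TRUE` (default) the two-toed sloth (*Choloepus
#' hoffmanni*) enhancer call is downgraded from absent to `no_coverage`:
#' no anchored upstream contig exists for this species (genome-wide BLAST
#' found nothing), and the survey's own loss accounting treats its state as
#' unresolved rather than as an additional independent loss.
#'
#' @param curated Apply the sloth coverage curation.
#' @param path Path to the survey TSV (defaults to the packaged table).
#' @return A `presence_matrix` data.frame.
#' @export
ucp1_survey <- function(curated = TRUE,
                        path = system.file("extdata", "ucp1_survey.tsv",
                                           package = "regelscreen")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  code <- c(Yes = "present", X = "absent", "/" = "no_coverage")
  long <- do.call(rbind, lapply(c("enhancer", "prr", "cpg_island"),
    function(el) data.frame(species_id = tab$species_id, element_id = el,
                            state = unname(code[tab[[el]]]))))
  if (any(is.na(long$state))) {
    regel_error("survey table contains states outside Yes/X//",
                "regel_parse_error")
  }
  if (curated) {
    long$state[long$species_id == "Choloepus_hoffmanni" &
                 long$element_id == "enhancer"] <- "no_coverage"
  }
  build_presence_matrix(long)
}

#' Load the packaged mammal species tree
#'
#' Rooted topology (no branch lengths) covering the 139 surveyed species.
#'
#' @return An `ape::phylo` tree.
#' @export
mammal_tree <- function() {
  ape::read.tree(system.file("extdata", "mammal_tree.nwk",
                             package = "regelscreen"))
}

#' Write a gain/loss map as TSV and annotated newick
#'
#' @param map A [dollo_losses()] result.
#' @param tree The tree the map was computed on.
#' @param tsv_path,nwk_path Output paths (NULL to skip one of them).
#' @export
write_gain_loss <- function(map, tree, tsv_path = NULL, nwk_path = NULL) {
  events <- data.frame(
    element_id = map$element_id,
    branch = c(map$gain_branch, map$loss_branches),
    event = c("gain", rep("loss", map$n_independent_losses)))
  if (!is.null(tsv_path)) {
    utils::write.table(events, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(nwk_path)) {
    tr <- tree
    n_tip <- length(tr$tip.label)
    tag <- function(node, what) {
      if (node <= n_tip) {
        tr$tip.label[node] <<- paste0(tr$tip.label[node], "[", what, "]")
      } else {
        lab <- tr$node.label[node - n_tip]
        tr$node.label[node - n_tip] <<-
          paste0(ifelse(is.na(lab) | !nzchar(lab), "", lab), "[", what, "]")
      }
    }
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    tag(map$gain_node, paste0("gain_", map$element_id))
    for (n in map$loss_nodes) tag(n, paste0("loss_", map$element_id))
    ape::write.tree(tr, file = nwk_path)
  }
  invisible(events)
}
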