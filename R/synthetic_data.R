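# Synthetic upstream-region generator: a fixed root template carrying the
# regulatory elements at their expected offsets is evolved down a rooted
# tree under a symmetric (JC-style) substitution model with geometric
# indels, per-branch rate multipliers for pseudogene lineages, and
# branch-specific element deletions. Every residue carries an ancestral
# coordinate so the generator can emit a gap-correct truth alignment and
# per-tip truth tables for all downstream stages.

SIM_BASES <- c("A", "C", "G", "T")

sample_background <- function(n, gc) {
  sample(SIM_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

concretize_iupac <- function(pattern, fallback) {
  ch <- strsplit(pattern, "")[[1]]
  vapply(seq_along(ch), function(i) {
    if (ch[i] %in% SIM_BASES) ch[i]
    else if (ch[i] == "N") fallback[i]
    else IUPAC_SETS[[ch[i]]][1]
  }, character(1))
}

#' Build the ancestral (root) upstream template
#'
#' Assembles, deterministically, the ancestral sequence the simulator
#' evolves: background at the given GC fraction over the anchored span,
#' with a 200 bp enhancer carrying the catalogued motifs at -4 kb, a 678 bp
#' PRR at -2.5 kb, a CpG-qualifying GC-rich block over the promoter/exon-1
#' boundary, and the basal promoter motifs (TATA near -270, the proximal
#' GCCCCT pair, CRE-4, CCAAT) at their anchored offsets. The murid-specific
#' most-upstream GCCCCT site is deliberately left out of the template.
#'
#' @param catalog A `motif_catalog`.
#' @param span Anchored half-open interval simulated (default
#'   `c(-10000, 200)`).
#' @param gc Background GC fraction (default 0.40).
#' @return A list with `bases` (character vector), `elements` and `motifs`
#'   (data.frames with 1-based root coordinates), `core_coords` (root
#'   coordinates of motif critical cores), `anchor_coord` (root coordinate
#'   of anchored position 0), and `span`.
#' @export
build_root_template <- function(catalog = load_default_catalog(),
                                span = c(-10000L, 200L), gc = 0.40) {
  stopifnot(span[1] < -5000L, span[2] >= 200L)
  withr::with_seed(20170920L, {
    L <- span[2] - span[1]
    to_root <- function(pos) pos - span[1] + 1L   # anchored -> 1-based root
    bases <- sample_background(L, gc)

    # CpG island block [-250, 150): GC-rich iid letters (independent letters
    # keep observed/expected CpG near 1, comfortably above the 0.6 bar)
    cpg_start <- to_root(-250L); cpg_len <- 400L
    bases[cpg_start:(cpg_start + cpg_len - 1L)] <-
      sample(SIM_BASES, cpg_len, replace = TRUE,
             prob = c(0.17, 0.33, 0.33, 0.17))

    # enhancer: 200 bp at -4000 with catalogued motifs at their offsets
    enh_start <- to_root(-4000L); enh_len <- 200L
    motif_rows <- list()
    place <- function(def, elem_start) {
      s <- elem_start + def$offset
      seg <- concretize_iupac(def$consensus,
                              bases[s:(s + nchar(def$consensus) - 1L)])
      bases[s:(s + length(seg) - 1L)] <<- seg
      motif_rows[[length(motif_rows) + 1L]] <<- data.frame(
        motif_id = def$motif_id, element = def$element,
        root_start = s, length = length(seg))
    }
    for (def in catalog) {
      if (def$type != "simple" || is.na(def$offset)) next
      if (def$element == "enhancer") place(def, enh_start)
    }

    # PRR: 678 bp of background at -2500 (conserved block, no fixed motifs)
    prr_start <- to_root(-2500L); prr_len <- 678L

    # promoter motifs at their anchored offsets (element local 0 = -600),
    # skipping the murid-restricted GCCCCT-1
    prom_start <- to_root(-600L)
    for (def in catalog) {
      if (def$type != "simple" || is.na(def$offset)) next
      if (def$element == "promoter" && def$motif_id != "GCCCCT-1") {
        place(def, prom_start)
      }
    }

    elements <- data.frame(
      element_id = c("enhancer", "prr", "cpg_island", "promoter"),
      root_start = c(enh_start, prr_start, cpg_start, prom_start),
      root_end = c(enh_start + enh_len, prr_start + prr_len,
                   cpg_start + cpg_len, prom_start + 600L))
    motifs <- do.call(rbind, motif_rows)
    core_coords <- unlist(lapply(catalog, function(def) {
      if (def$type != "simple" || is.na(def$offset) ||
          length(def$core) == 0L) return(integer(0))
      row <- motifs[motifs$motif_id == def$motif_id, , drop = FALSE]
      if (nrow(row) == 0L) return(integer(0))
      row$root_start[1] + def$core
    }))
    list(bases = bases, elements = elements, motifs = motifs,
         core_coords = sort(unique(core_coords)),
         anchor_coord = to_root(0L), span = as.integer(span))
  })
}

#' Reference element library derived from the root template
#'
#' Element definitions whose reference sequences are the synthetic template
#' slices, with the expected anchored search windows (enhancer -5 to -2 kb,
#' PRR around -2.7 to -1.8 kb, CpG island and promoter over the proximal
#' region).
#'
#' @param template A [build_root_template()] result.
#' @return Named list of [element_definition] objects.
#' @export
default_element_library <- function(template = build_root_template()) {
  el <- template$elements
  window <- list(enhancer = c(-5000L, -2000L), prr = c(-2700L, -1800L),
                 cpg_island = c(-600L, 200L), promoter = c(-600L, 0L))
  defs <- lapply(seq_len(nrow(el)), function(i) {
    id <- el$element_id[i]
    element_definition(
      element_id = id, reference_species = "synthetic",
      reference_sequence = paste(
        template$bases[el$root_start[i]:(el$root_end[i] - 1L)],
        collapse = ""),
      expected_window = window[[id]])
  })
  names(defs) <- el$element_id
  defs
}

#' Default simulation tree
#'
#' A 10-tip mammal-like topology with named internal nodes and branch
#' lengths in expected substitutions per site (root-to-tip paths around
#' 0.10-0.12). The cetacean clade doubles as the default pseudogene
#' lineage.
#'
#' @return An `ape::phylo` tree.
#' @export
default_sim_tree <- function() {
  ape::read.tree(text = paste0(
    "((((sperm_whale:0.030,(killer_whale:0.015,bottlenose_dolphin:0.015)",
    "delphinid:0.015)cetacea:0.020,cow:0.050)cetartiodactyla:0.030,",
    "(dog:0.040,cat:0.040)carnivora:0.040)laurasiatheria:0.030,",
    "((mouse:0.060,rat:0.060)muridae:0.030,(human:0.040,macaque:0.040)",
    "primates:0.050)euarchontoglires:0.020)eutheria;"))
}

#' Simulation configuration
#'
#' @param tree Rooted `phylo` tree with branch lengths in expected
#'   substitutions per site; internal node labels name branches for events.
#' @param span Anchored half-open interval simulated.
#' @param gc Background GC fraction.
#' @param indel_rate Indel events per site per substitution unit of branch
#'   length (default 0.05, i.e. one indel per 20 substitutions).
#' @param indel_mean_len Mean indel length in bp (geometric; default 3).
#' @param pseudogene_branches Branch labels whose entire descendant lineage
#'   evolves at `rate_multiplier` times the branch-length rate and whose
#'   descendant tips are flagged `pseudogene`.
#' @param rate_multiplier Substitution/indel rate multiplier on pseudogene
#'   lineages (>= 1; default 2).
#' @param deletion_events Named list: branch label -> element id(s) deleted
#'   on that branch.
#' @param indels_in_cores Allow indels inside motif critical cores
#'   (default FALSE, keeping motif-state truth well defined).
#' @param taxon_groups Optional named character vector tip -> taxon group.
#' @param seed Default seed used by [simulate_dataset()].
#' @param catalog Motif catalog used to build the root template.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tree = default_sim_tree(), span = c(-10000L, 200L),
                       gc = 0.40, indel_rate = 0.05, indel_mean_len = 3,
                       pseudogene_branches = "cetacea",
                       rate_multiplier = 2,
                       deletion_events = list(delphinid = "enhancer"),
                       indels_in_cores = FALSE, taxon_groups = NULL,
                       seed = 1L, catalog = load_default_catalog()) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            rate_multiplier >= 1, gc > 0, gc < 1,
            indel_rate >= 0, indel_mean_len >= 1)
  bad <- setdiff(unlist(deletion_events),
                 c("enhancer", "prr", "cpg_island", "promoter"))
  if (length(bad)) {
    regel_error(sprintf("unknown element(s) in deletion_events: %s",
                        paste(bad, collapse = ", ")),
                "regel_config_error")
  }
  structure(list(tree = tree, span = as.integer(span), gc = gc,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 pseudogene_branches = pseudogene_branches,
                 rate_multiplier = rate_multiplier,
                 deletion_events = deletion_events,
                 indels_in_cores = indels_in_cores,
                 taxon_groups = taxon_groups, seed = as.integer(seed),
                 catalog = catalog),
            class = "sim_config")
}

jc_subst_prob <- function(t) 0.75 * (1 - exp(-4 * t / 3))

#' Simulate an upstream-region dataset with ground truth
#'
#' Evolves the root template down the configured tree. Per branch of length
#' t (times the pseudogene multiplier where applicable) each site
#' substitutes with probability `3/4 (1 - exp(-4t/3))` to a uniformly
#' chosen different base; indel events arrive at `indel_rate` per site per
#' substitution unit with geometric lengths; configured deletions excise
#' the element's interval exactly. Deterministic for a fixed seed.
#'
#' @param config A [sim_config].
#' @param seed Seed for all randomness (default `config$seed`).
#' @return A list of class `sim_result` with `regions` (named list of
#'   [upstream_region]), `truth` (class `sim_truth`), and `meta`
#'   (species metadata data.frame).
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  template <- build_root_template(config$catalog, config$span, config$gc)
  tree <- config$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  L0 <- length(template$bases)
  core_set <- if (config$indels_in_cores) integer(0) else template$core_coords

  tips <- list()
  events <- list()
  uid_counter <- 0L

  withr::with_seed(seed, {
    evolve <- function(node, state, deleted, mult) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (length(kids) == 0L) {
        tips[[tree$tip.label[node]]] <<-
          c(state, list(deleted = deleted, pseudo = mult > 1))
        return(invisible())
      }
      for (k in seq_along(kids)) {
        child <- kids[k]
        t_len <- tree$edge.length[which(tree$edge[, 2] == child)]
        lab <- branch_label(tree, child)
        mult_k <- if (lab %in% config$pseudogene_branches)
          max(mult, config$rate_multiplier) else mult
        st <- state
        del_k <- deleted

        # branch-specific element deletions (exact template interval)
        if (lab %in% names(config$deletion_events)) {
          for (el in config$deletion_events[[lab]]) {
            if (el %in% del_k) {
              regel_error(sprintf(
                "element '%s' deleted twice on the path through '%s'",
                el, lab), "regel_config_error")
            }
            row <- template$elements[template$elements$element_id == el, ]
            drop <- st$coord >= row$root_start & st$coord < row$root_end
            st$b <- st$b[!drop]; st$coord <- st$coord[!drop]
            st$uid <- st$uid[!drop]
            del_k <- c(del_k, el)
            events[[length(events) + 1L]] <<-
              data.frame(branch = lab, type = "deletion", element = el)
          }
        }

        eff_t <- t_len * mult_k
        # substitutions
        p <- jc_subst_prob(eff_t)
        n_cur <- length(st$b)
        hit <- which(stats::runif(n_cur) < p)
        if (length(hit)) {
          cur <- match(st$b[hit], SIM_BASES)
          st$b[hit] <- SIM_BASES[((cur - 1L +
            sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
        }
        # indels
        n_ev <- stats::rpois(1L, length(st$b) * eff_t * config$indel_rate)
        for (ev in seq_len(n_ev)) {
          n_cur <- length(st$b)
          if (n_cur < 2L) break
          len_ev <- stats::rgeom(1L, 1 / config$indel_mean_len) + 1L
          if (stats::runif(1) < 0.5) {        # deletion
            pos <- sample.int(n_cur, 1L)
            idx <- pos:min(n_cur, pos + len_ev - 1L)
            if (any(st$coord[idx] %in% core_set)) next
            st$b <- st$b[-idx]; st$coord <- st$coord[-idx]
            st$uid <- st$uid[-idx]
          } else {                             # insertion after pos
            pos <- sample.int(n_cur - 1L, 1L)
            if (st$coord[pos] %in% core_set &&
                st$coord[pos + 1L] %in% core_set) next
            c_l <- st$coord[pos]; c_r <- st$coord[pos + 1L]
            new_coord <- c_l + (c_r - c_l) * seq_len(len_ev) / (len_ev + 1)
            new_uid <- uid_counter + seq_len(len_ev)
            uid_counter <<- uid_counter + len_ev
            ins <- sample_background(len_ev, config$gc)
            st$b <- append(st$b, ins, after = pos)
            st$coord <- append(st$coord, new_coord, after = pos)
            st$uid <- append(st$uid, new_uid, after = pos)
          }
        }
        evolve(child, st, del_k, mult_k)
      }
    }
    root_state <- list(b = template$bases, coord = as.numeric(seq_len(L0)),
                       uid = rep(0L, L0))
    evolve(root, root_state, character(0), 1)
  })

  # assemble outputs
  regions <- list(); elem_truth <- list(); motif_truth <- list()
  for (sp in names(tips)) {
    tp <- tips[[sp]]
    anchor <- sum(tp$coord < template$anchor_coord)
    regions[[sp]] <- upstream_region(sp, paste(tp$b, collapse = ""), anchor)
    for (i in seq_len(nrow(template$elements))) {
      el <- template$elements$element_id[i]
      rs <- template$elements$root_start[i]
      re <- template$elements$root_end[i]
      idx <- which(tp$coord >= rs & tp$coord < re)
      present <- !(el %in% tp$deleted) && length(idx) > 0L
      elem_truth[[length(elem_truth) + 1L]] <- data.frame(
        species_id = sp, element_id = el, present = present,
        start = if (length(idx)) min(idx) - 1L - anchor else NA_integer_,
        end = if (length(idx)) max(idx) - anchor else NA_integer_)
    }
    for (i in seq_len(nrow(template$motifs))) {
      m <- template$motifs[i, ]
      def <- config$catalog[[m$motif_id]]
      coords <- m$root_start:(m$root_start + m$length - 1L)
      hitpos <- match(coords, tp$coord)
      obs <- ifelse(is.na(hitpos), "-", tp$b[hitpos])
      call <- classify_motif_state(paste(obs, collapse = ""), def)
      motif_truth[[length(motif_truth) + 1L]] <- data.frame(
        species_id = sp, motif_id = m$motif_id, element = m$element,
        state = call$state)
    }
  }
  meta <- data.frame(
    species_id = names(tips),
    taxon_group = if (is.null(config$taxon_groups)) "simulated"
      else unname(config$taxon_groups[names(tips)]),
    ucp1_status = ifelse(vapply(tips, `[[`, logical(1), "pseudo"),
                         "pseudogene", "intact"))
  truth <- structure(list(
    config = config, template = template,
    tips = lapply(tips, function(tp) tp[c("b", "coord", "uid", "deleted")]),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(branch = character(0), type = character(0),
                 element = character(0)),
    elements = do.call(rbind, elem_truth),
    motifs = do.call(rbind, motif_truth)), class = "sim_truth")
  structure(list(regions = regions, truth = truth, meta = meta),
            class = "sim_result")
}

#' Alignment induced by the true homology map
#'
#' Builds the multiple alignment implied by each residue's ancestral
#' coordinate: one column per root residue (whether or not it survives
#' anywhere) plus one column per surviving inserted residue, so the column
#' count equals the root length plus the total surviving insertion length.
#'
#' @param truth A `sim_truth` from [simulate_dataset()].
#' @return Named character vector of gapped rows (one per tip) with
#'   attribute `column_coords` giving each column's ancestral coordinate.
#' @export
truth_alignment <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  L0 <- length(truth$template$bases)
  keys <- list(data.frame(coord = as.numeric(seq_len(L0)), uid = 0L))
  for (tp in truth$tips) {
    ins <- tp$uid > 0L
    if (any(ins)) {
      keys[[length(keys) + 1L]] <- data.frame(coord = tp$coord[ins],
                                              uid = tp$uid[ins])
    }
  }
  cols <- unique(do.call(rbind, keys))
  cols <- cols[order(cols$coord, cols$uid), , drop = FALSE]
  key_str <- paste(sprintf("%.12g", cols$coord), cols$uid)
  rows <- vapply(truth$tips, function(tp) {
    row <- rep("-", nrow(cols))
    at <- match(paste(sprintf("%.12g", tp$coord), tp$uid), key_str)
    row[at] <- tp$b
    paste(row, collapse = "")
  }, character(1))
  attr(rows, "column_coords") <- cols$coord
  rows
}
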