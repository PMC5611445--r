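# Motif catalog, IUPAC scanning, direct repeats, state classification.

test_that("the packaged catalog carries the documented consensi and cores", {
  cat_ <- load_default_catalog()
  expect_equal(cat_$`RARE-3`$consensus, "TGACCCTTTGGGGAT")
  expect_equal(cat_$`PPRE-2`$consensus, "GCAAACTTTC")
  expect_equal(cat_$`BRE-1`$consensus, "TTCC")
  expect_equal(cat_$`BRE-2`$core, 0:3)
  expect_equal(cat_$`CRE-4`$consensus, "TGACGCGC")
  expect_equal(cat_$URE1_PPRE$consensus, "TCACCCTTGACCA")
  expect_equal(cat_$URE1_PPRE$core, c(4L, 5L, 7L))  # bases of the two
  # non-binding mutants (CC->AA and T->A)
  expect_equal(cat_$TATA$consensus, "TATAAAA")
  expect_true(all(c("DR-1", "DR-3", "DR-4", "TRE_halfsite") %in% names(cat_)))
  expect_equal(cat_$`DR-1`$spacer, 1L)
})

test_that("IUPAC matching expands ambiguity codes and honors strand", {
  hits <- iupac_match("AGGTMA", "AGGTCATTAGGTAATTAGGTGA", 0)
  expect_equal(hits$position, c(1L, 9L))     # M = A or C; G fails
  # CRE core on the reverse strand of ...TGACG...
  rc <- iupac_match("CGTCA", "AATGACGAA", 0, orientation = "both")
  expect_equal(rc$strand, "-")
  expect_equal(rc$position, 3L)
  expect_equal(nrow(iupac_match("CGTCA", "AATGACGAA", 0)), 0)
  # N in the sequence is always a mismatch, even against pattern N
  expect_equal(nrow(iupac_match("NN", "AN", 0)), 0)
  expect_error(iupac_match("ACQ", "ACGT"), class = "regel_alphabet_error")
})

test_that("IUPAC scan equals the naive position-by-position oracle", {
  set.seed(51)
  pats <- c("TGACGTCA", "AGGTMA", "TRTAWAA", "CGNCG")
  for (case in 1:25) {
    s <- random_dna(sample(150:300, 1))
    pat <- sample(pats, 1)
    mm <- sample(0:2, 1)
    got <- iupac_match(pat, s, mm)
    exp <- bf_iupac_positions(pat, s, mm)
    expect_equal(got$position, exp$position, info = paste(case, pat, mm))
    expect_equal(got$mismatches, exp$mismatches, info = paste(case, pat, mm))
  }
})

test_that("direct repeats are found with exact spacers", {
  hit <- find_direct_repeat("AGGTCATAGGTCA", spacer = 1)
  expect_equal(hit$position, 1L)
  expect_equal(hit$mm1 + hit$mm2, 0L)
  expect_equal(nrow(find_direct_repeat("AGGTCATTAGGTCA", spacer = 1)), 0)
  # mouse-like context read on the complementary strand of TCACCCTTGACCA:
  # TGGTCAAGGGTGA holds a degenerate DR-1 at <= 2 mismatches per half
  rc <- reverse_complement("TCACCCTTGACCA")
  expect_equal(rc, "TGGTCAAGGGTGA")
  hit2 <- find_direct_repeat(rc, spacer = 1, max_mismatch_per_half = 2)
  expect_equal(hit2$position, 1L)
  expect_equal(nrow(find_direct_repeat(rc, spacer = 1,
                                       max_mismatch_per_half = 0)), 0)

  # random-sequence counts equal a brute-force enumeration
  set.seed(52)
  for (case in 1:15) {
    s <- random_dna(300)
    half <- "AGGTCA"; spc <- sample(0:4, 1); mm <- sample(0:2, 1)
    got <- find_direct_repeat(s, half, spc, mm)
    pos <- bf_iupac_positions(half, s, mm)$position
    exp <- pos[(pos + 6 + spc) %in% pos]
    expect_equal(got$position, exp, info = paste(case, spc, mm))
  }
})

test_that("motif states follow the mutagenesis rules", {
  cat_ <- load_default_catalog()
  # walrus-style TATA: A/T frame kept, two mismatches -> variant
  expect_equal(classify_motif_state("TAAATAA", cat_$TATA)$state, "variant")
  # cetacean-style TATA: G/C inside the frame -> disrupted
  expect_equal(classify_motif_state("GACGTCA", cat_$TATA)$state, "disrupted")
  # URE1 non-binding mutant
  u <- classify_motif_state("TCACAATTGACCA", cat_$URE1_PPRE)
  expect_equal(u$state, "disrupted")
  expect_equal(u$core_mismatch_positions, c(4L, 5L))
  expect_equal(classify_motif_state("TCACCCTAGACCA",
                                    cat_$URE1_PPRE)$state, "disrupted")
  # BRE TTCC -> GTAC abolishes activity
  expect_equal(classify_motif_state("GTAC", cat_$`BRE-1`)$state, "disrupted")
  # gap-majority rule
  expect_equal(classify_motif_state("----AAA", cat_$TATA)$state, "deleted")
  expect_equal(classify_motif_state("-------", cat_$TATA)$state, "not_found")
  expect_equal(classify_motif_state("", cat_$TATA)$state, "not_found")
  # no-core motifs never disrupt
  expect_equal(classify_motif_state("AAAAAT", cat_$`GCCCCT-2`)$state,
               "variant")
  # gc_to_at rule: G -> A inside a RARE half-site disrupts ...
  expect_equal(classify_motif_state("TAACCCTTTGGGGAT",
                                    cat_$`RARE-3`)$state, "disrupted")
  # ... but a G -> C change does not increase AT-richness
  expect_equal(classify_motif_state("TGACCCTTTCGGGAT",
                                    cat_$`RARE-3`)$state, "variant")
})

test_that("classification is total over the observed alphabet", {
  cat_ <- load_default_catalog()
  set.seed(53)
  states <- c("intact", "variant", "disrupted", "deleted", "not_found")
  for (rep in 1:100) {
    def <- cat_[[sample(which(vapply(cat_, function(m)
      m$type == "simple", logical(1))), 1)]]
    obs <- paste(sample(c("A", "C", "G", "T", "N", "-"),
                        nchar(def$consensus), replace = TRUE), collapse = "")
    st <- classify_motif_state(obs, def)$state
    expect_true(st %in% states)
  }
})

test_that("scanning the synthetic template yields all-intact states", {
  cat_ <- load_default_catalog()
  tpl <- build_root_template(cat_)
  lib <- default_element_library(tpl)
  r <- upstream_region("template", paste(tpl$bases, collapse = ""),
                       tpl$anchor_coord - 1L)
  enh <- scan_species_motifs(r, lib$enhancer, cat_,
                             located_interval = c(-4000L, -3800L))
  expect_equal(nrow(enh), 12)
  expect_true(all(enh$state == "intact"))
  prom <- scan_species_motifs(r, lib$promoter, cat_,
                              located_interval = c(-600L, 0L))
  placed <- prom$motif_id != "GCCCCT-1"
  expect_true(all(prom$state[placed] == "intact"))
})

test_that("a single planted core mutation yields exactly one disrupted call", {
  cat_ <- load_default_catalog()
  tpl <- build_root_template(cat_)
  lib <- default_element_library(tpl)
  enh_seq <- lib$enhancer$reference_sequence
  # CRE-3 core CGTCA starts at catalog offset 0 + core position 3
  ch <- strsplit(enh_seq, "")[[1]]
  expect_equal(paste(ch[4:8], collapse = ""), "CGTCA")
  ch[5] <- "A"                                    # CGTCA -> CATCA
  mut <- paste(ch, collapse = "")
  calls <- scan_species_motifs(mut, lib$enhancer, cat_,
                               located_interval = c(-4000L, -3800L),
                               species_id = "mut")
  expect_equal(sum(calls$state == "disrupted"), 1)
  expect_equal(calls$motif_id[calls$state == "disrupted"], "CRE-3")

  # region without the element: everything not_found
  nf <- scan_species_motifs(upstream_region("empty", strrep("A", 6000), 6000L),
                            lib$enhancer, cat_, located_interval = NULL)
  expect_true(all(nf$state == "not_found"))
})

test_that("intact fraction degrades monotonically with mutation load", {
  cat_ <- load_default_catalog()
  tpl <- build_root_template(cat_)
  lib <- default_element_library(tpl)
  enh_seq <- lib$enhancer$reference_sequence
  set.seed(54)
  frac_intact <- vapply(c(0, 10, 40), function(k) {
    mean(replicate(8, {
      calls <- scan_species_motifs(mutate_dna(enh_seq, k), lib$enhancer,
                                   cat_, located_interval = c(-4000L, -3800L),
                                   species_id = "m")
      mean(calls$state == "intact")
    }))
  }, numeric(1))
  expect_true(all(diff(frac_intact) < 0))
})
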