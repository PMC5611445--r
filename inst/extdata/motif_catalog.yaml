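# Catalog of putative UCP1 transcriptional regulatory motifs.
#
# Each entry gives the consensus reported from murid functional studies (IUPAC
# letters allowed), the critical core whose mutation was shown to abolish or
# drastically reduce factor binding, and the rule used to score core damage:
#   mismatch  - any non-consensus base (or gap) at a core position
#   gc_to_at  - a consensus G/C observed as A/T (AT-richness increase)
#   tata      - >= 3 core mismatches, or any G/C observed at positions 1-4
#   none      - no mutagenesis evidence; state space excludes "disrupted"
# offset: 0-based start of the motif inside its element's reference sequence.
# Entries of type direct_repeat are spacer-separated half-site patterns used
# for screening (DR-1/DR-3/DR-4 class) rather than fixed-offset instances.
motifs:
  - motif_id: CRE-3
    element: enhancer
    type: simple
    consensus: TKACGTCA
    core: [3, 4, 5, 6, 7]
    core_rule: mismatch
    orientation: as_given
    offset: 0
    source: CRE palindrome; CGTCA core mutagenesis
  - motif_id: RARE-1
    element: enhancer
    type: simple
    consensus: TTACCCTTGCTCA
    core: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
    core_rule: gc_to_at
    orientation: as_given
    offset: 14
    source: retinoic acid response element; AT-enrichment mutagenesis
  - motif_id: URE1_PPRE
    element: enhancer
    type: simple
    consensus: TCACCCTTGACCA
    core: [4, 5, 7]
    core_rule: mismatch
    orientation: as_given
    offset: 31
    source: degenerate DR-1 bound by PPARg-RXRa; two non-binding mutants
  - motif_id: CRE-2
    element: enhancer
    type: simple
    consensus: AGTCGTCA
    core: [3, 4, 5, 6, 7]
    core_rule: mismatch
    orientation: as_given
    offset: 50
    source: mouse CRE-2; CGTCA core mutagenesis
  - motif_id: BRE-1
    element: enhancer
    type: simple
    consensus: TTCC
    core: [0, 1, 2, 3]
    core_rule: mismatch
    orientation: as_given
    offset: 62
    source: brown adipocyte regulatory element; TTCC->GTAC mutagenesis
  - motif_id: RARE-2
    element: enhancer
    type: simple
    consensus: AGGTCA
    core: [0, 1, 2, 3, 4, 5]
    core_rule: gc_to_at
    orientation: as_given
    offset: 70
    source: retinoic acid response element half-site
  - motif_id: RARE-3
    element: enhancer
    type: simple
    consensus: TGACCCTTTGGGGAT
    core: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14]
    core_rule: gc_to_at
    orientation: as_given
    offset: 81
    source: eutherian consensus retinoic acid response element
  - motif_id: PPRE-2
    element: enhancer
    type: simple
    consensus: GCAAACTTTC
    core: []
    core_rule: none
    orientation: as_given
    offset: 101
    source: predicted second PPRE; no mutagenesis evidence
  - motif_id: upTRE
    element: enhancer
    type: simple
    consensus: AGGTMANNNNAGGCAA
    core: [10, 11, 12, 13, 14, 15]
    core_rule: mismatch
    orientation: as_given
    offset: 115
    source: rat upstream TRE; AGGCAA->ATTTAA mutagenesis
  - motif_id: dnTRE
    element: enhancer
    type: simple
    consensus: AGAAGGGGTGAGGTCA
    core: [10, 11, 12, 13, 14, 15]
    core_rule: mismatch
    orientation: as_given
    offset: 136
    source: downstream TRE, eutherian consensus; AGGTCA->ATATTA mutagenesis
  - motif_id: NBRE
    element: enhancer
    type: simple
    consensus: AAAGGTCA
    core: []
    core_rule: none
    orientation: as_given
    offset: 156
    source: NR4A-binding element; no mutagenesis evidence
  - motif_id: BRE-2
    element: enhancer
    type: simple
    consensus: TTCC
    core: [0, 1, 2, 3]
    core_rule: mismatch
    orientation: as_given
    offset: 169
    source: brown adipocyte regulatory element; TTCC->GTAC mutagenesis
  - motif_id: GCCCCT-1
    element: promoter
    type: simple
    consensus: GCCCCT
    core: []
    core_rule: none
    orientation: as_given
    offset: 180
    source: murid-restricted footprinted site; no binding factor identified
  - motif_id: CRE-4
    element: promoter
    type: simple
    consensus: TGACGCGC
    core: [0, 1, 2, 3, 4]
    core_rule: mismatch
    orientation: reverse_complement
    offset: 220
    source: mouse proximal CRE in reverse-complement orientation (TGACG = rc of CGTCA)
  - motif_id: CCAAT
    element: promoter
    type: simple
    consensus: CCAAT
    core: []
    core_rule: none
    orientation: as_given
    offset: 300
    source: NF-Y / C-EBP binding box; highly variable across eutherians
  - motif_id: TATA
    element: promoter
    type: simple
    consensus: TATAAAA
    core: [0, 1, 2, 3, 4, 5, 6]
    core_rule: tata
    orientation: as_given
    offset: 330
    source: basal promoter TATA box; A/T-rich frame
  - motif_id: GCCCCT-2
    element: promoter
    type: simple
    consensus: GCCCCT
    core: []
    core_rule: none
    orientation: as_given
    offset: 400
    source: proximal footprinted site, broadly conserved
  - motif_id: GCCCCT-3
    element: promoter
    type: simple
    consensus: GCCCCT
    core: []
    core_rule: none
    orientation: as_given
    offset: 470
    source: proximal footprinted site, broadly conserved
  - motif_id: DR-1
    element: prr
    type: direct_repeat
    half_site: AGGTCA
    spacer: 1
    orientation: both
    source: direct repeat, 1 bp spacer (PPAR class)
  - motif_id: DR-3
    element: prr
    type: direct_repeat
    half_site: AGGTCA
    spacer: 3
    orientation: both
    source: direct repeat, 3 bp spacer (VDR class)
  - motif_id: DR-4
    element: prr
    type: direct_repeat
    half_site: AGGTCA
    spacer: 4
    orientation: both
    source: direct repeat, 4 bp spacer (TR class)
  - motif_id: TRE_halfsite
    element: prr
    type: direct_repeat
    half_site: AGGTMA
    spacer: 4
    orientation: both
    source: thyroid response element half-site pair, 4 bp spacer
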