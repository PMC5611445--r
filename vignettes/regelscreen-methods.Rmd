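---
title: "Methods: screening UCP1 upstream regulatory elements across mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening UCP1 upstream regulatory elements across mammals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Uncoupling protein 1 (*UCP1*) drives non-shivering thermogenesis in the
brown adipose tissue of placental mammals. Its transcription is controlled
by a small set of upstream features: a conserved ~200 bp distal **enhancer
box** roughly 2–5 kb upstream of the start codon, a ~678 bp **putative
regulatory region** (PRR) around −2.1 to −2.7 kb, a **CpG island** over the
proximal promoter and first exon, and basal **promoter motifs** (TATA box,
CCAAT, CRE-4, GCCCCT sites) within a few hundred bp of the ATG. Comparative
questions about these features — which lineages carry them, where they were
gained, how often they were lost, and whether the murid-derived binding
motifs inside them are conserved — reduce to a reproducible screening
pipeline: locate each element in every species' upstream sequence, classify
each catalogued motif, and map presence/absence onto a species tree.

`regelscreen` implements that pipeline, together with a phylogenetic
sequence simulator that generates datasets with known truth so every stage
can be validated end to end.

## Coordinates and data model

All genomic positions are **0-based, half-open, anchored on the A of the
ATG start codon at position 0**; upstream positions are negative (−1 is the
base immediately 5′ of the A). An `upstream_region` couples a sequence with
its `anchor_offset` (the upstream extent in bp); FASTA headers carry the
anchor as `anchor=<int>`, so inputs remain plain FASTA. Only A/C/G/T/N are
kept: other IUPAC letters in input are mapped to N with a warning, and N
behaves as a universal mismatch in every scoring step — genome-mined
contigs are full of Ns and nothing should ever match them.

## Dot-plot homology screening

Element presence is decided the way a dot-plot reader decides it, made
deterministic:

* **Window scoring.** Every aligned window pair of query and reference is
  scored +5 per match, −4 per mismatch; a window of 25 bp is a *hit* when
  its sum reaches 45. Algebraically that is at least 17 identical bases in
  25 (68% local identity). Forward strand only: upstream regions are
  compared in genomic orientation.
* **Segment chaining.** Hits are chained into segments when the gap between
  their drawn window extents along the query is at most `max_gap` (10 bp by
  default) and their diagonals differ by at most `diag_drift` (default
  `max_gap`). Both tolerances matter: a cluster of three or four
  substitutions knocks out every window that covers it — a hole far wider
  than the mutations themselves — while a short indel shifts the diagonal
  without interrupting homology at all. Measuring gaps between window
  extents (not midpoints) and tolerating small diagonal drift reproduces
  what is visually continuous on the plot.
* **End trimming.** A segment's extent is the span covered by its hit
  windows, trimmed at each end by the terminal window's mismatch count.
  Without trimming, windows that hang over the edge of an exactly matching
  block (passing on 17 interior matches alone) would inflate a 90 bp
  homology into a ~106 bp segment; with it, an exact embedded block
  measures exactly its own length, and a full-length self comparison still
  spans the whole sequence.
* **Presence rule.** An element is `present` when the longest segment in
  its search window (the expected window padded by ±2 kb) exceeds 100 bp;
  `no_coverage` when the covered search window is shorter than 50% of the
  expected window and no qualifying segment exists (the packaged survey's
  "/" state); `absent` otherwise. All three cutoffs are arguments.

The iterative annotation route (`annotate_element_by_homology`) mirrors the
assemble-at-decreasing-stringency procedure: a local alignment of the
reference against the search window is accepted at the first threshold of a
strictly decreasing identity schedule (85% down to 60% in 5% steps) that
its percent identity meets. Percent identity is always *identical non-gap
columns / columns with at least one base*.

Pairwise alignment itself (global, local, and pattern-global/subject-local)
is delegated to `Biostrings::pairwiseAlignment` under the same +5/−4 matrix
with affine gaps (open −10, extend −1, conventional nucleotide defaults).

## CpG islands

The detector reimplements the classic observed/expected criteria: a 100 bp
window slides by 1 bp; a window qualifies when its CpG observed/expected
ratio `N_CpG × L / (N_C × N_G)` exceeds 0.6 **and** its GC fraction exceeds
0.5; all positions covered by qualifying windows are marked, and maximal
marked runs of at least 200 bp are reported. Union semantics — a qualifying
window marks all its positions, islands are trimmed to the outermost
qualifying window edges, no smoothing — is the deterministic reading of the
published criteria; a GC-rich but CpG-free repeat such as `GGGGGCCCCC`
(O/E = 0.36) correctly fails. Island-level means are taken over the
qualifying windows inside the island, so the reported statistics always
clear the thresholds they were selected by.

## The motif catalog and state classification

The packaged YAML catalog (`inst/extdata/motif_catalog.yaml`) records, for
each enhancer and promoter motif, the consensus reported from murid
functional work, the **critical core** whose mutation was shown to abolish
or drastically reduce factor binding, and the rule used to score core
damage:

* `mismatch` — any non-consensus base or gap at a core position disrupts
  (CRE cores `CGTCA`, BRE `TTCC`, the URE1 positions altered in the two
  non-binding mutants, the 3′ hexamers of the two TREs);
* `gc_to_at` — only a consensus G/C observed as A/T disrupts (the RARE
  sites, where AT-enrichment was the disruptive mutation class);
* `tata` — three or more core mismatches, or any G/C inside the A/T frame
  (positions 1–4), disrupts; A/T-preserving variants such as `TAAATAA`
  remain `variant`;
* `none` — sites with no mutagenesis evidence (GCCCCT, CCAAT, NBRE,
  PPRE-2) can be `variant` but never `disrupted`.

Each observed instance is read off an alignment of the element reference
against the located query element in the *reference frame* (one character
per consensus position, `-` where the query base is deleted), so indels
elsewhere in the element do not shift the motif windows. States follow a
fixed precedence: `not_found` (nothing aligns), `deleted` (gaps cover at
least 50% of the span — the threshold is configurable since the source
material gives no number), `disrupted`, `variant`, `intact`. The function is
total over `{A,C,G,T,N,-}`: every observed string maps to exactly one
state. Direct-repeat patterns (DR-1/DR-3/DR-4, TRE half-site pairs) are
screening patterns, not fixed instances, and are served by
`find_direct_repeat` with exact spacers and per-half mismatch budgets.

In the packaged synthetic enhancer the motifs are laid out sequentially
without the overlaps real murid elements show (RARE-1/URE1 overlap in the
rodent alignment); overlap bookkeeping is therefore not exercised by the
generator. The murid-restricted most-upstream GCCCCT site is deliberately
left out of the synthetic template, so it reads as `variant`
(background-like) rather than `intact` — mirroring its absence outside
murids.

## Consensus and conservation summaries

The eutherian consensus is a strict simple majority: per column, the most
frequent symbol among included rows if its frequency exceeds 50%, else `N`.
Gaps vote by default (`count_gaps = TRUE`) — in indel-rich regions a
gap-majority column is meaningful — and a gap-skipping mode is provided
because the source procedure does not say which convention it used.
Pseudogene species are excluded from the include set by the caller, mirroring
the published consensus construction. `motif_conservation_summary`
cross-tabulates motif states against gene status (intact vs pseudogene)
with `not_found` species removed from denominators.

## Gain/loss mapping under Dollo parsimony

Binary element characters are mapped with a single gain and irreversible
losses, the model the biology dictates (a complex enhancer is not regained
once lost). The gain branch subtends the MRCA of all present tips. Losses
are the minimal branch set such that a tip is absent iff it descends from a
loss: a loss is placed on the highest branch of each maximal present-free
subtree containing at least one covered absent tip. `no_coverage` tips are
missing data — compatible with either state, never forcing a loss — which
is exactly how the survey treats species whose contigs do not span the
element window. Minimality is certified in the test suite against
exhaustive subset enumeration on random trees. When missing-data tips make
the placement (not the count) ambiguous, the loss is reported at the
shallowest position with an `ambiguous_placement` flag.

The packaged survey (`ucp1_survey()`) is a transcription of the 139-species
presence table (`Yes`/`X`/`/`), and `mammal_tree()` encodes the
corresponding rooted topology. One curation is applied by default and fully
reversible (`curated = FALSE`): the two-toed sloth's enhancer is recorded
as `no_coverage` rather than absent, because no anchored upstream contig
exists for that species and the survey's own loss accounting treats it as
unresolved; with the printed value the sloth would add a sixth independent
loss that the source analysis does not count.

## The synthetic-data generator

`simulate_dataset` evolves a fixed ancestral template down a rooted tree:

* **Root template** (deterministic, independent of the simulation seed):
  10.2 kb spanning [−10000, +200) at background GC 0.40, with the 200 bp
  enhancer carrying all catalogued motifs at −4 kb, the 678 bp PRR at
  −2.5 kb, a 400 bp CpG-qualifying block over [−250, +150) (iid letters at
  GC 0.66 keep O/E near 1 while the AT-rich background fails on GC), and
  the promoter motifs at their anchored offsets (TATA at −270, CCAAT at
  −300, CRE-4 at −380, the proximal GCCCCT pair at −200/−130).
* **Substitutions** follow the single-parameter symmetric model: on a
  branch of length *t* (expected substitutions/site) each site changes with
  probability `3/4 (1 − exp(−4t/3))` to a uniformly chosen different base.
  Rate contrast between lineages — the signal that matters here — is a
  per-branch multiplier (default ×2) on designated pseudogene branches;
  within-element rate heterogeneity is deliberately not modelled.
* **Indels** arrive at 0.05 events per site per substitution unit (about
  one indel per twenty substitutions, a realistic non-coding ratio) with
  geometric lengths of mean 3 bp, insertions drawn from the background
  composition. Indels are suppressed inside motif critical cores by default
  so motif-state truth stays well defined.
* **Element deletions** excise exactly the template interval on a
  configured branch. The default configuration deletes the enhancer on the
  delphinid stem of a 10-tip mammal-like tree (root-to-tip paths
  0.10–0.12 substitutions/site) whose cetacean clade is the pseudogene
  lineage. A sperm-whale deletion can be added, but is not the default: on
  a small tree without present odontocete relatives, Dollo minimality
  correctly merges a sperm-whale loss and a delphinid loss into a single
  cetacean stem loss, which would make exact event recovery untestable.
* **Truth.** Every residue carries its ancestral coordinate (insertions get
  fractional coordinates between their neighbours plus a unique id), so the
  generator emits a gap-correct `truth_alignment` — one column per root
  residue plus one per surviving insertion — along with per-tip element
  intervals, survival flags, per-branch events, and per-motif true states
  (classified from the truth-aligned slice). Identical seeds reproduce
  identical datasets byte for byte.

What the generator emulates: elements at their expected offsets,
lineage-specific deletions, elevated decay on pseudogene branches, indels
that displace coordinates, CpG-qualifying composition against realistic
GC-rich-but-CpG-poor negatives. What it does not emulate: rearrangements,
segmental duplications, assembly gaps and chimeric contigs, overlapping
motif architecture, context-dependent substitution (CpG hypermutability),
and selection. Passing recovery tests therefore demonstrates correctness of
the screening logic under the stated generative model, not performance on
raw genome-mined contigs.

## Numerical choices and degenerate inputs

* Scoring: +5/−4 with N as universal mismatch; affine gaps −10/−1;
  alignment tie-breaking is delegated to `Biostrings` and is deterministic.
* Dot plots shorter than one window, and CpG scans shorter than one window,
  return empty results with a warning rather than an error.
* `slice_upstream` returns the covered suffix with a truncation flag when a
  request overruns coverage, and a typed coverage error when there is no
  overlap — callers map that to `no_coverage`.
* Consensus ties and sub-majority columns yield `N` (not an IUPAC code):
  the majority rule either holds or it does not.
* Empty include sets, conflicting duplicate presence calls, unknown species
  in trees, and double deletions along one path are typed errors.

## Problem sizes used by the packaged tests

The suite validates each screening primitive against exhaustive brute-force
reimplementations on 100 seeded instances per primitive (dot plots on
60–130 bp pairs, CpG scans on 250–600 bp regions, IUPAC/direct-repeat scans
on 150–400 bp, Dollo minima on trees of 5–12 tips), and runs the full
recovery study over 20 simulation seeds at the default 10.2 kb × 10-tip
configuration — sizes chosen so the whole suite completes in a few minutes
on one core while every claim stays at the defaults described above.

## Known limitations

* Presence calling at the default window/threshold is reliable up to
  roughly 20% divergence between query and reference; beyond that the
  17-of-25 hit rule starts to fragment and the >100 bp rule under-calls —
  the same regime where visual dot-plot reading becomes subjective.
* The survey transcription inherits two internal inconsistencies of its
  source (its running text reports 121 eutherian enhancers and 125
  PRR-covered species where the table tallies 123 and 123); the package
  reports what the table contains.
* Motif cores encode published murid mutagenesis; for motifs never
  mutagenized the `variant`/`intact` distinction is descriptive, not
  functional.
* The Dollo mapper assumes the rooted topology is correct; it does not
  average over trees or use branch lengths.
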