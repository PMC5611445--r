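# Dot plots, diagonal segments, presence calls, alignment utilities.

test_that("self comparison fills the main diagonal and one full-length segment", {
  set.seed(21)
  s <- random_dna(300)
  dp <- compute_dotplot(s, s)
  main <- dp$hits[dp$hits$i == dp$hits$j, ]
  expect_equal(nrow(main), 300 - 25 + 1)
  expect_true(all(main$score == 25 * 5))
  segs <- extract_diagonal_segments(dp)
  expect_equal(segs$length[1], 300)
  expect_equal(segs$start_a[1], 1)
})

test_that("a window hits iff it has at least 17 identical bases (w=25, t=45, +5/-4)", {
  # brute-force over the number of matching bases: 5m - 4(25 - m) >= 45
  scores <- vapply(0:25, function(m) 5 * m - 4 * (25 - m), numeric(1))
  expect_equal(min(which(scores >= 45)) - 1, 17)
  set.seed(22)
  base <- random_dna(25)
  for (m in c(15, 16, 17, 18, 25)) {
    probe <- mutate_dna(base, 25 - m)
    dp <- compute_dotplot(base, probe)
    # mutate_dna guarantees exactly 25 - m mismatches
    expect_equal(nrow(dp$hits) == 1, m >= 17, info = paste("m =", m))
  }
})

test_that("dot-plot hits equal the exhaustive window-pair oracle", {
  set.seed(23)
  for (case in 1:20) {
    la <- sample(60:140, 1); lb <- sample(60:140, 1)
    a <- random_dna(la); b <- random_dna(lb)
    # plant a shared block in half the cases so hits actually occur
    if (case %% 2 == 0) {
      block <- random_dna(40)
      a <- paste0(substr(a, 1, 20), block, substr(a, 61, la))
      b <- paste0(substr(b, 1, 10), block, substr(b, 51, lb))
    }
    p <- dotplot_params(window = 15, threshold = 30)
    got <- compute_dotplot(a, b, p)$hits
    exp <- bf_dotplot_hits(a, b, 15, 30)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got$i, exp$i); expect_equal(got$j, exp$j)
    expect_equal(got$score, exp$score)
  }
})

test_that("raising the threshold never adds hits; gaps beyond tolerance split segments", {
  set.seed(24)
  a <- random_dna(250); b <- random_dna(250)
  lo <- compute_dotplot(a, b, dotplot_params(window = 11, threshold = 10))
  hi <- compute_dotplot(a, b, dotplot_params(window = 11, threshold = 25))
  key <- function(h) paste(h$i, h$j)
  expect_true(all(key(hi$hits) %in% key(lo$hits)))

  # two synthetic hits on one diagonal, 149 apart: split at max_gap 25
  s <- random_dna(300)
  block <- substr(s, 1, 30)
  q <- paste0(block, random_dna(120), substr(s, 151, 180), random_dna(120))
  dp <- compute_dotplot(q, paste0(block, substr(s, 31, 150),
                                  substr(s, 151, 180)))
  segs <- extract_diagonal_segments(dp, max_gap = 25)
  d0 <- segs[segs$start_a == segs$start_b, ]
  expect_gte(nrow(d0), 2)
})

test_that("a shared 150 bp block yields a top segment covering it", {
  set.seed(25)
  block <- random_dna(150)
  a <- paste0(random_dna(100), block, random_dna(100))
  b <- paste0(random_dna(40), block, random_dna(60))
  segs <- extract_diagonal_segments(compute_dotplot(a, b))
  expect_gte(segs$length[1], 150)
  expect_true(segs$start_a[1] <= 101 && segs$start_a[1] + segs$length[1] >= 251)
})

test_that("global alignment matches exhaustive enumeration on tiny strings", {
  expect_error(global_align("", ""), class = "regel_validation_error")
  set.seed(26)
  s <- random_dna(40)
  self <- global_align(s, s)
  expect_equal(self$score, 40 * 5)
  expect_equal(self$a, self$b)
  for (case in 1:30) {
    a <- random_dna(sample(2:5, 1)); b <- random_dna(sample(2:5, 1))
    expect_equal(global_align(a, b)$score, bf_global_score(a, b),
                 info = paste(a, b))
  }
  got <- global_align("ACGT", "ACT")
  expect_equal(got$score, bf_global_score("ACGT", "ACT"))
})

test_that("percent identity follows the non-gap column definition", {
  expect_equal(percent_identity("ACGT", "ACGT"), 1.0)
  expect_equal(percent_identity("AC-GT", "ACAGT"), 0.8)
  expect_equal(percent_identity("AAAA", "CCCC"), 0.0)
  expect_error(percent_identity("AC", "ACG"), class = "regel_validation_error")
})

test_that("identity track is 1 on self, dips over a mutated block, degenerates to a scalar", {
  set.seed(27)
  s <- random_dna(600)
  tr <- identity_track(s, s, window = 50, step = 25)
  expect_true(all(tr$identity == 1))
  # mutate the central 100 bp heavily
  mid <- paste0(substr(s, 1, 250), mutate_dna(substr(s, 251, 350), 60),
                substr(s, 351, 600))
  tr2 <- identity_track(s, mid, window = 50, step = 25)
  inside <- tr2$position >= 250 & tr2$position <= 350
  expect_lt(min(tr2$identity[inside]), 0.7)
  expect_true(all(tr2$identity[tr2$position < 180] == 1))
  one <- identity_track(s, s, window = 5000)
  expect_equal(nrow(one), 1)
  expect_equal(one$identity, 1)
})

test_that("presence calls follow the conserved-length and coverage rules", {
  set.seed(28)
  upstream <- random_dna(5200)
  elem <- substr(upstream, 1001, 1200)              # anchored [-4200, -4000)
  ref <- element_definition("enhancer", "synthetic", elem,
                            c(-5000L, -2000L))
  q <- upstream_region("with", upstream, 5200L)
  pc <- call_element_presence(q, ref)
  expect_equal(pc$state, "present")
  expect_true(pc$located_interval[1] <= -4200 &&
                pc$located_interval[2] >= -4000)
  expect_gt(pc$best_segment_length, 100)

  # homologous block of only 90 bp: fails the > 100 bp rule
  q90 <- upstream_region("short_block",
                         paste0(random_dna(2500), substr(elem, 1, 90),
                                random_dna(2610)), 5200L)
  pc90 <- call_element_presence(q90, ref)
  expect_equal(pc90$state, "absent")

  # contig extending only ~1 kb upstream of a -5 to -2 kb element
  q1k <- upstream_region("hedgehog_like", random_dna(1100), 1100L)
  expect_equal(call_element_presence(q1k, ref)$state, "no_coverage")

  # raising min_conserved_length never converts absent -> present
  pc_strict <- call_element_presence(q90, ref, min_conserved_length = 200L)
  expect_equal(pc_strict$state, "absent")
})

test_that("any region longer than the rule length is present against itself", {
  set.seed(29)
  for (n in c(150, 400)) {
    s <- random_dna(n + 3000)
    elem <- substr(s, 501, 500 + n)
    ref <- element_definition("prr", "synthetic", elem,
                              c(-(3000 + n - 500), -(3000 + n - 500) + n))
    q <- upstream_region("self", s, nchar(s))
    expect_equal(call_element_presence(q, ref)$state, "present")
  }
})

test_that("homology annotation accepts at the right schedule threshold", {
  set.seed(30)
  elem <- random_dna(200)
  ref <- element_definition("enhancer", "synthetic", elem, c(-5000L, -2000L))
  make_query <- function(e) upstream_region(
    "q", paste0(random_dna(1500), e, random_dna(3500)), 5200L)

  exact <- annotate_element_by_homology(make_query(elem), ref)
  expect_equal(exact$threshold, 0.85)
  expect_equal(exact$identity, 1.0)

  mut <- annotate_element_by_homology(make_query(mutate_dna(elem, 56)), ref)
  expect_false(is.null(mut))
  expect_lte(mut$threshold, 0.72)

  none <- annotate_element_by_homology(make_query(random_dna(200)), ref)
  expect_null(none)

  # achieved identity is non-increasing in mutation load
  loads <- c(10, 30, 50)
  ids <- vapply(loads, function(k) {
    annotate_element_by_homology(make_query(mutate_dna(elem, k)), ref,
                                 identity_schedule = c(0.5))$identity
  }, numeric(1))
  expect_true(all(diff(ids) <= 0.02))
})
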