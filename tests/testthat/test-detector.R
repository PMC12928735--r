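mk_pair_row <- function(pos1, end1, strand1, pos2, end2, strand2,
                        clip = c(0, 0, 0, 0), nm = c(0, 0)) {
  left1 <- pos1 <= pos2
  lstr <- if (left1) strand1 else strand2
  rstr <- if (left1) strand2 else strand1
  data.frame(qname = "q", pos1 = pos1, end1 = end1, strand1 = strand1,
             clipL1 = clip[1], clipR1 = clip[2], nm1 = nm[1], indels1 = 0L,
             seq1 = "", pos2 = pos2, end2 = end2, strand2 = strand2,
             clipL2 = clip[3], clipR2 = clip[4], nm2 = nm[2], indels2 = 0L,
             seq2 = "", span = max(end1, end2) - min(pos1, pos2),
             orientation = paste0(ifelse(lstr == "+", "F", "R"),
                                  ifelse(rstr == "+", "F", "R")),
             stringsAsFactors = FALSE)
}

toy_arms <- function() {
  g <- circular_sequence("toyg", strrep("ACGT", 10000))  # placeholder genome
  structure(list(
    arm1 = list(start = 2000L, end = 2053L, seq = "", label = "sIR-1"),
    arm2 = list(start = 23947L, end = 24000L, seq = "", label = "sIR-2"),
    identity = 1, match_class = "complete",
    hr = interval(2000, 24000, length = 40000),
    spacer_bp = 21894L, genome_id = "toyg"), class = "sir_pair")
}

test_that("candidate rule: discordant orientation plus ~HR-span insert", {
  arms <- toy_arms()
  hr <- arms$hr
  prm <- detection_params()
  # proper FR pair with a short span is concordant
  conc <- mk_pair_row(5000, 5150, "+", 5250, 5400, "-")
  expect_false(is_discordant_candidate(conc, hr, prm))
  # FF pair spanning ~22 kb, overlapping arm1
  disc <- mk_pair_row(1990, 2140, "+", 23500, 23650, "+")
  expect_true(is_discordant_candidate(disc, hr, prm))
  # FR orientation is rejected even at matching span
  fr <- mk_pair_row(1990, 2140, "+", 23850, 24000, "-")
  expect_false(is_discordant_candidate(fr, hr, prm))
  # span outside tolerance
  off <- mk_pair_row(1990, 2140, "+", 30000, 30150, "+")
  expect_false(is_discordant_candidate(off, hr, prm))
  # clip path bypasses the span requirement
  expect_true(is_discordant_candidate(conc, hr, prm, has_qualifying_clip = TRUE))
})

test_that("arm-overlap rule distinguishes overlap, interior/exterior and fail", {
  arms <- toy_arms(); hr <- arms$hr; prm <- detection_params()
  # 1 bp of overlap with arm1 counts
  p1 <- mk_pair_row(1903, 2001, "+", 10000, 10150, "+")
  expect_equal(sir_overlap_rule(p1, arms, hr, prm), "arm_overlap")
  # one mate inside, the other 800 bp beyond arm2: vicinity 1000 passes
  p2 <- mk_pair_row(10000, 10150, "+", 24800, 24950, "+")
  expect_equal(sir_overlap_rule(p2, arms, hr, prm), "interior_exterior")
  # mate 5000 bp beyond arm2: fails
  p3 <- mk_pair_row(10000, 10150, "+", 29000, 29150, "+")
  expect_equal(sir_overlap_rule(p3, arms, hr, prm), "fail")
  # both mates interior: fails
  p4 <- mk_pair_row(10000, 10150, "+", 12000, 12150, "+")
  expect_equal(sir_overlap_rule(p4, arms, hr, prm), "fail")
})

test_that("soft-clip remapping enforces the length gate and identity floor", {
  set.seed(59)
  win <- rand_seq(2000)
  clip <- substr(win, 501, 530)
  prm <- detection_params()
  hit <- remap_softclip(clip, win, prm)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$offset, 500)
  expect_equal(hit$orientation, "+")
  # reverse-complement clips are found on the other orientation
  hit_rc <- remap_softclip(reverse_complement(clip), win, prm)
  expect_equal(hit_rc$orientation, "-")
  # one mismatch in 30 bp: 29/30 identity still accepted
  clip_mm <- paste0("A", substr(clip, 2, 30))
  if (substr(clip, 1, 1) == "A") clip_mm <- paste0("C", substr(clip, 2, 30))
  hit_mm <- remap_softclip(clip_mm, win, prm)
  expect_false(is.null(hit_mm))
  expect_gte(hit_mm$identity, 0.9)
  # a 15 bp clip is below the gate and not attempted
  expect_null(remap_softclip(substr(clip, 1, 15), win, prm))
  # a foreign clip finds no acceptable hit
  expect_null(remap_softclip(strrep("ACGT", 10), win, prm))
})

test_that("the inverted-reference check is strict on span and orientation", {
  prm <- detection_params()
  ok <- mk_pair_row(100, 250, "+", 449, 599, "-")
  expect_equal(ok$span, 499)
  expect_true(verify_on_inverted(ok, prm))
  at500 <- mk_pair_row(100, 250, "+", 450, 600, "-")
  expect_false(verify_on_inverted(at500, prm))
  ff <- mk_pair_row(100, 250, "+", 150, 300, "+")
  expect_false(verify_on_inverted(ff, prm))
  expect_false(verify_on_inverted(NULL, prm))
})

test_that("pattern taxonomy covers fully aligned and clipped geometries", {
  arms <- toy_arms(); hr <- arms$hr
  # arm1 overlap, mate outside -> I; mate inside -> III
  expect_equal(assign_pattern(mk_pair_row(1990, 2140, "+", 24100, 24250, "+"),
                              NULL, arms, hr), "I")
  expect_equal(assign_pattern(mk_pair_row(1990, 2140, "+", 10000, 10150, "+"),
                              NULL, arms, hr), "III")
  # arm2 overlap, mate outside -> II; inside -> IV
  expect_equal(assign_pattern(mk_pair_row(23900, 24050, "+", 1500, 1650, "+"),
                              NULL, arms, hr), "II")
  expect_equal(assign_pattern(mk_pair_row(23900, 24050, "+", 10000, 10150, "+"),
                              NULL, arms, hr), "IV")
  # no overlap, interior/exterior -> V
  expect_equal(assign_pattern(mk_pair_row(10000, 10150, "+", 24300, 24450, "+"),
                              NULL, arms, hr), "V")
  # clipped: arm1 clip with mate outside -> VI, arm2 -> VII, inside -> VIII
  pr <- mk_pair_row(1950, 2053, "+", 24100, 24250, "+")
  expect_equal(assign_pattern(pr, list(arm = "arm1", mate = 1L), arms, hr), "VI")
  expect_equal(assign_pattern(pr, list(arm = "arm2", mate = 1L), arms, hr), "VII")
  pr_in <- mk_pair_row(1950, 2053, "+", 10000, 10150, "+")
  expect_equal(assign_pattern(pr_in, list(arm = "arm1", mate = 1L), arms, hr),
               "VIII")
})

test_that("frequency arithmetic matches the supporting-pairs-per-depth definition", {
  ev0 <- data.frame(pattern = character(0))
  s0 <- estimate_frequency(ev0, 800)
  expect_equal(s0$frequency_pct, 0)
  expect_equal(s0$total_pairs, 0)

  ev35 <- data.frame(pattern = rep(c("I", "II", "IV", "V", "VI", "VII"),
                                   c(9, 2, 2, 11, 9, 2)))
  s35 <- estimate_frequency(ev35, 507.25)
  expect_equal(s35$total_pairs, 35)
  expect_equal(round(s35$frequency_pct, 2), 6.90)
  expect_equal(unname(s35$per_pattern_counts["V"]), 11L)

  s1 <- estimate_frequency(data.frame(pattern = "III"), 1111.1)
  expect_equal(round(s1$frequency_pct, 2), 0.09)

  expect_error(estimate_frequency(data.frame(pattern = "I"), 0), "zero mean depth")
  expect_warning(estimate_frequency(ev0, 0), "zero depth")
})

test_that("detect classifies a hand-built breakpoint fragment as clip evidence", {
  set.seed(61)
  cfg <- sim_config(genome_bp = 40000, hr_span_bp = 8000, f = 0, depth_x = 1,
                    seed = 61)
  g <- simulate_plastome(cfg)
  iso <- g$iso
  a1s <- iso$pair$arm1$start
  # fragment from the inverted isoform: R1 starts 60 bp outside arm1, runs
  # through the whole arm and 37 bp beyond the divergence point; R2 sits
  # wholly inside the inverted segment. The 60+53 bp left side anchors and
  # the 37 bp overhang is clipped at the arm1 inner boundary.
  x <- a1s - 60
  r1 <- substr(iso$inverted$seq, x + 1, x + 150)
  re <- x + 380
  r2 <- reverse_complement(substr(iso$inverted$seq, re - 150 + 1, re))
  aln <- lightweight_map(r1, r2, g$normal, ids = "hand")
  ev <- detect(aln, NULL, iso)
  expect_equal(nrow(ev$evidence), 1)
  expect_equal(ev$evidence$pattern, "VIII")
  # clip = 37 bp, shortened only by chance-match extension past the junction
  expect_lte(ev$evidence$clip_len, 37)
  expect_gte(ev$evidence$clip_len, 27)
  expect_equal(ev$evidence$clip_identity, 1.0)
  expect_equal(ev$evidence$variation, "exact")
})

test_that("detect is empty at frequency zero and deterministic on reruns", {
  cfg <- sim_config(genome_bp = 40000, hr_span_bp = 8000, f = 0,
                    depth_x = 40, seed = 67)
  d <- simulate_dataset(cfg)
  aln <- lightweight_map(d$r1, d$r2, d$normal, ids = d$ids)
  ev <- detect(aln, NULL, d$iso)
  expect_equal(nrow(ev$evidence), 0)
  # determinism: identical evidence on a full rerun
  d2 <- simulate_dataset(sim_config(genome_bp = 40000, hr_span_bp = 8000,
                                    f = 0.1, depth_x = 40, seed = 68))
  a2 <- lightweight_map(d2$r1, d2$r2, d2$normal, ids = d2$ids)
  e1 <- detect(a2, NULL, d2$iso)
  e2 <- detect(a2, NULL, d2$iso)
  expect_identical(e1$evidence, e2$evidence)
})
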