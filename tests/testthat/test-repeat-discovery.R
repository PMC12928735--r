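test_that("no inverted-repeat pair is reported in plain random sequence", {
  set.seed(3)
  g <- circular_sequence("bare", rand_seq(10000))
  expect_length(find_inverted_repeat_pairs(g, min_span_bp = 500,
                                           max_span_bp = 9000), 0)
})

test_that("a planted perfect pair is recovered at its exact coordinates", {
  set.seed(5)
  bg <- rand_seq(64000)
  arm <- rand_seq(53)
  s <- plant_ir(bg, arm, 3000, 3000 + 22000 - 53)
  g <- circular_sequence("planted", s)
  pp <- find_inverted_repeat_pairs(g)
  expect_length(pp, 1)
  p <- pp[[1]]
  expect_equal(p$arm1$start, 3000)
  expect_equal(p$arm1$end, 3053)
  expect_equal(p$arm2$end, 25000)
  expect_equal(p$identity, 1.0)
  expect_equal(p$match_class, "complete")
  expect_equal(interval_span(p$hr), 22000)
  expect_equal(p$spacer_bp, 22000 - 2 * 53)
})

test_that("discovery is covariant under strand flip and rotation", {
  set.seed(13)
  bg <- rand_seq(12000)
  arm <- rand_seq(40)
  s <- plant_ir(bg, arm, 2000, 8000)
  g <- circular_sequence("cov", s)
  args <- list(min_span_bp = 1000, max_span_bp = 11000)
  p0 <- do.call(find_inverted_repeat_pairs, c(list(g), args))[[1]]

  grc <- circular_sequence("cov_rc", reverse_complement(s))
  prc <- do.call(find_inverted_repeat_pairs, c(list(grc), args))[[1]]
  n <- nchar(s)
  # mirrored coordinates: arm labels swap
  expect_equal(prc$arm1$start, n - p0$arm2$end)
  expect_equal(prc$arm2$end, n - p0$arm1$start)
  expect_equal(prc$arm1$seq, reverse_complement(p0$arm2$seq))

  k <- 500L
  grot <- rotate(g, k)
  prot <- do.call(find_inverted_repeat_pairs, c(list(grot), args))[[1]]
  expect_equal(prot$arm1$start, (p0$arm1$start - k) %% n)
  expect_equal(prot$arm2$end, (p0$arm2$end - k) %% n)
})

test_that("substituted and indel-bearing arms are reported as incomplete", {
  set.seed(21)
  bg <- rand_seq(20000)
  arm <- rand_seq(53)
  a1s <- 2500; a2s <- 12500
  s <- plant_ir(bg, arm, a1s, a2s)
  # one substitution in the middle of arm2
  mid <- a2s + 26
  orig <- substr(s, mid + 1, mid + 1)
  sub <- setdiff(c("A", "C", "G", "T"), orig)[1]
  s_sub <- paste0(substr(s, 1, mid), sub, substr(s, mid + 2, nchar(s)))
  p <- find_inverted_repeat_pairs(circular_sequence("s", s_sub),
                                  min_span_bp = 1000, max_span_bp = 19000)[[1]]
  expect_equal(p$match_class, "incomplete")
  expect_equal(p$identity, 52 / 53, tolerance = 1e-9)
  expect_equal(p$arm1$start, a1s)
  expect_equal(p$arm2$end, a2s + 53)

  # 1 bp deletion in arm2: still found, incomplete, arms differ in length
  s_del <- paste0(substr(s, 1, mid), substr(s, mid + 2, nchar(s)))
  p2 <- find_inverted_repeat_pairs(circular_sequence("d", s_del),
                                   min_span_bp = 1000, max_span_bp = 19000)[[1]]
  expect_equal(p2$match_class, "incomplete")
  expect_lt(p2$identity, 1)
  expect_gte(p2$identity, 0.9)
})

test_that("classify_match demands identity 1 and equal arm lengths", {
  set.seed(77)
  g <- circular_sequence("t", plant_ir(rand_seq(5000), "TTCAGGACTTAAGC",
                                       100, 3000))
  p <- find_inverted_repeat_pairs(g, min_arm_bp = 12, min_span_bp = 500,
                                  max_span_bp = 4500)[[1]]
  expect_equal(classify_match(p), "complete")
  p$identity <- 52 / 53
  expect_equal(classify_match(p), "incomplete")
})

test_that("hairpin prediction agrees with exhaustive enumeration", {
  hp <- predict_hairpin("TTTGATTCCTGATTCAATCAAA")
  expect_equal(hp$stem_bp, 7L)
  expect_equal(hp$loop_nt, 8L)
  expect_equal(hp$stem5_interval, c(0L, 7L))
  expect_equal(hp$stem3_interval, c(15L, 22L))

  expect_null(predict_hairpin("AAAAAAAAAA"))
  hp2 <- predict_hairpin("GCGCAAAAGCGC")
  expect_equal(c(hp2$stem_bp, hp2$loop_nt), c(4L, 4L))

  set.seed(31)
  for (i in 1:60) {
    s <- rand_seq(sample(6:14, 1), gc = 0.5)
    got <- predict_hairpin(s)
    want <- oracle_hairpin(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(got$stem_bp, got$loop_nt), unname(want),
                   info = sprintf("sequence %s", s))
      # structural invariants
      expect_gte(got$loop_nt, 3L)
      expect_lte(2 * got$stem_bp + got$loop_nt, nchar(s))
      stem5 <- substr(s, got$stem5_interval[1] + 1, got$stem5_interval[2])
      stem3 <- substr(s, got$stem3_interval[1] + 1, got$stem3_interval[2])
      expect_identical(stem5, reverse_complement(stem3))
    }
  }
})

test_that("pair report table carries 1-based coordinates and hairpin calls", {
  set.seed(8)
  s <- plant_ir(rand_seq(15000), rand_seq(53), 1000, 9000)
  g <- circular_sequence("tab", s)
  tab <- ir_pairs_table(find_inverted_repeat_pairs(g, min_span_bp = 1000,
                                                   max_span_bp = 14000))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$arm1_start, 1001)
  expect_equal(tab$arm2_end, 9053)
  expect_equal(tab$hr_span_bp, 8053)
  expect_true(is.na(tab$hairpin_stem_bp) || tab$hairpin_stem_bp >= 2)
})
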