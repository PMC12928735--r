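make_sam <- function(lines, ref = "ref", len = 1000L) {
  tmp <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref, len), lines), tmp)
  tmp
}

test_that("read_sam parses mandatory fields, CIGAR arithmetic and flags", {
  sq <- strrep("A", 100)
  sam <- make_sam(c(
    paste("p1", 99, "ref", 11, 60, "100M", "=", 311, 400, sq, "*", "NM:i:2",
          sep = "\t"),
    paste("p1", 147, "ref", 311, 60, "100M", "=", 11, -400, sq, "*",
          sep = "\t")))
  aln <- read_sam(sam)
  expect_equal(nrow(aln), 2)
  expect_equal(aln$pos, c(10, 310))      # 0-based internally
  expect_equal(aln$ref_end, c(110, 410))
  expect_equal(aln$mate, c(1L, 2L))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$nm, c(2L, 0L))
  pp <- pair_alignments(aln)
  expect_equal(nrow(pp$pairs), 1)
  expect_equal(pp$pairs$span, 400)
  expect_equal(pp$pairs$orientation, "FR")
})

test_that("soft clips consume read but not reference", {
  sq <- strrep("C", 150)
  sam <- make_sam(paste("c1", 0, "ref", 101, 60, "100M50S", "*", 0, 0, sq,
                        "*", sep = "\t"))
  aln <- read_sam(sam)
  expect_equal(aln$ref_span, 100)
  expect_equal(aln$clip_right, 50)
  expect_equal(aln$clip_left, 0)
})

test_that("a CIGAR/sequence length mismatch is a record-level error", {
  sam <- make_sam(paste("bad", 0, "ref", 1, 60, "100M", "*", 0, 0,
                        strrep("A", 90), "*", sep = "\t"))
  expect_error(read_sam(sam), "line 3")
})

test_that("SAM writing then reading preserves alignment fields", {
  set.seed(41)
  ref <- circular_sequence("rt", rand_seq(5000))
  starts <- c(100, 900, 2400)
  r1 <- substring(ref$seq, starts + 1, starts + 150)
  r2 <- vapply(starts, function(s)
    reverse_complement(substring(ref$seq, s + 251, s + 400)), character(1))
  aln <- lightweight_map(r1, r2, ref, ids = paste0("p", 1:3))
  tmp <- tempfile(fileext = ".sam")
  write_sam(aln, tmp)
  back <- read_sam(tmp)
  for (col in c("qname", "flag", "pos", "mapq", "cigar", "seq", "nm"))
    expect_identical(back[[col]], aln[[col]])
  expect_equal(attr(back, "ref_id"), "rt")
  expect_equal(attr(back, "ref_len"), 5000)
})

test_that("mean_depth averages covering alignments over the region", {
  empty <- read_sam(make_sam(character(0)))
  expect_equal(mean_depth(empty, interval(0, 300)), 0)
  sq <- strrep("G", 150)
  aln <- read_sam(make_sam(paste("d1", 0, "ref", 51, 60, "150M", "*", 0, 0,
                                 sq, "*", sep = "\t")))
  expect_equal(mean_depth(aln, interval(50, 350)), 0.5)   # 150 / 300
  # soft-clipped part contributes nothing
  aln2 <- read_sam(make_sam(paste("d2", 0, "ref", 51, 60, "100M50S", "*", 0,
                                  0, sq, "*", sep = "\t")))
  expect_equal(mean_depth(aln2, interval(50, 350)), 100 / 300)
  # secondary/duplicate records are excluded
  aln3 <- read_sam(make_sam(paste("d3", 1024, "ref", 51, 60, "150M", "*", 0,
                                  0, sq, "*", sep = "\t")))
  expect_equal(mean_depth(aln3, interval(50, 350)), 0)
  expect_error(mean_depth(aln, interval(100, 50, wraps = TRUE, length = 1000)),
               "wrap")
})

test_that("depth is conserved: column sums equal covered M-span", {
  set.seed(43)
  cfg <- sim_config(genome_bp = 30000, hr_span_bp = 6000, f = 0,
                    depth_x = 20, seed = 43)
  d <- simulate_dataset(cfg)
  aln <- lightweight_map(d$r1, d$r2, d$normal, ids = d$ids)
  n <- nchar(d$normal$seq)
  # depth over [0, n) equals the summed M-span clamped at n (alignments of
  # origin-wrapping reads run past n on the doubled reference)
  covered <- sum(pmin(aln$ref_end, n) - aln$pos)
  expect_equal(mean_depth(aln, interval(0, n)) * n, covered)
})

test_that("the internal mapper recovers exact origins and clips at breakpoints", {
  set.seed(47)
  ref <- circular_sequence("m", rand_seq(20000))
  # error-free read from positions 1000..1149 (0-based)
  rd <- substr(ref$seq, 1001, 1150)
  a <- lightweight_map(rd, reverse_complement(substr(ref$seq, 1301, 1450)),
                       ref, ids = "x")
  expect_equal(a$pos[1], 1000)
  expect_equal(a$cigar[1], "150M")
  expect_equal(a$strand[1], "+")
  expect_equal(a$pos[2], 1300)
  expect_equal(a$strand[2], "-")

  # read straddling a planted inversion breakpoint: half maps, half clips
  s <- plant_ir(rand_seq(20000), rand_seq(53), 2000, 12000)
  g <- circular_sequence("bp", s)
  p <- sirhet:::.new_sir_pair(g, 2000L, 2053L, 12000L, 12053L)
  iso <- build_inverted_isoform(g, p)
  # 75 bp each side of the left divergence point (arm1 inner boundary).
  # The mirror-side alignment continues straight through arm2 (= revcomp of
  # arm1), so 75 + 53 = 128 bases anchor and the remaining 22 bp overhang
  # beyond the arm's outer boundary is clipped (minus chance extension).
  rd <- substr(iso$inverted$seq, 2053 - 75 + 1, 2053 + 75)
  a <- lightweight_map(rd, rd, g, ids = "bp")[1, ]
  expect_gte(a$clip_left + a$clip_right, 12)
  expect_lte(a$clip_left + a$clip_right, 22)
  expect_gte(a$ref_span, 128 - 10)
  expect_equal(a$clip_left + a$ref_span + a$clip_right, 150)
  # the same read maps end-to-end on the inverted reference
  ai <- lightweight_map(rd, rd, iso$inverted, ids = "bp")[1, ]
  expect_equal(ai$cigar, "150M")
  expect_equal(ai$nm, 0)
})

test_that("mapper soundness: error-free simulated reads map to their origin", {
  set.seed(53)
  cfg <- sim_config(genome_bp = 50000, hr_span_bp = 10000, f = 0,
                    depth_x = 30, seed = 53)
  d <- simulate_dataset(cfg)
  aln <- lightweight_map(d$r1, d$r2, d$normal, ids = d$ids)
  expect_true(all(aln$mapped))
  full <- aln$cigar == "150M" & aln$nm == 0
  expect_gte(mean(full), 0.999)
  m1 <- aln[aln$mate == 1, ]
  truth_start <- d$truth$start[match(m1$qname, d$truth$fragment_id)]
  expect_true(all(m1$pos == truth_start))
})
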