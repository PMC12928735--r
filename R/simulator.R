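## Synthetic-data generator emulating the study inputs: a circular plastome
## with one planted sIR pair, a two-isoform mixture at a chosen frequency,
## paired-end reads, and a truth table that supports oracle tests of the
## detector.

#' Simulation configuration
#'
#' Defaults emulate the study system: a ~160 kb circular plastome at ~38% GC
#' carrying a 53 bp sIR pair spanning a 22 kb region, sequenced with 150 bp
#' paired-end reads (insert 400 +/- 50 bp) at a chosen depth, with a fraction
#' `f` of fragments drawn from the inverted isoform.
#'
#' @param genome_bp genome length (default 160000).
#' @param gc GC fraction of the background sequence (default 0.38).
#' @param arm_bp sIR arm length (default 53).
#' @param hr_span_bp width of the spanned (HR) region, arm1 start to arm2
#'   end (default 22000).
#' @param f inverted-isoform fraction in `[0, 1]` (default 0).
#' @param depth_x target mean read depth (default 500).
#' @param read_bp read length (default 150).
#' @param insert_mean,insert_sd fragment-size distribution in bp (400/50),
#'   truncated below at `2 * read_bp`.
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer RNG seed; one stream consumed in a fixed order
#'   (background, arm, arm placement, then fragments).
#' @param incomplete_subs,incomplete_indels optional mutations applied to the
#'   second arm to simulate an incomplete-match pair (substitution count and
#'   single-bp deletion count; default 0).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_bp = 160000L, gc = 0.38, arm_bp = 53L,
                       hr_span_bp = 22000L, f = 0, depth_x = 500,
                       read_bp = 150L, insert_mean = 400, insert_sd = 50,
                       error_rate = 0, seed = 1L, incomplete_subs = 0L,
                       incomplete_indels = 0L) {
  stopifnot(arm_bp >= 12L, f >= 0, f <= 1,
            hr_span_bp + 2 * insert_mean < genome_bp,
            hr_span_bp > 2 * arm_bp, read_bp < insert_mean)
  structure(list(genome_bp = as.integer(genome_bp), gc = gc,
                 arm_bp = as.integer(arm_bp),
                 hr_span_bp = as.integer(hr_span_bp), f = f,
                 depth_x = depth_x, read_bp = as.integer(read_bp),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed),
                 incomplete_subs = as.integer(incomplete_subs),
                 incomplete_indels = as.integer(incomplete_indels)),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

.sim_plastome_impl <- function(cfg, max_attempts = 20L) {
  n <- cfg$genome_bp
  margin <- 2000L
  probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  k0 <- min(30L, cfg$arm_bp)
  for (attempt in seq_len(max_attempts)) {
    bg <- sample(.BASES, n, replace = TRUE, prob = probs)
    arm <- paste(sample(.BASES, cfg$arm_bp, replace = TRUE, prob = probs),
                 collapse = "")
    a1s <- margin + sample.int(n - cfg$hr_span_bp - 2L * margin, 1L) - 1L
    a1e <- a1s + cfg$arm_bp
    a2e <- a1s + cfg$hr_span_bp
    a2s <- a2e - cfg$arm_bp
    arm2 <- reverse_complement(arm)
    if (cfg$incomplete_subs > 0L || cfg$incomplete_indels > 0L) {
      a2c <- strsplit(arm2, "", fixed = TRUE)[[1L]]
      if (cfg$incomplete_subs > 0L) {
        at <- sample.int(length(a2c), cfg$incomplete_subs)
        for (t in at) a2c[t] <- sample(setdiff(.BASES, a2c[t]), 1L)
      }
      if (cfg$incomplete_indels > 0L) {
        del <- sample.int(length(a2c) - 2L, cfg$incomplete_indels) + 1L
        a2c <- a2c[-del]
      }
      arm2 <- paste(a2c, collapse = "")
    }
    seqv <- bg
    seqv[(a1s + 1L):a1e] <- strsplit(arm, "", fixed = TRUE)[[1L]]
    s <- paste(seqv, collapse = "")
    s <- paste0(substr(s, 1L, a2s), arm2, substr(s, a2s + nchar(arm2) + 1L, n))
    a2e <- a2s + nchar(arm2)
    ## keep the planted arms maximal: the bases flanking the pair must not
    ## extend the reverse-complement match by chance
    comp1 <- function(x) chartr("ACGT", "TGCA", x)
    sub1 <- function(str, at, b) paste0(substr(str, 1L, at), b,
                                        substr(str, at + 2L, nchar(str)))
    while (substr(s, a1s, a1s) == comp1(substr(s, a2e + 1L, a2e + 1L)))
      s <- sub1(s, a1s - 1L, sample(.BASES, 1L, prob = probs))
    while (substr(s, a1e + 1L, a1e + 1L) == comp1(substr(s, a2s, a2s)))
      s <- sub1(s, a1e, sample(.BASES, 1L, prob = probs))
    genome <- circular_sequence("sim_plastome", s)
    ## rejection: no unplanted inverted repeat of >= k0 exact bases
    sd_ <- .shared_kmer_seeds(s, reverse_complement(s), k0)
    clean <- TRUE
    if (!is.null(sd_) && nrow(sd_) > 0L) {
      j <- nchar(s) - sd_$p - k0   # genome-side start of the rc k-mer
      in1 <- function(x) x >= a1s & x + k0 <= a1e
      in2 <- function(x) x >= a2s & x + k0 <= a2e
      planted <- (in1(sd_$i) & in2(j)) | (in2(sd_$i) & in1(j))
      clean <- all(planted)
    }
    if (!clean) next
    pair <- .new_sir_pair(genome, a1s, a1e, a2s, a2e)
    iso <- build_inverted_isoform(genome, pair)
    return(list(normal = genome, pair = pair, inverted = iso$inverted,
                iso = iso))
  }
  stop("could not generate a clean plastome in ", max_attempts,
       " attempts; try another seed", call. = FALSE)
}

#' Simulate a plastome with a planted sIR pair
#'
#' Draws an i.i.d. background at the configured GC, plants a random arm and
#' its reverse complement `hr_span_bp` apart (so the spanned region has
#' exactly that width), and rejects genomes in which any other exact
#' inverted repeat of at least `min(30, arm_bp)` bp arises by chance. The
#' genomes do not depend on `f`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `normal` and `inverted` ([circular_sequence()]), `pair`
#'   (the planted `sir_pair`) and `iso` (the [build_inverted_isoform()]
#'   result).
#' @export
simulate_plastome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .sim_plastome_impl(cfg)
}

.sim_reads_impl <- function(normal, inverted, cfg) {
  n <- nchar(normal$seq)
  rd <- cfg$read_bp
  N <- round(cfg$depth_x * n / (2 * rd))
  starts <- sample.int(n, N, replace = TRUE) - 1L
  ins <- as.integer(round(rnorm(N, cfg$insert_mean, cfg$insert_sd)))
  while (any(bad <- ins < 2L * rd))
    ins[bad] <- as.integer(round(rnorm(sum(bad), cfg$insert_mean, cfg$insert_sd)))
  u <- runif(N)
  inverted_origin <- u < cfg$f
  dn <- paste0(normal$seq, normal$seq)
  di <- paste0(inverted$seq, inverted$seq)
  r1 <- character(N); r2 <- character(N)
  for (grp in list(list(w = which(!inverted_origin), d = dn),
                   list(w = which(inverted_origin), d = di))) {
    if (length(grp$w) == 0L) next
    st <- starts[grp$w]
    r1[grp$w] <- substring(grp$d, st + 1L, st + rd)
    en <- st + ins[grp$w]
    r2[grp$w] <- substring(grp$d, en - rd + 1L, en)
  }
  r2 <- revcomp_vec(r2)
  err1 <- character(N); err2 <- character(N)
  err1[] <- ""; err2[] <- ""
  if (cfg$error_rate > 0) {
    mutate <- function(reads) {
      cnt <- rbinom(N, rd, cfg$error_rate)
      tot <- sum(cnt)
      rec <- character(N); rec[] <- ""
      if (tot > 0L) {
        ridx <- rep.int(which(cnt > 0L), cnt[cnt > 0L])
        at <- sample.int(rd, tot, replace = TRUE)
        off <- sample.int(3L, tot, replace = TRUE)
        orig <- substr(reads[ridx], at, at)
        newb <- .BASES[((match(orig, .BASES) - 1L + off) %% 4L) + 1L]
        reads <- apply_substitutions(reads, ridx, at, newb)
        rec_ev <- split(at, ridx)
        rec[as.integer(names(rec_ev))] <-
          vapply(rec_ev, paste, character(1), collapse = ";")
      }
      list(reads = reads, rec = rec)
    }
    m1 <- mutate(r1); r1 <- m1$reads; err1 <- m1$rec
    m2 <- mutate(r2); r2 <- m2$reads; err2 <- m2$rec
  }
  ids <- sprintf("frag%06d", seq_len(N))
  truth <- data.frame(fragment_id = ids,
                      origin = ifelse(inverted_origin, "inverted", "normal"),
                      start = starts, insert = ins,
                      crosses_breakpoint = FALSE,
                      err1 = err1, err2 = err2, stringsAsFactors = FALSE)
  list(ids = ids, r1 = r1, r2 = r2, truth = truth)
}

#' Simulate paired-end reads from a two-isoform mixture
#'
#' Fragment count `N = round(depth_x * genome_bp / (2 * read_bp))`; each
#' fragment's origin is Bernoulli(`f`), its start uniform on the circle, its
#' length Normal(insert_mean, insert_sd) truncated at `2 * read_bp`. R1 is
#' the forward strand at the fragment start, R2 the reverse complement of
#' the fragment end (FR layout). Substitution errors are i.i.d. at
#' `error_rate`. Qualities are constant Q40.
#'
#' @param normal,inverted the two isoform references ([circular_sequence()]).
#' @param cfg a [sim_config()].
#' @param iso optional `isoform_pair` used to annotate breakpoint-crossing
#'   fragments in the truth table.
#' @param seed optional; when given, reseeds the stream (otherwise the call
#'   continues the stream left by [simulate_plastome()]).
#' @return list with `ids`, `r1`, `r2` (character vectors) and `truth` (one
#'   row per fragment: origin, start, insert, crosses_breakpoint, error
#'   positions).
#' @export
simulate_reads <- function(normal, inverted, cfg, iso = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- .sim_reads_impl(normal, inverted, cfg)
  if (!is.null(iso)) {
    bounds <- c(iso$pair$arm1$start, iso$pair$arm1$end,
                iso$pair$arm2$start, iso$pair$arm2$end)
    n <- nchar(normal$seq)
    cross <- rep(FALSE, nrow(out$truth))
    for (b in bounds)
      cross <- cross | (((b - out$truth$start) %% n) < out$truth$insert)
    out$truth$crosses_breakpoint <- cross
  }
  out
}

#' Simulate a full dataset (genome + reads) from one seed
#'
#' Single RNG stream: genome, arm placement, then fragments, so the run is
#' byte-reproducible from `cfg$seed` and the genomes are identical across
#' runs that differ only in `f` (fragment origins are coupled through the
#' same uniform draws).
#'
#' @param cfg a [sim_config()].
#' @return list with `normal`, `inverted`, `pair`, `iso`, `ids`, `r1`, `r2`,
#'   `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- .sim_plastome_impl(cfg)
  rds <- simulate_reads(g$normal, g$inverted, cfg, iso = g$iso)
  c(g, rds, list(cfg = cfg))
}

## ---- truth oracle -----------------------------------------------------------

## mirror of the mapper's maximal-scoring-window rule (match +1, mismatch
## -mm_pen; earliest window of the maximal score)
.kadane_window <- function(match_profile, mm_pen) {
  best_s <- 0L; best_b <- 0L; best_e <- 0L
  cur_s <- 0L; cur_b <- 0L
  for (i in seq_along(match_profile)) {
    sc <- if (match_profile[i]) 1L else -mm_pen
    if (cur_s <= 0L) { cur_s <- sc; cur_b <- i - 1L } else cur_s <- cur_s + sc
    if (cur_s > best_s) { best_s <- cur_s; best_b <- cur_b; best_e <- i }
  }
  nm <- if (best_e > best_b) sum(!match_profile[(best_b + 1L):best_e]) else 0L
  list(b = best_b, e = best_e, score = best_s, nm = nm)
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## analytic placement of one read of an inverted-origin fragment on the
## normal reference: evaluates the identity diagonal and the mirror diagonal
## exactly as the internal mapper would (seedability, scoring window,
## tie-breaks), but with the search replaced by the known truth coordinates
.oracle_align_read <- function(x, y, mate, iso, k, stride, mm_pen) {
  n <- nchar(iso$normal$seq)
  L <- y - x
  iseq <- .chars(substr(iso$inverted$seq, x + 1L, y))
  ms <- iso$hr_start + iso$hr_end - y
  nseq_ident <- .chars(substr(iso$normal$seq, x + 1L, y))
  nseq_mirr <- .chars(substr(iso$normal$seq, ms + 1L, ms + L))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  irev <- rev(unname(comp[iseq]))
  prof_ident <- iseq == nseq_ident
  prof_mirr <- irev == nseq_mirr
  offsets <- unique(c(seq(0L, L - k, by = stride), L - k))
  seedable <- function(prof) {
    for (o in offsets) if (all(prof[(o + 1L):(o + k)])) return(TRUE)
    FALSE
  }
  cands <- list()
  if (seedable(prof_ident))
    cands[[length(cands) + 1L]] <-
      c(list(start = x, strand_eval = if (mate == 1L) "+" else "-"),
        .kadane_window(prof_ident, mm_pen))
  if (seedable(prof_mirr))
    cands[[length(cands) + 1L]] <-
      c(list(start = ms, strand_eval = if (mate == 1L) "-" else "+"),
        .kadane_window(prof_mirr, mm_pen))
  if (length(cands) == 0L) return(NULL)
  best <- cands[[1L]]
  for (c2 in cands[-1]) {
    if (c2$score > best$score ||
        (c2$score == best$score &&
         (c2$start < best$start ||
          (c2$start == best$start && c2$strand_eval == "+" &&
           best$strand_eval == "-")))) best <- c2
  }
  list(pos = best$start + best$b, end = best$start + best$e,
       strand = best$strand_eval, clipL = best$b, clipR = L - best$e,
       nm = best$nm, score = best$score)
}

#' Truth-oracle set of supporting fragments
#'
#' Computes, directly from the simulator's truth coordinates (never from
#' alignments), the set of inverted-origin fragments whose read geometry on
#' the normal reference satisfies the detection criteria: arm overlap or the
#' interior/exterior rule, the span tolerance or a qualifying arm-boundary
#' clip, and the strict mate-span bound on the inverted reference. Each
#' read's placement is derived analytically from the coordinate map
#' (including the deterministic scoring-window behaviour at a breakpoint).
#' Valid for error-free reads.
#'
#' @param truth the truth table from [simulate_reads()].
#' @param iso the `isoform_pair` of the simulated genomes.
#' @param cfg the [sim_config()] used.
#' @param params [detection_params()].
#' @param k,stride,mm_pen internal-mapper parameters (must match those used
#'   when mapping, see [lightweight_map()]).
#' @return character vector of supporting `fragment_id`s.
#' @export
truth_supporting_set <- function(truth, iso, cfg, params = detection_params(),
                                 k = 21L, stride = 7L, mm_pen = 3L) {
  stopifnot(inherits(iso, "isoform_pair"), inherits(cfg, "sim_config"))
  ## divergence zone between the two references
  a <- utf8ToInt(iso$normal$seq); b <- utf8ToInt(iso$inverted$seq)
  dif <- which(a != b)
  if (length(dif) == 0L) return(character(0))
  b1 <- dif[1L] - 1L; b2 <- dif[length(dif)]    # 0-based half-open
  rd <- cfg$read_bp
  cand <- truth[truth$origin == "inverted" &
                  truth$start < b2 & truth$start + truth$insert > b1, ,
                drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  if (any(nzchar(cand$err1) | nzchar(cand$err2)))
    stop("truth oracle requires error-free reads for candidate fragments",
         call. = FALSE)
  arms <- iso$pair
  hr <- interval(iso$hr_start, iso$hr_end, length = nchar(iso$normal$seq))
  hr_span <- interval_span(hr)
  supported <- character(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; ins <- cand$insert[i]
    al1 <- .oracle_align_read(s, s + rd, 1L, iso, k, stride, mm_pen)
    al2 <- .oracle_align_read(s + ins - rd, s + ins, 2L, iso, k, stride, mm_pen)
    if (is.null(al1) || is.null(al2)) next
    pr <- data.frame(qname = cand$fragment_id[i],
                     pos1 = al1$pos, end1 = al1$end, strand1 = al1$strand,
                     clipL1 = al1$clipL, clipR1 = al1$clipR, nm1 = al1$nm,
                     indels1 = 0L, seq1 = "",
                     pos2 = al2$pos, end2 = al2$end, strand2 = al2$strand,
                     clipL2 = al2$clipL, clipR2 = al2$clipR, nm2 = al2$nm,
                     indels2 = 0L, seq2 = "", stringsAsFactors = FALSE)
    left1 <- pr$pos1 <= pr$pos2
    pr$span <- max(pr$end1, pr$end2) - min(pr$pos1, pr$pos2)
    pr$orientation <- paste0(
      ifelse((if (left1) pr$strand1 else pr$strand2) == "+", "F", "R"),
      ifelse((if (left1) pr$strand2 else pr$strand1) == "+", "F", "R"))
    ## clip path: junction within an arm (+slop); remapping of a true
    ## breakpoint clip always succeeds at identity 1 within the window
    slop <- params$clip_junction_slop_bp
    junction_in_arm <- function(x)
      (x >= arms$arm1$start - slop & x <= arms$arm1$end + slop) |
      (x >= arms$arm2$start - slop & x <= arms$arm2$end + slop)
    clip_ok <- function(al) {
      (al$clipL >= params$min_clip_bp && junction_in_arm(al$pos)) ||
        (al$clipR >= params$min_clip_bp && junction_in_arm(al$end))
    }
    has_clip <- clip_ok(al1) || clip_ok(al2)
    full_ok <- pr$orientation != "FR" &&
      abs(pr$span - hr_span) <= params$span_tolerance_bp &&
      sir_overlap_rule(pr, arms, hr, params) != "fail"
    if (!(has_clip || full_ok)) next
    ## inverted-reference check: both reads align fully FR at span == insert
    if (!(ins < params$inverted_max_span_bp)) next
    if (al1$nm + al2$nm > params$variant_tolerance) next
    supported <- c(supported, cand$fragment_id[i])
  }
  supported
}
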