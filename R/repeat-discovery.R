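## Discovery of short inverted-repeat (sIR) pairs by self-comparison of a
## genome against its reverse complement.
##
## An sIR pair report is built from exact-match runs (>= seed length) on a
## diagonal of genome vs revcomp(genome), merged across substitution gaps
## (and small diagonal shifts for indels) while the combined identity stays
## above the identity floor. Arm ends are therefore always exact matches, so
## a perfect planted pair is reported at exactly its planted coordinates.

.pa_identity <- function(a, b, type = "overlap") {
  # identity = matches / alignment columns; match +1, mismatch -1, gap -2
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::pattern(al)))
  if (cols == 0L) return(0)
  Biostrings::nmatch(al) / cols
}

.new_sir_pair <- function(genome, a1s, a1e, a2s, a2e, identity = NULL) {
  n <- nchar(genome$seq)
  arm1_seq <- substr(genome$seq, a1s + 1L, a1e)
  arm2_seq <- substr(genome$seq, a2s + 1L, a2e)
  if (is.null(identity)) {
    identity <- if (arm1_seq == reverse_complement(arm2_seq)) 1.0 else
      .pa_identity(arm1_seq, reverse_complement(arm2_seq))
  }
  pair <- structure(list(
    arm1 = list(start = as.integer(a1s), end = as.integer(a1e),
                seq = arm1_seq, label = "sIR-1"),
    arm2 = list(start = as.integer(a2s), end = as.integer(a2e),
                seq = arm2_seq, label = "sIR-2"),
    identity = identity,
    match_class = NA_character_,
    hr = interval(a1s, a2e, length = n),
    spacer_bp = as.integer(a2s - a1e),
    genome_id = genome$id), class = "sir_pair")
  pair$match_class <- classify_match(pair)
  pair
}

#' @export
print.sir_pair <- function(x, ...) {
  cat(sprintf("<sir_pair> %s: sIR-1 %d-%d | sIR-2 %d-%d (1-based), identity %.4f, %s, HR span %d bp\n",
              x$genome_id, x$arm1$start + 1L, x$arm1$end, x$arm2$start + 1L,
              x$arm2$end, x$identity, x$match_class, interval_span(x$hr)))
  invisible(x)
}

#' Classify an sIR pair as complete or incomplete match
#'
#' A pair is a complete match iff the two arms have equal length and arm1
#' equals the reverse complement of arm2 exactly (identity 1); any
#' substitution, insertion or deletion makes it incomplete.
#'
#' @param pair a `sir_pair` as returned by [find_inverted_repeat_pairs()].
#' @return `"complete"` or `"incomplete"`.
#' @export
classify_match <- function(pair) {
  stopifnot(inherits(pair, "sir_pair"))
  same_len <- (pair$arm1$end - pair$arm1$start) == (pair$arm2$end - pair$arm2$start)
  if (same_len && pair$identity == 1) "complete" else "incomplete"
}

## seeds: positions of shared k-mers between s and revcomp(s)
.shared_kmer_seeds <- function(s, rc, k) {
  n <- nchar(s)
  if (n < k) return(NULL)
  ks <- substring(s, 1:(n - k + 1L), k:n)
  kr <- substring(rc, 1:(n - k + 1L), k:n)
  hit <- kr %in% ks
  if (!any(hit)) return(NULL)
  vals <- unique(kr[hit])
  pos_s <- split(which(ks %in% vals), ks[ks %in% vals])
  pos_r <- split(which(hit), kr[hit])
  i <- integer(0); p <- integer(0)
  for (v in vals) {
    g <- expand.grid(i = pos_s[[v]], p = pos_r[[v]])
    i <- c(i, g$i); p <- c(p, g$p)
  }
  data.frame(i = i - 1L, p = p - 1L)  # 0-based starts on s and rc
}

#' Find short inverted-repeat pairs in a genome
#'
#' Self-comparison of the genome against its reverse complement: exact k-mer
#' seeding, extension to maximal exact-match runs on each seeded diagonal,
#' and merging of nearby runs (substitution gaps on the same diagonal, small
#' diagonal shifts for indels) while the merged identity stays at or above
#' `min_identity`. Reported arms always begin and end on exact matches.
#'
#' @param genome a [circular_sequence()]. Discovery is performed on the given
#'   linearisation; a pair whose spanned region would cross the origin is not
#'   reported (rotate first).
#' @param min_arm_bp,max_arm_bp accepted arm-length range (default 30-1000 bp;
#'   the upper bound excludes the canonical large IRs).
#' @param min_span_bp,max_span_bp accepted range for the spanned (HR) region,
#'   measured from arm1 start to arm2 end (default 5-60 kb).
#' @param min_identity identity floor for an arm pair, matches over alignment
#'   columns of an end-free global alignment (match +1, mismatch -1, gap -2).
#' @param seed_k exact seed length (default 12).
#' @return list of `sir_pair` objects sorted by descending identity then
#'   descending arm length; empty list when nothing qualifies.
#' @export
find_inverted_repeat_pairs <- function(genome, min_arm_bp = 30L, max_arm_bp = 1000L,
                                       min_span_bp = 5000L, max_span_bp = 60000L,
                                       min_identity = 0.8, seed_k = 12L) {
  stopifnot(inherits(genome, "circular_sequence"))
  n <- nchar(genome$seq)
  if (min_arm_bp < 12L) stop("min_arm_bp must be >= 12", call. = FALSE)
  if (!(min_span_bp < max_span_bp && max_span_bp <= n))
    stop("need min_span_bp < max_span_bp <= genome length", call. = FALSE)
  s <- genome$seq
  rc <- reverse_complement(s)
  seeds <- .shared_kmer_seeds(s, rc, seed_k)
  if (is.null(seeds) || nrow(seeds) == 0L) return(list())

  ## extend seeds into maximal exact runs, one diagonal at a time
  seeds$d <- seeds$i - seeds$p
  runs <- list()
  for (d in unique(seeds$d)) {
    sd_ <- seeds[seeds$d == d, , drop = FALSE]
    lo <- max(min(sd_$i) - max_arm_bp, max(0L, d))
    hi <- min(max(sd_$i) + seed_k + max_arm_bp, n, n + d)
    if (hi - lo < seed_k) next
    a_sub <- substr(s, lo + 1L, hi)
    b_sub <- substr(rc, lo - d + 1L, hi - d)
    rr <- match_runs(a_sub, b_sub, as.integer(seed_k))
    if (nrow(rr) == 0L) next
    runs[[length(runs) + 1L]] <- data.frame(i1 = rr[, 1] + lo, i2 = rr[, 2] + lo, d = d)
  }
  if (length(runs) == 0L) return(list())
  runs <- do.call(rbind, runs)
  runs <- unique(runs)

  ## greedy clustering of runs: same or nearby diagonal, small coordinate gap
  max_shift <- 10L   # max cumulative indel between merged runs
  max_gap <- 40L     # max unmatched stretch bridged between runs
  runs <- runs[order(runs$i1), , drop = FALSE]
  cluster <- rep(NA_integer_, nrow(runs))
  nclust <- 0L
  last_i2 <- integer(0); last_d <- integer(0)
  for (r in seq_len(nrow(runs))) {
    placed <- FALSE
    if (nclust > 0L) {
      for (cid in seq_len(nclust)) {
        if (abs(runs$d[r] - last_d[cid]) <= max_shift &&
            runs$i1[r] - last_i2[cid] <= max_gap &&
            runs$i1[r] - last_i2[cid] >= -seed_k) {
          cluster[r] <- cid
          last_i2[cid] <- max(last_i2[cid], runs$i2[r])
          last_d[cid] <- runs$d[r]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      nclust <- nclust + 1L
      cluster[r] <- nclust
      last_i2[nclust] <- runs$i2[r]
      last_d[nclust] <- runs$d[r]
    }
  }

  pairs <- list()
  seen <- character(0)
  for (cid in seq_len(nclust)) {
    cl <- runs[cluster == cid, , drop = FALSE]
    ## candidate arm on s and on rc, each bounded by exact runs
    i1 <- min(cl$i1); i2 <- max(cl$i2)
    p1 <- min(cl$i1 - cl$d); p2 <- max(cl$i2 - cl$d)
    ## map rc coordinates back to the genome: rc[p] pairs with genome[n-1-p]
    a1s <- i1; a1e <- i2
    a2s <- n - p2; a2e <- n - p1
    ## drop the within-identity-floor requirement test below via identity calc
    if (a1s >= a2s) { tmp <- c(a2s, a2e); a2s <- a1s; a2e <- a1e; a1s <- tmp[1]; a1e <- tmp[2] }
    key <- paste(a1s, a1e, a2s, a2e)
    if (key %in% seen) next
    seen <- c(seen, key)
    len1 <- a1e - a1s; len2 <- a2e - a2s
    if (min(len1, len2) < min_arm_bp || max(len1, len2) > max_arm_bp) next
    if (a1e > a2s) next                       # overlapping arms (palindrome core)
    span <- a2e - a1s
    if (span < min_span_bp || span > max_span_bp) next
    pr <- .new_sir_pair(genome, a1s, a1e, a2s, a2e)
    if (pr$identity < min_identity) next
    pairs[[length(pairs) + 1L]] <- pr
  }
  if (length(pairs) == 0L) return(list())
  ord <- order(-vapply(pairs, function(p) p$identity, numeric(1)),
               -vapply(pairs, function(p) p$arm1$end - p$arm1$start, numeric(1)))
  pairs[ord]
}

#' Tabulate sIR pairs (1-based coordinates)
#'
#' One row per pair with the TSV report columns: arm coordinates (1-based
#' inclusive), arm sequences, identity, match class, HR span, and the
#' predicted hairpin of the sIR-2 arm.
#'
#' @param pairs list of `sir_pair` objects.
#' @return data.frame.
#' @export
ir_pairs_table <- function(pairs) {
  if (inherits(pairs, "sir_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    hp <- predict_hairpin(p$arm2$seq)
    data.frame(genome_id = p$genome_id,
               arm1_start = p$arm1$start + 1L, arm1_end = p$arm1$end,
               arm2_start = p$arm2$start + 1L, arm2_end = p$arm2$end,
               arm1_seq = p$arm1$seq, arm2_seq = p$arm2$seq,
               identity = p$identity, match_class = p$match_class,
               hr_span_bp = interval_span(p$hr),
               hairpin_stem_bp = if (is.null(hp)) NA_integer_ else hp$stem_bp,
               hairpin_loop_nt = if (is.null(hp)) NA_integer_ else hp$loop_nt,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), arm1_start = integer(0),
                      arm1_end = integer(0), arm2_start = integer(0),
                      arm2_end = integer(0), arm1_seq = character(0),
                      arm2_seq = character(0), identity = numeric(0),
                      match_class = character(0), hr_span_bp = integer(0),
                      hairpin_stem_bp = integer(0), hairpin_loop_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write the sIR pair report to TSV
#' @param pairs list of `sir_pair` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(ir_pairs_table(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Predict the maximal stem-loop (hairpin) of a short DNA sequence
#'
#' Combinatorial model: among all antiparallel stems of strict Watson-Crick
#' pairs (no G-T wobble, no bulges) with an unpaired loop of at least
#' `min_loop_nt`, returns the structure maximising the stem length; ties are
#' broken by smaller loop, then by smaller 5' start. No structure is reported
#' when the best stem is shorter than 2 bp.
#'
#' @param arm_seq nucleotide string (an sIR arm).
#' @param min_loop_nt minimum unpaired loop length (default 3).
#' @return a list of class `hairpin` with `stem_bp`, `loop_nt`,
#'   `stem5_interval`, `stem3_interval` (0-based half-open offsets within
#'   `arm_seq`), or `NULL` when no stem of at least 2 bp exists.
#' @examples
#' predict_hairpin("TTTGATTCCTGATTCAATCAAA")  # 7 bp stem, 8 nt loop
#' @export
predict_hairpin <- function(arm_seq, min_loop_nt = 3L) {
  stopifnot(is.character(arm_seq), length(arm_seq) == 1L)
  arm_seq <- toupper(arm_seq)
  .check_nucleotides(arm_seq)
  n <- nchar(arm_seq)
  if (n < min_loop_nt + 2L) stop("sequence shorter than min_loop_nt + 2", call. = FALSE)
  x <- strsplit(arm_seq, "", fixed = TRUE)[[1L]]
  cx <- chartr("ACGTN", "TGCAN", x)
  min_loop_nt <- as.integer(min_loop_nt)
  best <- list(stem = 0L, loop = .Machine$integer.max, i = .Machine$integer.max,
               e = NA_integer_)
  # enumerate by antidiagonal m = i + e (0-based outer pair); a stem starting
  # at (i, e = m - i) runs inward along the same antidiagonal
  for (m in seq(min_loop_nt + 2L, 2L * n - 2L)) {
    i_lo <- max(0L, m - n + 1L)
    i_hi <- (m - 1L) %/% 2L            # need i < e
    if (i_hi < i_lo) next
    ii <- i_lo:i_hi
    ok <- x[ii + 1L] == cx[m - ii + 1L] & x[ii + 1L] != "N"
    if (!any(ok)) next
    # consecutive-TRUE run length starting at each position, running inward
    r <- rle(ok)
    run <- unlist(lapply(seq_along(r$lengths), function(j)
      if (r$values[j]) rev(seq_len(r$lengths[j])) else integer(r$lengths[j])),
      use.names = FALSE)
    run[!ok] <- 0L
    # loop = m - 2i + 1 - 2L must stay >= min_loop_nt
    cap <- (m - 2L * ii + 1L - min_loop_nt) %/% 2L
    L <- pmin(run, pmax(cap, 0L))
    cand <- which(L >= 1L)
    if (length(cand) == 0L) next
    loops <- m - 2L * ii[cand] + 1L - 2L * L[cand]
    o <- order(-L[cand], loops, ii[cand])[1L]
    Lt <- L[cand][o]; lt <- loops[o]; it <- ii[cand][o]
    if (Lt > best$stem ||
        (Lt == best$stem && (lt < best$loop ||
                             (lt == best$loop && it < best$i)))) {
      best <- list(stem = Lt, loop = lt, i = it, e = m - it)
    }
  }
  if (best$stem < 2L) return(NULL)
  structure(list(stem_bp = best$stem, loop_nt = best$loop,
                 stem5_interval = c(best$i, best$i + best$stem),
                 stem3_interval = c(best$e - best$stem + 1L, best$e + 1L)),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> stem %d bp, loop %d nt; stem positions %d-%d / %d-%d (1-based)\n",
              x$stem_bp, x$loop_nt, x$stem5_interval[1] + 1L, x$stem5_interval[2],
              x$stem3_interval[1] + 1L, x$stem3_interval[2]))
  invisible(x)
}
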