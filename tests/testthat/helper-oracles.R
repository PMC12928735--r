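# Independent brute-force oracles used by the test suite. They share only
# the documented definitions with the implementation, never its code paths.

rand_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant arm + revcomp(arm) into a background string; 0-based starts. The
# flanking bases are adjusted (deterministically) so the planted match is
# maximal: discovery reports the pair at exactly these coordinates.
plant_ir <- function(bg, arm, a1s, a2s) {
  n <- nchar(bg)
  arm2 <- reverse_complement(arm)
  stopifnot(a1s + nchar(arm) <= a2s, a2s + nchar(arm2) <= n)
  s <- paste0(substr(bg, 1, a1s), arm,
              substr(bg, a1s + nchar(arm) + 1, a2s), arm2,
              substr(bg, a2s + nchar(arm2) + 1, n))
  a1e <- a1s + nchar(arm); a2e <- a2s + nchar(arm2)
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  fix <- function(s, at, partner) {
    # replace base at 0-based `at` with one that cannot pair with `partner`
    if (at < 0 || at >= n) return(s)
    if (substr(s, at + 1, at + 1) != comp1(partner)) return(s)
    repl <- setdiff(c("A", "C", "G", "T"), comp1(partner))[1]
    paste0(substr(s, 1, at), repl, substr(s, at + 2, n))
  }
  s <- fix(s, a1s - 1, substr(s, a2e + 1, a2e + 1))
  s <- fix(s, a1e, substr(s, a2s, a2s))
  s
}

# Brute-force inverted-repeat finder: scans every diagonal of s vs
# revcomp(s) exhaustively, takes maximal exact runs, and applies the
# arm-length / span / non-overlap filters. Returns a canonical data.frame
# sorted by coordinates (perfect-match pairs only).
oracle_find_ir <- function(s, min_arm, min_span, max_span, max_arm = 1000L) {
  n <- nchar(s)
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  y <- strsplit(reverse_complement(s), "", fixed = TRUE)[[1L]]
  hits <- list()
  for (d in (-(n - min_arm)):(n - min_arm)) {
    lo <- max(0L, d); hi <- min(n, n + d)        # i range on s (0-based)
    if (hi - lo < min_arm) next
    ii <- (lo + 1L):hi
    eq <- x[ii] == y[ii - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_arm)) {
      i1 <- lo + starts[j] - 1L; i2 <- lo + ends[j]   # 0-based half-open on s
      p1 <- i1 - d; p2 <- i2 - d                       # on revcomp(s)
      b1 <- n - p2; b2 <- n - p1                       # partner arm on s
      a <- c(min(i1, b1), min(i1, b1) + (i2 - i1), max(i1, b1),
             max(i1, b1) + (i2 - i1))
      if (a[2] - a[1] > max_arm) next
      if (a[2] > a[3]) next                            # overlapping arms
      span <- a[4] - a[1]
      if (span < min_span || span > max_span) next
      hits[[length(hits) + 1L]] <- a
    }
  }
  if (length(hits) == 0L)
    return(data.frame(a1s = integer(0), a1e = integer(0),
                      a2s = integer(0), a2e = integer(0)))
  m <- unique(do.call(rbind, hits))
  m <- m[order(m[, 1], m[, 3]), , drop = FALSE]
  data.frame(a1s = m[, 1], a1e = m[, 2], a2s = m[, 3], a2e = m[, 4])
}

pairs_to_coords <- function(pairs) {
  if (length(pairs) == 0L)
    return(data.frame(a1s = integer(0), a1e = integer(0),
                      a2s = integer(0), a2e = integer(0)))
  m <- t(vapply(pairs, function(p)
    c(p$arm1$start, p$arm1$end, p$arm2$start, p$arm2$end), integer(4)))
  m <- m[order(m[, 1], m[, 3]), , drop = FALSE]
  data.frame(a1s = m[, 1], a1e = m[, 2], a2s = m[, 3], a2e = m[, 4],
             row.names = NULL)
}

# Exhaustive hairpin oracle: enumerates every (i, j, L) triple directly.
# 0-based i (5' stem start), j (3' stem start); positions i+t pair with
# j+L-1-t; loop = j - (i + L) >= min_loop. Returns c(stem, loop) or NULL.
oracle_hairpin <- function(seq, min_loop = 3L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  n <- length(x)
  best <- NULL
  for (i in 0:(n - 1L)) for (j in (i + 1L):(n - 1L)) {
    if (j <= i) next
    maxL <- min(j - i - min_loop, n - j)
    if (maxL < 1L) next
    for (L in 1:maxL) {
      ok <- TRUE
      for (t in 0:(L - 1L)) {
        if (comp[[x[i + t + 1L]]] != x[j + L - 1L - t + 1L]) { ok <- FALSE; break }
      }
      if (!ok) next    # pairing partners shift with L: try longer stems too
      loop <- j - (i + L)
      cand <- c(L, loop, i)
      if (is.null(best) || cand[1] > best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
                                  (cand[2] == best[2] && cand[3] < best[3]))))
        best <- cand
    }
  }
  if (is.null(best) || best[1] < 2L) return(NULL)
  best[1:2]
}
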