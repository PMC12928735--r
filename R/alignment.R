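## SAM-text parsing/writing (minimal dialect: @HD/@SQ headers, 11 mandatory
## columns, NM tag), per-base depth, and the internal seed-and-extend mapper.
## Positions are 0-based half-open internally; SAM I/O converts.

.FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, mate_unmapped = 8L,
           reverse = 16L, mate_reverse = 32L, first = 64L, second = 128L,
           secondary = 256L, qcfail = 512L, dup = 1024L, supplementary = 2048L)

.has_flag <- function(flag, bit) bitwAnd(flag, .FLAG[[bit]]) != 0L

## cigar summaries, computed once per unique cigar string
.cigar_stats <- function(cigar) {
  u <- unique(cigar)
  stats <- vapply(u, function(cg) {
    if (cg == "*") return(c(0, 0, 0, 0, 0, 0))
    m <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[A-Z=]$", "", m))
    op <- sub("^[0-9]+", "", m)
    ref_span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    read_len <- sum(len[op %in% c("M", "I", "S", "=", "X")])
    clip_l <- if (op[1L] %in% c("S", "H")) len[1L] else 0L
    k <- length(op)
    clip_r <- if (op[k] %in% c("S", "H")) len[k] else 0L
    indels <- sum(len[op %in% c("I", "D")])
    c(ref_span, read_len, clip_l, clip_r, indels,
      as.integer(any(op %in% c("H"))))
  }, numeric(6))
  i <- match(cigar, u)
  data.frame(ref_span = stats[1L, i], read_len = stats[2L, i],
             clip_left = stats[3L, i], clip_right = stats[4L, i],
             indels = stats[5L, i])
}

.aln_df <- function(qname, flag, rname, pos0, mapq, cigar, seq, nm) {
  cs <- .cigar_stats(cigar)
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos0), mapq = as.integer(mapq), cigar = cigar,
             seq = seq, nm = as.integer(nm),
             mate = ifelse(bitwAnd(flag, 64L) != 0L, 1L,
                           ifelse(bitwAnd(flag, 128L) != 0L, 2L, 0L)),
             strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
             mapped = bitwAnd(flag, 4L) == 0L,
             primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
             dup = bitwAnd(flag, 1024L) != 0L,
             qcfail = bitwAnd(flag, 512L) != 0L,
             ref_span = as.integer(cs$ref_span),
             ref_end = as.integer(pos0) + as.integer(cs$ref_span),
             clip_left = as.integer(cs$clip_left),
             clip_right = as.integer(cs$clip_right),
             indels = as.integer(cs$indels),
             stringsAsFactors = FALSE)
}

#' Read a SAM text file
#'
#' Minimal dialect: header lines are skipped (reference name/length captured
#' from `@SQ`), the 11 mandatory columns are parsed, and an `NM:i:` tag is
#' used when present. Records whose CIGAR-implied read length disagrees with
#' the stored sequence raise an error naming the line.
#'
#' @param path SAM file path.
#' @param expected_ref optional reference name; mismatching records raise an
#'   error.
#' @return a `read_alignments` data.frame (0-based `pos`), with attributes
#'   `ref_id` and `ref_len` when an `@SQ` header is present.
#' @export
read_sam <- function(path, expected_ref = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  ref_id <- NA_character_; ref_len <- NA_integer_
  sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
  if (length(sq) >= 1L) {
    ref_id <- sub(".*SN:([^\t]+).*", "\\1", sq[1L])
    ref_len <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq[1L]))
  }
  body <- lines[!hdr]
  if (length(body) == 0L) {
    out <- .aln_df(character(0), integer(0), character(0), integer(0),
                   integer(0), character(0), character(0), integer(0))
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 11L))
      stop(sprintf("SAM record with fewer than 11 fields at line %d",
                   which(!hdr)[which(nf < 11L)[1L]]), call. = FALSE)
    get <- function(i) vapply(f, `[[`, character(1), i)
    qname <- get(1); flag <- as.integer(get(2)); rname <- get(3)
    pos1 <- as.integer(get(4)); mapq <- as.integer(get(5)); cigar <- get(6)
    seq <- toupper(get(10))
    nm <- rep(NA_integer_, length(body))
    extra <- vapply(f, function(x) paste(x[-(1:11)], collapse = "\t"), character(1))
    has_nm <- grepl("NM:i:", extra, fixed = TRUE)
    nm[has_nm] <- as.integer(sub(".*NM:i:([0-9]+).*", "\\1", extra[has_nm]))
    nm[is.na(nm)] <- 0L
    out <- .aln_df(qname, flag, rname, pos1 - 1L, mapq, cigar, seq, nm)
    bad <- out$mapped & out$seq != "*" & out$cigar != "*" &
      (nchar(out$seq) != .cigar_stats(out$cigar)$read_len)
    if (any(bad))
      stop(sprintf("CIGAR/sequence length mismatch at line %d",
                   which(!hdr)[which(bad)[1L]]), call. = FALSE)
    if (!is.null(expected_ref)) {
      wrong <- out$mapped & out$rname != expected_ref
      if (any(wrong))
        stop(sprintf("alignment to unexpected reference '%s' (expected '%s')",
                     out$rname[which(wrong)[1L]], expected_ref), call. = FALSE)
    }
  }
  attr(out, "ref_id") <- ref_id
  attr(out, "ref_len") <- ref_len
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Write alignments to SAM text
#'
#' @param aln a `read_alignments` data.frame.
#' @param path output path.
#' @param ref_id,ref_len reference name and length for the `@SQ` header;
#'   defaults to the attributes carried by `aln`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref_id = attr(aln, "ref_id"),
                      ref_len = attr(aln, "ref_len")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_id, as.integer(ref_len)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  rname <- ifelse(aln$mapped, ref_id, "*")
  pos1 <- ifelse(aln$mapped, aln$pos + 1L, 0L)
  cigar <- ifelse(aln$mapped, aln$cigar, "*")
  recs <- paste(aln$qname, aln$flag, rname, pos1, aln$mapq, cigar,
                "=", 0L, 0L, aln$seq, "*",
                paste0("NM:i:", aln$nm), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Pair primary alignments by read name
#'
#' Joins primary mate-1 and mate-2 records into one row per read pair, with
#' the observed outer span (leftmost to rightmost mapped base) and the pair
#' orientation (`FR`, `RF`, `FF`, `RR`; the leftmost read's strand first).
#' Pairs with an unmapped or absent mate are returned separately.
#'
#' @param aln a `read_alignments` data.frame.
#' @return list with `pairs` (one row per complete pair) and `incomplete`
#'   (qnames with a missing/unmapped mate).
#' @export
pair_alignments <- function(aln) {
  a <- aln[aln$primary & aln$mapped & aln$mate %in% c(1L, 2L), , drop = FALSE]
  m1 <- a[a$mate == 1L, , drop = FALSE]
  m2 <- a[a$mate == 2L, , drop = FALSE]
  common <- intersect(m1$qname, m2$qname)
  i1 <- match(common, m1$qname); i2 <- match(common, m2$qname)
  p <- data.frame(qname = common,
                  pos1 = m1$pos[i1], end1 = m1$ref_end[i1],
                  strand1 = m1$strand[i1], clipL1 = m1$clip_left[i1],
                  clipR1 = m1$clip_right[i1], nm1 = m1$nm[i1],
                  indels1 = m1$indels[i1], seq1 = m1$seq[i1],
                  pos2 = m2$pos[i2], end2 = m2$ref_end[i2],
                  strand2 = m2$strand[i2], clipL2 = m2$clip_left[i2],
                  clipR2 = m2$clip_right[i2], nm2 = m2$nm[i2],
                  indels2 = m2$indels[i2], seq2 = m2$seq[i2],
                  stringsAsFactors = FALSE)
  if (nrow(p) > 0L) {
    left1 <- p$pos1 <= p$pos2
    lstr <- ifelse(left1, p$strand1, p$strand2)
    rstr <- ifelse(left1, p$strand2, p$strand1)
    p$span <- pmax(p$end1, p$end2) - pmin(p$pos1, p$pos2)
    p$orientation <- paste0(ifelse(lstr == "+", "F", "R"),
                            ifelse(rstr == "+", "F", "R"))
  } else {
    p$span <- integer(0); p$orientation <- character(0)
  }
  incomplete <- setdiff(union(m1$qname, m2$qname), common)
  list(pairs = p, incomplete = incomplete)
}

#' Mean read depth over a region
#'
#' Average, over the positions of `region`, of the number of alignments whose
#' reference span (CIGAR M/D) covers the position. Unmapped, secondary,
#' supplementary, duplicate and QC-fail records are excluded; soft-clipped
#' portions contribute no coverage (mirrors the common depth-utility default;
#' no MAPQ or base-quality threshold).
#'
#' @param aln a `read_alignments` data.frame.
#' @param region a [interval()] (must not wrap).
#' @return mean depth (reads per base).
#' @export
mean_depth <- function(aln, region) {
  stopifnot(inherits(region, "genome_interval"))
  if (region$wraps) stop("region must not wrap the origin", call. = FALSE)
  w <- interval_span(region)
  if (w <= 0L) stop("empty region", call. = FALSE)
  a <- aln[aln$mapped & aln$primary & !aln$dup & !aln$qcfail, , drop = FALSE]
  if (nrow(a) == 0L) return(0)
  s <- pmax(a$pos, region$start) - region$start
  e <- pmin(a$ref_end, region$end) - region$start
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0L) return(0)
  ts <- tabulate(s + 1L, nbins = w + 1L)
  te <- tabulate(e + 1L, nbins = w + 1L)
  cov <- cumsum(ts - te)[seq_len(w)]
  sum(as.numeric(cov)) / w
}

.cigar_string <- function(clip_l, m_len, clip_r) {
  paste0(ifelse(clip_l > 0L, paste0(clip_l, "S"), ""),
         m_len, "M",
         ifelse(clip_r > 0L, paste0(clip_r, "S"), ""))
}

#' Map paired-end reads with the internal seed-and-extend mapper
#'
#' Exact k-mer seeding against the (doubled, for circularity) reference and
#' ungapped verification; the maximal-scoring contiguous window (match +1,
#' mismatch `-mm_pen`) is reported as M and the remainder as soft clips, so a
#' read crossing a structural breakpoint is clipped at the breakpoint. Among
#' equal-scoring placements the lowest reference offset wins. The internal
#' mapper handles substitutions but not indels; externally produced SAM is
#' the production path for indel-containing data.
#'
#' @param r1,r2 character vectors of read sequences (R2 as sequenced, i.e.
#'   reverse-complemented relative to the fragment), or lists as returned by
#'   [read_fastq()].
#' @param ref a [circular_sequence()] reference.
#' @param ids read-pair names; defaults to those in `r1` or `read1..N`.
#' @param k seed length (default 21).
#' @param stride seed sampling stride along the read (default 7).
#' @param min_score minimum accepted window score (default 30).
#' @param mm_pen mismatch penalty (default 3).
#' @return a `read_alignments` data.frame on `ref` (0-based `pos`), two rows
#'   per pair; unmapped reads are flagged, never dropped.
#' @export
lightweight_map <- function(r1, r2, ref, ids = NULL, k = 21L, stride = 7L,
                            min_score = 30L, mm_pen = 3L) {
  stopifnot(inherits(ref, "circular_sequence"))
  if (is.list(r1)) { if (is.null(ids)) ids <- sub("/[12]$", "", r1$id); r1 <- r1$seq }
  if (is.list(r2)) r2 <- r2$seq
  stopifnot(length(r1) == length(r2))
  if (is.null(ids)) ids <- paste0("read", seq_along(r1))
  res <- lapply(list(r1, r2), function(rds)
    map_reads_cpp(ref$seq, rds, as.integer(k), as.integer(stride),
                  as.integer(min_score), as.integer(mm_pen)))
  one_mate <- function(m, rds, mres, ores) {
    minus <- !is.na(mres$strand) & mres$strand == "-"
    seq_store <- rds
    if (any(minus)) seq_store[minus] <- revcomp_vec(rds[minus])
    flag <- rep(1L, length(rds)) +
      (if (m == 1L) 64L else 128L) +
      ifelse(mres$mapped, 0L, 4L) +
      ifelse(ores$mapped, 0L, 8L) +
      ifelse(minus, 16L, 0L) +
      ifelse(!is.na(ores$strand) & ores$strand == "-", 32L, 0L)
    cigar <- ifelse(mres$mapped,
                    .cigar_string(mres$clip_left, mres$m_len, mres$clip_right),
                    "*")
    .aln_df(ids, flag, ifelse(mres$mapped, ref$id, "*"),
            ifelse(mres$mapped, mres$pos, 0L),
            ifelse(mres$mapped, mres$mapq, 0L), cigar, seq_store,
            ifelse(mres$mapped, mres$nm, 0L))
  }
  out <- rbind(one_mate(1L, r1, res[[1L]], res[[2L]]),
               one_mate(2L, r2, res[[2L]], res[[1L]]))
  attr(out, "ref_id") <- ref$id
  attr(out, "ref_len") <- nchar(ref$seq)
  class(out) <- c("read_alignments", "data.frame")
  out
}
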