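#' @useDynLib sirhet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils read.delim write.table
#' @importFrom stats rbinom rnorm runif setNames
NULL

.VALID_BASES <- c("A", "C", "G", "T", "N")

.check_nucleotides <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("%s contains non-nucleotide character '%s' at position %d",
                 what, substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(seq)
}

#' Circular nucleotide sequence
#'
#' Container for an assembled (typically circular) genome such as a plastome.
#' Sequences are uppercased on construction; characters outside A/C/G/T/N are
#' rejected.
#'
#' @param id character label.
#' @param seq nucleotide string over A/C/G/T/N (case-insensitive).
#' @param circular logical; whether the molecule is circular. Circularity is
#'   declared, never inferred.
#' @return an object of class `circular_sequence` with fields `id`, `seq`,
#'   `circular`.
#' @export
circular_sequence <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("sequence must be non-empty", call. = FALSE)
  .check_nucleotides(seq, sprintf("sequence '%s'", id))
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("<circular_sequence> %s: %s bp (%s)\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circular_sequence <- function(x) nchar(x$seq)

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement of the reversed string; N maps to N. Fails on any
#' character outside A/C/G/T/N, naming the offending position.
#'
#' @param seq nucleotide string (character scalar, may be empty).
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  seq <- toupper(seq)
  .check_nucleotides(seq)
  # chartr + vectorised reversal; avoids DNAString overhead for hot small calls
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Rotate a circular sequence
#'
#' Returns the sequence re-linearised at offset `k` (0-based), i.e.
#' `seq[k:] + seq[:k]`. Used so that a region of interest never crosses the
#' origin of the circle.
#'
#' @param genome a [circular_sequence()].
#' @param k 0-based rotation offset, `0 <= k < length`.
#' @return a `circular_sequence` of the same length.
#' @export
rotate <- function(genome, k) {
  stopifnot(inherits(genome, "circular_sequence"))
  if (!genome$circular) stop("cannot rotate a non-circular sequence", call. = FALSE)
  n <- nchar(genome$seq)
  k <- as.integer(k)
  if (k < 0L || k >= n) stop("rotation offset must satisfy 0 <= k < length", call. = FALSE)
  if (k == 0L) return(genome)
  genome$seq <- paste0(substr(genome$seq, k + 1L, n), substr(genome$seq, 1L, k))
  genome
}

#' GC fraction of a nucleotide string
#'
#' (#G + #C) / (#A + #C + #G + #T); N is excluded from numerator and
#' denominator. Errors if the sequence contains only N.
#'
#' @param seq nucleotide string or a [circular_sequence()].
#' @return fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  if (inherits(seq, "circular_sequence")) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- toupper(seq)
  .check_nucleotides(seq)
  counts <- count_bases(seq)  # Rcpp: A,C,G,T,N counts
  acgt <- sum(counts[1:4])
  if (acgt == 0L) stop("GC fraction undefined: sequence contains only N", call. = FALSE)
  (counts[2L] + counts[3L]) / acgt
}

## ---- intervals (0-based, half-open internally) ------------------------------

#' Genomic interval
#'
#' 0-based, half-open interval, optionally wrapping the origin of a circular
#' sequence. User-facing reports convert to 1-based inclusive coordinates.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param wraps logical; TRUE when the interval crosses the origin.
#' @param length sequence length; required to validate a wrapping interval.
#' @return object of class `genome_interval`.
#' @export
interval <- function(start, end, wraps = FALSE, length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (!wraps) {
    if (start < 0L || end <= start) stop("invalid interval: need 0 <= start < end", call. = FALSE)
    if (!is.null(length) && end > length) stop("interval end beyond sequence length", call. = FALSE)
  } else {
    if (is.null(length)) stop("a wrapping interval needs the sequence length", call. = FALSE)
    if (start >= length || end > start) stop("invalid wrapping interval", call. = FALSE)
  }
  structure(list(start = start, end = end, wraps = isTRUE(wraps),
                 length = if (is.null(length)) NA_integer_ else as.integer(length)),
            class = "genome_interval")
}

#' Width of an interval in bp
#' @param x a [interval()].
#' @return integer span.
#' @export
interval_span <- function(x) {
  stopifnot(inherits(x, "genome_interval"))
  if (!x$wraps) x$end - x$start else (x$length - x$start) + x$end
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("<interval> [%d, %d) %s(%d bp)\n", x$start, x$end,
              if (x$wraps) "wrapping " else "", interval_span(x)))
  invisible(x)
}

## ---- FASTA / FASTQ ----------------------------------------------------------

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file path.
#' @param circular logical, recycled over records; circularity is declared by
#'   the caller, not inferred from sequence.
#' @return list of [circular_sequence()] objects, named by record id.
#' @export
read_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  circular <- rep_len(circular, length(ss))
  out <- lapply(seq_along(ss), function(i)
    circular_sequence(ids[i], as.character(ss[[i]]), circular = circular[i]))
  names(out) <- ids
  out
}

#' Write sequences to FASTA (70-column wrap)
#'
#' @param seqs a `circular_sequence` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circular_sequence")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(ss) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path FASTQ file path.
#' @return list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  list(id = sub("^@", "", lines[idx]),
       seq = toupper(lines[idx + 1L]),
       qual = lines[idx + 3L])
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param id,seq character vectors of read names and sequences.
#' @param path output file path.
#' @param qual quality strings; defaults to constant Q40 ('I').
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, path, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  out <- character(4L * length(id))
  out[seq(1L, by = 4L, length.out = length(id))] <- paste0("@", id)
  out[seq(2L, by = 4L, length.out = length(id))] <- seq
  out[seq(3L, by = 4L, length.out = length(id))] <- "+"
  out[seq(4L, by = 4L, length.out = length(id))] <- qual
  writeLines(out, path)
  invisible(path)
}

## internal: circular substring on a pre-doubled sequence
.sub_circ <- function(doubled, n, start0, width) {
  substring(doubled, start0 + 1L, start0 + width)
}
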