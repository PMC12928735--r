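## Construction of the alternative (inverted-type) reference from the
## normal-type reference and a selected sIR pair, with the coordinate map
## between the two references.

#' Build the inverted-type isoform of a genome
#'
#' Replaces the substring spanned by the sIR pair (inclusive of both arms)
#' with its reverse complement, emulating intramolecular homologous
#' recombination between the two arms. For a complete-match pair the arm
#' sequences at the boundaries are unchanged, and applying the operation
#' twice restores the original string.
#'
#' @param genome a [circular_sequence()] (the normal-type reference).
#' @param pair a `sir_pair` with coordinates on `genome`; its spanned region
#'   must not cross the origin (rotate first, see [rotate_clear()]).
#' @return an object of class `isoform_pair`: fields `normal`, `inverted`
#'   (both `circular_sequence`), `pair`, `hr_start`, `hr_end` (0-based
#'   half-open span of the recombination region).
#' @export
build_inverted_isoform <- function(genome, pair) {
  stopifnot(inherits(genome, "circular_sequence"), inherits(pair, "sir_pair"))
  n <- nchar(genome$seq)
  if (pair$hr$wraps)
    stop("the spanned region crosses the origin; rotate the genome first (see rotate_clear())",
         call. = FALSE)
  hs <- pair$hr$start; he <- pair$hr$end
  if (hs < 0L || he > n) stop("sIR pair does not lie on the genome", call. = FALSE)
  inv_seq <- paste0(substr(genome$seq, 1L, hs),
                    reverse_complement(substr(genome$seq, hs + 1L, he)),
                    substr(genome$seq, he + 1L, n))
  inverted <- circular_sequence(paste0(genome$id, "_inverted"), inv_seq,
                                circular = genome$circular)
  structure(list(normal = genome, inverted = inverted, pair = pair,
                 hr_start = as.integer(hs), hr_end = as.integer(he)),
            class = "isoform_pair")
}

#' @export
print.isoform_pair <- function(x, ...) {
  cat(sprintf("<isoform_pair> %s <-> %s; inverted segment %d-%d (1-based, %d bp)\n",
              x$normal$id, x$inverted$id, x$hr_start + 1L, x$hr_end,
              x$hr_end - x$hr_start))
  invisible(x)
}

#' Map positions between the two isoform references
#'
#' Identity outside the inverted segment; order-reversing reflection inside
#' it. The map is an involution: applying it twice returns the input.
#'
#' @param iso an `isoform_pair`.
#' @param pos integer vector of 0-based positions on either reference.
#' @return integer vector of 0-based positions on the other reference.
#' @export
map_position <- function(iso, pos) {
  stopifnot(inherits(iso, "isoform_pair"))
  n <- nchar(iso$normal$seq)
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= n)) stop("position out of range", call. = FALSE)
  inside <- pos >= iso$hr_start & pos < iso$hr_end
  out <- pos
  out[inside] <- iso$hr_start + (iso$hr_end - 1L - pos[inside])
  out
}

#' Rotate a genome so a region of interest is clear of the origin
#'
#' Convenience pre-rotation: re-linearises the circular genome so that the
#' midpoint of the complement of `[start, end)` becomes the new origin,
#' leaving `[start, end)` maximally far from it. Returns the rotated genome
#' and the applied offset (positions shift by `-k` mod length).
#'
#' @param genome a circular [circular_sequence()].
#' @param start,end 0-based half-open region to keep away from the origin
#'   (may wrap).
#' @return list with `genome` (rotated) and `offset` `k`.
#' @export
rotate_clear <- function(genome, start, end) {
  stopifnot(inherits(genome, "circular_sequence"))
  n <- nchar(genome$seq)
  gap_mid <- (end + ((start - end) %% n) %/% 2L) %% n
  list(genome = rotate(genome, as.integer(gap_mid)), offset = as.integer(gap_mid))
}

#' Write an isoform pair to FASTA plus a JSON sidecar
#'
#' Writes the inverted-type reference (record id suffixed `_inverted`) and a
#' JSON sidecar with arm coordinates on both references (1-based inclusive).
#'
#' @param iso an `isoform_pair`.
#' @param fasta_path,json_path output paths.
#' @param include_normal also write the normal-type record (default FALSE).
#' @return `fasta_path`, invisibly.
#' @export
write_isoform <- function(iso, fasta_path, json_path = NULL,
                          include_normal = FALSE) {
  stopifnot(inherits(iso, "isoform_pair"))
  seqs <- if (include_normal) list(iso$normal, iso$inverted) else list(iso$inverted)
  write_fasta(seqs, fasta_path)
  if (!is.null(json_path)) {
    p <- iso$pair
    n <- nchar(iso$normal$seq)
    # arm coordinates on the inverted reference via the coordinate map
    inv_a1 <- sort(map_position(iso, c(p$arm2$start, p$arm2$end - 1L)))
    inv_a2 <- sort(map_position(iso, c(p$arm1$start, p$arm1$end - 1L)))
    side <- list(
      normal = list(id = iso$normal$id,
                    arm1 = c(p$arm1$start + 1L, p$arm1$end),
                    arm2 = c(p$arm2$start + 1L, p$arm2$end),
                    hr = c(iso$hr_start + 1L, iso$hr_end)),
      inverted = list(id = iso$inverted$id,
                      arm1 = c(inv_a1[1] + 1L, inv_a1[2] + 1L),
                      arm2 = c(inv_a2[1] + 1L, inv_a2[2] + 1L),
                      hr = c(iso$hr_start + 1L, iso$hr_end)),
      length = n, identity = p$identity, match_class = p$match_class)
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(fasta_path)
}
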