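## Classification of discordant / soft-clipped read pairs against the two
## isoform references (Patterns I-VIII) and estimation of the minor-isoform
## frequency as supporting pairs per mean depth over the recombination region.

#' Detection parameters
#'
#' Tunable thresholds of the heteroplasmy detector.
#'
#' @param span_tolerance_bp allowed deviation of the observed pair span on the
#'   normal reference from the spanned-region width (default 1000 bp; the
#'   expected insert of an inversion-supporting pair is the ~22 kb region
#'   itself, and the tolerance absorbs insert-size variance).
#' @param vicinity_bp window beyond each arm defining "in the vicinity of" an
#'   arm for the no-direct-overlap (Pattern V) rule (default 1000 bp).
#' @param inverted_max_span_bp maximum mate span on the inverted reference,
#'   strict less-than (default 500 bp).
#' @param min_clip_bp minimum soft-clip length considered for remapping
#'   (default 20 bp).
#' @param clip_min_identity minimum identity of a remapped clip (default 0.9),
#'   required over at least 90% of the clip.
#' @param variant_tolerance maximum mismatches+indels for the "minor
#'   variation" class (default 3); pairs above it are excluded with a reason.
#' @param clip_junction_slop_bp how far outside an arm a clip junction may
#'   fall and still count as an arm-boundary clip (default 30 bp).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(span_tolerance_bp = 1000L, vicinity_bp = 1000L,
                             inverted_max_span_bp = 500L, min_clip_bp = 20L,
                             clip_min_identity = 0.9, variant_tolerance = 3L,
                             clip_junction_slop_bp = 30L) {
  stopifnot(inverted_max_span_bp > 0L, min_clip_bp >= 10L)
  structure(list(span_tolerance_bp = as.integer(span_tolerance_bp),
                 vicinity_bp = as.integer(vicinity_bp),
                 inverted_max_span_bp = as.integer(inverted_max_span_bp),
                 min_clip_bp = as.integer(min_clip_bp),
                 clip_min_identity = clip_min_identity,
                 variant_tolerance = as.integer(variant_tolerance),
                 clip_junction_slop_bp = as.integer(clip_junction_slop_bp)),
            class = "detection_params")
}

## interval helpers on plain integers (0-based half-open)
.overlaps <- function(s, e, ts, te) s < te & e > ts

## read-vs-region relation: "inside" (wholly within hr), "outside" (disjoint),
## "straddle" (crosses an hr boundary)
.rel_hr <- function(pos, end, hs, he) {
  ifelse(pos >= hs & end <= he, "inside",
         ifelse(end <= hs | pos >= he, "outside", "straddle"))
}

#' Candidate test for a discordant pair on the normal reference
#'
#' A pair is a candidate when its orientation is not proper FR and its outer
#' span deviates from the spanned-region width by at most
#' `span_tolerance_bp`, or when it carries a qualifying arm-boundary soft
#' clip (the clip path is exempt from the span requirement).
#'
#' @param pair_row one row of [pair_alignments()]`$pairs`.
#' @param hr the spanned (HR) region as an [interval()].
#' @param params [detection_params()].
#' @param has_qualifying_clip logical; whether an arm-boundary clip of at
#'   least `min_clip_bp` was found (see [detect()] for the full pipeline).
#' @return logical.
#' @export
is_discordant_candidate <- function(pair_row, hr, params = detection_params(),
                                    has_qualifying_clip = FALSE) {
  span_ok <- abs(pair_row$span - interval_span(hr)) <= params$span_tolerance_bp
  (pair_row$orientation != "FR" & span_ok) | has_qualifying_clip
}

#' Arm-overlap rule for a candidate pair
#'
#' `arm_overlap` when either mate's aligned span intersects an arm;
#' otherwise `interior_exterior` when one mate lies wholly inside the spanned
#' region and the other wholly outside but within `vicinity_bp` of an arm;
#' otherwise `fail`.
#'
#' @param pair_row one row of [pair_alignments()]`$pairs`.
#' @param arms a `sir_pair` (arm coordinates on the normal reference).
#' @param hr the spanned region as an [interval()].
#' @param params [detection_params()].
#' @return one of `"arm_overlap"`, `"interior_exterior"`, `"fail"`.
#' @export
sir_overlap_rule <- function(pair_row, arms, hr, params = detection_params()) {
  a1 <- arms$arm1; a2 <- arms$arm2
  ov <- function(pos, end)
    .overlaps(pos, end, a1$start, a1$end) | .overlaps(pos, end, a2$start, a2$end)
  if (ov(pair_row$pos1, pair_row$end1) || ov(pair_row$pos2, pair_row$end2))
    return("arm_overlap")
  rel1 <- .rel_hr(pair_row$pos1, pair_row$end1, hr$start, hr$end)
  rel2 <- .rel_hr(pair_row$pos2, pair_row$end2, hr$start, hr$end)
  near <- function(pos, end) {
    (end <= hr$start & end >= a1$start - params$vicinity_bp) |
      (pos >= hr$end & pos <= a2$end + params$vicinity_bp)
  }
  if (rel1 == "inside" && rel2 == "outside" && near(pair_row$pos2, pair_row$end2))
    return("interior_exterior")
  if (rel2 == "inside" && rel1 == "outside" && near(pair_row$pos1, pair_row$end1))
    return("interior_exterior")
  "fail"
}

#' Remap a soft-clipped fragment to the window around the opposite arm
#'
#' Local alignment (match +1, mismatch -1, gap -2) of the clip (and its
#' reverse complement) within the target window; reported only when the
#' aligned part covers at least 90% of the clip at identity
#' `>= clip_min_identity`.
#'
#' @param clip_seq the clipped fragment (reference-orientation, as stored in
#'   the SAM record).
#' @param target_window nucleotide string around the opposite arm.
#' @param params [detection_params()].
#' @return list with `identity`, `offset` (0-based within the window) and
#'   `orientation` (`+`/`-`), or `NULL` when no acceptable hit exists.
#' @export
remap_softclip <- function(clip_seq, target_window, params = detection_params()) {
  if (nchar(clip_seq) < params$min_clip_bp) return(NULL)
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  best <- NULL
  for (ori in c("+", "-")) {
    qs <- if (ori == "+") clip_seq else reverse_complement(clip_seq)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qs), Biostrings::DNAString(target_window),
      type = "local", substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::pattern(al)))
    if (cols == 0L) next
    covered <- Biostrings::width(Biostrings::pattern(al))  # clip bases aligned
    identity <- Biostrings::nmatch(al) / cols
    if (covered >= 0.9 * nchar(clip_seq) && identity >= params$clip_min_identity) {
      hit <- list(identity = identity,
                  offset = Biostrings::start(Biostrings::subject(al)) - 1L,
                  orientation = ori)
      if (is.null(best) || hit$identity > best$identity) best <- hit
    }
  }
  best
}

#' Mate-span check on the inverted reference
#'
#' A supporting pair must align to the inverted-type reference in proper FR
#' orientation with an outer mate span strictly below
#' `inverted_max_span_bp`.
#'
#' @param pair_row one row of [pair_alignments()]`$pairs` computed on the
#'   inverted reference, or `NULL` when a mate is unmapped there.
#' @param params [detection_params()].
#' @return logical.
#' @export
verify_on_inverted <- function(pair_row, params = detection_params()) {
  if (is.null(pair_row) || nrow(pair_row) == 0L) return(FALSE)
  pair_row$orientation == "FR" & pair_row$span < params$inverted_max_span_bp
}

## clip-side inspection for one read of a pair: returns NULL or a list
## describing the best qualifying arm-boundary clip
.qualifying_clip <- function(pos, end, clipL, clipR, seq, arms, params) {
  slop <- params$clip_junction_slop_bp
  in_arm <- function(x, a) x >= a$start - slop & x <= a$end + slop
  out <- NULL
  consider <- function(len, junction, side) {
    if (len < params$min_clip_bp) return(NULL)
    arm <- if (in_arm(junction, arms$arm1)) "arm1"
           else if (in_arm(junction, arms$arm2)) "arm2" else return(NULL)
    sq <- if (side == "L") substr(seq, 1L, len)
          else substr(seq, nchar(seq) - len + 1L, nchar(seq))
    list(len = len, junction = junction, arm = arm, clip_seq = sq)
  }
  cl <- consider(clipL, pos, "L")
  cr <- consider(clipR, end, "R")
  if (!is.null(cl) && (is.null(cr) || cl$len >= cr$len)) out <- cl
  else if (!is.null(cr)) out <- cr
  out
}

#' Classify candidate read pairs into Patterns I-VIII
#'
#' Runs the full classification over externally supplied or internally
#' produced alignments: candidate test (discordant orientation with a span
#' near the spanned-region width, or an arm-boundary soft clip), the
#' arm-overlap rule, soft-clip remapping to the opposite arm's flank,
#' verification of proper short-span alignment on the inverted reference,
#' and pattern assignment. Fully aligned pairs give Patterns I-V (V when
#' neither mate touches an arm); soft-clipped pairs give Patterns VI-VIII.
#' Pairs with 1 to `variant_tolerance` mismatches+indels are flagged
#' `minor_variant`; noisier pairs are excluded with a reason, never silently
#' dropped.
#'
#' @param normal_aln alignments on the normal reference: a `read_alignments`
#'   data.frame or a SAM path.
#' @param inverted_aln alignments of (at least) the candidate read pairs on
#'   the inverted reference: a `read_alignments` data.frame, a SAM path, or
#'   `NULL` to map candidates on the fly with the internal mapper.
#' @param iso the [build_inverted_isoform()] result tying the two references
#'   together.
#' @param params [detection_params()].
#' @param map_args arguments passed to [lightweight_map()] when
#'   `inverted_aln` is `NULL`.
#' @return list of class `heteroplasmy_evidence`: `evidence` (one row per
#'   supporting pair: read_id, pattern, variation, 1-based mate positions on
#'   the normal reference, inverted-reference span, clip length/identity) and
#'   `excluded` (read_id, reason) for candidates that failed a later test.
#' @export
detect <- function(normal_aln, inverted_aln = NULL, iso,
                   params = detection_params(), map_args = list()) {
  stopifnot(inherits(iso, "isoform_pair"))
  if (is.character(normal_aln)) normal_aln <- read_sam(normal_aln)
  if (is.character(inverted_aln)) inverted_aln <- read_sam(inverted_aln)
  rid <- attr(normal_aln, "ref_id")
  if (!is.na(rid) && !is.null(rid) && rid != iso$normal$id)
    stop(sprintf("normal-reference SAM is for '%s', not '%s'", rid,
                 iso$normal$id), call. = FALSE)
  if (!is.null(inverted_aln)) {
    rid_i <- attr(inverted_aln, "ref_id")
    if (!is.na(rid_i) && !is.null(rid_i) && rid_i != iso$inverted$id)
      stop(sprintf("inverted-reference SAM is for '%s', not '%s'", rid_i,
                   iso$inverted$id), call. = FALSE)
  }
  arms <- iso$pair
  hr <- interval(iso$hr_start, iso$hr_end, length = nchar(iso$normal$seq))
  hr_span <- interval_span(hr)

  pp <- pair_alignments(normal_aln)
  pairs <- pp$pairs
  empty_ev <- data.frame(read_id = character(0), pattern = character(0),
                         variation = character(0), normal_pos1 = integer(0),
                         normal_pos2 = integer(0), inverted_span = integer(0),
                         clip_len = integer(0), clip_identity = numeric(0),
                         stringsAsFactors = FALSE)
  excluded <- data.frame(read_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  res <- structure(list(evidence = empty_ev, excluded = excluded),
                   class = "heteroplasmy_evidence")
  if (nrow(pairs) == 0L) return(res)

  ## fast pre-screen (vectorised): span/orientation path or a large clip
  span_ok <- abs(pairs$span - hr_span) <= params$span_tolerance_bp
  disc <- pairs$orientation != "FR" & span_ok
  big_clip <- pmax(pairs$clipL1, pairs$clipR1, pairs$clipL2, pairs$clipR2) >=
    params$min_clip_bp
  cand_idx <- which(disc | big_clip)
  if (length(cand_idx) == 0L) return(res)

  ## per-candidate clip qualification + remap
  vic <- params$vicinity_bp
  win_of <- function(arm) {
    a <- arms[[arm]]
    lo <- max(0L, a$start - vic); hi <- min(nchar(iso$normal$seq), a$end + vic)
    substr(iso$normal$seq, lo + 1L, hi)
  }
  win1 <- win_of("arm1"); win2 <- win_of("arm2")

  cand <- pairs[cand_idx, , drop = FALSE]
  clip_info <- vector("list", nrow(cand))
  clip_fail <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    q1 <- .qualifying_clip(cand$pos1[i], cand$end1[i], cand$clipL1[i],
                           cand$clipR1[i], cand$seq1[i], arms, params)
    q2 <- .qualifying_clip(cand$pos2[i], cand$end2[i], cand$clipL2[i],
                           cand$clipR2[i], cand$seq2[i], arms, params)
    q <- if (!is.null(q1) && (is.null(q2) || q1$len >= q2$len)) {
      q1$mate <- 1L; q1
    } else if (!is.null(q2)) { q2$mate <- 2L; q2 } else NULL
    if (is.null(q)) next
    opp <- if (q$arm == "arm1") win2 else win1
    hit <- remap_softclip(q$clip_seq, opp, params)
    if (is.null(hit)) { clip_fail[i] <- TRUE; next }
    q$identity <- hit$identity
    clip_info[[i]] <- q
  }
  has_clip <- !vapply(clip_info, is.null, logical(1))

  ## overlap rule for the fully-aligned path
  ov_rule <- character(nrow(cand))
  for (i in seq_len(nrow(cand)))
    ov_rule[i] <- sir_overlap_rule(cand[i, ], arms, hr, params)
  full_ok <- disc[cand_idx] & ov_rule != "fail"

  keep <- has_clip | full_ok
  drop_reason <- rep(NA_character_, nrow(cand))
  drop_reason[!keep & clip_fail] <- "clip_remap_fail"
  drop_reason[!keep & !clip_fail & disc[cand_idx]] <- "overlap_rule_fail"
  drop_reason[!keep & is.na(drop_reason)] <- "not_candidate"
  ## pairs that only tripped the big-clip pre-screen and have no qualifying
  ## clip and no discordant geometry are not candidates at all: don't log
  log_these <- !keep & (disc[cand_idx] | clip_fail)
  excluded <- rbind(excluded,
                    data.frame(read_id = cand$qname[log_these],
                               reason = drop_reason[log_these],
                               stringsAsFactors = FALSE))
  cand <- cand[keep, , drop = FALSE]
  clip_info <- clip_info[keep]
  has_clip <- has_clip[keep]
  ov_rule <- ov_rule[keep]
  if (nrow(cand) == 0L) { res$excluded <- excluded; return(res) }

  ## inverted-reference verification
  if (is.null(inverted_aln)) {
    orig1 <- ifelse(cand$strand1 == "-", revcomp_vec(cand$seq1), cand$seq1)
    orig2 <- ifelse(cand$strand2 == "-", revcomp_vec(cand$seq2), cand$seq2)
    inverted_aln <- do.call(lightweight_map,
                            c(list(r1 = orig1, r2 = orig2, ref = iso$inverted,
                                   ids = cand$qname), map_args))
  }
  ip <- pair_alignments(inverted_aln)$pairs
  im <- match(cand$qname, ip$qname)
  inv_ok <- !is.na(im) &
    ip$orientation[pmax(im, 1L)] == "FR" &
    ip$span[pmax(im, 1L)] < params$inverted_max_span_bp
  inv_ok[is.na(im)] <- FALSE
  excluded <- rbind(excluded,
                    data.frame(read_id = cand$qname[is.na(im)],
                               reason = rep("inverted_unmapped", sum(is.na(im))),
                               stringsAsFactors = FALSE),
                    data.frame(read_id = cand$qname[!is.na(im) & !inv_ok],
                               reason = rep("inverted_span_fail",
                                            sum(!is.na(im) & !inv_ok)),
                               stringsAsFactors = FALSE))
  cand$inv_span <- ifelse(is.na(im), NA_integer_, ip$span[pmax(im, 1L)])
  cand <- cand[inv_ok, , drop = FALSE]
  clip_info <- clip_info[inv_ok]
  has_clip <- has_clip[inv_ok]
  ov_rule <- ov_rule[inv_ok]
  if (nrow(cand) == 0L) { res$excluded <- excluded; return(res) }

  ## variation class
  nm_tot <- cand$nm1 + cand$nm2 + cand$indels1 + cand$indels2
  too_var <- nm_tot > params$variant_tolerance
  excluded <- rbind(excluded,
                    data.frame(read_id = cand$qname[too_var],
                               reason = rep("excessive_variation", sum(too_var)),
                               stringsAsFactors = FALSE))
  cand <- cand[!too_var, , drop = FALSE]
  clip_info <- clip_info[!too_var]
  has_clip <- has_clip[!too_var]
  ov_rule <- ov_rule[!too_var]
  nm_tot <- nm_tot[!too_var]
  if (nrow(cand) == 0L) { res$excluded <- excluded; return(res) }

  ## pattern assignment
  pattern <- character(nrow(cand))
  clip_len <- rep(NA_integer_, nrow(cand))
  clip_id <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pattern[i] <- assign_pattern(cand[i, ], clip_info[[i]], arms, hr)
    if (has_clip[i]) {
      clip_len[i] <- clip_info[[i]]$len
      clip_id[i] <- clip_info[[i]]$identity
    }
  }

  res$evidence <- data.frame(
    read_id = cand$qname, pattern = pattern,
    variation = ifelse(nm_tot == 0L, "exact", "minor_variant"),
    normal_pos1 = cand$pos1 + 1L, normal_pos2 = cand$pos2 + 1L,
    inverted_span = cand$inv_span, clip_len = clip_len,
    clip_identity = clip_id, stringsAsFactors = FALSE)
  res$excluded <- excluded
  res
}

#' Assign the Pattern (I-VIII) of one supporting pair
#'
#' Operational taxonomy: fully aligned pairs give I (a mate overlaps arm1,
#' the other outside the spanned region), II (arm2, mate outside), III
#' (arm1, mate not outside), IV (arm2, mate not outside), V (no arm overlap,
#' interior/exterior geometry); soft-clipped pairs give VI (clip at arm1,
#' mate outside), VII (clip at arm2, mate outside), VIII (clip at an arm,
#' mate inside the spanned region).
#'
#' @param pair_row one row of [pair_alignments()]`$pairs` on the normal
#'   reference.
#' @param clip `NULL` for the fully-aligned path, else the qualifying-clip
#'   descriptor (fields `arm`, `mate`).
#' @param arms a `sir_pair`; `hr` the spanned region [interval()].
#' @param hr spanned-region interval.
#' @return the pattern label, one of `"I"`..`"VIII"` (roman numerals).
#' @export
assign_pattern <- function(pair_row, clip = NULL, arms, hr) {
  rel1 <- .rel_hr(pair_row$pos1, pair_row$end1, hr$start, hr$end)
  rel2 <- .rel_hr(pair_row$pos2, pair_row$end2, hr$start, hr$end)
  if (!is.null(clip)) {
    mate_rel <- if (clip$mate == 1L) rel2 else rel1
    if (mate_rel == "outside") {
      if (clip$arm == "arm1") return("VI") else return("VII")
    }
    return("VIII")
  }
  ov <- function(pos, end, a) .overlaps(pos, end, a$start, a$end)
  ov1 <- ov(pair_row$pos1, pair_row$end1, arms$arm1) |
    ov(pair_row$pos2, pair_row$end2, arms$arm1)
  ov2 <- ov(pair_row$pos1, pair_row$end1, arms$arm2) |
    ov(pair_row$pos2, pair_row$end2, arms$arm2)
  if (ov1) {
    this1 <- ov(pair_row$pos1, pair_row$end1, arms$arm1)
    mate_rel <- if (this1) rel2 else rel1
    return(if (mate_rel == "outside") "I" else "III")
  }
  if (ov2) {
    this1 <- ov(pair_row$pos1, pair_row$end1, arms$arm2)
    mate_rel <- if (this1) rel2 else rel1
    return(if (mate_rel == "outside") "II" else "IV")
  }
  "V"
}

#' Summarise supporting evidence into the per-sample frequency estimate
#'
#' The minor-isoform frequency is estimated as the number of supporting read
#' pairs divided by the mean depth over the spanned (HR) region, expressed as
#' a percentage. One pair counts one unit of support.
#'
#' @param evidence the `evidence` data.frame from [detect()] (or a
#'   `heteroplasmy_evidence` object).
#' @param mean_depth_hr mean read depth over the spanned region (see
#'   [mean_depth()]).
#' @return list of class `evidence_summary`: `per_pattern_counts` (named
#'   I-VIII), `total_pairs`, `mean_depth_hr`, `frequency_pct`.
#' @export
estimate_frequency <- function(evidence, mean_depth_hr) {
  if (inherits(evidence, "heteroplasmy_evidence")) evidence <- evidence$evidence
  patterns <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  counts <- setNames(integer(8L), patterns)
  if (nrow(evidence) > 0L) {
    tab <- table(factor(evidence$pattern, levels = patterns))
    counts[] <- as.integer(tab)
  }
  total <- sum(counts)
  if (total > 0L && mean_depth_hr <= 0)
    stop("nonzero evidence with zero mean depth", call. = FALSE)
  freq <- if (total == 0L) {
    if (mean_depth_hr <= 0)
      warning("zero depth and zero evidence: frequency reported as 0")
    0
  } else 100 * total / mean_depth_hr
  structure(list(per_pattern_counts = counts, total_pairs = total,
                 mean_depth_hr = mean_depth_hr, frequency_pct = freq),
            class = "evidence_summary")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat("<evidence_summary>\n")
  cat("  pattern counts:",
      paste(names(x$per_pattern_counts), x$per_pattern_counts,
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  total supporting pairs: %d\n", x$total_pairs))
  cat(sprintf("  mean depth over HR region: %.2f\n", x$mean_depth_hr))
  cat(sprintf("  estimated minor-isoform frequency: %.2f%%\n", x$frequency_pct))
  invisible(x)
}
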