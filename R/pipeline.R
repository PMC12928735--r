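## End-to-end pipeline: repeat discovery -> isoform construction ->
## (mapping) -> pair classification -> frequency estimate, with
## machine-readable outputs and a run manifest.

.file_digest <- function(path) {
  if (is.null(path) || !is.character(path) || !file.exists(path)) return(NA_character_)
  sprintf("size:%d", file.info(path)$size)
}

#' Run the full heteroplasmy-detection pipeline
#'
#' Discovers sIR pairs in the reference, builds the inverted-type isoform for
#' the selected pair, obtains alignments against both references (either
#' externally supplied SAM files or the internal mapper on a FASTQ pair),
#' classifies discordant and soft-clipped read pairs, and estimates the
#' minor-isoform frequency. When no sIR pair qualifies the run completes
#' cleanly with an empty evidence set.
#'
#' @param ref the normal-type reference: a FASTA path or a
#'   [circular_sequence()].
#' @param r1,r2 FASTQ paths (or read-sequence character vectors) for the
#'   internal-mapper path; ignored when SAM files are given.
#' @param normal_sam,inverted_sam optional SAM paths from an external
#'   aligner (the production path).
#' @param out_dir output directory (created if missing); set `NULL` to skip
#'   writing files.
#' @param params [detection_params()].
#' @param pair_index which discovered pair to analyse (0 = best, default).
#' @param discovery_args arguments for [find_inverted_repeat_pairs()].
#' @param map_args arguments for [lightweight_map()].
#' @return list of class `pipeline_result`: `pairs`, `iso`, `evidence`
#'   (a `heteroplasmy_evidence`), `summary` (an `evidence_summary`), plus
#'   the paths written.
#' @export
run_pipeline <- function(ref, r1 = NULL, r2 = NULL, normal_sam = NULL,
                         inverted_sam = NULL, out_dir = NULL,
                         params = detection_params(), pair_index = 0L,
                         discovery_args = list(), map_args = list()) {
  t0 <- Sys.time()
  if (is.character(ref)) ref <- read_fasta(ref)[[1L]]
  stopifnot(inherits(ref, "circular_sequence"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  pth <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)

  if (is.null(discovery_args$max_span_bp))
    discovery_args$max_span_bp <- min(60000L, nchar(ref$seq))
  pairs <- do.call(find_inverted_repeat_pairs, c(list(ref), discovery_args))
  if (!is.null(out_dir)) write_pairs_tsv(pairs, pth("sir_pairs.tsv"))

  if (length(pairs) == 0L) {
    summary <- suppressWarnings(estimate_frequency(
      data.frame(pattern = character(0), stringsAsFactors = FALSE), 0))
    res <- structure(list(pairs = pairs, iso = NULL,
                          evidence = NULL, summary = summary,
                          status = "no_candidate_pair"),
                     class = "pipeline_result")
    if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir, params, t0)
    return(res)
  }
  if (pair_index + 1L > length(pairs))
    stop("pair_index beyond the number of discovered pairs", call. = FALSE)
  pair <- pairs[[pair_index + 1L]]
  iso <- build_inverted_isoform(ref, pair)
  if (!is.null(out_dir))
    write_isoform(iso, pth("inverted.fasta"), pth("isoform.json"))

  if (!is.null(normal_sam)) {
    aln_n <- if (is.character(normal_sam)) read_sam(normal_sam) else normal_sam
    aln_i <- if (is.character(inverted_sam)) read_sam(inverted_sam) else inverted_sam
  } else {
    if (is.null(r1) || is.null(r2))
      stop("provide either SAM files or a FASTQ read pair", call. = FALSE)
    if (is.character(r1) && length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
    if (is.character(r2) && length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
    aln_n <- do.call(lightweight_map, c(list(r1 = r1, r2 = r2, ref = ref), map_args))
    aln_i <- NULL  # detect() maps the candidate subset lazily
  }

  ev <- detect(aln_n, aln_i, iso, params, map_args = map_args)
  hr <- interval(iso$hr_start, iso$hr_end, length = nchar(ref$seq))
  depth <- mean_depth(aln_n, hr)
  summary <- estimate_frequency(ev, depth)

  res <- structure(list(pairs = pairs, iso = iso, evidence = ev,
                        summary = summary, status = "ok"),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir, params, t0)
  res
}

.write_pipeline_outputs <- function(res, out_dir, params, t0) {
  pth <- function(f) file.path(out_dir, f)
  if (!is.null(res$evidence)) {
    write.table(res$evidence$evidence, pth("evidence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$evidence$excluded, pth("excluded.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  s <- res$summary
  jsonlite::write_json(
    list(schema = "sirhet_summary_v1",
         status = res$status,
         per_pattern_counts = as.list(s$per_pattern_counts),
         total_pairs = s$total_pairs,
         mean_depth_hr = s$mean_depth_hr,
         frequency_pct = s$frequency_pct),
    pth("summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(tool = "sirhet",
         version = as.character(utils::packageVersion("sirhet")),
         parameters = unclass(params),
         started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    pth("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> status: %s; %d sIR pair(s) found\n",
              x$status, length(x$pairs)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
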