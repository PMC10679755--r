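# Read filtering and on-target depth summaries.
#
# Two filters reflect the adaptive-sampling workflow: reads must have a
# mean quality score above a threshold (default Q10, strict), and only
# reads positively selected by the adaptive-sampling software are kept,
# since rejected strands leave short fragments that often do not map
# uniquely.

#' Filter a read summary table
#'
#' @param records data.frame with columns read_id, length, quality and
#'   (when `accepted_only`) decision in {accepted, rejected, no_decision}.
#' @param min_quality quality threshold, default 10.
#' @param accepted_only keep only adaptive-sampling-accepted reads.
#'   Default TRUE.
#' @param inclusive when TRUE the quality filter keeps reads at exactly
#'   `min_quality` (>=); default FALSE (strictly above, "quality score
#'   above 10").
#' @return list with `reads` (retained rows) and `counts` (input,
#'   removed_quality, removed_decision, retained).
#' @export
filter_reads <- function(records, min_quality = 10, accepted_only = TRUE,
                         inclusive = FALSE) {
  stopifnot(all(c("read_id", "length", "quality") %in% names(records)))
  if (accepted_only && !"decision" %in% names(records))
    stop_no_call("accepted_only requires a 'decision' column")
  q_ok <- if (inclusive) records$quality >= min_quality
          else records$quality > min_quality
  d_ok <- if (accepted_only) records$decision == "accepted" else TRUE
  keep <- q_ok & d_ok
  list(reads = records[keep, , drop = FALSE],
       counts = list(input = nrow(records),
                     removed_quality = sum(!q_ok),
                     removed_decision = if (accepted_only) sum(q_ok & !d_ok) else 0L,
                     retained = sum(keep)))
}

#' On-target depth statistics
#'
#' Statistics are computed over the targeted bases only. Panel bases absent
#' from the depth track count as depth 0 and stay in every denominator.
#'
#' @param track depth track data.frame: chrom, start, end (0-based
#'   half-open, non-overlapping), depth.
#' @param panel a `pgx_panel` or region data.frame (chrom, start, end).
#' @param thresholds depth thresholds for the "fraction of targeted bases at
#'   X" rows, default c(15, 20, 30).
#' @return object of class `coverage_report`: mean_depth (depth-weighted
#'   over targeted bases), `fraction_at` (named vector, fraction of targeted
#'   bases with depth >= threshold) and `target_bases`.
#' @export
depth_stats <- function(track, panel, thresholds = c(15, 20, 30)) {
  regions <- if (inherits(panel, "pgx_panel")) panel$regions else panel
  if (nrow(regions) == 0) stop_no_call("empty panel")
  pan <- GenomicRanges::reduce(regions_to_granges(regions), min.gapwidth = 1L)
  target_bases <- sum(as.numeric(GenomicRanges::width(pan)))
  if (nrow(track) > 0) {
    tr <- regions_to_granges(track)
    hits <- GenomicRanges::findOverlaps(tr, pan)
    ov <- GenomicRanges::pintersect(
      tr[S4Vectors::queryHits(hits)], pan[S4Vectors::subjectHits(hits)])
    w <- as.numeric(GenomicRanges::width(ov))
    d <- track$depth[S4Vectors::queryHits(hits)]
  } else {
    w <- numeric(0); d <- numeric(0)
  }
  mean_depth <- sum(d * w) / target_bases
  fraction_at <- vapply(sort(thresholds), function(th)
    sum(w[d >= th]) / target_bases, numeric(1))
  names(fraction_at) <- paste0(sort(thresholds), "X")
  structure(list(mean_depth = mean_depth, fraction_at = fraction_at,
                 target_bases = target_bases, thresholds = sort(thresholds)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Average depth on-target: %.1fX over %s bases\n",
              x$mean_depth, format(x$target_bases, big.mark = ",")))
  for (nm in rev(names(x$fraction_at)))
    cat(sprintf("  %% at %s: %.1f\n", nm, 100 * x$fraction_at[nm]))
  invisible(x)
}

#' Read a sequencing read-summary table
#'
#' Accepts the sequencing-summary dialect (read_id,
#' sequence_length_template, mean_qscore_template, end_reason) and maps the
#' end reason onto an adaptive-sampling decision: signal_positive ->
#' accepted; unblock (strand ejected) -> rejected; anything else ->
#' no_decision. Tables already carrying read_id/length/quality/decision
#' columns pass through unchanged.
#'
#' @param path TSV path.
#' @return data.frame with read_id, length, quality, decision.
#' @export
read_read_summary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("read_id", "length", "quality", "decision") %in% names(d)))
    return(d[, c("read_id", "length", "quality", "decision")])
  req <- c("read_id", "sequence_length_template", "mean_qscore_template")
  stopifnot(all(req %in% names(d)))
  decision <- if ("end_reason" %in% names(d)) {
    ifelse(d$end_reason == "signal_positive", "accepted",
           ifelse(grepl("unblock", d$end_reason), "rejected", "no_decision"))
  } else rep("no_decision", nrow(d))
  data.frame(read_id = d$read_id, length = d$sequence_length_template,
             quality = d$mean_qscore_template, decision = decision,
             stringsAsFactors = FALSE)
}

#' Read a bedGraph depth track
#' @param path bedGraph file (chrom, start, end, depth; 0-based half-open).
#' @return data.frame with chrom, start, end, depth.
#' @export
read_depth_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_regions(gr)
  out$depth <- as.numeric(S4Vectors::mcols(gr)$score)
  out
}

#' Write a depth track as bedGraph
#' @param track data.frame with chrom, start, end, depth.
#' @param path output path.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a coverage report as TSV
#' @param report a `coverage_report`.
#' @param path output path.
#' @export
write_coverage_report <- function(report, path) {
  d <- data.frame(
    statistic = c("mean_depth_on_target",
                  paste0("pct_at_", names(report$fraction_at))),
    value = c(round_half_up(report$mean_depth, 2),
              as_pct(report$fraction_at)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
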