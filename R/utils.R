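# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; benchmarking tables in the PGx
#' literature round half up. A small epsilon guards against values such as
#' 0.995 being stored as 0.99499999....
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

#' Format a fraction as a percentage rounded half-up to two decimals
#' @param x fraction in \[0,1\] (NA allowed).
#' @return numeric percentage (e.g. 99.59), NA preserved.
#' @keywords internal
as_pct <- function(x) {
  ifelse(is.na(x), NA_real_, round_half_up(100 * x, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 0-based half-open region data frame to GRanges
#' @param regions data.frame with columns chrom, start, end (0-based half-open).
#' @return a `GenomicRanges::GRanges` (1-based closed, as usual in Bioconductor).
#' @keywords internal
regions_to_granges <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Convert GRanges back to a 0-based half-open region data frame
#' @param gr a GRanges object.
#' @return data.frame with chrom, start, end (0-based half-open).
#' @keywords internal
granges_to_regions <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Test 1-based positions for membership in 0-based half-open regions
#' @keywords internal
pos_in_regions <- function(chrom, pos, regions) {
  if (length(chrom) == 0L) return(logical(0))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  reg <- regions_to_granges(regions)
  IRanges::overlapsAny(gr, reg)
}

stop_no_call <- function(...) stop(..., call. = FALSE)
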