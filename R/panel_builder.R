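# Target-panel construction for adaptive-sampling enrichment.
#
# Clinically annotated PGx variants are mapped onto gene bodies: a variant
# inside a gene pulls in the whole gene; a variant within a distance
# threshold (default 100 kb) of a gene boundary pulls in the span from the
# gene through the variant; anything further away is discarded. Each raw
# target region is then padded (default 20 kb) so that long DNA molecules
# whose leading bases fall outside the target still cover it, and
# overlapping or bookended regions are collapsed.
#
# All panel coordinates are 0-based half-open (BED convention); 1-based
# variant positions are converted at the parser boundary.

#' Panel construction parameters
#'
#' @param max_dist maximum distance (bases) from the nearer gene boundary at
#'   which an extragenic variant is still attached to its gene; inclusive at
#'   exactly `max_dist`. Default 100,000.
#' @param flank padding (bases) added to both sides of every raw target
#'   region before merging, so that long molecules entering the target from
#'   outside are still accepted. Default 20,000.
#' @param fraction_window recommended on-target fraction of the genome for
#'   adaptive sampling, as a `(low, high)` pair. Default `c(0.01, 0.10)`.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(max_dist = 100000L, flank = 20000L,
                         fraction_window = c(0.01, 0.10)) {
  stopifnot(max_dist >= 0, flank >= 0, length(fraction_window) == 2,
            fraction_window[1] <= fraction_window[2])
  structure(list(max_dist = as.integer(max_dist), flank = as.integer(flank),
                 fraction_window = as.numeric(fraction_window)),
            class = "panel_config")
}

#' Assign clinically annotated variants to gene targets
#'
#' Applies the targeting rules: a variant within the gene body (exon or
#' intron) selects the entire gene; a variant within `config$max_dist` of the
#' nearer gene boundary selects the span from the gene through the variant
#' (the gene body is always included); a variant further away is discarded.
#' Records with unknown gene symbols or malformed coordinates are rejected
#' individually, never aborting the batch.
#'
#' @param annotations data.frame with columns `variant_id`, `gene`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param genes data.frame with columns `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`.
#' @param config a [panel_config()].
#' @return data.frame with one row per annotation: the input columns plus
#'   `class` (`SNV`/`INDEL`), `status` (one of `intragenic`, `flanking`,
#'   `discarded_distance`, `unmapped_gene`, `rejected`), `region_start`,
#'   `region_end` (0-based half-open raw target region, NA when no region)
#'   and `reason` (non-NA only for rejected records).
#' @export
assign_variant_targets <- function(annotations, genes, config = panel_config()) {
  req <- c("variant_id", "gene", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(annotations)))
    stop_no_call("annotations must have columns: ", paste(req, collapse = ", "))
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$symbol))
    stop_no_call("duplicate gene symbols in gene table")

  gidx <- match(annotations$gene, genes$symbol)
  n <- nrow(annotations)
  out <- annotations
  out$class <- variant_class(annotations$ref, annotations$alt)
  out$status <- rep(NA_character_, n)
  out$region_start <- rep(NA_integer_, n)
  out$region_end <- rep(NA_integer_, n)
  out$reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    pos <- suppressWarnings(as.numeric(annotations$pos[i]))
    if (is.na(pos) || pos < 1 || pos != floor(pos)) {
      out$status[i] <- "rejected"
      out$reason[i] <- sprintf("malformed position '%s'", annotations$pos[i])
      next
    }
    gi <- gidx[i]
    if (is.na(gi)) {
      out$status[i] <- "unmapped_gene"
      next
    }
    if (as.character(annotations$chrom[i]) != as.character(genes$chrom[gi])) {
      out$status[i] <- "rejected"
      out$reason[i] <- sprintf("variant on %s but gene %s on %s",
                               annotations$chrom[i], genes$symbol[gi],
                               genes$chrom[gi])
      next
    }
    gs <- genes$start[gi]; ge <- genes$end[gi]
    p0 <- pos - 1  # 0-based base index
    if (p0 >= gs && p0 < ge) {
      out$status[i] <- "intragenic"
      out$region_start[i] <- gs
      out$region_end[i] <- ge
    } else if (p0 < gs) {
      dist <- gs - p0  # bases from 1-based gene start to variant
      if (dist <= config$max_dist) {
        out$status[i] <- "flanking"
        out$region_start[i] <- p0
        out$region_end[i] <- ge
      } else out$status[i] <- "discarded_distance"
    } else {
      dist <- pos - ge  # bases from 1-based gene end to variant
      if (dist <= config$max_dist) {
        out$status[i] <- "flanking"
        out$region_start[i] <- gs
        out$region_end[i] <- pos  # half-open end covers the variant base
      } else out$status[i] <- "discarded_distance"
    }
  }
  out
}

#' Build the merged adaptive-sampling panel
#'
#' Pads every raw target region by `config$flank` on both sides, clips to the
#' chromosome, and collapses overlapping or bookended regions into single
#' targets. Panel variants are all annotations that produced a region
#' (intragenic or flanking).
#'
#' @param assignments output of [assign_variant_targets()].
#' @param genome data.frame with columns `chrom`, `length`.
#' @param config a [panel_config()].
#' @return an object of class `pgx_panel`: a list with `regions` (data.frame
#'   `chrom`, `start`, `end`, `genes`; 0-based half-open, sorted,
#'   non-overlapping, non-adjacent), `variants` (the retained annotation
#'   rows) and `config`.
#' @export
build_panel <- function(assignments, genome, config = panel_config()) {
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  if (anyDuplicated(genome$chrom)) stop_no_call("duplicate chromosome names")
  if (any(genome$length <= 0)) stop_no_call("chromosome lengths must be > 0")

  keep <- assignments$status %in% c("intragenic", "flanking")
  raw <- assignments[keep, , drop = FALSE]
  unknown <- setdiff(unique(raw$chrom), genome$chrom)
  if (length(unknown) > 0)
    stop_no_call("target region on unknown chromosome: ",
                 paste(unknown, collapse = ", "))

  if (nrow(raw) == 0) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), genes = character(),
                          stringsAsFactors = FALSE)
  } else {
    chrlen <- genome$length[match(raw$chrom, genome$chrom)]
    ext_start <- pmax(0, raw$region_start - config$flank)
    ext_end <- pmin(chrlen, raw$region_end + config$flank)
    gr <- GenomicRanges::GRanges(
      as.character(raw$chrom),
      IRanges::IRanges(start = ext_start + 1, end = ext_end))
    S4Vectors::mcols(gr)$gene <- raw$gene
    merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)  # merges bookended
    hits <- GenomicRanges::findOverlaps(gr, merged)
    gene_lists <- vapply(seq_along(merged), function(j) {
      g <- sort(unique(S4Vectors::mcols(gr)$gene[
        S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == j]]))
      paste(g, collapse = ";")
    }, character(1))
    merged <- GenomicRanges::sort(merged)
    regions <- granges_to_regions(merged)
    regions$genes <- gene_lists
    ord <- order(regions$chrom, regions$start)
    regions <- regions[ord, , drop = FALSE]
    rownames(regions) <- NULL
  }
  structure(list(regions = regions, variants = raw, config = config,
                 genome = genome),
            class = "pgx_panel")
}

#' Fraction of the genome covered by a panel
#'
#' @param panel a `pgx_panel`.
#' @param genome data.frame with columns `chrom`, `length`; defaults to the
#'   genome the panel was built against.
#' @return list with `fraction` (merged target bases / total genome bases)
#'   and `in_window` (TRUE when the fraction lies inside the recommended
#'   adaptive-sampling window of the panel's config).
#' @export
genome_fraction <- function(panel, genome = panel$genome) {
  stopifnot(inherits(panel, "pgx_panel"))
  total <- sum(as.numeric(genome$length))
  if (!is.finite(total) || total <= 0) stop_no_call("empty genome")
  covered <- sum(as.numeric(panel$regions$end - panel$regions$start))
  frac <- covered / total
  win <- panel$config$fraction_window
  list(fraction = frac, in_window = frac >= win[1] && frac <= win[2])
}

#' @export
print.pgx_panel <- function(x, ...) {
  cat(sprintf("pgx_panel: %d merged target regions, %d panel variants, %d genes\n",
              nrow(x$regions), nrow(x$variants),
              length(unique(x$variants$gene))))
  cat(sprintf("  total target: %s bases (flank %d, max distance %d)\n",
              format(sum(as.numeric(x$regions$end - x$regions$start)),
                     big.mark = ","),
              x$config$flank, x$config$max_dist))
  invisible(x)
}

#' @export
summary.pgx_panel <- function(object, ...) {
  gf <- genome_fraction(object)
  cls <- table(object$variants$class)
  cat(sprintf(
    "Panel of %d variants (%d SNVs, %d INDELs) linked to %d genes\n",
    nrow(object$variants), cls["SNV"] %||% 0L,
    if ("INDEL" %in% names(cls)) cls[["INDEL"]] else 0L,
    length(unique(object$variants$gene))))
  cat(sprintf("%d merged regions targeting %.2f%% of the genome (%s the recommended window)\n",
              nrow(object$regions), 100 * gf$fraction,
              if (gf$in_window) "inside" else "outside"))
  invisible(object)
}

# ---- file plumbing ---------------------------------------------------------

#' Write panel regions as a BED file
#'
#' 0-based half-open, tab-separated, sorted by (chrom, start); column 4 holds
#' the semicolon-joined contributing gene symbols.
#' @param panel a `pgx_panel` or a region data.frame.
#' @param path output path.
#' @export
write_target_bed <- function(panel, path) {
  regions <- if (inherits(panel, "pgx_panel")) panel$regions else panel
  ord <- order(regions$chrom, regions$start)
  bed <- regions[ord, c("chrom", "start", "end"), drop = FALSE]
  bed$name <- if ("genes" %in% names(regions)) regions$genes[ord] else "."
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of target regions
#' @param path BED file path (0-based half-open).
#' @return data.frame with chrom, start, end and, when present, genes.
#' @export
read_target_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_regions(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$genes <- as.character(nm)
  out
}

#' Read a gene coordinate table
#' @param path TSV with header columns symbol, chrom, start, end, strand
#'   (start/end 0-based half-open).
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(g)))
  if (!"strand" %in% names(g)) g$strand <- "unknown"
  g
}

#' Read a clinical-annotation table
#'
#' The clinical-annotation dialect carries variant id, gene symbol and
#' evidence level but no genomic coordinates; positions come from a separate
#' coordinate table joined on variant id (see
#' [read_variant_coordinates()] and [join_annotation_coordinates()]).
#' @param path TSV with header columns variant_id, gene and optionally
#'   evidence_level.
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "gene") %in% names(a)))
  a
}

#' Read a variant coordinate table
#' @param path TSV with header columns variant_id, chrom, pos (1-based),
#'   ref, alt.
#' @export
read_variant_coordinates <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(v)))
  v
}

#' Join annotations with variant coordinates on variant id
#' @param annotations output of [read_annotation_table()].
#' @param coords output of [read_variant_coordinates()].
#' @return annotation data.frame with chrom/pos/ref/alt filled in; rows
#'   without coordinates are dropped with a warning.
#' @export
join_annotation_coordinates <- function(annotations, coords) {
  m <- match(annotations$variant_id, coords$variant_id)
  miss <- is.na(m)
  if (any(miss))
    warning(sum(miss), " annotation(s) without coordinates dropped")
  out <- annotations[!miss, , drop = FALSE]
  mm <- m[!miss]
  out$chrom <- coords$chrom[mm]
  out$pos <- coords$pos[mm]
  out$ref <- coords$ref[mm]
  out$alt <- coords$alt[mm]
  rownames(out) <- NULL
  out
}

#' Read a genome (chromosome length) table
#' @param path TSV with header columns chrom, length.
#' @export
read_genome_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(g)))
  g
}
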