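# VCF plumbing: callsets travel as plain data frames with one sample.
#
# A callset data.frame has columns chrom, pos (1-based), ref, alt, gt
# (e.g. "0|1", "0/1", "1|1"), ps (phase-set id or NA) and filter.

#' Read a single-sample VCF into a callset data frame
#'
#' Uses vcfR for parsing; extracts GT and, when present, the PS phase-set
#' tag for the first sample.
#'
#' @param path VCF file (plain or bgzipped).
#' @return callset data.frame with chrom, pos, ref, alt, gt, ps, filter.
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (is.null(n) || n == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), ps = character(),
                      filter = character(), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[, 1],
                 error = function(e) rep(NA_character_, n))
  if (is.null(ps)) ps <- rep(NA_character_, n)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, gt = unname(gt), ps = unname(ps),
             filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
             stringsAsFactors = FALSE)
}

#' Write a callset data frame as a VCF 4.2 file
#'
#' Emits a minimal single-sample VCF with GT and PS format fields; records
#' are sorted by (chrom, pos).
#'
#' @param callset callset data.frame (chrom, pos, ref, alt, gt; optional ps,
#'   filter).
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @param genome optional data.frame (chrom, length) for contig header lines.
#' @export
write_callset_vcf <- function(callset, path, sample = "SAMPLE", genome = NULL) {
  if (!"ps" %in% names(callset)) callset$ps <- NA_character_
  if (!"filter" %in% names(callset)) callset$filter <- "PASS"
  ord <- order(callset$chrom, callset$pos)
  cs <- callset[ord, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chrom, as.integer(genome$length)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sample))
  has_ps <- !is.na(cs$ps)
  fmt <- ifelse(has_ps, "GT:PS", "GT")
  smp <- ifelse(has_ps, paste(cs$gt, cs$ps, sep = ":"), cs$gt)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\t%s\t%s",
                  cs$chrom, as.integer(cs$pos), cs$ref, cs$alt,
                  ifelse(is.na(cs$filter), ".", cs$filter), fmt, smp)
  writeLines(c(hdr, body), path)
  invisible(path)
}
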