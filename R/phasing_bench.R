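# Per-gene haplotype-phasing concordance.
#
# Phase is only meaningful within a haplotype block (phase set), and the
# labelling of the two haplotypes within a block is arbitrary. A query
# block is therefore compared with the truth haplotypes under the better of
# its two orientations (identity or global flip), separately for each gene
# it intersects, and the per-gene phasing success rate is the fraction of
# the truth's phased heterozygous variants in the gene span recovered this
# way. Truth variants the query leaves unphased (or misses entirely) count
# against the rate: the reference considers them.

#' Extract phased heterozygous variants within a region
#'
#' In a phased genotype "a|b" the left allele belongs to haplotype 1; the
#' haplotype assignment records which haplotype carries the ALT allele.
#' Homozygous sites carry no phase information and are excluded; half-calls
#' and missing genotypes are skipped (their count is attached as the
#' `skipped` attribute).
#'
#' @param callset callset data.frame (chrom, pos, ref, alt, gt, ps).
#' @param region list or one-row data.frame with chrom, start, end (0-based
#'   half-open); NULL takes the whole callset.
#' @return data.frame with key, chrom, pos, gt, hap_alt (1 or 2),
#'   phase_set ("unphased" for unphased hets), ordered by position.
#' @export
extract_phased_het <- function(callset, region = NULL) {
  cs <- normalize_callset(callset)
  if (!is.null(region)) {
    keep <- cs$chrom == as.character(region$chrom) &
      cs$pos >= region$start + 1L & cs$pos <= region$end
    cs <- cs[keep, , drop = FALSE]
  }
  al <- strsplit(cs$gt, "[/|]")
  n_al <- lengths(al)
  half <- n_al != 2L | vapply(al, function(a) any(a == "." | is.na(a)), logical(1))
  skipped <- sum(half)
  cs <- cs[!half, , drop = FALSE]
  al <- al[!half]
  het <- vapply(al, function(a) sum(a == "1") == 1L, logical(1))
  cs <- cs[het, , drop = FALSE]
  al <- al[het]
  phased <- grepl("|", cs$gt, fixed = TRUE)
  hap_alt <- ifelse(vapply(al, `[`, character(1), 1) == "1", 1L, 2L)
  out <- data.frame(
    key = cs$key, chrom = cs$chrom, pos = cs$pos, gt = cs$gt,
    hap_alt = ifelse(phased, hap_alt, NA_integer_),
    phase_set = ifelse(phased & !is.na(cs$ps), cs$ps,
                       ifelse(phased, "default", "unphased")),
    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Best orientation of a query block against truth haplotypes
#'
#' Within-block phase is relative, so the block as a whole may be compared
#' under the identity or the flipped labelling; the orientation maximizing
#' the number of shared variants whose haplotype assignment agrees with
#' truth is chosen, ties broken toward identity.
#'
#' @param truth_hap named integer vector (variant key -> haplotype 1/2
#'   carrying ALT) from the truth callset.
#' @param query_hap named integer vector for the members of one query block
#'   (restricted to the gene region of interest).
#' @return list with `orientation` ("identity" or "flipped"), `n_match`, and
#'   `matched` (keys agreeing under the chosen orientation). With zero
#'   shared variants the block contributes nothing (n_match 0).
#' @export
best_orientation <- function(truth_hap, query_hap) {
  shared <- intersect(names(truth_hap), names(query_hap))
  if (length(shared) == 0)
    return(list(orientation = "identity", n_match = 0L, matched = character(0)))
  t <- truth_hap[shared]; q <- query_hap[shared]
  id_match <- t == q
  fl_match <- t == (3L - q)
  if (sum(id_match) >= sum(fl_match))
    list(orientation = "identity", n_match = sum(id_match),
         matched = shared[id_match])
  else
    list(orientation = "flipped", n_match = sum(fl_match),
         matched = shared[fl_match])
}

#' Per-gene phasing success rate
#'
#' The denominator is the number of phased heterozygous truth variants in
#' the gene span (the considered reference variants). Each query phase
#' block intersecting the gene is oriented independently against the truth
#' (see [best_orientation()]); the numerator is the total number of
#' reference variants matched. Reference variants unphased or absent in the
#' query are counted as not correctly phased.
#'
#' @param truth,query callset data.frames.
#' @param gene one-row data.frame or list with symbol, chrom, start, end
#'   (0-based half-open).
#' @return list of class `gene_phasing`: gene, n_reference, n_correct,
#'   rate (NA with `no_reference = TRUE` when the gene has no reference
#'   variants).
#' @export
gene_phasing_success <- function(truth, query, gene) {
  region <- list(chrom = gene$chrom, start = gene$start, end = gene$end)
  th <- extract_phased_het(truth, region)
  th <- th[th$phase_set != "unphased", , drop = FALSE]
  n_ref <- nrow(th)
  if (n_ref == 0)
    return(structure(list(gene = gene$symbol, n_reference = 0L,
                          n_correct = 0L, rate = NA_real_,
                          no_reference = TRUE), class = "gene_phasing"))
  qh <- extract_phased_het(query, region)
  qh <- qh[qh$phase_set != "unphased", , drop = FALSE]
  truth_hap <- stats::setNames(th$hap_alt, th$key)
  n_correct <- 0L
  for (ps in unique(qh$phase_set)) {
    blk <- qh[qh$phase_set == ps, , drop = FALSE]
    query_hap <- stats::setNames(blk$hap_alt, blk$key)
    n_correct <- n_correct + best_orientation(truth_hap, query_hap)$n_match
  }
  structure(list(gene = gene$symbol, n_reference = n_ref,
                 n_correct = n_correct, rate = n_correct / n_ref,
                 no_reference = FALSE), class = "gene_phasing")
}

#' @export
print.gene_phasing <- function(x, ...) {
  if (x$no_reference)
    cat(sprintf("%s: no reference variants\n", x$gene))
  else
    cat(sprintf("%s: %d/%d reference variants phased correctly (%.1f%%)\n",
                x$gene, x$n_correct, x$n_reference, 100 * x$rate))
  invisible(x)
}

#' Phasing success rates for a set of genes
#'
#' @param truth,query callset data.frames.
#' @param genes data.frame with symbol, chrom, start, end.
#' @return data.frame with gene, span (end - start), n_reference, n_correct,
#'   rate.
#' @export
phasing_success_table <- function(truth, query, genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    r <- gene_phasing_success(truth, query, genes[i, ])
    data.frame(gene = r$gene, span = genes$end[i] - genes$start[i],
               n_reference = r$n_reference, n_correct = r$n_correct,
               rate = r$rate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify gene spans by phasing success threshold
#'
#' Splits genes with a defined phasing rate into a below-threshold and an
#' at-or-above-threshold group (the threshold is inclusive in the upper
#' group) and summarises the gene span lengths of each group, reflecting
#' the observation that long genes accumulate unphased variants because
#' even long reads cannot span the whole locus.
#'
#' @param results output of [phasing_success_table()].
#' @param threshold phased-fraction cut, default 0.90.
#' @return list with `below` and `at_or_above`, each holding `genes`,
#'   `count` and `span_summary` (five-number summary: min, lower hinge,
#'   median, upper hinge, max), plus `no_rate` (genes with NA rate).
#' @export
span_phasing_groups <- function(results, threshold = 0.90) {
  defined <- results[!is.na(results$rate), , drop = FALSE]
  hi <- defined[defined$rate >= threshold, , drop = FALSE]
  lo <- defined[defined$rate < threshold, , drop = FALSE]
  summ <- function(d) {
    if (nrow(d) == 0) return(rep(NA_real_, 5))
    stats::setNames(stats::fivenum(d$span),
                    c("min", "q1", "median", "q3", "max"))
  }
  list(
    below = list(genes = lo$gene, count = nrow(lo), span_summary = summ(lo)),
    at_or_above = list(genes = hi$gene, count = nrow(hi),
                       span_summary = summ(hi)),
    no_rate = results$gene[is.na(results$rate)],
    threshold = threshold)
}
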