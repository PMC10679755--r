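# Panel-restricted small-variant benchmarking.
#
# A query callset is compared with a truth callset at the predetermined
# panel sites only. Because the assay reports a fixed variant panel, absence
# of the ALT allele is as informative as its presence, so true negatives are
# counted and an accuracy (truth_tp + truth_tn) / (panel variants present in
# the truth set) is reported alongside the usual recall and precision.

#' Derive the variant class from allele strings
#' @param ref,alt character vectors of alleles.
#' @return "SNV" when both alleles are single bases, "INDEL" otherwise.
#' @keywords internal
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

#' Normalize a variant record to a canonical key
#'
#' Shared trailing then leading bases are trimmed (always keeping at least
#' one base on each allele), the position advanced over trimmed leading
#' bases, and the SNV/INDEL class derived from the trimmed alleles. Padded
#' representations of the same allele therefore map to identical keys.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref,alt allele strings (non-empty).
#' @return list with `chrom`, `pos`, `ref`, `alt`, `class` and `key`
#'   ("chrom:pos:ref:alt"), or NULL when ref and alt are identical after
#'   trimming (a rejected, non-variant record).
#' @export
normalize_record <- function(chrom, pos, ref, alt) {
  if (is.na(ref) || is.na(alt) || nchar(ref) == 0 || nchar(alt) == 0)
    stop_no_call("ref and alt must be non-empty")
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) return(NULL)
  # trim shared trailing bases
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared leading bases, advancing pos
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) return(NULL)
  list(chrom = as.character(chrom), pos = as.integer(pos), ref = ref,
       alt = alt, class = variant_class(ref, alt),
       key = paste(chrom, pos, ref, alt, sep = ":"))
}

#' Normalize a callset table
#'
#' Splits multi-allelic records into one record per ALT allele (recoding the
#' genotype so allele 1 refers to that ALT), trims shared padding bases, and
#' decomposes MNPs (equal-length multi-base ref/alt) into per-base SNVs.
#' Records whose ref and alt are identical after trimming are dropped.
#'
#' @param callset data.frame with columns chrom, pos, ref, alt, gt and
#'   optionally ps, filter.
#' @return normalized data.frame with columns chrom, pos, ref, alt, class,
#'   key, gt, ps, filter.
#' @export
normalize_callset <- function(callset) {
  if (nrow(callset) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), class = character(), key = character(),
                      gt = character(), ps = character(), filter = character(),
                      stringsAsFactors = FALSE))
  if (!"ps" %in% names(callset)) callset$ps <- NA_character_
  if (!"filter" %in% names(callset)) callset$filter <- "PASS"
  rows <- vector("list", nrow(callset))
  for (i in seq_len(nrow(callset))) {
    rec <- callset[i, ]
    alts <- strsplit(as.character(rec$alt), ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      gt <- recode_genotype(rec$gt, ai)
      norm <- normalize_record(rec$chrom, rec$pos, rec$ref, alts[ai])
      if (is.null(norm)) next
      sub <- decompose_mnp(norm)
      for (s in sub) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
          class = s$class, key = s$key, gt = gt,
          ps = as.character(rec$ps), filter = as.character(rec$filter),
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) return(normalize_callset(callset[0, ]))
  rownames(out) <- NULL
  out
}

# Recode a multiallelic genotype so the ai-th ALT becomes allele 1 and all
# other non-reference alleles become 0. Separator (| vs /) is preserved.
recode_genotype <- function(gt, ai) {
  gt <- as.character(gt)
  sep <- if (grepl("|", gt, fixed = TRUE)) "|" else "/"
  al <- strsplit(gt, "[/|]")[[1]]
  al <- ifelse(al == ".", ".", ifelse(al == as.character(ai), "1", "0"))
  paste(al, collapse = sep)
}

# Decompose an MNP (equal-length multi-base alleles) into component SNVs at
# the differing bases; other records pass through unchanged.
decompose_mnp <- function(norm) {
  if (nchar(norm$ref) == nchar(norm$alt) && nchar(norm$ref) > 1) {
    r <- strsplit(norm$ref, "")[[1]]
    a <- strsplit(norm$alt, "")[[1]]
    idx <- which(r != a)
    lapply(idx, function(j)
      normalize_record(norm$chrom, norm$pos + j - 1L, r[j], a[j]))
  } else list(norm)
}

#' Classify panel sites against truth and query callsets
#'
#' Every panel variant receives exactly one status. Sites outside the truth
#' high-confidence regions (when provided) are excluded from benchmarking.
#' A site is TP when truth and query both carry the ALT with identical
#' genotype, FN when only truth does, FP when only the query does, TN when
#' neither does, and genotype_mismatch when both carry the ALT with
#' different genotypes (counted downstream as one truth FN plus one query
#' FP, mirroring standard small-variant benchmarking). FILTER-failed query
#' records are treated as no-calls.
#'
#' @param truth,query callset data.frames (chrom, pos, ref, alt, gt, and
#'   optionally filter, ps); normalized internally via [normalize_callset()].
#' @param panel a `pgx_panel` or a data.frame of panel variants with columns
#'   chrom, pos, ref, alt and optionally gene.
#' @param confident optional data.frame of truth high-confidence regions
#'   (chrom, start, end; 0-based half-open).
#' @return data.frame with one row per panel variant: chrom, pos, ref, alt,
#'   class, key, gene, truth_gt, query_gt and status.
#' @export
classify_panel_sites <- function(truth, query, panel, confident = NULL) {
  pv <- if (inherits(panel, "pgx_panel")) panel$variants else panel
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(pv)))
  if (!"gene" %in% names(pv)) pv$gene <- NA_character_

  # normalize panel variant representation the same way as callsets
  norm <- lapply(seq_len(nrow(pv)), function(i)
    normalize_record(pv$chrom[i], pv$pos[i], pv$ref[i], pv$alt[i]))
  keep <- !vapply(norm, is.null, logical(1))
  pv <- pv[keep, , drop = FALSE]
  norm <- norm[keep]
  sites <- data.frame(
    chrom = vapply(norm, `[[`, character(1), "chrom"),
    pos = vapply(norm, `[[`, integer(1), "pos"),
    ref = vapply(norm, `[[`, character(1), "ref"),
    alt = vapply(norm, `[[`, character(1), "alt"),
    class = vapply(norm, `[[`, character(1), "class"),
    key = vapply(norm, `[[`, character(1), "key"),
    gene = pv$gene, stringsAsFactors = FALSE)

  tn <- normalize_callset(truth)
  qn <- normalize_callset(query)
  qn <- qn[qn$filter %in% c("PASS", ".", NA_character_), , drop = FALSE]

  tgt <- tn$gt[match(sites$key, tn$key)]
  qgt <- qn$gt[match(sites$key, qn$key)]
  sites$truth_gt <- tgt
  sites$query_gt <- qgt

  t_alt <- !is.na(tgt) & gt_carries_alt(tgt)
  q_alt <- !is.na(qgt) & gt_carries_alt(qgt)
  same_gt <- !is.na(tgt) & !is.na(qgt) &
    gt_unordered(tgt) == gt_unordered(qgt)

  status <- character(nrow(sites))
  status[t_alt & q_alt & same_gt] <- "TP"
  status[t_alt & q_alt & !same_gt] <- "genotype_mismatch"
  status[t_alt & !q_alt] <- "FN"
  status[!t_alt & q_alt] <- "FP"
  status[!t_alt & !q_alt] <- "TN"

  if (!is.null(confident)) {
    inside <- pos_in_regions(sites$chrom, sites$pos, confident)
    status[!inside] <- "excluded_no_truth_coverage"
  }
  sites$status <- status
  sites
}

# does a genotype string carry at least one ALT (allele "1") call?
gt_carries_alt <- function(gt) {
  vapply(strsplit(as.character(gt), "[/|]"),
         function(a) any(a == "1"), logical(1))
}

# order-independent genotype representation ("1|0" == "0/1")
gt_unordered <- function(gt) {
  vapply(strsplit(as.character(gt), "[/|]"),
         function(a) paste(sort(a), collapse = "/"), character(1))
}

#' Aggregate site classifications into benchmarking counts
#'
#' @param classifications output of [classify_panel_sites()] (possibly a
#'   subset defining a stratum).
#' @return list of class `bench_counts`: truth_tp, truth_fn, query_tp,
#'   query_fp, truth_tn, truth_alt and denominator (assessable panel
#'   variants, i.e. those present in the truth high-confidence evaluation).
#'   Genotype mismatches contribute one truth_fn and one query_fp.
#' @export
count_classifications <- function(classifications) {
  st <- classifications$status
  tp <- sum(st == "TP")
  mm <- sum(st == "genotype_mismatch")
  counts <- list(
    truth_tp = tp,
    truth_fn = sum(st == "FN") + mm,
    query_tp = tp,
    query_fp = sum(st == "FP") + mm,
    truth_tn = sum(st == "TN"),
    truth_alt = sum(st %in% c("TP", "FN", "genotype_mismatch")),
    denominator = sum(st != "excluded_no_truth_coverage"))
  structure(counts, class = "bench_counts")
}

#' Recall, precision and TN-inclusive accuracy from benchmarking counts
#'
#' recall = truth_tp / (truth_tp + truth_fn);
#' precision = query_tp / (query_tp + query_fp);
#' accuracy = (truth_tp + truth_tn) / denominator, the denominator being the
#' panel variants present in the truth set evaluation. Any 0/0 ratio is
#' undefined and reported as NA.
#'
#' @param counts a `bench_counts` list (or any list with the same fields).
#' @return list of class `bench_metrics` with fractions `recall`,
#'   `precision`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  fields <- c("truth_tp", "truth_fn", "query_tp", "query_fp", "truth_tn",
              "denominator")
  vals <- unlist(counts[fields])
  if (any(is.na(vals)) || any(vals < 0)) stop_no_call("negative or missing counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    recall = ratio(counts$truth_tp, counts$truth_tp + counts$truth_fn),
    precision = ratio(counts$query_tp, counts$query_tp + counts$query_fp),
    accuracy = ratio(counts$truth_tp + counts$truth_tn, counts$denominator)),
    class = "bench_metrics")
}

#' Stratified benchmarking report
#'
#' Computes counts and metrics for the whole panel, per variant class (SNV,
#' INDEL) and, optionally, per gene. Metrics are reported as percentages
#' rounded half-up to two decimals, matching the convention of published
#' benchmarking tables.
#'
#' @param classifications output of [classify_panel_sites()].
#' @param by_gene also emit one stratum per gene symbol. Default FALSE.
#' @return data.frame of class `bench_report` with columns stratum,
#'   denominator, truth_alt, truth_tp, truth_fn, query_tp, query_fp,
#'   truth_tn, recall, precision, accuracy (percentages, NA when undefined).
#' @export
stratify <- function(classifications, by_gene = FALSE) {
  strata <- list(all = classifications)
  for (cl in c("SNV", "INDEL"))
    strata[[cl]] <- classifications[classifications$class == cl, , drop = FALSE]
  if (by_gene) {
    for (g in sort(unique(stats::na.omit(classifications$gene))))
      strata[[paste0("gene:", g)]] <-
        classifications[!is.na(classifications$gene) &
                          classifications$gene == g, , drop = FALSE]
  }
  rows <- lapply(names(strata), function(nm) {
    cnt <- count_classifications(strata[[nm]])
    met <- compute_metrics(cnt)
    data.frame(stratum = nm, denominator = cnt$denominator,
               truth_alt = cnt$truth_alt, truth_tp = cnt$truth_tp,
               truth_fn = cnt$truth_fn, query_tp = cnt$query_tp,
               query_fp = cnt$query_fp, truth_tn = cnt$truth_tn,
               recall = as_pct(met$recall), precision = as_pct(met$precision),
               accuracy = as_pct(met$accuracy), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bench_report", "data.frame")
  out
}

#' @export
print.bench_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", as_pct(v))
  cat(sprintf("recall %s  precision %s  accuracy %s\n",
              fmt(x$recall), fmt(x$precision), fmt(x$accuracy)))
  invisible(x)
}

#' @export
print.bench_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a stratified benchmarking report as TSV
#' @param report a `bench_report`.
#' @param path output path.
#' @export
write_bench_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
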