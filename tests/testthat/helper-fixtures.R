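# Fixture builders and independent brute-force oracles. The oracles use
# plain R vectors only, independent of the interval machinery under test.

make_callset <- function(chrom, pos, ref = "A", alt = "G", gt = "0|1",
                         ps = NA_character_, filter = "PASS") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             ps = ps, filter = filter, stringsAsFactors = FALSE)
}

# Per-base boolean-mask union of 0-based half-open regions; returns the
# total covered base count per genome.
brute_union_bases <- function(regions, genome) {
  total <- 0
  for (i in seq_len(nrow(genome))) {
    mask <- logical(genome$length[i])
    r <- regions[regions$chrom == genome$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      if (r$end[j] > r$start[j])
        mask[(r$start[j] + 1):r$end[j]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# Per-base depth scan over the panel: mean depth and fraction of targeted
# bases at each threshold, with uncovered panel bases counted as depth 0.
brute_depth_stats <- function(track, panel_regions, genome,
                              thresholds = c(15, 20, 30)) {
  depth_vec <- numeric(0)
  for (i in seq_len(nrow(genome))) {
    dv <- numeric(genome$length[i])
    tr <- track[track$chrom == genome$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(tr)))
      dv[(tr$start[j] + 1):tr$end[j]] <- tr$depth[j]
    pmask <- logical(genome$length[i])
    pr <- panel_regions[panel_regions$chrom == genome$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(pr)))
      pmask[(pr$start[j] + 1):pr$end[j]] <- TRUE
    depth_vec <- c(depth_vec, dv[pmask])
  }
  list(mean_depth = mean(depth_vec),
       fraction_at = vapply(sort(thresholds),
                            function(th) mean(depth_vec >= th), numeric(1)))
}

# Random 0-based half-open regions on a toy genome.
random_regions <- function(n, genome) {
  idx <- sample.int(nrow(genome), n, replace = TRUE)
  start <- floor(runif(n, 0, genome$length[idx] - 1))
  len <- pmax(1, floor(runif(n, 1, pmax(2, genome$length[idx] / 10))))
  data.frame(chrom = genome$chrom[idx], start = start,
             end = pmin(genome$length[idx], start + len),
             stringsAsFactors = FALSE)
}

# Truth/query callset pair over a synthetic panel with an exact injected
# composition per variant class: n_sites panel sites of which n_alt carry
# ALT in truth; the query drops the first n_drop ALT sites, genotype-
# mismatches the next n_mm, and adds ALT at the first n_fp truth-REF sites.
bench_fixture <- function(spec) {
  panel <- NULL; truth <- NULL; query <- NULL
  offset <- 0L
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    pos <- offset + 10L * seq_len(s$n_sites)
    offset <- max(pos) + 1000L
    if (s$class == "SNV") { ref <- "A"; alt <- "G" } else { ref <- "AT"; alt <- "A" }
    panel <- rbind(panel, data.frame(chrom = "chr1", pos = pos, ref = ref,
                                     alt = alt, gene = paste0("G", i),
                                     stringsAsFactors = FALSE))
    alt_pos <- pos[seq_len(s$n_alt)]
    truth <- rbind(truth, make_callset("chr1", alt_pos, ref, alt, "0|1", "1"))
    q_keep <- alt_pos[-seq_len(s$n_drop + s$n_mm)]
    mm_pos <- alt_pos[s$n_drop + seq_len(s$n_mm)]
    query <- rbind(query,
                   make_callset("chr1", q_keep, ref, alt, "0|1", "1"),
                   if (s$n_mm > 0) make_callset("chr1", mm_pos, ref, alt,
                                                "1|1", "1"),
                   if (s$n_fp > 0) make_callset(
                     "chr1", pos[s$n_alt + seq_len(s$n_fp)], ref, alt,
                     "0|1", "1"))
  }
  list(panel = panel, truth = truth, query = query)
}

# One-gene phasing fixture: truth hets at the given positions, all 0|1 on a
# chromosome-wide phase set.
phasing_truth <- function(pos, chrom = "chr1") {
  make_callset(chrom, pos, "A", "G", "0|1", "1")
}

toy_gene <- function(symbol = "GENE1", chrom = "chr1", start = 0,
                     end = 10000) {
  data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
             strand = "+", stringsAsFactors = FALSE)
}

# Exact binomial two-sided interval for an observed proportion.
binom_interval <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
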