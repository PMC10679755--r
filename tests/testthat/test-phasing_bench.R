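# Phasing concordance: haplotype extraction, block orientation, gene rates.

test_that("phased het extraction applies the haplotype convention", {
  cs <- make_callset("chr1", c(100, 200, 300, 400, 500),
                     gt = c("0|1", "1|0", "0/1", "1|1", "./."),
                     ps = c("1", "1", NA, "1", NA))
  h <- extract_phased_het(cs)
  expect_equal(h$pos, c(100, 200, 300))       # hom and half-call dropped
  expect_equal(h$hap_alt, c(2L, 1L, NA))      # left allele is haplotype 1
  expect_equal(h$phase_set, c("1", "1", "unphased"))
  expect_equal(attr(h, "skipped"), 1L)
  r <- list(chrom = "chr1", start = 150, end = 450)
  expect_equal(extract_phased_het(cs, r)$pos, c(200, 300))
})

test_that("best_orientation maximizes matches with ties broken toward identity", {
  truth <- setNames(c(1L, 1L, 1L), c("a", "b", "c"))
  # all flipped relative to truth
  bo <- best_orientation(truth, setNames(c(2L, 2L, 2L), c("a", "b", "c")))
  expect_equal(bo$orientation, "flipped")
  expect_equal(bo$n_match, 3L)
  # one agreeing per orientation: tie -> identity
  bo2 <- best_orientation(setNames(c(1L, 1L), c("a", "b")),
                          setNames(c(1L, 2L), c("a", "b")))
  expect_equal(bo2$orientation, "identity")
  expect_equal(bo2$n_match, 1L)
  # no shared variants
  bo3 <- best_orientation(truth, setNames(2L, "z"))
  expect_equal(bo3$n_match, 0L)
})

test_that("random blocks agree with brute force over both orientations", {
  set.seed(99)
  for (rep in 1:20) {
    keys <- paste0("v", 1:8)
    truth <- setNames(sample(1:2, 8, TRUE), keys)
    query <- setNames(sample(1:2, 8, TRUE), sample(keys))
    bo <- best_orientation(truth, query)
    shared <- intersect(keys, names(query))
    brute <- max(sum(truth[shared] == query[shared]),
                 sum(truth[shared] == 3 - query[shared]))
    expect_equal(bo$n_match, brute)
  }
})

test_that("a query identical to truth in one block phases every gene perfectly", {
  truth <- phasing_truth(c(1000, 2000, 3000, 4000))
  r <- gene_phasing_success(truth, truth, toy_gene())
  expect_equal(r$n_reference, 4L)
  expect_equal(r$rate, 1)
})

test_that("one recoverable variant out of three gives rate 1/3", {
  truth <- phasing_truth(c(1000, 2000, 3000))
  query <- make_callset("chr1", c(1000, 2000, 3000), "A", "G",
                        gt = c("0|1", "1|0", "0/1"),
                        ps = c("1000", "1000", NA))
  r <- gene_phasing_success(truth, query, toy_gene())
  expect_equal(r$n_reference, 3L)
  expect_equal(r$n_correct, 1L)
  expect_equal(r$rate, 1 / 3)
})

test_that("truth variants missing from the query count as incorrectly phased", {
  truth <- phasing_truth(c(1000, 2000))
  query <- make_callset("chr1", 1000, "A", "G", gt = "0|1", ps = "1000")
  r <- gene_phasing_success(truth, query, toy_gene())
  expect_equal(r$rate, 1 / 2)
})

test_that("genes without reference variants are flagged, not scored", {
  truth <- make_callset("chr1", 1000, gt = "1|1", ps = "1")  # hom: no phase
  r <- gene_phasing_success(truth, truth, toy_gene())
  expect_true(r$no_reference)
  expect_true(is.na(r$rate))
})

test_that("orientation is chosen per block-gene intersection, insulating distant switches", {
  gene <- toy_gene(end = 5000)
  truth <- phasing_truth(c(1000, 2000, 8000, 9000))
  # one long query block, switched after the gene: inside the gene it is
  # flipped consistently, outside it matches identity
  query <- make_callset("chr1", c(1000, 2000, 8000, 9000), "A", "G",
                        gt = c("1|0", "1|0", "0|1", "0|1"), ps = "1000")
  r <- gene_phasing_success(truth, query, gene)
  expect_equal(r$rate, 1)  # both in-gene variants recovered under the flip
})

test_that("global haplotype relabelling leaves every rate unchanged", {
  cfg <- sim_config(seed = 21, switch_error_rate = 0.05,
                    block_break_rate = 0.2)
  w <- simulate_reference_world(cfg)
  p <- build_panel(assign_variant_targets(w$annotations, w$genes), w$genome)
  tr <- simulate_truth_callset(p$variants, cfg, w$genome)
  qu <- corrupt_callset(tr$callset, p$variants, cfg)$callset
  flipped <- qu
  flipped$gt <- chartr("01", "10", flipped$gt)  # swap haplotype labels 1<->2
  flipped$gt <- sub("^1/0$", "0/1", flipped$gt)
  res1 <- phasing_success_table(tr$callset, qu, w$genes)
  res2 <- phasing_success_table(tr$callset, flipped, w$genes)
  expect_equal(res1$rate, res2$rate)
})

test_that("Markov-corrupted blocks score exactly max(majority) per block", {
  set.seed(17)
  gene <- toy_gene(end = 1e6)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    pos <- sort(sample(1000:999000, n))
    truth <- phasing_truth(pos)
    # independent corruption: explicit Markov orientation chain
    s <- runif(1, 0, 0.4)
    state <- cumsum(c(0, runif(n - 1) < s)) %% 2
    gt <- ifelse(state == 0, "0|1", "1|0")
    query <- make_callset("chr1", pos, "A", "G", gt = gt, ps = "b1")
    expected <- max(sum(state == 0), sum(state == 1))
    r <- gene_phasing_success(truth, query, gene)
    expect_equal(r$n_correct, expected)
  }
})

test_that("switch errors never increase the expected phasing rate", {
  gene <- toy_gene(end = 1e6)
  pos <- seq(1000, 150000, by = 1000)
  truth <- phasing_truth(pos)
  pv <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  mean_rate <- function(s) {
    rates <- vapply(1:200, function(seed) {
      cfg <- sim_config(seed = 1000 + seed, fn_rate = 0, fp_rate = 0,
                        gt_error_rate = 0, block_break_rate = 0,
                        switch_error_rate = s)
      qu <- corrupt_callset(truth, pv, cfg)$callset
      gene_phasing_success(truth, qu, gene)$rate
    }, numeric(1))
    mean(rates)
  }
  m0 <- mean_rate(0); m1 <- mean_rate(0.02); m2 <- mean_rate(0.1)
  expect_equal(m0, 1)    # no switches, one block -> perfect phasing
  expect_gt(m0, m1)
  expect_gt(m1, m2)
})

test_that("span stratification is exhaustive and inclusive at the threshold", {
  results <- data.frame(gene = c("A", "B", "C", "D"),
                        span = c(10000, 200000, 5000, 700),
                        n_reference = c(10, 10, 10, 0),
                        n_correct = c(10, 5, 9, 0),
                        rate = c(1, 0.5, 0.9, NA))
  g <- span_phasing_groups(results)
  expect_equal(sort(c(g$below$genes, g$at_or_above$genes)), c("A", "B", "C"))
  expect_true("C" %in% g$at_or_above$genes)  # rate exactly 0.90 -> upper group
  expect_equal(g$no_rate, "D")
  expect_equal(g$below$count + g$at_or_above$count, 3)
  # all rates 1 -> one group empty
  allone <- results[1, , drop = FALSE]
  g2 <- span_phasing_groups(allone)
  expect_equal(g2$below$count, 0)
  expect_true(all(is.na(g2$below$span_summary)))
})

test_that("fragmented long genes depress the upper group's spans", {
  # construct short genes phased perfectly and long genes with fragmented,
  # switch-ridden blocks: the >=90% group must have the smaller median span
  genes <- rbind(toy_gene("S1", start = 0, end = 20000),
                 toy_gene("S2", start = 50000, end = 72000),
                 toy_gene("L1", start = 200000, end = 800000),
                 toy_gene("L2", start = 1000000, end = 1900000))
  truth <- NULL; query <- NULL
  set.seed(4)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pos <- sort(sample(seq(g$start + 1, g$end), 40))
    truth <- rbind(truth, phasing_truth(pos))
    long <- g$end - g$start > 1e5
    if (!long) {
      query <- rbind(query, phasing_truth(pos))
    } else {
      # many small blocks with half the variants flipped within each
      blk <- rep(seq_len(8), each = 5)
      gt <- ifelse(seq_along(pos) %% 2 == 0, "1|0", "0|1")
      query <- rbind(query, make_callset(g$chrom, pos, "A", "G", gt,
                                         ps = paste0("b", blk)))
    }
  }
  res <- phasing_success_table(truth, query, genes)
  grp <- span_phasing_groups(res)
  expect_lt(grp$at_or_above$span_summary[["median"]],
            grp$below$span_summary[["median"]])
})
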