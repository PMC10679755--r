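# Target-panel construction: assignment rules, flank/merge, genome fraction.

toy_genome <- data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 5e5),
                         stringsAsFactors = FALSE)
toy_genes <- data.frame(symbol = "ABC1", chrom = "chr1", start = 10000,
                        end = 30000, strand = "+", stringsAsFactors = FALSE)

ann_row <- function(pos, id = "rs1", gene = "ABC1", chrom = "chr1",
                    ref = "A", alt = "G") {
  data.frame(variant_id = id, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

test_that("variants are assigned intragenic, flanking or discarded by the distance rule", {
  ann <- rbind(ann_row(15000, "rs_in"),      # inside the gene body
               ann_row(80000, "rs_down"),    # 50 kb downstream
               ann_row(200000, "rs_far"),    # beyond 100 kb
               ann_row(5000, "rs_up"),       # 5 kb upstream
               ann_row(130000, "rs_edge"),   # exactly 100 kb downstream
               ann_row(50, "rs_none", gene = "NOPE"),
               ann_row("oops", "rs_bad"))
  a <- assign_variant_targets(ann, toy_genes)

  expect_equal(a$status, c("intragenic", "flanking", "discarded_distance",
                           "flanking", "flanking", "unmapped_gene",
                           "rejected"))
  # intragenic: the entire gene body
  expect_equal(unlist(a[1, c("region_start", "region_end")],
                      use.names = FALSE), c(10000, 30000))
  # downstream flanking: span from the gene through the variant
  expect_equal(unlist(a[2, c("region_start", "region_end")],
                      use.names = FALSE), c(10000, 80000))
  # upstream flanking also keeps the gene body
  expect_equal(unlist(a[4, c("region_start", "region_end")],
                      use.names = FALSE), c(4999, 30000))
  # inclusive at exactly the threshold
  expect_equal(a$region_end[5], 130000)
  expect_true(is.na(a$region_start[3]))
  expect_match(a$reason[7], "malformed")
})

test_that("build_panel pads, clips and merges regions; variants stay contained", {
  ann <- rbind(ann_row(15000, "rs1"), ann_row(80000, "rs2"))
  a <- assign_variant_targets(ann, toy_genes)
  p <- build_panel(a, toy_genome, panel_config(flank = 20000))
  # both raw regions overlap after padding -> one merged region
  expect_equal(nrow(p$regions), 1)
  expect_equal(p$regions$start, 0)       # 10000 - 20000 clipped at 0
  expect_equal(p$regions$end, 100000)    # 80000 + 20000
  expect_equal(p$regions$genes, "ABC1")
  expect_equal(nrow(p$variants), 2)
  expect_true(all(pos_in <- p$variants$pos >= p$regions$start + 1 &
                    p$variants$pos <= p$regions$end))
})

test_that("overlapping and bookended regions merge; merge is idempotent", {
  mk_assign <- function(regions) {
    data.frame(variant_id = paste0("rs", seq_len(nrow(regions))),
               gene = "ABC1", chrom = regions$chrom,
               pos = regions$start + 1, ref = "A", alt = "G", class = "SNV",
               status = "intragenic", region_start = regions$start,
               region_end = regions$end, reason = NA, stringsAsFactors = FALSE)
  }
  r <- data.frame(chrom = "chr1", start = c(0, 500, 2000),
                  end = c(1000, 2000, 3000))
  p <- build_panel(mk_assign(r), toy_genome, panel_config(flank = 0))
  expect_equal(p$regions$start, 0)   # overlap and bookend both collapse
  expect_equal(p$regions$end, 3000)
  p2 <- build_panel(mk_assign(p$regions), toy_genome, panel_config(flank = 0))
  expect_equal(p2$regions[, c("chrom", "start", "end")],
               p$regions[, c("chrom", "start", "end")])
})

test_that("merged base counts equal the per-base boolean-mask oracle on random panels", {
  set.seed(42)
  for (rep in 1:5) {
    regions <- random_regions(50, toy_genome)
    assign <- data.frame(variant_id = paste0("rs", seq_len(nrow(regions))),
                         gene = "ABC1", chrom = regions$chrom,
                         pos = regions$start + 1, ref = "A", alt = "G",
                         class = "SNV", status = "intragenic",
                         region_start = regions$start,
                         region_end = regions$end, reason = NA,
                         stringsAsFactors = FALSE)
    p <- build_panel(assign, toy_genome, panel_config(flank = 0))
    expect_equal(sum(p$regions$end - p$regions$start),
                 brute_union_bases(regions, toy_genome))
    # regions are sorted, non-overlapping, non-adjacent
    for (ch in unique(p$regions$chrom)) {
      r <- p$regions[p$regions$chrom == ch, ]
      if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
    gf <- genome_fraction(p)
    expect_equal(gf$fraction,
                 brute_union_bases(regions, toy_genome) /
                   sum(toy_genome$length))
  }
})

test_that("genome_fraction handles trivial panels and flags the recommended window", {
  assign <- data.frame(variant_id = "rs1", gene = "ABC1", chrom = "chr1",
                       pos = 1, ref = "A", alt = "G", class = "SNV",
                       status = "intragenic", region_start = 0,
                       region_end = 100, reason = NA, stringsAsFactors = FALSE)
  genome <- data.frame(chrom = "chr1", length = 1000)
  p <- build_panel(assign, genome, panel_config(flank = 0))
  gf <- genome_fraction(p)
  expect_equal(gf$fraction, 0.10)
  expect_true(gf$in_window)

  p_empty <- build_panel(assign[0, ], genome, panel_config(flank = 0))
  gf0 <- genome_fraction(p_empty)
  expect_equal(gf0$fraction, 0)
  expect_false(gf0$in_window)
  expect_error(genome_fraction(p_empty, genome[0, ]), "empty genome")
})

test_that("increasing the flank never decreases genome_fraction", {
  set.seed(7)
  regions <- random_regions(20, toy_genome)
  assign <- data.frame(variant_id = paste0("rs", seq_len(nrow(regions))),
                       gene = "ABC1", chrom = regions$chrom,
                       pos = regions$start + 1, ref = "A", alt = "G",
                       class = "SNV", status = "intragenic",
                       region_start = regions$start, region_end = regions$end,
                       reason = NA, stringsAsFactors = FALSE)
  fracs <- vapply(c(0, 1000, 5000, 20000), function(fl)
    genome_fraction(build_panel(assign, toy_genome,
                                panel_config(flank = fl)))$fraction,
    numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("unknown chromosomes are rejected with the chromosome named", {
  assign <- data.frame(variant_id = "rs1", gene = "ABC1", chrom = "chrZ",
                       pos = 1, ref = "A", alt = "G", class = "SNV",
                       status = "intragenic", region_start = 0,
                       region_end = 100, reason = NA, stringsAsFactors = FALSE)
  expect_error(build_panel(assign, toy_genome), "chrZ")
})

test_that("BED round trip and annotation-coordinate join work", {
  ann <- rbind(ann_row(15000, "rs1"), ann_row(80000, "rs2"))
  a <- assign_variant_targets(ann, toy_genes)
  p <- build_panel(a, toy_genome)
  bed <- file.path(tempdir(), "panel.bed")
  write_target_bed(p, bed)
  rt <- read_target_bed(bed)
  expect_equal(rt$start, p$regions$start)
  expect_equal(rt$end, p$regions$end)
  expect_equal(rt$genes, p$regions$genes)

  ann_tsv <- file.path(tempdir(), "ann.tsv")
  coord_tsv <- file.path(tempdir(), "coord.tsv")
  write.table(data.frame(variant_id = c("rs1", "rs9"), gene = "ABC1",
                         evidence_level = "1A"),
              ann_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(variant_id = "rs1", chrom = "chr1", pos = 15000,
                         ref = "A", alt = "G"),
              coord_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(
    joined <- join_annotation_coordinates(read_annotation_table(ann_tsv),
                                          read_variant_coordinates(coord_tsv)),
    "without coordinates")
  expect_equal(nrow(joined), 1)
  expect_equal(joined$pos, 15000)
})
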