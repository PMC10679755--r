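# Synthetic inputs with known ground truth.
#
# Generates every input the pipeline reads — genome, gene and annotation
# tables, phased truth and corrupted query callsets, confident-region BED,
# depth tracks and read summaries — with the statistical structure the
# analysis assumes, at a desk scale (tens of megabases, tens of genes).
# Every generator is deterministic under the config seed and emits a
# ground-truth sidecar (intent labels) that oracle tests in the other
# modules consume. Variant positions are unique per chromosome, so
# representation normalization never has to disambiguate simulated sites.

#' Simulation configuration
#'
#' Defaults emulate the study conditions at a reduced scale: a 24 Mb
#' four-chromosome genome carrying 20 non-overlapping genes whose merged
#' 20 kb-flanked targets cover roughly 5% of the genome (inside the
#' recommended 1%-10% adaptive-sampling window, near the study's 5.68%); about 38% of panel sites
#' carry the ALT allele in truth (roughly 1,229 ALT of 3,262 assessable
#' sites in the flagship sample), ~2.5% of panel sites fall outside the
#' truth high-confidence regions (3,347 panel variants vs 3,262 assessed),
#' ~2.5% of variants are INDELs (85 of 3,347), and query error rates are of
#' the order observed for the nanopore callsets (FN ~0.5%). Depth follows a
#' negative binomial with mean 47 (the flagship run's on-target average).
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_chrom,chrom_length genome shape.
#' @param n_genes number of genes; `gene_length_range` log-uniform bounds.
#' @param variants_per_gene_range inclusive integer range of clinical
#'   variants per gene.
#' @param intent_probs probabilities of placing a variant intragenic,
#'   flanking (within `max_dist` of a boundary) or as a beyond-threshold
#'   decoy.
#' @param max_dist,decoy_max_dist flanking threshold and maximum decoy
#'   distance (bases).
#' @param indel_fraction fraction of variants simulated as INDELs.
#' @param alt_fraction probability a panel site carries ALT in truth;
#'   `het_fraction` probability an ALT site is heterozygous.
#' @param confident_exclusion fraction of panel sites excluded from the
#'   truth high-confidence regions.
#' @param fn_rate,fp_rate,gt_error_rate query corruption rates: truth-ALT
#'   site dropped; spurious ALT added at a truth-REF panel site; genotype
#'   flipped het<->hom.
#' @param block_break_rate probability of starting a new phase block
#'   between consecutive heterozygous sites; `switch_error_rate`
#'   probability the haplotype labelling flips after each site (Markov
#'   switch-error model).
#' @param depth_mean,depth_dispersion negative-binomial depth model
#'   (dispersion = nbinom size); `depth_chunk` piecewise-constant interval
#'   length in bases.
#' @param n_reads,accept_fraction,quality_mean,quality_sd,
#'   read_length_meanlog,read_length_sdlog read-summary model.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L, chrom_length = 6e6,
                       n_genes = 20L, gene_length_range = c(5e3, 3e4),
                       variants_per_gene_range = c(1L, 4L),
                       intent_probs = c(intragenic = 0.7, flanking = 0.2,
                                        decoy = 0.1),
                       max_dist = 100000L, decoy_max_dist = 150000L,
                       indel_fraction = 0.025,
                       alt_fraction = 0.38, het_fraction = 0.6,
                       confident_exclusion = 0.025,
                       fn_rate = 0.005, fp_rate = 0.002,
                       gt_error_rate = 0.002,
                       block_break_rate = 0.1, switch_error_rate = 0.01,
                       depth_mean = 47, depth_dispersion = 10,
                       depth_chunk = 500L,
                       n_reads = 5000L, accept_fraction = 0.6,
                       quality_mean = 12, quality_sd = 2.5,
                       read_length_meanlog = log(5000),
                       read_length_sdlog = 0.6) {
  cfg <- as.list(environment())
  rates <- c(cfg$intent_probs, cfg$indel_fraction, cfg$alt_fraction,
             cfg$het_fraction, cfg$confident_exclusion, cfg$fn_rate,
             cfg$fp_rate, cfg$gt_error_rate, cfg$block_break_rate,
             cfg$switch_error_rate, cfg$accept_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), cfg$chrom_length > 0,
            cfg$gene_length_range[1] > 0, cfg$depth_mean >= 0,
            abs(sum(cfg$intent_probs) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

# deterministic sub-seeds (kept well below 2^31)
sub_seed <- function(config, offset) (config$seed %% 1000000L) * 1000L + offset

DNA_BASES <- c("A", "C", "G", "T")

rand_alleles <- function(is_indel) {
  ref <- sample(DNA_BASES, 1)
  if (!is_indel) {
    list(ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1))
  } else if (stats::runif(1) < 0.5) {  # insertion
    list(ref = ref, alt = paste0(ref, paste(
      sample(DNA_BASES, sample(1:3, 1), replace = TRUE), collapse = "")))
  } else {                             # deletion
    list(ref = paste0(ref, paste(
      sample(DNA_BASES, sample(1:3, 1), replace = TRUE), collapse = "")),
      alt = ref)
  }
}

#' Simulate the reference world: genome, genes and clinical annotations
#'
#' Genes are placed non-overlapping with generous margins so that flanking
#' and decoy variants of one gene never collide with a neighbour. Variants
#' are placed intragenic, flanking (distance 1..max_dist from the nearer
#' boundary) or as decoys (beyond max_dist) in the configured proportions,
#' and the generator records its intent per variant.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (chrom, length), `genes` (symbol, chrom,
#'   start, end, strand; 0-based half-open), `annotations` (variant_id,
#'   gene, chrom, pos, ref, alt, evidence_level) and `intent` (variant_id,
#'   intent).
#' @export
simulate_reference_world <- function(config = sim_config()) {
  set.seed(sub_seed(config, 1L))
  genome <- data.frame(chrom = paste0("chr", seq_len(config$n_chrom)),
                       length = rep(config$chrom_length, config$n_chrom),
                       stringsAsFactors = FALSE)
  margin <- config$decoy_max_dist + 10000
  chrom_of <- rep(genome$chrom, length.out = config$n_genes)
  per_chrom <- table(chrom_of)
  genes <- NULL
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    slot <- config$chrom_length / k
    if (slot < 2 * margin + config$gene_length_range[2])
      stop_no_call("chromosomes too short for the requested gene density")
    for (j in seq_len(k)) {
      len <- round(exp(stats::runif(1, log(config$gene_length_range[1]),
                                    log(config$gene_length_range[2]))))
      lo <- (j - 1) * slot + margin
      hi <- j * slot - margin - len
      start <- round(stats::runif(1, lo, hi))
      genes <- rbind(genes, data.frame(
        symbol = sprintf("GENE%03d", nrow(genes %||% data.frame()) + 1),
        chrom = ch, start = start, end = start + len,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
    }
  }
  rownames(genes) <- NULL

  draw_pos <- function(g, intent) {
    if (intent == "intragenic") {
      sample(seq.int(g$start, g$end - 1L), 1) + 1L   # 1-based
    } else {
      d <- if (intent == "flanking") sample.int(config$max_dist, 1)
           else config$max_dist + sample.int(config$decoy_max_dist -
                                               config$max_dist, 1)
      if (stats::runif(1) < 0.5) g$start - d + 1L else g$end + d
    }
  }

  ann <- NULL; taken <- list()
  vid <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    nv <- sample(seq.int(config$variants_per_gene_range[1],
                         config$variants_per_gene_range[2]), 1)
    for (v in seq_len(nv)) {
      intent <- sample(names(config$intent_probs), 1,
                       prob = config$intent_probs)
      pos <- draw_pos(g, intent)
      tries <- 0
      while ((pos < 1 || pos > config$chrom_length ||
              pos %in% (taken[[g$chrom]] %||% integer())) && tries < 100) {
        pos <- draw_pos(g, intent); tries <- tries + 1
      }
      taken[[g$chrom]] <- c(taken[[g$chrom]] %||% integer(), pos)
      al <- rand_alleles(stats::runif(1) < config$indel_fraction)
      vid <- vid + 1L
      ann <- rbind(ann, data.frame(
        variant_id = sprintf("rs%07d", 1000000L + vid), gene = g$symbol,
        chrom = g$chrom, pos = pos, ref = al$ref, alt = al$alt,
        evidence_level = sample(c("1A", "1B", "2A", "2B", "3", "4"), 1),
        intent = intent, stringsAsFactors = FALSE))
    }
  }
  rownames(ann) <- NULL
  list(genome = genome, genes = genes,
       annotations = ann[, setdiff(names(ann), "intent")],
       intent = ann[, c("variant_id", "intent")])
}

#' Simulate a phased truth callset over panel sites
#'
#' Each panel site carries the ALT allele with probability `alt_fraction`;
#' ALT sites are heterozygous with probability `het_fraction`. Truth
#' heterozygotes are globally phased per chromosome (a single phase set
#' spanning the chromosome). A configurable fraction of panel sites is
#' excluded from the high-confidence regions.
#'
#' @param panel_variants data.frame with variant_id (optional), chrom, pos,
#'   ref, alt — e.g. `build_panel(...)$variants`.
#' @param config a [sim_config()].
#' @param genome data.frame (chrom, length) used for the confident-region
#'   complement.
#' @return list with `callset` (ALT records only: chrom, pos, ref, alt, gt,
#'   ps, filter), `confident` (chrom, start, end; 0-based half-open) and
#'   `sites` sidecar (chrom, pos, genotype in {hom_ref, het, hom_alt},
#'   excluded flag).
#' @export
simulate_truth_callset <- function(panel_variants, config = sim_config(),
                                   genome = NULL) {
  set.seed(sub_seed(config, 2L))
  pv <- panel_variants
  n <- nrow(pv)
  carries <- stats::runif(n) < config$alt_fraction
  het <- carries & (stats::runif(n) < config$het_fraction)
  genotype <- ifelse(!carries, "hom_ref", ifelse(het, "het", "hom_alt"))
  gt <- ifelse(het, ifelse(stats::runif(n) < 0.5, "0|1", "1|0"), "1|1")
  excluded <- stats::runif(n) < config$confident_exclusion

  callset <- data.frame(chrom = pv$chrom[carries], pos = pv$pos[carries],
                        ref = pv$ref[carries], alt = pv$alt[carries],
                        gt = gt[carries],
                        ps = "1",  # chromosome-spanning phase set
                        filter = "PASS", stringsAsFactors = FALSE)
  callset <- callset[order(callset$chrom, callset$pos), , drop = FALSE]
  rownames(callset) <- NULL

  if (is.null(genome)) {
    genome <- stats::aggregate(pos ~ chrom, data = pv, FUN = max)
    names(genome) <- c("chrom", "length")
    genome$length <- genome$length + 200000
  }
  conf_gr <- regions_to_granges(
    data.frame(chrom = genome$chrom, start = 0, end = genome$length))
  if (any(excluded)) {
    excl_gr <- GenomicRanges::GRanges(
      pv$chrom[excluded],
      IRanges::IRanges(pv$pos[excluded], pv$pos[excluded]))
    conf_gr <- GenomicRanges::setdiff(conf_gr, excl_gr)
  }
  confident <- granges_to_regions(GenomicRanges::sort(conf_gr))

  sites <- data.frame(chrom = pv$chrom, pos = pv$pos, genotype = genotype,
                      excluded = excluded, stringsAsFactors = FALSE)
  if ("variant_id" %in% names(pv)) sites$variant_id <- pv$variant_id
  list(callset = callset, confident = confident, sites = sites)
}

#' Corrupt a truth callset into a query callset with known error rates
#'
#' Truth-ALT sites are dropped with `fn_rate`; spurious heterozygous ALT
#' calls are added at truth-REF panel sites with `fp_rate`; genotypes flip
#' het<->hom with `gt_error_rate`. Phase sets are fragmented by starting a
#' new block between consecutive heterozygous sites with
#' `block_break_rate`, and the haplotype labelling flips after each site
#' with `switch_error_rate` (Markov switch-error model). Phase-set ids
#' follow the convention of naming the block after its first position.
#'
#' @param truth truth callset data.frame (ALT records, phased hets).
#' @param panel_variants all panel sites (for FP injection at truth-REF
#'   sites).
#' @param config a [sim_config()].
#' @return list with `callset` (the query) and `events` sidecar (chrom,
#'   pos, event in {kept, fn, fp, gt_error}).
#' @export
corrupt_callset <- function(truth, panel_variants, config = sim_config()) {
  set.seed(sub_seed(config, 3L))
  n <- nrow(truth)
  drop <- stats::runif(n) < config$fn_rate
  ev_truth <- data.frame(chrom = truth$chrom, pos = truth$pos,
                         event = ifelse(drop, "fn", "kept"),
                         stringsAsFactors = FALSE)
  q <- truth[!drop, , drop = FALSE]

  gt_err <- stats::runif(nrow(q)) < config$gt_error_rate
  is_het <- gt_carries_alt(q$gt) & !(gt_unordered(q$gt) == "1/1")
  q$gt[gt_err & is_het] <- "1|1"
  q$gt[gt_err & !is_het] <- "0|1"
  ev_truth$event[match(paste(q$chrom[gt_err], q$pos[gt_err]),
                       paste(ev_truth$chrom, ev_truth$pos))] <- "gt_error"

  truth_key <- paste(truth$chrom, truth$pos)
  ref_sites <- panel_variants[!(paste(panel_variants$chrom,
                                      panel_variants$pos) %in% truth_key), ,
                              drop = FALSE]
  fp <- stats::runif(nrow(ref_sites)) < config$fp_rate
  if (any(fp)) {
    add <- data.frame(chrom = ref_sites$chrom[fp], pos = ref_sites$pos[fp],
                      ref = ref_sites$ref[fp], alt = ref_sites$alt[fp],
                      gt = ifelse(stats::runif(sum(fp)) < 0.5, "0|1", "1|0"),
                      ps = NA_character_, filter = "PASS",
                      stringsAsFactors = FALSE)
    q <- rbind(q[, names(add)], add)
  }
  q <- q[order(q$chrom, q$pos), , drop = FALSE]

  # fragment phase sets and apply Markov switch errors along each chromosome
  for (ch in unique(q$chrom)) {
    idx <- which(q$chrom == ch & gt_carries_alt(q$gt) &
                   gt_unordered(q$gt) != "1/1")
    if (length(idx) == 0) next
    block_start <- q$pos[idx[1]]
    flipped <- FALSE
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (k > 1) {
        if (stats::runif(1) < config$block_break_rate) {
          block_start <- q$pos[i]
          flipped <- FALSE  # orientation is arbitrary per block; reset
        } else if (stats::runif(1) < config$switch_error_rate) {
          flipped <- !flipped
        }
      }
      if (flipped)
        q$gt[i] <- if (q$gt[i] == "0|1") "1|0" else if (q$gt[i] == "1|0") "0|1" else q$gt[i]
      q$ps[i] <- as.character(block_start)
    }
  }
  rownames(q) <- NULL

  events <- rbind(ev_truth,
                  if (any(fp)) data.frame(chrom = ref_sites$chrom[fp],
                                          pos = ref_sites$pos[fp],
                                          event = "fp",
                                          stringsAsFactors = FALSE))
  events <- events[order(events$chrom, events$pos), , drop = FALSE]
  rownames(events) <- NULL
  list(callset = q, events = events)
}

#' Simulate an on-target depth track
#'
#' Piecewise-constant negative-binomial depths over the panel regions, in
#' chunks of `depth_chunk` bases.
#'
#' @param panel a `pgx_panel` or region data.frame (chrom, start, end).
#' @param config a [sim_config()].
#' @return depth track data.frame (chrom, start, end, depth).
#' @export
simulate_depth <- function(panel, config = sim_config()) {
  set.seed(sub_seed(config, 4L))
  regions <- if (inherits(panel, "pgx_panel")) panel$regions else panel
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    starts <- seq(regions$start[i], regions$end[i] - 1, by = config$depth_chunk)
    ends <- pmin(starts + config$depth_chunk, regions$end[i])
    data.frame(chrom = regions$chrom[i], start = starts, end = ends,
               depth = stats::rnbinom(length(starts),
                                      size = config$depth_dispersion,
                                      mu = config$depth_mean),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a sequencing read-summary table
#'
#' Log-normal read lengths, normal quality scores (truncated at 0) and
#' adaptive-sampling decisions (accepted with `accept_fraction`, the rest
#' mostly rejected with a small no-decision remainder).
#'
#' @param config a [sim_config()].
#' @return data.frame with read_id, length, quality, decision.
#' @export
simulate_read_summary <- function(config = sim_config()) {
  set.seed(sub_seed(config, 5L))
  n <- config$n_reads
  decision <- ifelse(stats::runif(n) < config$accept_fraction, "accepted",
                     ifelse(stats::runif(n) < 0.95, "rejected", "no_decision"))
  len <- pmax(100L, round(stats::rlnorm(n, config$read_length_meanlog,
                                        config$read_length_sdlog)))
  # rejected strands are ejected early and stay short
  len[decision != "accepted"] <-
    pmax(100L, round(stats::runif(sum(decision != "accepted"), 400, 1200)))
  data.frame(read_id = sprintf("read-%05d", seq_len(n)), length = len,
             quality = pmax(0.1, stats::rnorm(n, config$quality_mean,
                                              config$quality_sd)),
             decision = decision, stringsAsFactors = FALSE)
}
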