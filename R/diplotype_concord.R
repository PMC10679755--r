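# Star-allele diplotype concordance.
#
# Pharmacogene haplotypes are named with star (*) designations; a diplotype
# is the unordered pair of star alleles on the two chromosomes (e.g.
# "*1/*2"). Automated calls are compared against consensus reference calls
# from reference-material studies, with three outcomes: concordant
# (identical under the matching rules below), discordant, or no reference
# when no consensus call exists. A discordant call may additionally be
# flagged as augmenting the reference (e.g. the reference assays did not
# test the allele found); that judgement reflects assay coverage and is
# supplied as a curation list rather than computed from the strings.
#
# Matching rules:
#   * a bare core allele matches any of its single-letter suballeles
#     ("*1" ~ "*1A"), but two fully specified suballeles differ
#     ("*1F" !~ "*1M"); a trailing digit is never a suballele letter
#     ("*1" !~ "*12");
#   * multi-copy sides ("*1+*1") and compound alleles ("*5A_7A_1B") match
#     only as equal multisets of members under the same rule;
#   * the two sides of a diplotype are unordered ("*1/*2" ~ "*2/*1").

# characters used as footnote markers in printed tables
FOOTNOTE_CHARS <- "[∆≠‡^]"

clean_cell <- function(text) {
  text <- gsub(FOOTNOTE_CHARS, "", text)
  text <- gsub("\\s*\\(curated:[^)]*\\)", "", text)  # printed curation notes
  trimws(text)
}

#' Parse one side (haplotype) of a diplotype string
#'
#' A side may carry several gene copies joined by '+' and each copy may be
#' a compound allele joined by '_'. Labels are normalized by stripping a
#' leading '*', any suffix after a '.', surrounding whitespace, and case.
#'
#' @param text one haplotype side, e.g. "*1+*1" or "*5A_7A_1B".
#' @return list of copies, each a character vector of normalized member
#'   labels.
#' @export
parse_allele_side <- function(text) {
  text <- gsub("[()]", "", clean_cell(text))
  copies <- strsplit(text, "+", fixed = TRUE)[[1]]
  copies <- lapply(copies, function(cp) {
    members <- strsplit(trimws(cp), "_", fixed = TRUE)[[1]]
    members <- vapply(members, function(m) {
      m <- trimws(m)
      m <- sub("^\\*", "", m)
      m <- sub("\\..*$", "", m)  # tolerate caller-specific suffixes (*4N.ALDY)
      toupper(m)
    }, character(1), USE.NAMES = FALSE)
    members <- members[nzchar(members)]
    members
  })
  copies <- copies[lengths(copies) > 0]
  if (length(copies) == 0)
    stop_no_call("empty allele token in '", text, "'")
  copies
}

#' Parse a diplotype string into its two haplotype sides
#' @param text diplotype, e.g. "*1/*2" or "*1+*1/*12".
#' @return list of class `diplotype` with `side1`, `side2` (see
#'   [parse_allele_side()]) and the raw text.
#' @export
parse_diplotype <- function(text) {
  raw <- text
  text <- gsub("[()]", "", clean_cell(text))
  sides <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop_no_call("diplotype must have exactly two sides: '", raw, "'")
  structure(list(side1 = parse_allele_side(sides[1]),
                 side2 = parse_allele_side(sides[2]), raw = raw),
            class = "diplotype")
}

# single normalized labels: equal, or one is the other plus exactly one
# trailing alphabetic character (bare core vs suballele)
label_match <- function(a, b) {
  if (a == b) return(TRUE)
  wild <- function(core, sub) {
    nchar(sub) == nchar(core) + 1L && startsWith(sub, core) &&
      grepl("^[A-Za-z]$", substr(sub, nchar(sub), nchar(sub)))
  }
  wild(a, b) || wild(b, a)
}

# perfect matching between two small multisets under a pairwise predicate
multiset_match <- function(xs, ys, pred) {
  if (length(xs) != length(ys)) return(FALSE)
  if (length(xs) == 0) return(TRUE)
  for (j in seq_along(ys)) {
    if (pred(xs[[1]], ys[[j]]) &&
        multiset_match(xs[-1], ys[-j], pred)) return(TRUE)
  }
  FALSE
}

copy_match <- function(ca, cb) {
  multiset_match(as.list(ca), as.list(cb), label_match)
}

side_match <- function(sa, sb) multiset_match(sa, sb, copy_match)

#' Do two allele tokens (haplotype sides) match?
#'
#' Exposes the suballele-wildcard matching rule on single sides: bare cores
#' match their lettered suballeles, fully specified suballeles must be
#' equal, and '+'/'_' structures match as equal multisets of members.
#'
#' @param a,b haplotype side strings (e.g. "*1A", "*1+*1").
#' @return logical.
#' @export
alleles_match <- function(a, b) {
  side_match(parse_allele_side(a), parse_allele_side(b))
}

#' Do two diplotypes match (unordered sides)?
#' @param d1,d2 `diplotype` objects or strings.
#' @return logical.
#' @export
diplotypes_match <- function(d1, d2) {
  if (is.character(d1)) d1 <- parse_diplotype(d1)
  if (is.character(d2)) d2 <- parse_diplotype(d2)
  (side_match(d1$side1, d2$side1) && side_match(d1$side2, d2$side2)) ||
    (side_match(d1$side1, d2$side2) && side_match(d1$side2, d2$side1))
}

# Gene-specific aliases mapping assay shorthand to a diplotype. "NEG" in
# the G6PD reference denotes absence of the A+/A- allele, i.e. wild type,
# which the caller reports as *B/*B.
default_reference_aliases <- function() {
  list(G6PD = c(NEG = "*B/*B"))
}

#' Parse a reference star-allele call cell
#'
#' Handles the conventions of printed reference tables: a bare dash means
#' no reference; a dash followed by a parenthetical diplotype is an
#' assigned reference (taken from a secondary source); any cell containing
#' "no consensus" is treated as absent even when a candidate is printed;
#' ";"-separated entries are ambiguous alternatives; gene-specific
#' shorthand (e.g. G6PD "NEG") is resolved through an alias table;
#' parentheses inside a diplotype are stripped.
#'
#' @param text reference cell text.
#' @param gene gene symbol (for alias lookup).
#' @param aliases gene alias table, see `default_reference_aliases()`.
#' @return list of class `reference_call` with `kind` (one of "unique",
#'   "assigned", "alternatives", "none") and `diplotypes` (list of
#'   `diplotype`, empty for kind "none").
#' @export
parse_reference_call <- function(text, gene = NA_character_,
                                 aliases = default_reference_aliases()) {
  if (is.na(text) || !nzchar(trimws(text)))
    stop_no_call("empty reference cell")
  txt <- clean_cell(text)
  txt <- gsub("–", "-", txt)  # en dash
  ref <- function(kind, dips = list())
    structure(list(kind = kind, diplotypes = dips, raw = text),
              class = "reference_call")
  if (txt == "-") return(ref("none"))
  if (grepl("no consensus", txt, ignore.case = TRUE)) return(ref("none"))
  m <- regmatches(txt, regexec("^-\\s*\\((.+)\\)$", txt))[[1]]
  if (length(m) == 2)
    return(ref("assigned", list(parse_diplotype(m[2]))))
  if (!is.na(gene) && gene %in% names(aliases) && txt %in% names(aliases[[gene]]))
    return(ref("unique", list(parse_diplotype(aliases[[gene]][[txt]]))))
  if (grepl(";", txt, fixed = TRUE)) {
    parts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1]])
    return(ref("alternatives", lapply(parts, parse_diplotype)))
  }
  ref("unique", list(parse_diplotype(txt)))
}

#' Classify one diplotype call against its reference
#'
#' A call is concordant when the reference is unique or assigned and the
#' two diplotypes match as unordered pairs of matching sides; ambiguous
#' (alternatives) references never yield concordance; absent references
#' yield class no_reference. Calls on the curation list are flagged as
#' augmenting the reference (only meaningful for discordant calls).
#'
#' @param call diplotype string (the automated call).
#' @param reference reference cell text or a parsed `reference_call`.
#' @param gene gene symbol.
#' @param sample,platform identifiers used to look up the curation list.
#' @param curation data.frame with columns gene, sample, platform listing
#'   discordant calls curated as augmenting; see [default_curation()].
#' @return list of class `concordance_record`: gene, sample, platform,
#'   call, reference kind, class ("concordant", "discordant",
#'   "no_reference") and curated_augmenting.
#' @export
classify_call <- function(call, reference, gene = NA_character_,
                          sample = NA_character_, platform = NA_character_,
                          curation = default_curation()) {
  if (is.na(call) || !nzchar(trimws(call))) stop_no_call("missing call")
  d_call <- parse_diplotype(call)
  ref <- if (inherits(reference, "reference_call")) reference
         else parse_reference_call(reference, gene)
  cls <- if (ref$kind == "none") "no_reference"
  else if (ref$kind %in% c("unique", "assigned") &&
           diplotypes_match(d_call, ref$diplotypes[[1]])) "concordant"
  else "discordant"
  curated <- cls == "discordant" && !is.null(curation) && nrow(curation) > 0 &&
    any(curation$gene == gene &
          (is.na(curation$sample) | curation$sample == sample) &
          (is.na(curation$platform) | curation$platform == platform))
  structure(list(gene = gene, sample = sample, platform = platform,
                 call = call, reference_kind = ref$kind, class = cls,
                 curated_augmenting = curated),
            class = "concordance_record")
}

#' Default curation list of reference-augmenting discordant calls
#'
#' Genes whose discordant automated call was manually shown to improve on
#' the reference because the reference assays did not test the allele
#' found (HG001 on the R9.4.1 flow cell: CYP1A2, DPYD, GSTP1).
#' @return data.frame with gene, sample, platform.
#' @export
default_curation <- function() {
  data.frame(gene = c("CYP1A2", "DPYD", "GSTP1"),
             sample = "HG001", platform = "R9.4.1",
             stringsAsFactors = FALSE)
}

#' Classify a table of diplotype calls
#'
#' @param calls data.frame with columns gene, sample, platform, call,
#'   reference.
#' @param curation curation list, see [default_curation()].
#' @return data.frame of class `pgx_concordance` with one row per input
#'   call plus reference_kind, class and curated_augmenting.
#' @export
classify_diplotype_table <- function(calls, curation = default_curation()) {
  req <- c("gene", "sample", "platform", "call", "reference")
  if (!all(req %in% names(calls)))
    stop_no_call("calls must have columns: ", paste(req, collapse = ", "))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    r <- classify_call(calls$call[i], calls$reference[i], calls$gene[i],
                       calls$sample[i], calls$platform[i], curation)
    data.frame(gene = r$gene, sample = r$sample, platform = r$platform,
               call = r$call, reference = calls$reference[i],
               reference_kind = r$reference_kind, class = r$class,
               curated_augmenting = r$curated_augmenting,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pgx_concordance", "data.frame")
  out
}

#' Summarise concordance classes per sample-platform column
#' @param records output of [classify_diplotype_table()].
#' @return data.frame with sample, platform, n, concordant, discordant,
#'   no_reference, curated_augmenting.
#' @export
summarize_concordance <- function(records) {
  key <- interaction(records$sample, records$platform, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- records[key == k, , drop = FALSE]
    data.frame(sample = d$sample[1], platform = d$platform[1], n = nrow(d),
               concordant = sum(d$class == "concordant"),
               discordant = sum(d$class == "discordant"),
               no_reference = sum(d$class == "no_reference"),
               curated_augmenting = sum(d$curated_augmenting),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pgx_concordance <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pgx_concordance <- function(object, ...) {
  summarize_concordance(object)
}

#' Bundled transcription of the VIP-gene diplotype comparison table
#'
#' Long-format table of GeT-RM reference calls and automated star-allele
#' calls for the 24 VIP genes across the HG001, HG01190 and NA19785
#' reference samples and flow-cell chemistries. Footnote markers from the
#' printed table are dropped; curation notes are kept verbatim in the call
#' strings and stripped by the parser.
#'
#' @return data.frame with gene, sample, platform, reference, call.
#' @export
example_diplotype_table <- function() {
  path <- system.file("extdata", "table5_diplotypes.tsv",
                      package = "pgxbench", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
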