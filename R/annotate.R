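#' Read a gene annotation track
#'
#' Imports a BED or GFF3 gene track via rtracklayer and returns a tibble in
#' the package's 1-based inclusive convention (rtracklayer performs the BED
#' 0-based half-open conversion).  For GFF3, rows of type `gene` are used
#' when present, otherwise all rows; the gene identifier is taken from
#' `gene_id`, `ID` or `Name`, whichever exists first, and `symbol` from
#' `Name` when available.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `symbol`.
#' @export
read_gene_track <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors_mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
    mc <- S4Vectors_mcols(gr)
  }
  pick <- function(cols) {
    for (cl in cols) if (cl %in% names(mc)) return(as.character(mc[[cl]]))
    rep(NA_character_, length(gr))
  }
  gene_id <- pick(c("gene_id", "ID", "name", "Name"))
  symbol <- pick(c("Name", "name", "gene_name"))
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 gene_id = gene_id, symbol = symbol)
}

# avoids importing S4Vectors explicitly for one accessor
S4Vectors_mcols <- function(gr) {
  as.data.frame(GenomicRanges::mcols(gr), stringsAsFactors = FALSE)
}

#' Genes overlapping ROH / shared intervals
#'
#' Reports every gene whose bp range intersects an interval by at least one
#' base, in both conventions 1-based inclusive.  Chromosome labels present
#' in only one of the two inputs are reported with a warning rather than
#' silently dropped.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   e.g. from [shared_private_rohs()] or [consensus_rohs()].
#' @param gene_track Tibble from [read_gene_track()] (or with the same
#'   columns).
#' @return A tibble with one row per (interval, overlapping gene) pair:
#'   `interval_id`, `chrom`, `start`, `end`, `gene_id`, `symbol`,
#'   `gene_start`, `gene_end`.  Intervals without genes appear once with
#'   `NA` gene columns.
#' @export
genes_in_intervals <- function(intervals, gene_track) {
  intervals <- tibble::as_tibble(intervals)
  gene_track <- tibble::as_tibble(gene_track)
  gene_track$gene_id <- as.character(gene_track$gene_id)
  if (!"symbol" %in% names(gene_track)) gene_track$symbol <- NA_character_
  gene_track$symbol <- as.character(gene_track$symbol)
  if (nrow(intervals) == 0) {
    return(tibble::tibble(interval_id = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          gene_id = character(), symbol = character(),
                          gene_start = integer(), gene_end = integer()))
  }
  only_iv <- setdiff(unique(intervals$chrom), unique(gene_track$chrom))
  only_gn <- setdiff(unique(gene_track$chrom), unique(intervals$chrom))
  if (length(only_iv) > 0) {
    warning("chromosome(s) in intervals but not in gene track: ",
            paste(only_iv, collapse = ", "))
  }
  if (length(only_gn) > 0) {
    warning("chromosome(s) in gene track but not in intervals: ",
            paste(only_gn, collapse = ", "))
  }
  gr_iv <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
  gr_gn <- GenomicRanges::GRanges(
    gene_track$chrom, IRanges::IRanges(gene_track$start, gene_track$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_iv, gr_gn))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  base <- tibble::tibble(interval_id = seq_len(nrow(intervals)),
                         chrom = intervals$chrom,
                         start = intervals$start, end = intervals$end)
  found <- dplyr::bind_cols(
    base[qh, ],
    tibble::tibble(gene_id = gene_track$gene_id[sh],
                   symbol = gene_track$symbol[sh],
                   gene_start = gene_track$start[sh],
                   gene_end = gene_track$end[sh]))
  missing_iv <- setdiff(base$interval_id, unique(qh))
  if (length(missing_iv) > 0) {
    found <- dplyr::bind_rows(
      found,
      dplyr::mutate(base[missing_iv, ], gene_id = NA_character_,
                    symbol = NA_character_, gene_start = NA_integer_,
                    gene_end = NA_integer_))
  }
  dplyr::arrange(found, .data$interval_id, .data$gene_start)
}

#' Group-contrast functional variants inside ROH regions
#'
#' Retains variants inside the supplied intervals whose predicted impact is
#' in `impact_filter` and whose genotype pattern contrasts two sample
#' groups: every `group_a` member homozygous for the alternate allele while
#' every `group_b` member is heterozygous or homozygous reference.  Impact
#' labels and deleteriousness scores are consumed from the panel's site
#' annotations (externally produced); a variant with a score below
#' `score_cutoff` is marked deleterious.
#'
#' @param panel A [genotype_panel()] whose sites carry `impact` (and
#'   optionally `score`) annotations.
#' @param intervals Interval tibble (`chrom`, `start`, `end`); the search
#'   space, typically private or shared ROH regions.
#' @param group_a,group_b Character vectors of sample names (disjoint).
#' @param impact_filter Impact classes retained; `NULL` or empty retains all.
#' @param missing `"strict"` (default): any missing genotype in either group
#'   disqualifies the variant; `"lenient"`: missing calls are ignored, but
#'   each group must retain at least one called member.
#' @param score_cutoff Deleteriousness threshold (score strictly below is
#'   deleterious).
#' @return Tibble of retained variants: `chrom`, `pos`, `ref`, `alt`,
#'   `impact`, `score`, `deleterious`, `pattern`.  The number of in-interval
#'   variants lacking an impact label under a non-empty filter is attached
#'   as attribute `n_unassessable` and messaged.
#' @export
group_contrast_variants <- function(panel, intervals, group_a, group_b,
                                    impact_filter = c("HIGH", "MODERATE"),
                                    missing = c("strict", "lenient"),
                                    score_cutoff = 0.05) {
  missing <- match.arg(missing)
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  ja <- match(group_a, sample_names(panel))
  jb <- match(group_b, sample_names(panel))
  if (anyNA(c(ja, jb))) stop("unknown sample(s) in groups")

  inside <- rep(FALSE, nrow(panel$sites))
  for (k in seq_len(nrow(intervals))) {
    inside <- inside | (panel$sites$chrom == intervals$chrom[k] &
                          panel$sites$pos >= intervals$start[k] &
                          panel$sites$pos <= intervals$end[k])
  }
  idx <- which(inside)
  n_unassessable <- 0L
  if (!is.null(impact_filter) && length(impact_filter) > 0) {
    imp <- panel$sites$impact[idx]
    n_unassessable <- sum(is.na(imp))
    if (n_unassessable > 0) {
      message(n_unassessable,
              " in-interval variant(s) without impact label are unassessable")
    }
    idx <- idx[!is.na(imp) & imp %in% impact_filter]
  }

  keep <- logical(length(idx))
  for (i in seq_along(idx)) {
    ga <- panel$geno[idx[i], ja]
    gb <- panel$geno[idx[i], jb]
    if (missing == "strict") {
      if (anyNA(ga) || anyNA(gb)) next
    } else {
      ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
      if (length(ga) == 0 || length(gb) == 0) next
    }
    keep[i] <- all(ga == 2L) && all(gb %in% c(0L, 1L))
  }
  idx <- idx[keep]
  out <- tibble::tibble(
    chrom = panel$sites$chrom[idx], pos = panel$sites$pos[idx],
    ref = panel$sites$ref[idx], alt = panel$sites$alt[idx],
    impact = panel$sites$impact[idx], score = panel$sites$score[idx],
    deleterious = !is.na(panel$sites$score[idx]) &
      panel$sites$score[idx] < score_cutoff,
    pattern = "group_hom_alt_vs_other_not")
  attr(out, "n_unassessable") <- n_unassessable
  out
}
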