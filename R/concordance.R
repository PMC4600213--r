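#' Cross-classify array vs sequence genotypes for one sample
#'
#' Counts the array/sequence genotype cross-classification at positions
#' assayed on both platforms and derives the error rates used to judge
#' sequencing genotype quality against an array truth set:
#' false negatives are array-heterozygous calls that are homozygous in
#' sequence (heterozygote undercalling), false positives are
#' array-homozygous calls that are heterozygous in sequence.  All rates use
#' the number of positions called on both platforms (`n_validated`) as the
#' denominator, the convention under which the published BeadChip
#' comparisons reproduce (e.g. 12,867/49,813 = 25.83 %) even though the
#' prose definition might suggest platform-specific denominators.
#'
#' @param array_panel Array [genotype_panel()] (e.g. [read_array_table()]).
#' @param seq_panel Sequence [genotype_panel()] on the same coordinates.
#' @param sample Sample name present in both panels.
#' @return A one-row tibble: `sample`, `het_seq` (genome-wide sequence
#'   heterozygote count), `het_array`, `hom_array` (array-called counts at
#'   shared positions), `n_validated`, `het_both`, `fn_count`, `fp_count`,
#'   `fn_rate`, `fp_rate`, `het_both_rate`.  With zero validated positions
#'   the rates are `NA` with a warning.
#' @export
cross_classify <- function(array_panel, seq_panel, sample) {
  ja <- match(sample, sample_names(array_panel))
  js <- match(sample, sample_names(seq_panel))
  if (is.na(ja) || is.na(js)) stop("sample not present in both panels: ", sample)

  key_a <- paste(array_panel$sites$chrom, array_panel$sites$pos)
  key_s <- paste(seq_panel$sites$chrom, seq_panel$sites$pos)
  m <- match(key_a, key_s)
  shared <- !is.na(m)
  a <- array_panel$geno[shared, ja]
  q <- seq_panel$geno[m[shared], js]

  het_seq <- sum(seq_panel$geno[, js] == 1L, na.rm = TRUE)
  called_a <- !is.na(a)
  het_array <- sum(called_a & a == 1L)
  hom_array <- sum(called_a & a != 1L)
  validated <- called_a & !is.na(q)
  n_validated <- sum(validated)
  het_both <- sum(validated & a == 1L & q == 1L)
  fn_count <- sum(validated & a == 1L & q != 1L)
  fp_count <- sum(validated & a != 1L & q == 1L)

  if (n_validated == 0) {
    warning("no positions validated on both platforms for ", sample,
            ": rates undefined")
  }
  rate <- function(x) if (n_validated > 0) x / n_validated else NA_real_
  tibble::tibble(sample = sample, het_seq = het_seq,
                 het_array = het_array, hom_array = hom_array,
                 n_validated = n_validated, het_both = het_both,
                 fn_count = fn_count, fp_count = fp_count,
                 fn_rate = rate(fn_count), fp_rate = rate(fp_count),
                 het_both_rate = rate(het_both))
}

#' Long ROH regions in array data
#'
#' Runs the sliding-window ROH scanner on array genotypes with array-scale
#' settings (20-SNP windows, no heterozygotes and at most two missing calls
#' per window, 1-Mb minimum length, 50 kb-per-SNP density) and optionally
#' keeps only regions exceeding a long-region threshold -- 10 Mb for the
#' robust false-positive rate, where the array run is assumed to hold
#' error-free homozygous genotypes.
#'
#' @param array_panel Array [genotype_panel()].
#' @param sample Sample to scan.
#' @param window_snps,max_het,max_missing,min_length_bp,density_kb_per_snp
#'   Scanner settings at array scale.
#' @param max_gap_bp Maximum within-segment gap between consecutive SNPs.
#' @param long_region_bp Optional secondary threshold; regions must strictly
#'   exceed it (use `1e7` for the robust rate).  `NULL` keeps all regions.
#' @return Segment tibble as from [scan_sample()].
#' @export
array_roh_regions <- function(array_panel, sample, window_snps = 20,
                              max_het = 0, max_missing = 2,
                              min_length_bp = 1e6,
                              density_kb_per_snp = 50,
                              max_gap_bp = 1e6,
                              long_region_bp = NULL) {
  st <- scan_settings(window_snps = window_snps,
                      max_het_per_window = max_het,
                      max_missing_per_window = max_missing,
                      min_length_bp = min_length_bp,
                      min_snps_per_segment = window_snps,
                      max_gap_bp = max_gap_bp,
                      max_density_kb_per_snp = density_kb_per_snp)
  segs <- scan_sample(array_panel, sample, st)
  if (!is.null(long_region_bp)) {
    segs <- segs[segs$length_bp > long_region_bp, , drop = FALSE]
  }
  segs
}

#' Robust false-positive rate inside long array ROH regions
#'
#' Within long array-defined ROH regions the true genotype is assumed
#' homozygous throughout, so any heterozygous sequence call there is counted
#' as a sequencing error.  The rate is heterozygous sequence calls inside
#' the regions divided by all non-missing sequence calls inside them.
#'
#' @param seq_panel Sequence [genotype_panel()].
#' @param sample Sample name.
#' @param long_regions Interval tibble (`chrom`, `start`, `end`), e.g. from
#'   [array_roh_regions()] with `long_region_bp = 1e7`.
#' @return One-row tibble: `sample`, `n_called`, `n_het`, `robust_fp_rate`.
#'   Empty regions give an `NA` rate with a warning.
#' @export
robust_fp <- function(seq_panel, sample, long_regions) {
  js <- match(sample, sample_names(seq_panel))
  if (is.na(js)) stop("unknown sample: ", sample)
  if (is.null(long_regions) || nrow(long_regions) == 0) {
    warning("no long regions supplied: robust rate undefined")
    return(tibble::tibble(sample = sample, n_called = 0L, n_het = 0L,
                          robust_fp_rate = NA_real_))
  }
  inside <- rep(FALSE, nrow(seq_panel$sites))
  for (k in seq_len(nrow(long_regions))) {
    inside <- inside | (seq_panel$sites$chrom == long_regions$chrom[k] &
                          seq_panel$sites$pos >= long_regions$start[k] &
                          seq_panel$sites$pos <= long_regions$end[k])
  }
  g <- seq_panel$geno[inside, js]
  n_called <- sum(!is.na(g))
  n_het <- sum(g == 1L, na.rm = TRUE)
  if (n_called == 0) warning("no called sequence positions inside regions")
  tibble::tibble(sample = sample, n_called = n_called, n_het = n_het,
                 robust_fp_rate = if (n_called > 0) n_het / n_called else NA_real_)
}
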