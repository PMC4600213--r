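#' Settings for the sliding-window ROH scanner
#'
#' The scanner reproduces the PLINK 1.07 `--homozyg` window-hit formulation.
#' Windows of `window_snps` consecutive sites slide one SNP at a time; a
#' window passes when it contains at most `max_het_per_window` heterozygous
#' and `max_missing_per_window` missing calls for the scanned sample.  A SNP
#' is ROH-eligible when at least `hit_proportion` of the windows covering it
#' pass.  Maximal runs of eligible SNPs, trimmed so both ends are homozygous
#' non-missing calls, become segments and are kept when they satisfy the
#' length, SNP-count, gap and density constraints.
#'
#' Two canonical scales are used for whole-genome sequence panels:
#' 50-SNP windows with a 40-kb minimum length, and 500-SNP windows with a
#' 400-kb minimum.
#'
#' @param window_snps Number of SNPs per sliding window (50 or 500 for the
#'   canonical scales).
#' @param max_het_per_window Maximum heterozygous calls allowed per window.
#' @param max_missing_per_window Maximum missing calls allowed per window.
#' @param min_length_bp Minimum segment length; segments must exceed this
#'   value (strictly, by default -- see `strict_min_length`).
#' @param min_snps_per_segment Minimum SNPs in a final segment; defaults to
#'   `window_snps`.
#' @param hit_proportion Fraction of covering windows that must pass for a
#'   SNP to be eligible (PLINK default 0.05).
#' @param max_gap_bp Maximum distance between consecutive SNPs of a segment
#'   (PLINK default 1000 kb).
#' @param max_density_kb_per_snp Maximum average SNP spacing within a
#'   segment, in kb per SNP (PLINK `--homozyg-density`; default 50).  Dense
#'   sequence panels can tighten this to sub-kb values to reject segments
#'   supported by sparse SNP cover.
#' @param strict_min_length When `TRUE` (default) a segment must be strictly
#'   longer than `min_length_bp` ("> 40 kb"); when `FALSE`, `>=` is used.
#' @return A `scan_settings` list.
#' @export
scan_settings <- function(window_snps = 50,
                          max_het_per_window = 3,
                          max_missing_per_window = 3,
                          min_length_bp = 40000,
                          min_snps_per_segment = window_snps,
                          hit_proportion = 0.05,
                          max_gap_bp = 1e6,
                          max_density_kb_per_snp = 50,
                          strict_min_length = TRUE) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0, min_length_bp >= 0,
            min_snps_per_segment >= 1,
            hit_proportion > 0, hit_proportion <= 1,
            max_gap_bp > 0, max_density_kb_per_snp > 0)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 min_length_bp = min_length_bp,
                 min_snps_per_segment = as.integer(min_snps_per_segment),
                 hit_proportion = hit_proportion,
                 max_gap_bp = max_gap_bp,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 strict_min_length = isTRUE(strict_min_length)),
            class = "scan_settings")
}

# scan one chromosome of one sample; g coded 0/1/2/NA, pos sorted increasing
scan_chromosome <- function(g, pos, st) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          n_snps = integer(), n_het = integer(),
                          n_missing = integer())
  n <- length(g)
  w <- st$window_snps
  if (n < w) return(empty)

  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nw <- n - w + 1L
  starts <- seq_len(nw)
  wh <- ch[starts + w] - ch[starts]
  wm <- cm[starts + w] - cm[starts]
  pass <- wh <= st$max_het_per_window & wm <= st$max_missing_per_window

  cp <- c(0L, cumsum(pass))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  hits <- cp[hi + 1L] - cp[lo]
  eligible <- hits / (hi - lo + 1L) >= st$hit_proportion

  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  hom <- !is.na(g) & g != 1L

  segs <- list()
  for (k in which(r$values)) {
    a <- begs[k]; b <- ends[k]
    # trim to homozygous non-missing endpoints
    hom_in <- which(hom[a:b])
    if (length(hom_in) == 0) next
    a2 <- a + hom_in[1] - 1L
    b2 <- a + hom_in[length(hom_in)] - 1L
    n_snps <- b2 - a2 + 1L
    len <- pos[b2] - pos[a2] + 1L
    if (n_snps < st$min_snps_per_segment) next
    ok_len <- if (st$strict_min_length) len > st$min_length_bp else
      len >= st$min_length_bp
    if (!ok_len) next
    if (n_snps > 1L && max(diff(pos[a2:b2])) > st$max_gap_bp) next
    if ((len / 1000) / n_snps > st$max_density_kb_per_snp) next
    segs[[length(segs) + 1L]] <- tibble::tibble(
      start = pos[a2], end = pos[b2], n_snps = n_snps,
      n_het = sum(het[a2:b2]), n_missing = sum(mis[a2:b2]))
  }
  if (length(segs) == 0) return(empty)
  dplyr::bind_rows(segs)
}

#' Detect runs of homozygosity for one sample
#'
#' @param panel A filtered [genotype_panel()].
#' @param sample Sample name present in the panel.
#' @param settings A [scan_settings()].
#' @return A tibble of segments with columns `sample`, `chrom`, `start`,
#'   `end` (1-based inclusive bp at the first/last SNP of the run),
#'   `n_snps`, `n_het`, `n_missing`, `length_bp`.  Segments of one sample on
#'   one chromosome are non-overlapping and sorted.
#' @export
scan_sample <- function(panel, sample, settings = scan_settings()) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- match(sample, sample_names(panel))
  if (is.na(j)) stop("unknown sample: ", sample)
  chroms <- unique(panel$sites$chrom)
  out <- purrr::map(chroms, function(ch) {
    idx <- panel$sites$chrom == ch
    segs <- scan_chromosome(panel$geno[idx, j], panel$sites$pos[idx], settings)
    if (nrow(segs) == 0) return(NULL)
    dplyr::mutate(segs, sample = sample, chrom = ch, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_snps = integer(), n_het = integer(),
                          n_missing = integer(), length_bp = numeric()))
  }
  dplyr::mutate(out, length_bp = as.numeric(.data$end - .data$start + 1))
}

#' Detect runs of homozygosity for all samples
#'
#' Applies [scan_sample()] to every sample of the panel and summarises the
#' per-sample segment counts and total lengths, including the mean count
#' across samples.
#'
#' @inheritParams scan_sample
#' @return A `roh_scan` object: a list with `segments` (tibble), `summary`
#'   (tibble with per-sample `n_roh`, `total_bp`, `f_roh`), `settings`, and
#'   `genome_covered_length`.  Use [generics::tidy()] for the segments,
#'   [generics::glance()] for one-row panel-level results, and
#'   [ggplot2::autoplot()] for a size-class figure.
#' @export
scan_all <- function(panel, settings = scan_settings()) {
  segs <- dplyr::bind_rows(
    purrr::map(sample_names(panel), ~scan_sample(panel, .x, settings)))
  glen <- covered_length(panel)
  summary <- dplyr::left_join(
    tibble::tibble(sample = sample_names(panel)),
    dplyr::summarise(dplyr::group_by(segs, .data$sample),
                     n_roh = dplyr::n(),
                     total_bp = sum(.data$length_bp), .groups = "drop"),
    by = "sample")
  summary$n_roh[is.na(summary$n_roh)] <- 0L
  summary$total_bp[is.na(summary$total_bp)] <- 0
  summary$f_roh <- summary$total_bp / glen
  structure(list(segments = segs, summary = summary, settings = settings,
                 genome_covered_length = glen),
            class = "roh_scan")
}

#' @export
print.roh_scan <- function(x, ...) {
  cat(sprintf("<roh_scan> window_snps=%d, min_length=%g bp: %d segments in %d sample(s); mean %.1f ROH/sample\n",
              x$settings$window_snps, x$settings$min_length_bp,
              nrow(x$segments), nrow(x$summary), mean(x$summary$n_roh)))
  print(x$summary)
  invisible(x)
}

#' Classify ROH segments by size
#'
#' Adds a `size_class` column: `small` for segments up to `small_max_bp`,
#' `large` for segments of at least `large_min_bp`, `medium` in between.
#' With the canonical 50-SNP scan, small is 40-59 kb and large is >= 400 kb.
#'
#' @param segments Segment tibble (from [scan_sample()] / [scan_all()]), with
#'   a `length_bp` column.
#' @param small_max_bp Upper bound (inclusive) of the small class.
#' @param large_min_bp Lower bound (inclusive) of the large class.
#' @return The segment tibble with a `size_class` factor column
#'   (`small` < `medium` < `large`).  Classes partition the segments; counts
#'   are one `dplyr::count(sample, size_class)` away.
#' @export
classify_sizes <- function(segments, small_max_bp = 59000,
                           large_min_bp = 400000) {
  stopifnot(small_max_bp < large_min_bp)
  cls <- ifelse(segments$length_bp <= small_max_bp, "small",
                ifelse(segments$length_bp >= large_min_bp, "large", "medium"))
  segments$size_class <- factor(cls, levels = c("small", "medium", "large"))
  segments
}

#' Export segments as a PLINK-style .hom table or BED
#'
#' `write_hom()` writes a TSV with `sample`, `chrom`, `start`, `end`,
#' `n_snps`, `length_kb` (1-based inclusive coordinates).  `segments_to_bed()`
#' converts to BED's 0-based half-open convention.
#'
#' @param segments Segment tibble.
#' @param path Output path.
#' @return Invisibly, `path` (or the BED tibble for `segments_to_bed()` when
#'   `path` is `NULL`).
#' @export
write_hom <- function(segments, path) {
  out <- dplyr::transmute(segments, .data$sample, .data$chrom, .data$start,
                          .data$end, .data$n_snps,
                          length_kb = .data$length_bp / 1000)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hom
#' @param name_col Column used for the BED name field.
#' @export
segments_to_bed <- function(segments, path = NULL, name_col = "sample") {
  bed <- tibble::tibble(chrom = segments$chrom,
                        start = segments$start - 1L,
                        end = segments$end,
                        name = segments[[name_col]])
  if (is.null(path)) return(bed)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
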