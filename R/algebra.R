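#' Homozygous-variant position sets inside ROH segments
#'
#' The private/shared/consensus region algebra operates on the positions of
#' homozygous variants that fall inside each sample's ROH segments, not on
#' the segment intervals themselves.  This function extracts those position
#' sets (per sample, per chromosome) together with the panel's full site
#' list, which defines adjacency when surviving positions are regrouped into
#' intervals.
#'
#' Matching downstream is by position only, not by homozygous allele class;
#' pass `allele_aware = TRUE` to carry the allele class so that set
#' operations require the same homozygous genotype.
#'
#' @param panel The filtered [genotype_panel()] the scan was run on.
#' @param segments Segment tibble from [scan_all()] (or a `roh_scan` object).
#' @param allele_aware Carry the homozygous class (0/2) for allele-aware
#'   matching.
#' @return An `roh_positions` object.
#' @export
roh_position_sets <- function(panel, segments, allele_aware = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (inherits(segments, "roh_scan")) segments <- segments$segments
  samples <- sample_names(panel)
  res <- list()
  for (s in unique(segments$sample)) {
    j <- match(s, samples)
    if (is.na(j)) stop("segment sample not in panel: ", s)
    segs <- segments[segments$sample == s, ]
    g <- panel$geno[, j]
    hom <- !is.na(g) & g != 1L
    inside <- rep(FALSE, nrow(panel$sites))
    for (ch in unique(segs$chrom)) {
      on_ch <- panel$sites$chrom == ch
      p <- panel$sites$pos
      sc <- segs[segs$chrom == ch, ]
      for (k in seq_len(nrow(sc))) {
        inside <- inside | (on_ch & p >= sc$start[k] & p <= sc$end[k])
      }
    }
    take <- inside & hom
    res[[s]] <- tibble::tibble(sample = s,
                               chrom = panel$sites$chrom[take],
                               pos = panel$sites$pos[take],
                               allele = if (allele_aware) g[take] else NA_integer_)
  }
  structure(list(positions = dplyr::bind_rows(res),
                 panel_positions = panel$sites[c("chrom", "pos")],
                 samples = samples,
                 allele_aware = allele_aware),
            class = "roh_positions")
}

#' @export
print.roh_positions <- function(x, ...) {
  cat(sprintf("<roh_positions> %d samples, %d ROH positions over %d panel sites\n",
              length(unique(x$positions$sample)), nrow(x$positions),
              nrow(x$panel_positions)))
  invisible(x)
}

# group surviving positions into maximal runs of panel-consecutive SNPs:
# a run breaks whenever an intervening panel SNP is not in the surviving set
group_positions <- function(surviving, panel_pos) {
  if (length(surviving) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_snps = integer()))
  }
  idx <- match(sort(surviving), sort(panel_pos))
  brk <- c(TRUE, diff(idx) > 1L)
  run <- cumsum(brk)
  pos <- sort(surviving)
  tibble::tibble(
    start = as.integer(tapply(pos, run, min)),
    end = as.integer(tapply(pos, run, max)),
    n_snps = as.integer(tapply(pos, run, length)))
}

pos_key <- function(df, allele_aware) {
  if (allele_aware) paste(df$pos, df$allele) else as.character(df$pos)
}

#' Private ROH regions of one sample
#'
#' Positions inside the target sample's ROHs that are found in no other
#' sample's ROHs, regrouped into maximal runs of panel-consecutive SNPs.
#' Whole private ROHs or private parts of ROHs are reported.
#'
#' @param position_sets An [roh_position_sets()] object built from one scan
#'   run (one window scale).
#' @param target_sample Sample whose private regions are wanted.
#' @return Tibble with `sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `length_bp`.
#' @export
private_rohs <- function(position_sets, target_sample) {
  ps <- position_sets
  stopifnot(inherits(ps, "roh_positions"))
  if (!target_sample %in% ps$samples) stop("unknown sample: ", target_sample)
  others <- setdiff(unique(ps$positions$sample), target_sample)
  out <- purrr::map(split_chrom(ps), function(d) {
    tgt <- d$sets[[target_sample]]
    if (is.null(tgt) || nrow(tgt) == 0) return(NULL)
    other_keys <- unlist(lapply(others, function(s) {
      x <- d$sets[[s]]; if (is.null(x)) character() else pos_key(x, ps$allele_aware)
    }))
    surv <- tgt$pos[!pos_key(tgt, ps$allele_aware) %in% other_keys]
    iv <- group_positions(surv, d$panel_pos)
    if (nrow(iv) == 0) return(NULL)
    dplyr::mutate(iv, sample = target_sample, chrom = d$chrom, .before = 1)
  })
  finish_intervals(dplyr::bind_rows(out))
}

#' Shared private ROH regions of a sample group
#'
#' Positions present in every in-group member's ROH position set and absent
#' from every out-group member's, regrouped into intervals.  With
#' `out_group = character(0)` this reports plain shared regions; with all
#' samples in the in-group it coincides with [consensus_rohs()].
#'
#' @inheritParams private_rohs
#' @param in_group,out_group Character vectors of sample names; must be
#'   disjoint, `in_group` non-empty.
#' @return Tibble with `chrom`, `start`, `end`, `n_snps`, `length_bp`,
#'   `member_samples`, `excluded_samples`.
#' @export
shared_private_rohs <- function(position_sets, in_group,
                                out_group = character()) {
  ps <- position_sets
  stopifnot(inherits(ps, "roh_positions"))
  if (length(in_group) == 0) stop("in_group must be non-empty")
  if (length(intersect(in_group, out_group)) > 0) {
    stop("in_group and out_group overlap: ",
         paste(intersect(in_group, out_group), collapse = ", "))
  }
  unknown <- setdiff(c(in_group, out_group), ps$samples)
  if (length(unknown) > 0) stop("unknown sample(s): ",
                                paste(unknown, collapse = ", "))
  out <- purrr::map(split_chrom(ps), function(d) {
    keys <- lapply(in_group, function(s) {
      x <- d$sets[[s]]
      if (is.null(x)) character() else pos_key(x, ps$allele_aware)
    })
    shared <- Reduce(intersect, keys)
    if (length(shared) == 0) return(NULL)
    out_keys <- unlist(lapply(out_group, function(s) {
      x <- d$sets[[s]]; if (is.null(x)) character() else pos_key(x, ps$allele_aware)
    }))
    shared <- setdiff(shared, out_keys)
    if (length(shared) == 0) return(NULL)
    surv <- as.integer(vapply(strsplit(shared, " "), `[[`, "", 1))
    iv <- group_positions(surv, d$panel_pos)
    dplyr::mutate(iv, chrom = d$chrom, .before = 1)
  })
  out <- finish_intervals(dplyr::bind_rows(out))
  out$member_samples <- paste(in_group, collapse = ",")
  out$excluded_samples <- paste(out_group, collapse = ",")
  out
}

#' Consensus ROH regions across all samples
#'
#' Intersection of the homozygous-variant position sets inside ROHs of every
#' sample, regrouped into intervals.  A sample with an empty ROH set empties
#' the consensus.
#'
#' @inheritParams private_rohs
#' @return As [shared_private_rohs()].
#' @export
consensus_rohs <- function(position_sets) {
  stopifnot(inherits(position_sets, "roh_positions"))
  if (length(position_sets$samples) < 2) stop("need at least 2 samples")
  shared_private_rohs(position_sets, position_sets$samples, character())
}

# per-chromosome view: sets = list of per-sample tibbles, panel_pos = vector
split_chrom <- function(ps) {
  chroms <- unique(ps$panel_positions$chrom)
  lapply(stats::setNames(chroms, chroms), function(ch) {
    sets <- split(ps$positions[ps$positions$chrom == ch, ],
                  ps$positions$sample[ps$positions$chrom == ch])
    # ensure every sample key resolves (possibly to NULL)
    list(chrom = ch, sets = sets,
         panel_pos = ps$panel_positions$pos[ps$panel_positions$chrom == ch])
  })
}

finish_intervals <- function(iv) {
  if (nrow(iv) == 0) {
    iv <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer(), n_snps = integer())
  }
  iv$length_bp <- as.numeric(iv$end) - as.numeric(iv$start) + 1
  dplyr::arrange(iv, .data$chrom, .data$start)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH is the summed length of a sample's ROH segments divided by the
#' length of the genome covered by the SNP set (for the motivating horse
#' dataset, 2,242,879,462 bp).
#'
#' @param x A `roh_scan` object or a segment tibble with `sample` and
#'   `length_bp` columns.
#' @param genome_covered_length Denominator in bp; defaults to the value
#'   stored in a `roh_scan` object.
#' @param samples Optional character vector of samples to report (samples
#'   without segments get F_ROH 0).
#' @return Tibble with `sample`, `total_roh_bp`, `f_roh` (in `[0, 1]`).
#' @export
f_roh <- function(x, genome_covered_length = NULL, samples = NULL) {
  if (inherits(x, "roh_scan")) {
    if (is.null(genome_covered_length)) {
      genome_covered_length <- x$genome_covered_length
    }
    if (is.null(samples)) samples <- x$summary$sample
    x <- x$segments
  }
  if (is.null(genome_covered_length) || genome_covered_length <= 0) {
    stop("`genome_covered_length` must be a positive number of bp")
  }
  if (is.null(samples)) samples <- unique(x$sample)
  tot <- dplyr::summarise(dplyr::group_by(x, .data$sample),
                          total_roh_bp = sum(.data$length_bp),
                          .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(sample = samples), tot, by = "sample")
  out$total_roh_bp[is.na(out$total_roh_bp)] <- 0
  out$f_roh <- out$total_roh_bp / genome_covered_length
  if (any(out$f_roh > 1 + 1e-9)) warning("F_ROH above 1: check genome length")
  out
}
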