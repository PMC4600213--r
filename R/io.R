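#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCF 4.2 with vcfR, keeps biallelic SNP records only (indels and
#' multi-allelic records are excluded), collapses phased and unphased
#' genotypes to the same class, and returns a position-sorted
#' [genotype_panel()].  Optional `IMPACT` and `SIFT` INFO keys are carried
#' into the site table for downstream functional-variant filtering; they are
#' consumed as externally produced annotations, never computed here.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_config Optional mapping of VCF samples to groups: a data
#'   frame with columns `sample`, `group` and optionally `subgroup`, or a
#'   named character vector `c(sampleA = "breed", ...)`.  When given, every
#'   VCF sample must be present in the mapping; unknown samples are an error.
#' @param genome_covered_length Optional genome length (bp) used as the F_ROH
#'   denominator; see [covered_length()].  The horse dataset that motivated
#'   this package used 2,242,879,462 bp.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, sample_config = NULL,
                     genome_covered_length = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0) stop("VCF contains no genotype records")
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT FORMAT field")

  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  if (n_excluded > 0) {
    message(n_excluded, " non-SNP or multi-allelic record(s) excluded")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  } else NULL
  if (!is.null(dp) && is.null(dim(dp))) dp <- t(dp)
  impact <- tryCatch(vcfR::extract.info(vcf, "IMPACT"),
                     error = function(e) NULL)
  score <- tryCatch(suppressWarnings(
    vcfR::extract.info(vcf, "SIFT", as.numeric = TRUE)),
    error = function(e) NULL)

  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L

  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = ref, alt = alt,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    impact = if (is.null(impact)) NA_character_ else as.character(impact),
    score = if (is.null(score)) NA_real_ else as.numeric(score))

  keep <- which(snp)
  sites <- sites[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]

  # duplicated positions: keep the first record, report the rest
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  dup <- duplicated(sites[c("chrom", "pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate position(s) dropped (first record kept), e.g. ",
            sites$chrom[dup][1], ":", sites$pos[dup][1])
    sites <- sites[!dup, , drop = FALSE]
    geno <- geno[!dup, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[!dup, , drop = FALSE]
  }

  vcf_samples <- colnames(gt)
  samples <- resolve_sample_config(vcf_samples, sample_config)

  genotype_panel(sites, geno, samples,
                 depth = if (!is.null(dp)) round(dp),
                 genome_covered_length = genome_covered_length)
}

resolve_sample_config <- function(vcf_samples, sample_config) {
  if (is.null(sample_config)) {
    return(tibble::tibble(sample = vcf_samples))
  }
  if (is.character(sample_config) && !is.null(names(sample_config))) {
    sample_config <- tibble::tibble(sample = names(sample_config),
                                    group = unname(sample_config))
  }
  sample_config <- tibble::as_tibble(sample_config)
  stopifnot(all(c("sample", "group") %in% names(sample_config)))
  unknown <- setdiff(vcf_samples, sample_config$sample)
  if (length(unknown) > 0) {
    stop("VCF sample(s) not present in sample_config: ",
         paste(unknown, collapse = ", "))
  }
  extra <- setdiff(sample_config$sample, vcf_samples)
  if (length(extra) > 0) {
    warning("sample_config entries absent from the VCF ignored: ",
            paste(extra, collapse = ", "))
  }
  out <- sample_config[match(vcf_samples, sample_config$sample), , drop = FALSE]
  out
}

#' Read an array genotype table
#'
#' Reads a long-format TSV with columns `sample`, `chrom`, `pos`, `call`,
#' where `call` is one of `AA`, `AB`, `BB`, `NC` (no call).  `AA`/`BB` map to
#' the two homozygous classes, `AB` to heterozygous and `NC` to missing.
#' Without allele orientation the two homozygous codes are interchangeable;
#' concordance functions treat them as "homozygous" by default.
#'
#' @param path Path to the TSV.
#' @return An array-platform [genotype_panel()].
#' @export
read_array_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("sample", "chrom", "pos", "call")
  if (!all(need %in% names(raw))) {
    stop("array table must have columns: ", paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) | !raw$call %in% c("AA", "AB", "BB", "NC"))
  if (length(bad) > 0) {
    stop("malformed array-table row(s) at line(s): ",
         paste(utils::head(bad + 1L, 20), collapse = ", "))
  }
  code <- c(AA = 0L, AB = 1L, BB = 2L)
  df <- tibble::tibble(sample = raw$sample, chrom = raw$chrom, pos = pos,
                       g = unname(code[raw$call]))
  wide <- tidyr::pivot_wider(df, names_from = "sample", values_from = "g")
  wide <- dplyr::arrange(wide, .data$chrom, .data$pos)
  samples <- sort(unique(df$sample))
  geno <- as.matrix(wide[, samples, drop = FALSE])
  genotype_panel(wide[c("chrom", "pos")], geno, samples, platform = "array")
}

#' Filter a panel for ROH analysis
#'
#' Applies the site- and call-level filters used upstream of ROH detection:
#' a site is dropped when its mean read depth across samples is below
#' `min_mean_depth` or its quality is below `min_qual`; an individual call
#' with depth outside `[min_depth, max_depth]` is set to missing; all sites
#' on the chromosomes in `drop_chroms` (the X by default) are removed.
#' Depth bounds are call-level and mean-depth/quality are site-level, which
#' keeps the retained site set identical across samples.
#'
#' Filtering is idempotent: applying it twice gives the same panel.
#'
#' @param panel A sequence [genotype_panel()] with depths.
#' @param min_depth,max_depth Per-call depth bounds (calls outside become
#'   missing).
#' @param min_mean_depth Minimum site mean depth across samples.
#' @param min_qual Minimum site quality; sites with missing quality are kept.
#' @param drop_chroms Chromosome labels to remove entirely.
#' @return The filtered [genotype_panel()], with a `filter_log` attribute
#'   (tibble of counts).  Errors if nothing survives.
#' @export
filter_for_roh <- function(panel, min_depth = 3, max_depth = 60,
                           min_mean_depth = 12, min_qual = 20,
                           drop_chroms = c("X", "chrX")) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$depth)) stop("panel has no per-call depths")
  n_input <- nrow(panel$sites)

  on_x <- panel$sites$chrom %in% drop_chroms
  mean_dp <- rowMeans(panel$depth, na.rm = TRUE)
  low_mean <- mean_dp < min_mean_depth
  low_qual <- !is.na(panel$sites$qual) & panel$sites$qual < min_qual
  keep <- !on_x & !low_mean & !low_qual
  if (!any(keep)) stop("all sites removed by filtering: empty panel")

  out <- subset_sites(panel, keep)
  mask <- !is.na(out$depth) & (out$depth < min_depth | out$depth > max_depth)
  n_masked <- sum(mask & !is.na(out$geno))
  out$geno[mask] <- NA_integer_

  log <- tibble::tibble(
    n_input = n_input,
    n_dropped_chrom = sum(on_x),
    n_dropped_mean_depth = sum(low_mean & !on_x),
    n_dropped_qual = sum(low_qual & !on_x & !low_mean),
    n_retained = nrow(out$sites),
    n_calls_set_missing = n_masked)
  attr(out, "filter_log") <- log
  out
}
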