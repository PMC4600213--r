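#' Genotype panel container
#'
#' A `genotype_panel` holds an ordered set of biallelic sites for a fixed set
#' of samples, together with the per-call genotype class and (for sequence
#' panels) per-call read depth.  Genotypes are coded as an integer matrix with
#' one row per site and one column per sample: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternate, `NA` = missing.  Array
#' panels use the same coding; when the array platform does not report allele
#' orientation the `0`/`2` distinction is nominal and downstream comparisons
#' treat both as "homozygous" unless allele-aware matching is requested.
#'
#' Sites are kept sorted by `(chrom, pos)` with strictly increasing positions
#' within each chromosome; the sample order of the `samples` tibble is the
#' single source of truth for every downstream operation.
#'
#' @param sites Data frame with at least `chrom` (character) and `pos`
#'   (1-based integer bp); optionally `ref`, `alt`, `qual`, `impact`
#'   (one of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"` or `NA`) and
#'   `score` (deleteriousness score in `[0, 1]`).
#' @param geno Integer matrix, `nrow(sites)` x `nrow(samples)`, coded
#'   0/1/2/`NA` as described above.
#' @param samples Data frame with column `sample` and optionally `group`
#'   (e.g. `"breed"` / `"non_breed"`) and `subgroup` (e.g. a breed name), or a
#'   character vector of sample names.
#' @param depth Optional integer matrix of per-call read depths, same
#'   dimensions as `geno`.
#' @param genome_covered_length Length in bp of the genome covered by the SNP
#'   set, used as the denominator of F_ROH.  When `NULL` it is computed on
#'   demand as the sum over chromosomes of (last SNP position - first SNP
#'   position + 1).
#' @param platform `"sequence"` or `"array"`.
#'
#' @return An object of class `genotype_panel`.
#' @seealso [read_vcf()], [simulate_panel()], [filter_for_roh()]
#' @export
genotype_panel <- function(sites, geno, samples, depth = NULL,
                           genome_covered_length = NULL,
                           platform = c("sequence", "array")) {
  platform <- match.arg(platform)
  if (is.character(samples)) samples <- tibble::tibble(sample = samples)
  samples <- tibble::as_tibble(samples)
  stopifnot("sample" %in% names(samples))
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  if (!"subgroup" %in% names(samples)) samples$subgroup <- NA_character_
  if (anyDuplicated(samples$sample)) {
    stop("duplicate sample names in `samples`")
  }

  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  for (col in c("ref", "alt")) if (!col %in% names(sites)) sites[[col]] <- NA_character_
  if (!"qual" %in% names(sites)) sites$qual <- NA_real_
  if (!"impact" %in% names(sites)) sites$impact <- NA_character_
  if (!"score" %in% names(sites)) sites$score <- NA_real_
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")

  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples)) {
    stop("`geno` must be n_sites x n_samples")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  colnames(geno) <- samples$sample
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(geno))) stop("`depth` must match `geno` dimensions")
    colnames(depth) <- samples$sample
  }
  if (!is.null(genome_covered_length)) {
    genome_covered_length <- as.numeric(genome_covered_length)
    if (genome_covered_length <= 0) stop("`genome_covered_length` must be > 0")
  }

  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
  }
  dup <- duplicated(sites[c("chrom", "pos")])
  if (any(dup)) stop("duplicate positions within a chromosome")

  structure(
    list(sites = sites, geno = geno, depth = depth, samples = samples,
         genome_covered_length = genome_covered_length, platform = platform),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %s platform: %d sites, %d samples, %d chromosome(s)\n",
              x$platform, nrow(x$sites), nrow(x$samples),
              length(unique(x$sites$chrom))))
  cat("samples:", paste(utils::head(x$samples$sample, 10), collapse = ", "))
  if (nrow(x$samples) > 10) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$sites), nrow(x$samples))

sample_names <- function(panel) panel$samples$sample

#' Genome length covered by the panel's SNPs
#'
#' Returns the configured `genome_covered_length` or, when unset, the sum over
#' chromosomes of (last SNP position - first SNP position + 1).
#'
#' @param panel A [genotype_panel()].
#' @return A length-one numeric (bp).
#' @export
covered_length <- function(panel) {
  if (!is.null(panel$genome_covered_length)) return(panel$genome_covered_length)
  spans <- tapply(panel$sites$pos, panel$sites$chrom,
                  function(p) max(p) - min(p) + 1)
  sum(as.numeric(spans))
}

# subset a panel to a logical/integer site index, keeping all samples
subset_sites <- function(panel, idx) {
  genotype_panel(panel$sites[idx, , drop = FALSE],
                 panel$geno[idx, , drop = FALSE],
                 panel$samples,
                 depth = if (!is.null(panel$depth)) panel$depth[idx, , drop = FALSE],
                 genome_covered_length = panel$genome_covered_length,
                 platform = panel$platform)
}

#' Per-sample heterozygosity
#'
#' Proportion of heterozygous calls among non-missing calls for every sample.
#' In the horse panels that motivated this package the per-sample values fall
#' between 0.21 and 0.29.
#'
#' @param panel A [genotype_panel()].
#' @return A tibble with columns `sample`, `n_called`, `n_het`,
#'   `heterozygosity`.  A sample with zero non-missing calls gets an `NA`
#'   heterozygosity and a warning.
#' @export
per_sample_heterozygosity <- function(panel) {
  if (nrow(panel$sites) == 0) stop("empty panel")
  called <- colSums(!is.na(panel$geno))
  nhet <- colSums(panel$geno == 1L, na.rm = TRUE)
  het <- unname(ifelse(called > 0, nhet / called, NA_real_))
  if (any(called == 0)) {
    warning("sample(s) with zero non-missing calls: ",
            paste(sample_names(panel)[called == 0], collapse = ", "))
  }
  tibble::tibble(sample = sample_names(panel),
                 n_called = as.integer(called),
                 n_het = as.integer(nhet),
                 heterozygosity = het)
}
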