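# build a small genotype panel from a genotype matrix/vector (0/1/2/NA)
make_panel <- function(geno, pos = NULL, chrom = "chr1", qual = 100,
                       depth = 30, samples = NULL, platform = "sequence",
                       genome_covered_length = NULL) {
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(geno)))
  chrom <- rep_len(chrom, n)
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = "A", alt = "G",
                          qual = rep_len(qual, n))
  dp <- if (is.null(depth)) NULL else
    matrix(rep_len(depth, n * ncol(geno)), n, ncol(geno))
  genotype_panel(sites, geno, samples, depth = dp,
                 genome_covered_length = genome_covered_length,
                 platform = platform)
}

# roh_positions object from explicit per-sample position lists (one chromosome)
make_position_sets <- function(sets, panel_pos, chrom = "chr1") {
  positions <- dplyr::bind_rows(lapply(names(sets), function(s) {
    tibble::tibble(sample = s, chrom = chrom, pos = as.integer(sets[[s]]),
                   allele = NA_integer_)
  }))
  structure(list(positions = positions,
                 panel_positions = tibble::tibble(chrom = chrom,
                                                  pos = as.integer(sort(panel_pos))),
                 samples = names(sets), allele_aware = FALSE),
            class = "roh_positions")
}
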