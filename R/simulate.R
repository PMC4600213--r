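#' Simulation configuration for synthetic genotype panels
#'
#' Describes a multi-sample panel of biallelic autosomal SNPs with planted
#' autozygous tracts, call-level missingness and an optional simulated
#' genotyping array.  Defaults emulate the whole-genome horse panels that
#' motivated the package: roughly one SNP per 0.2 kb, per-sample background
#' heterozygosity around 0.25, read depth averaging 18x, and array
#' discordance structured like an SNP50 BeadChip comparison (most array
#' heterozygotes undercalled to homozygous in sequence, a ~6e-4 chance of a
#' spurious sequence heterozygote at an array-homozygous site).
#'
#' @param n_samples Number of diploid samples.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param snp_density Mean SNPs per kb (sites are a Poisson process along each
#'   chromosome).
#' @param het_rate_per_sample Probability that a call outside planted tracts is
#'   heterozygous; scalar or one value per sample.
#' @param planted_tracts Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp) and `samples` (list-column of character vectors,
#'   or `"all"`), one row per tract.  `NULL` for none.
#' @param missing_rate Probability that any call is missing (applied after
#'   tract planting, independently per call).
#' @param array_site_fraction Fraction of panel sites retained on the
#'   simulated array.
#' @param array_discord_fn Probability that an array-heterozygous site is
#'   sequenced homozygous (heterozygote undercalling).
#' @param array_discord_fp Probability that an array-homozygous site is
#'   sequenced heterozygous.
#' @param depth_mean Mean per-call read depth (Poisson).
#' @param qual_range Range of per-site quality values (uniform).
#' @param groups Optional character vector of group labels, one per sample
#'   (e.g. `"breed"` / `"non_breed"`).
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   panel exactly.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 10,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       snp_density = 5,
                       het_rate_per_sample = 0.25,
                       planted_tracts = NULL,
                       missing_rate = 0.02,
                       array_site_fraction = 0.1,
                       array_discord_fn = 0.78,
                       array_discord_fp = 6e-4,
                       depth_mean = 18,
                       qual_range = c(30, 90),
                       groups = NULL,
                       seed = 1L) {
  stopifnot(n_samples >= 1, length(chrom_lengths) >= 1, snp_density > 0,
            depth_mean > 0, length(qual_range) == 2)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  het_rate_per_sample <- rep_len(het_rate_per_sample, n_samples)
  rates <- c(het_rate_per_sample, missing_rate, array_site_fraction,
             array_discord_fn, array_discord_fp)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (!is.null(groups)) groups <- rep_len(groups, n_samples)

  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  tracts <- normalize_tracts(planted_tracts, chrom_lengths, sample_ids)

  structure(list(n_samples = n_samples, chrom_lengths = chrom_lengths,
                 snp_density = snp_density,
                 het_rate_per_sample = het_rate_per_sample,
                 planted_tracts = tracts, missing_rate = missing_rate,
                 array_site_fraction = array_site_fraction,
                 array_discord_fn = array_discord_fn,
                 array_discord_fp = array_discord_fp,
                 depth_mean = depth_mean, qual_range = qual_range,
                 groups = groups, sample_ids = sample_ids,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# expand/validate the planted-tract table: one row per (tract, sample)
normalize_tracts <- function(tracts, chrom_lengths, sample_ids) {
  if (is.null(tracts) || nrow(as.data.frame(tracts)) == 0) {
    return(tibble::tibble(tract_id = integer(), sample = character(),
                          chrom = character(), start = integer(),
                          end = integer()))
  }
  tracts <- tibble::as_tibble(tracts)
  stopifnot(all(c("chrom", "start", "end", "samples") %in% names(tracts)))
  if (!is.list(tracts$samples)) tracts$samples <- as.list(tracts$samples)
  rows <- purrr::map(seq_len(nrow(tracts)), function(i) {
    s <- tracts$samples[[i]]
    if (identical(s, "all")) s <- sample_ids
    if (!all(s %in% sample_ids)) {
      stop("unknown sample(s) in planted tract ", i, ": ",
           paste(setdiff(s, sample_ids), collapse = ", "))
    }
    chrom <- as.character(tracts$chrom[i])
    if (!chrom %in% names(chrom_lengths)) {
      stop("planted tract ", i, " on unknown chromosome ", chrom)
    }
    start <- as.integer(tracts$start[i]); end <- as.integer(tracts$end[i])
    if (start > end) stop("planted tract ", i, ": start > end")
    if (start < 1 || end > chrom_lengths[[chrom]]) {
      stop("planted tract ", i, " outside chromosome bounds")
    }
    tibble::tibble(tract_id = i, sample = s, chrom = chrom,
                   start = start, end = end)
  })
  out <- dplyr::bind_rows(rows)
  # overlapping tracts for the same sample on the same chromosome are rejected
  chk <- dplyr::group_by(out, .data$sample, .data$chrom)
  chk <- dplyr::arrange(chk, .data$start, .by_group = TRUE)
  bad <- dplyr::filter(chk, dplyr::lag(.data$end, default = -1L) >= .data$start)
  if (nrow(bad) > 0) {
    stop("overlapping planted tracts for sample ", bad$sample[1],
         " on ", bad$chrom[1], " (tract ", bad$tract_id[1], ")")
  }
  out
}

#' Simulate a genotype panel with planted autozygous tracts
#'
#' Sites are drawn by a Poisson process along each chromosome.  Outside
#' planted tracts each call is heterozygous with the sample's configured rate
#' and otherwise homozygous (reference vs alternate 50/50).  Inside a planted
#' tract every member sample is homozygous, with the homozygous class drawn
#' per site and shared by all members of the tract, mimicking a shared
#' autozygous haplotype.  Missingness is applied last, independently per call.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (planted tracts, per-sample true autozygous fraction, and the
#'   configuration echo).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- config$n_samples
  chroms <- names(config$chrom_lengths)

  site_list <- purrr::map(chroms, function(ch) {
    len <- config$chrom_lengths[[ch]]
    n <- stats::rpois(1, len / 1000 * config$snp_density)
    n <- min(n, len)
    pos <- sort(sample.int(len, n))
    tibble::tibble(chrom = ch, pos = pos)
  })
  sites <- dplyr::bind_rows(site_list)
  n_sites <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  sites$ref <- ref
  sites$alt <- alt
  sites$qual <- round(stats::runif(n_sites, config$qual_range[1],
                                   config$qual_range[2]), 1)

  # background genotypes: het with per-sample rate, else hom ref/alt 50/50
  geno <- matrix(0L, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    is_het <- stats::runif(n_sites) < config$het_rate_per_sample[j]
    hom <- 2L * stats::rbinom(n_sites, 1L, 0.5)
    geno[, j] <- ifelse(is_het, 1L, hom)
  }

  # plant tracts: per-site homozygous class shared by the tract's members
  tracts <- config$planted_tracts
  if (nrow(tracts) > 0) {
    for (tid in unique(tracts$tract_id)) {
      tr <- tracts[tracts$tract_id == tid, ]
      idx <- which(sites$chrom == tr$chrom[1] &
                     sites$pos >= tr$start[1] & sites$pos <= tr$end[1])
      if (length(idx) == 0) next
      cls <- 2L * stats::rbinom(length(idx), 1L, 0.5)
      for (s in tr$sample) {
        geno[idx, match(s, config$sample_ids)] <- cls
      }
    }
  }

  depth <- matrix(stats::rpois(n_sites * n_samp, config$depth_mean),
                  n_sites, n_samp)

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n_sites * n_samp) < config$missing_rate,
                   n_sites, n_samp)
    geno[miss] <- NA_integer_
  }

  samples <- tibble::tibble(
    sample = config$sample_ids,
    group = if (is.null(config$groups)) NA_character_ else config$groups,
    subgroup = NA_character_)

  panel <- genotype_panel(sites, geno, samples, depth = depth,
                          genome_covered_length = sum(config$chrom_lengths))

  genome_len <- sum(config$chrom_lengths)
  frac <- vapply(config$sample_ids, function(s) {
    tr <- tracts[tracts$sample == s, ]
    sum(as.numeric(tr$end) - as.numeric(tr$start) + 1) / genome_len
  }, numeric(1))

  truth <- list(
    tracts = tracts,
    autozygous_fraction = tibble::tibble(sample = config$sample_ids,
                                         true_fraction = unname(frac)),
    chrom_lengths = config$chrom_lengths,
    het_rate_per_sample = config$het_rate_per_sample,
    seed = config$seed)

  list(panel = panel, truth = truth)
}

#' Simulate an array genotyping run with injected sequence discordance
#'
#' Retains a uniform random fraction of panel sites as the simulated array and
#' treats the array calls as the error-free truth at those sites.  Discordance
#' is then injected into the *sequence* panel: at a retained site where the
#' array call is heterozygous the sequence call becomes homozygous with
#' probability `array_discord_fn` (heterozygote undercalling); where the array
#' call is homozygous the sequence call becomes heterozygous with probability
#' `array_discord_fp`.  Every injection is logged.
#'
#' @param panel A sequence [genotype_panel()] (as from [simulate_panel()]).
#' @param config The [sim_config()] used to generate it.
#' @return A list with `array` (an array-platform [genotype_panel()] on the
#'   retained sites), `panel` (the sequence panel with injected discordance),
#'   `injections` (tibble `chrom`, `pos`, `sample`, `type` in `"fn"`/`"fp"`)
#'   and `retained` (tibble of retained sites).
#' @export
simulate_array <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  set.seed((config$seed %% 1000000000L) + 7L)
  n_sites <- nrow(panel$sites)
  n_keep <- round(config$array_site_fraction * n_sites)
  keep <- sort(sample.int(n_sites, n_keep))

  array_geno <- panel$geno[keep, , drop = FALSE]
  seq_geno <- panel$geno
  logs <- list()
  for (j in seq_len(ncol(seq_geno))) {
    g <- array_geno[, j]
    called <- !is.na(g)
    het <- called & g == 1L
    hom <- called & g != 1L
    flip_fn <- het & stats::runif(length(g)) < config$array_discord_fn
    flip_fp <- hom & stats::runif(length(g)) < config$array_discord_fp
    if (any(flip_fn)) {
      seq_geno[keep[flip_fn], j] <- 2L * stats::rbinom(sum(flip_fn), 1L, 0.5)
    }
    if (any(flip_fp)) seq_geno[keep[flip_fp], j] <- 1L
    s <- sample_names(panel)[j]
    logs[[j]] <- dplyr::bind_rows(
      tibble::tibble(chrom = panel$sites$chrom[keep[flip_fn]],
                     pos = panel$sites$pos[keep[flip_fn]],
                     sample = s, type = "fn"),
      tibble::tibble(chrom = panel$sites$chrom[keep[flip_fp]],
                     pos = panel$sites$pos[keep[flip_fp]],
                     sample = s, type = "fp"))
  }
  injections <- dplyr::bind_rows(logs)

  array_panel <- genotype_panel(
    panel$sites[keep, c("chrom", "pos", "ref", "alt")],
    array_geno, panel$samples, platform = "array")
  seq_panel <- genotype_panel(panel$sites, seq_geno, panel$samples,
                              depth = panel$depth,
                              genome_covered_length = panel$genome_covered_length)

  list(array = array_panel, panel = seq_panel, injections = injections,
       retained = panel$sites[keep, c("chrom", "pos")])
}

#' Write a simulated panel to disk as plain-text fixtures
#'
#' Emits a multi-sample VCF 4.2 (GT and DP per sample, QUAL per site), a BED
#' of planted tracts (0-based half-open), a JSON ground-truth record, and --
#' when an array is supplied -- a long-format array genotype TSV with calls in
#' `AA`/`AB`/`BB`/`NC`.  The VCF round-trips losslessly through [read_vcf()].
#'
#' @param panel A sequence [genotype_panel()].
#' @param truth The `truth` element returned by [simulate_panel()].
#' @param out_dir Output directory (created if needed).
#' @param array Optional array [genotype_panel()] from [simulate_array()].
#' @param injections Optional injection log from [simulate_array()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(panel, truth, out_dir, array = NULL,
                          injections = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  files <- c(vcf = file.path(out_dir, "panel.vcf"),
             bed = file.path(out_dir, "tracts.bed"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(panel, files[["vcf"]], chrom_lengths = truth$chrom_lengths)

  tr <- truth$tracts
  bed <- if (nrow(tr) > 0) {
    sprintf("%s\t%d\t%d\t%s", tr$chrom, tr$start - 1L, tr$end, tr$sample)
  } else character()
  writeLines(bed, files[["bed"]])

  truth_json <- list(
    tracts = as.data.frame(truth$tracts),
    autozygous_fraction = as.data.frame(truth$autozygous_fraction),
    chrom_lengths = as.list(truth$chrom_lengths),
    het_rate_per_sample = truth$het_rate_per_sample,
    seed = truth$seed)
  if (!is.null(injections)) {
    truth_json$injection_counts <-
      as.data.frame(dplyr::count(injections, .data$sample, .data$type))
  }
  jsonlite::write_json(truth_json, files[["truth"]], auto_unbox = TRUE,
                       digits = NA)

  if (!is.null(array)) {
    files <- c(files, array = file.path(out_dir, "array.tsv"))
    code <- c(`0` = "AA", `1` = "AB", `2` = "BB")
    long <- tidyr::pivot_longer(
      dplyr::bind_cols(array$sites[c("chrom", "pos")],
                       tibble::as_tibble(array$geno)),
      cols = -c("chrom", "pos"), names_to = "sample", values_to = "g")
    long$call <- ifelse(is.na(long$g), "NC", code[as.character(long$g)])
    utils::write.table(long[c("sample", "chrom", "pos", "call")],
                       files[["array"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}

#' Write a genotype panel as a VCF 4.2 text file
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @param chrom_lengths Optional named vector used for `##contig` headers.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(panel, path, chrom_lengths = NULL) {
  s <- panel$sites
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  chroms <- unique(s$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(s$pos[s$chrom == ch]),
                            numeric(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohscape",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted variant impact class">',
           '##INFO=<ID=SIFT,Number=1,Type=Float,Description="Deleteriousness score">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names(panel)), collapse = "\t"))
  n <- nrow(s)
  info <- rep(".", n)
  has_imp <- !is.na(s$impact)
  has_sc <- !is.na(s$score)
  info[has_imp] <- paste0("IMPACT=", s$impact[has_imp])
  info[has_imp & has_sc] <- paste0(info[has_imp & has_sc], ";SIFT=",
                                   s$score[has_imp & has_sc])
  info[!has_imp & has_sc] <- paste0("SIFT=", s$score[!has_imp & has_sc])

  gt <- matrix(gt_code[as.character(panel$geno)], nrow = n)
  gt[is.na(panel$geno)] <- "./."
  if (!is.null(panel$depth)) {
    fmt <- "GT:DP"
    gt <- matrix(paste0(gt, ":", panel$depth), nrow = n)
  } else fmt <- "GT"
  qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE))
  ref <- ifelse(is.na(s$ref), "N", s$ref)
  alt <- ifelse(is.na(s$alt), "A", s$alt)
  body <- paste(s$chrom, s$pos, ".", ref, alt, qual, "PASS", info, fmt,
                sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
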