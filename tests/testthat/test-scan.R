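# random genotype vector with controllable het/missing content
rand_geno <- function(n, p_het = 0.2, p_miss = 0.05) {
  g <- sample(c(0L, 2L), n, replace = TRUE)
  g[runif(n) < p_het] <- 1L
  g[runif(n) < p_miss] <- NA_integer_
  g
}

expect_same_segments <- function(got, oracle) {
  expect_equal(nrow(got), nrow(oracle))
  if (nrow(got) > 0) {
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    expect_equal(got$n_snps, oracle$n_snps)
  }
}

test_that("an all-homozygous chromosome yields one full-span segment at both scales", {
  n <- 600
  pos <- sort(sample.int(5e5, n))
  while (pos[n] - pos[1] + 1 <= 4e5) pos <- sort(sample.int(5e5, n))
  p <- make_panel(rep(2L, n), pos = pos)
  for (st in list(scan_settings(50, min_length_bp = 40000),
                  scan_settings(500, min_length_bp = 400000))) {
    segs <- scan_sample(p, "S01", st)
    expect_equal(nrow(segs), 1)
    expect_equal(segs$start, pos[1])
    expect_equal(segs$end, pos[n])
    expect_equal(segs$n_snps, n)
  }
})

test_that("the minimum-length rule is strictly greater-than at the bp level", {
  # 100 homozygous SNPs spanning exactly 39,999 bp, then exactly 40,000
  p1 <- make_panel(rep(0L, 100), pos = c(seq(1, 39200, length.out = 99), 39999))
  expect_equal(nrow(scan_sample(p1, "S01", scan_settings(50))), 0)
  p2 <- make_panel(rep(0L, 100), pos = c(seq(1, 39200, length.out = 99), 40000))
  expect_equal(nrow(scan_sample(p2, "S01", scan_settings(50))), 0)
  p3 <- make_panel(rep(0L, 100), pos = c(seq(1, 39200, length.out = 99), 40001))
  expect_equal(nrow(scan_sample(p3, "S01", scan_settings(50))), 1)
  # the >= variant admits the exact boundary
  st_ge <- scan_settings(50, strict_min_length = FALSE)
  expect_equal(nrow(scan_sample(p2, "S01", st_ge)), 1)
})

test_that("a 200-SNP chromosome with planted heterozygotes matches the exhaustive oracle", {
  set.seed(401)
  g <- rep(2L, 200)
  g[c(40, 41, 100, 155, 156)] <- 1L
  pos <- sort(sample.int(60000, 200))
  st <- scan_settings(window_snps = 20, max_het_per_window = 1,
                      max_missing_per_window = 1, min_length_bp = 1000,
                      min_snps_per_segment = 20)
  got <- scan_sample(make_panel(g, pos = pos), "S01", st)
  expect_same_segments(got, oracle_scan_chrom(g, pos, st))
  expect_gt(nrow(got), 0)
})

test_that("random panels match the exhaustive-window oracle", {
  set.seed(402)
  for (rep_i in 1:25) {
    n <- sample(60:400, 1)
    pos <- sort(sample.int(n * 300, n))
    g <- rand_geno(n, p_het = runif(1, 0, 0.3), p_miss = runif(1, 0, 0.1))
    st <- scan_settings(window_snps = sample(c(5, 20, 50), 1),
                        max_het_per_window = sample(0:3, 1),
                        max_missing_per_window = sample(0:3, 1),
                        min_length_bp = sample(c(0, 5000, 20000), 1),
                        min_snps_per_segment = sample(c(1, 10, 25), 1),
                        hit_proportion = sample(c(0.05, 0.5, 1), 1),
                        max_gap_bp = sample(c(500, 1e6), 1),
                        max_density_kb_per_snp = sample(c(0.3, 50), 1))
    got <- scan_sample(make_panel(g, pos = pos), "S01", st)
    expect_same_segments(got, oracle_scan_chrom(g, pos, st))
  }
})

test_that("chromosomes shorter than the window yield no segments, unknown samples error", {
  p <- make_panel(rep(0L, 30))
  expect_equal(nrow(scan_sample(p, "S01", scan_settings(50))), 0)
  expect_error(scan_sample(p, "nope"), "unknown sample")
})

test_that("segment ends are trimmed to homozygous non-missing calls", {
  g <- c(1L, rep(0L, 98), NA_integer_)
  pos <- seq(1, 99001, length.out = 100)
  st <- scan_settings(window_snps = 10, max_het_per_window = 3,
                      max_missing_per_window = 3, min_length_bp = 1000,
                      min_snps_per_segment = 10)
  segs <- scan_sample(make_panel(g, pos = pos), "S01", st)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, pos[2])
  expect_equal(segs$end, pos[99])
  expect_equal(segs$n_het, 0L)
  expect_equal(segs$n_missing, 0L)
})

test_that("thresholds are monotone: longer minima never add segments, laxer het never shrinks coverage", {
  set.seed(403)
  covered <- function(segs, pos) {
    out <- logical(length(pos))
    for (k in seq_len(nrow(segs))) {
      out <- out | (pos >= segs$start[k] & pos <= segs$end[k])
    }
    pos[out]
  }
  for (rep_i in 1:10) {
    n <- 300
    pos <- sort(sample.int(1e5, n))
    g <- rand_geno(n, 0.1, 0.05)
    p <- make_panel(g, pos = pos)
    base <- scan_settings(window_snps = 20, min_length_bp = 2000,
                          min_snps_per_segment = 20)
    longer <- scan_settings(window_snps = 20, min_length_bp = 20000,
                            min_snps_per_segment = 20)
    n_base <- nrow(scan_sample(p, "S01", base))
    expect_lte(nrow(scan_sample(p, "S01", longer)), n_base)
    # allowing more heterozygotes can merge adjacent runs (fewer, longer
    # segments) but the covered position set only ever grows once the
    # length/gap/density filters are made non-restrictive
    open_base <- scan_settings(window_snps = 20, min_length_bp = 0,
                               min_snps_per_segment = 1, max_gap_bp = 1e9,
                               max_density_kb_per_snp = 1e9)
    open_lax <- scan_settings(window_snps = 20, min_length_bp = 0,
                              min_snps_per_segment = 1, max_gap_bp = 1e9,
                              max_density_kb_per_snp = 1e9,
                              max_het_per_window = 5)
    cov0 <- covered(scan_sample(p, "S01", open_base), pos)
    cov1 <- covered(scan_sample(p, "S01", open_lax), pos)
    expect_true(all(cov0 %in% cov1))
  }
})

test_that("scan_all summarises per-sample counts including zero-segment samples", {
  g <- cbind(rep(2L, 200), rep(c(1L, 0L), 100))  # S02 is het every other SNP
  p <- make_panel(g, pos = 1:200 * 300L)
  sc <- scan_all(p, scan_settings(window_snps = 50, min_length_bp = 10000))
  expect_s3_class(sc, "roh_scan")
  expect_equal(sc$summary$n_roh, c(1L, 0L))
  expect_equal(mean(sc$summary$n_roh), 0.5)
  # one sample, no segments -> mean 0
  p2 <- make_panel(rep(c(1L, 0L), 100), pos = 1:200 * 300L)
  sc2 <- scan_all(p2, scan_settings(window_snps = 50, min_length_bp = 10000))
  expect_equal(mean(sc2$summary$n_roh), 0)
})

test_that("size classification partitions segments at the documented bounds", {
  segs <- tibble::tibble(sample = "S01", length_bp = c(45000, 59000, 59001,
                                                       100000, 399999, 400000,
                                                       500000))
  cls <- classify_sizes(segs)
  expect_equal(as.character(cls$size_class),
               c("small", "small", "medium", "medium", "medium", "large",
                 "large"))
  # brute-force re-binning of random lengths
  set.seed(404)
  lens <- sample.int(1e6, 1000) + 39999
  got <- as.character(classify_sizes(tibble::tibble(sample = "x",
                                                    length_bp = lens))$size_class)
  brute <- vapply(lens, function(L) {
    if (L <= 59000) "small" else if (L >= 400000) "large" else "medium"
  }, character(1))
  expect_identical(got, brute)
  expect_equal(length(got), 1000)  # classes partition: every segment classed
})

test_that("planted tracts are recovered with window-bounded boundary error and no false calls", {
  tr <- tibble::tibble(chrom = "chr1",
                       start = c(1000001, 3500001), end = c(1800000, 3600000),
                       samples = list("S01", "S01"))
  cfg <- sim_config(n_samples = 2, chrom_lengths = c(chr1 = 5e6),
                    het_rate_per_sample = 0.25, missing_rate = 0,
                    planted_tracts = tr, seed = 77)
  sim <- simulate_panel(cfg)
  st <- scan_settings(window_snps = 50, max_het_per_window = 0,
                      max_missing_per_window = 0, min_length_bp = 40000)
  segs <- scan_sample(sim$panel, "S01", st)
  expect_equal(nrow(segs), 2)
  # boundary error bounded by the bp span of window_snps SNPs at each end
  span <- 50 / 5 * 1000  # 50 SNPs at 5 SNPs per kb
  for (k in 1:2) {
    expect_lt(abs(segs$start[k] - tr$start[k]), span)
    expect_lt(abs(segs$end[k] - tr$end[k]), span)
  }
  # the non-tract sample gets no segments at zero window allowances
  expect_equal(nrow(scan_sample(sim$panel, "S02", st)), 0)
})

test_that("hom table and BED exports use the documented conventions", {
  segs <- tibble::tibble(sample = "S01", chrom = "chr1", start = 101L,
                         end = 200L, n_snps = 10L, length_bp = 100)
  bed <- segments_to_bed(segs)
  expect_equal(bed$start, 100L)  # 0-based half-open
  expect_equal(bed$end, 200L)
  f <- withr::local_tempfile(fileext = ".hom")
  write_hom(segs, f)
  back <- read.table(f, header = TRUE)
  expect_equal(back$length_kb, 0.1)
})

test_that("tidy, glance and autoplot expose the scan results", {
  p <- make_panel(matrix(rep(2L, 400), ncol = 2), pos = 1:200 * 300L)
  sc <- scan_all(p, scan_settings(window_snps = 50, min_length_bp = 10000))
  expect_identical(generics::tidy(sc), sc$segments)
  gl <- generics::glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mean_n_roh, 1)
  expect_equal(gl$window_snps, 50L)
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})
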