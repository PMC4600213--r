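test_that("degenerate rates produce the expected call structure", {
  cfg <- sim_config(n_samples = 3, chrom_lengths = c(chr1 = 2e5),
                    het_rate_per_sample = 0, missing_rate = 0, seed = 11)
  sim <- simulate_panel(cfg)
  expect_equal(sum(sim$panel$geno == 1L, na.rm = TRUE), 0)
  expect_equal(sum(is.na(sim$panel$geno)), 0)
})

test_that("autozygous-fraction bookkeeping is exact by construction", {
  tr <- tibble::tibble(chrom = "chr1", start = 1000001, end = 1500000,
                       samples = list("S01"))
  cfg <- sim_config(n_samples = 1, chrom_lengths = c(chr1 = 5e6),
                    planted_tracts = tr, seed = 2)
  sim <- simulate_panel(cfg)
  expect_equal(sim$truth$autozygous_fraction$true_fraction, 0.1)
  # sum of tract lengths / genome length, exactly
  tl <- sum(sim$truth$tracts$end - sim$truth$tracts$start + 1)
  expect_identical(tl / 5e6, sim$truth$autozygous_fraction$true_fraction)
})

test_that("emitted heterozygosity is calibrated to the configured rate", {
  cfg <- sim_config(n_samples = 4, chrom_lengths = c(chr1 = 3e6),
                    het_rate_per_sample = 0.28, missing_rate = 0, seed = 7)
  sim <- simulate_panel(cfg)
  n <- nrow(sim$panel$sites)
  expect_gt(n, 10000)
  se <- sqrt(0.28 * 0.72 / n)
  # direct counting over the emitted calls
  for (j in 1:4) {
    p_hat <- mean(sim$panel$geno[, j] == 1L)
    expect_lt(abs(p_hat - 0.28), 3 * se)
  }
})

test_that("planted tracts are homozygous before missingness and shared per site", {
  tr <- tibble::tibble(chrom = "chr1", start = 50001, end = 150000,
                       samples = list(c("S01", "S03")))
  cfg <- sim_config(n_samples = 3, chrom_lengths = c(chr1 = 3e5),
                    missing_rate = 0, planted_tracts = tr, seed = 5)
  sim <- simulate_panel(cfg)
  idx <- sim$panel$sites$pos >= 50001 & sim$panel$sites$pos <= 150000
  expect_true(all(sim$panel$geno[idx, c(1, 3)] != 1L))
  # tract members share the homozygous class at every site
  expect_identical(sim$panel$geno[idx, 1], sim$panel$geno[idx, 3])
})

test_that("overlapping tracts for one sample are rejected with a diagnostic", {
  tr <- tibble::tibble(chrom = c("chr1", "chr1"),
                       start = c(1000, 5000), end = c(6000, 9000),
                       samples = list("S01", c("S01", "S02")))
  expect_error(sim_config(n_samples = 2, chrom_lengths = c(chr1 = 1e4),
                          planted_tracts = tr),
               "overlapping planted tracts")
  # same coordinates on different samples are fine
  tr2 <- tibble::tibble(chrom = c("chr1", "chr1"),
                        start = c(1000, 5000), end = c(6000, 9000),
                        samples = list("S01", "S02"))
  expect_s3_class(sim_config(n_samples = 2, chrom_lengths = c(chr1 = 1e4),
                             planted_tracts = tr2), "sim_config")
})

test_that("config validation rejects out-of-range rates and bad tracts", {
  expect_error(sim_config(het_rate_per_sample = 1.2), "rates")
  expect_error(sim_config(missing_rate = -0.1), "rates")
  tr <- tibble::tibble(chrom = "chr1", start = 100, end = 50,
                       samples = list("S01"))
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e4), planted_tracts = tr),
               "start > end")
  tr2 <- tibble::tibble(chrom = "chr1", start = 100, end = 2e4,
                        samples = list("S01"))
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e4), planted_tracts = tr2),
               "outside chromosome")
})

test_that("the same seed and config reproduce the panel byte-identically", {
  cfg <- sim_config(n_samples = 2, chrom_lengths = c(chr1 = 2e5), seed = 99)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$panel$sites, s2$panel$sites)

  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  write_fixture(s1$panel, s1$truth, d1)
  write_fixture(s2$panel, s2$truth, d2)
  for (f in c("panel.vcf", "tracts.bed", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("simulated array with zero discordance equals the panel at retained sites", {
  cfg <- sim_config(n_samples = 3, chrom_lengths = c(chr1 = 5e5),
                    array_site_fraction = 0.5, array_discord_fn = 0,
                    array_discord_fp = 0, seed = 3)
  sim <- simulate_panel(cfg)
  arr <- simulate_array(sim$panel, cfg)
  expect_equal(nrow(arr$injections), 0)
  m <- match(paste(arr$array$sites$chrom, arr$array$sites$pos),
             paste(sim$panel$sites$chrom, sim$panel$sites$pos))
  expect_identical(arr$array$geno, sim$panel$geno[m, ])
  expect_identical(arr$panel$geno, sim$panel$geno)
})

test_that("injected discordance counts match the log and binomial expectation", {
  cfg <- sim_config(n_samples = 2, chrom_lengths = c(chr1 = 2e6),
                    array_site_fraction = 1, array_discord_fn = 0,
                    array_discord_fp = 0.01, missing_rate = 0, seed = 21)
  sim <- simulate_panel(cfg)
  arr <- simulate_array(sim$panel, cfg)
  for (s in c("S01", "S02")) {
    j <- match(s, sim$panel$samples$sample)
    n_hom <- sum(arr$array$geno[, j] != 1L, na.rm = TRUE)
    injected <- sum(arr$injections$sample == s & arr$injections$type == "fp")
    se <- sqrt(0.01 * 0.99 * n_hom)
    expect_lt(abs(injected - 0.01 * n_hom), 3 * se)
    # the log is the truth: every logged site is discordant in the stated way
    fp_sites <- arr$injections$pos[arr$injections$sample == s]
    i <- match(fp_sites, arr$panel$sites$pos)
    expect_true(all(arr$panel$geno[i, j] == 1L))
    ia <- match(fp_sites, arr$array$sites$pos)
    expect_true(all(arr$array$geno[ia, j] != 1L))
  }
})

test_that("array site retention is exact and reproducible under a seed", {
  cfg <- sim_config(n_samples = 2, chrom_lengths = c(chr1 = 2e6),
                    array_site_fraction = 0.5, seed = 13)
  sim <- simulate_panel(cfg)
  a1 <- simulate_array(sim$panel, cfg)
  a2 <- simulate_array(sim$panel, cfg)
  expect_equal(nrow(a1$retained), round(0.5 * nrow(sim$panel$sites)))
  expect_identical(a1$retained, a2$retained)
  expect_identical(a1$array$geno, a2$array$geno)
})

test_that("fixtures round-trip and the tract BED mirrors the ground truth", {
  tr <- tibble::tibble(chrom = "chr1", start = 20001, end = 80000,
                       samples = list("S02"))
  cfg <- sim_config(n_samples = 2, chrom_lengths = c(chr1 = 2e5),
                    planted_tracts = tr, array_site_fraction = 0.3, seed = 31)
  sim <- simulate_panel(cfg)
  arr <- simulate_array(sim$panel, cfg)
  d <- file.path(tempdir(), "fix_rt")
  files <- write_fixture(arr$panel, sim$truth, d, array = arr$array,
                         injections = arr$injections)

  back <- read_vcf(files[["vcf"]])
  expect_identical(unname(back$geno), unname(arr$panel$geno))
  expect_identical(back$sites$pos, arr$panel$sites$pos)
  expect_identical(unname(back$depth), unname(arr$panel$depth))

  bed <- read.table(files[["bed"]], sep = "\t")
  expect_equal(bed$V2 + 1L, sim$truth$tracts$start) # 0-based half-open BED
  expect_equal(bed$V3, sim$truth$tracts$end)

  arr_back <- read_array_table(files[["array"]])
  expect_identical(unname(arr_back$geno[, sort(colnames(arr$array$geno))]),
                   unname(arr$array$geno[, sort(colnames(arr$array$geno))]))

  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$autozygous_fraction$true_fraction,
               sim$truth$autozygous_fraction$true_fraction)
})

test_that("emitted VCF passes an external format validator", {
  cfg <- sim_config(n_samples = 3, chrom_lengths = c(chr1 = 2e4), seed = 17)
  sim <- simulate_panel(cfg)
  expect_gt(nrow(sim$panel$sites), 50)
  d <- file.path(tempdir(), "fix_val")
  files <- write_fixture(sim$panel, sim$truth, d)
  out <- system2("bcftools", c("view", files[["vcf"]]), stdout = TRUE,
                 stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  n_records <- sum(!startsWith(out, "#"))
  expect_equal(n_records, nrow(sim$panel$sites))
})
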